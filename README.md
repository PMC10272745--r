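# itpk — distributed mechanistic PK of intrathecal drug delivery

Intrathecal (IT) injection delivers CNS therapeutics — antisense
oligonucleotides (ASOs) in particular — directly into the cerebrospinal fluid
of the spinal subarachnoid space, bypassing the blood–brain barrier. How much
drug actually reaches the brain depends strongly on *how* it is infused:
volume, rate, site and schedule. `itpk` is an R package for clinical
pharmacologists and modellers who want those dependencies to come out of
transport physics rather than black-box exponential fits.

## The model

The spinal CSF is a one-dimensional channel along the neuraxis (sacral end
closed at *x* = 0, cervical end at *x* = *L* open to the cranial CSF):

```
∂C₁/∂t = −∇(u C₁) + D ∇²C₁ − k₁C₁ − ṁ₁,₂ − ṁ₁,₅
```

where *D* is an **effective dispersion coefficient** standing in for
pulsation-driven, geometry-induced mixing, and *u(x,t)* is the plug-flow
velocity induced by the infusion itself: each bolus enters through a compact
2 cm point-spread kernel and pushes the CSF column rostrally,
*u* = (1/*A*) ∫₀ˣ *f* d*x*′. A parallel spinal-tissue rod, lumped cranial-CSF,
cranial-tissue, blood and peripheral compartments, first-order clearances
*k₁..k₆*, and reversible exchange fluxes with trapping coefficients
(ṁᵢⱼ = *U*ᵢⱼ(*C*ᵢ − *β*ᵢⱼ*C*ⱼ)) complete a linear system of 2*N* + 4 ODEs
(*N* = 100 finite volumes per distributed compartment in the reference
configuration). Cranial tissue is partitioned into pons, hippocampus,
cerebellum and cortex by volumetric coefficients φᵢ (Σφᵢ = 1). The methods
vignette (`vignettes/intrathecal-dmpk.Rmd`) derives every piece and records
the numerical design choices.

## A worked example

```r
library(itpk)

params   <- reference_parameters()                       # NHP reference set
schedule <- build_schedule(dose_ug = 12000, volume_ml = 1, duration_min = 1,
                           site_cm = 3, flush_volume_ml = 0.25,
                           horizon_min = 10080)          # 12 mg + flush, 7 days
sim <- simulate(params, schedule, t_end = 10080,
                output_times = seq(0, 10080, by = 60))
sim
#> intrathecal PK simulation: 169 time points, 100 axial elements ( 204 state variables )
#>   t in [0, 10080] min; dosed 12000 ug; mass in system at t_end: 14.8218 ug

pk_metrics(sample_region(sim, "spinal_csf", "lumbar"))
#> $cmax 2280.7   $tmax 50.4   $auc 3.62e+05
```

The lumbar CSF peaks near 2.3 mg/mL shortly after the bolus (12 mg entering a
few mL of local CSF), then decays as the drug disperses rostrally, is taken up
by spinal tissue, and leaks to plasma; after a week only ~15 µg of the 12 mg
remain in the body. Brain delivery is slower and much smaller:

```r
tail(brain_trajectories(sim), 1)
#>   time_min  pons hippocampus cerebellum cortex
#>      10080 0.487       0.487      0.378  0.179      # ug/mL at day 7

exposure_fraction(sim, threshold = 0.01, at_time = 10080)
#> [1] 0.41   # 41% of the cord holds >= 0.01 ug/mL tissue drug at day 7
```

A regimen sweep maps cranial delivery over the infusion-volume ×
infusion-duration plane at fixed dose (one simulation per sampled regimen,
reproducible from the seed):

```r
sweep <- regimen_sweep(params, dose_ug = 12000, n_samples = 400, seed = 1)
plot_sweep(sweep, "cranial_cmax")
```

Cranial-tissue exposure rises steeply with infusion volume and only weakly
with shorter durations — the heatmap's gradient points toward the
high-volume, short-duration corner.

Synthetic data and calibration close the loop:

```r
ds  <- generate_synthetic(params, schedule, times = seq(420, 10080, by = 420),
                          observables = "lumbar_csf", noise_cv = 0)
fs  <- fit_spec("dispersion", lower = c(dispersion = 1e-3),
                upper = c(dispersion = 10))
fit(fs, ds, params, schedule, start = c(dispersion = 0.5))
#> least-squares calibration: converged (loss 1.87e-11, 5 iterations)
#>   dispersion   = 0.0999996   (recovery error -0.000394%)
```

A command-line front end wraps the same functions
(`inst/cli/itpk simulate | sweep | calibrate | synth | validate`); every run
writes CSV/JSON artifacts plus a JSON manifest sufficient to reproduce it.

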
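---
title: "A distributed mechanistic PK model of intrathecal drug delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A distributed mechanistic PK model of intrathecal drug delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itpk)
```

## The model

Intrathecal (IT) administration injects a drug solution directly into the
CSF-filled subarachnoid space of the spine, bypassing the blood–brain barrier.
`itpk` simulates the resulting spatiotemporal pharmacokinetics with a
*distributed mechanistic* model: instead of fitting black-box exponentials, the
spinal CSF is resolved as a one-dimensional advection–dispersion–reaction
channel along the neuraxis, so that infusion volume, rate, site and schedule
act through explicit transport physics.

Six compartments are modelled. Spinal CSF (C1) is a cylindrical channel of
uniform cross-section $A$, closed at the sacral end ($x = 0$) and open to the
cranial CSF at the cervical end ($x = L$):

$$\frac{\partial C_1}{\partial t}
  = -\nabla (u\, C_1) + D \nabla^2 C_1 - k_1 C_1
    - \dot m_{1,2} - \dot m_{1,5},$$

where $D$ is an *effective* dispersion coefficient representing
pulsation-driven, geometry-induced mixing (orders of magnitude above molecular
diffusion), $u(x,t)$ is the infusion-induced plug-flow velocity and $k_1$ a
first-order clearance. Spinal tissue (C2) is a parallel rod of cells with no
axial transport of its own; cranial CSF (C3), cranial tissue (C4), blood (C5)
and a peripheral compartment (C6) are well-stirred. Reversible exchanges take
the form $\dot m_{i,j} = U_{i,j}(C_i - \beta_{i,j} C_j)$ with a trapping
("stickiness") coefficient $\beta \in [0,1]$ that biases exchange toward slow
tissue release; the cervical boundary flux has no trapping term,
$\dot m_{1,3} = U_{1,3}(C_1(L,t) - C_3)$, and the cranial-tissue-to-blood flux
uses the asymmetric form $\dot m_{4,5} = U_{4,5}(\beta_{4,5} C_4 - C_5)$, with
the trapping coefficient attenuating the donor side. The last form and the
choice to resolve $\dot m_{2,5}$ with the same pairwise law as the others are
deliberate design decisions of this package; both are isolated behind
`exchange_flux()` so a different closure is a one-line change.

Cranial tissue is split into pons, hippocampus, cerebellum and cortex by a
volumetric partition rule, $C_i = \phi_i V_4 C_4 / V_i$ with
$\sum_i \phi_i = 1$ and $\sum_i V_i = V_4$ — the cortex is defined as the
remainder of the brain after the three named regions are subtracted from the
cranial-tissue volume. Partitioning conserves amount exactly and is linear in
the $\phi_i$, which is what makes `fit_partition()` a direct (non-iterative)
estimator.

### Infusion source and plug flow

An infusion is not a point source: the catheter mixes the infusate within a
small finite zone. Each event distributes its volumetric flow through a
raised-cosine point-spread kernel of half-width 2 cm (configurable) centred on
the injection site — smooth, compactly supported, and integrable in closed
form, which keeps the volume accounting exact:
$V_{inj} = \int_{t_1}^{t_2}\!\!\int_0^L f(t,x)\,dx\,dt$. A kernel clipped at a
domain boundary is renormalized so this identity still holds. Incompressibility
and the closed sacral end then give a unidirectional rostral plug flow
$u(x,t) = \frac{1}{A}\int_0^x f(t,x')\,dx'$, zero whenever no event is active.
Overlapping events superpose linearly. A flush is an ordinary event whose
infusate carries zero drug: it adds convective drive without adding dose. The
flush is assumed to share the drug bolus's point-spread width, since both pass
through the same catheter.

### Discretization and integration

Both distributed compartments are discretized into $N$ uniform finite volumes
($N = 100$ in the reference configuration, giving $2N + 4 = 204$ ODEs).
Advection uses first-order upwinding — the infusion-driven flow is
unidirectional, and a monotone, positivity-preserving scheme is worth more
here than formal order; dispersion uses central second differences with a
reflecting condition at the closed sacral end. `convergence_study()` confirms
the expected asymptotics (observed order ~2 on dispersion-dominated, ~1 on
advection-dominated problems).

The plainly written channel equations couple C1 to C3 only diffusively at the
cervical boundary, but a plug flow through a closed-ended channel must push
the infused volume *somewhere*. During infusion the advective efflux
$A\,u(L,t)\,C_1(L,t)$ is therefore delivered into cranial CSF, which makes the
scheme conservative to round-off: with all clearances zero, total mass equals
total dosed mass for any schedule. A switch (`advective_boundary = FALSE`)
restores the literal diffusive-only coupling for comparison.

Because every flux law is linear in concentration, the semi-discrete system is
$y' = A(t)y + b(t)$ with $A$ and $b$ *piecewise-constant between infusion-event
boundaries*. `simulate()` exploits this: event starts and ends are integration
breakpoints (a 1-minute bolus can never be stepped over), and within each
segment `deSolve::lsoda` integrates with the exact Jacobian at
`rtol = 1e-6`, `atol = 1e-9` by default. The assembled $A$ is a Metzler matrix
(non-negative off-diagonals) with a non-negative source, so the exact solution
is non-negative; numerical undershoots within integrator tolerance are clamped
to zero and anything larger aborts the run. Linearity also means doubling the
dose doubles every concentration — a property the test suite checks, and a
useful sanity anchor when rescaling doses.

## Units and key parameters

Lengths are cm, times min, volumes mL, drug amounts µg, concentrations µg/mL
(`ugml_to_nM()` converts for molar figure axes given a molecular weight).

| parameter | meaning | default | why |
|---|---|---|---|
| `length_cm` | spinal channel length | 20 | cervical end of an adult NHP neuraxis at 20 cm |
| `area_csf_cm2` | CSF channel cross-section | 0.35 | spinal CSF volume of 7 mL over 20 cm |
| `area_tissue_cm2` | cord cross-section | 0.3 | cyno spinal-cord volume ~6 mL |
| `n_elements` | finite volumes per compartment | 100 | resolves a 2 cm kernel with 10 cells; see convergence study |
| `dispersion_cm2_min` | effective CSF dispersion $D$ | 0.1 | NHP-scale geometry-induced mixing (in-vitro human values are 1.5–4.7) |
| `spread_cm` | infusion point-spread half-width | 2 | finite catheter mixing zone |
| `U`, `beta`, `k1..k6` | exchange, trapping, clearance | see `reference_parameters()` | documented stand-ins in physiological NHP ranges |
| `landmarks` | lumbar/thoracic/cervical fractions | 0.15, 0.5, 0.9 | configurable sampling anatomy |

The exchange coefficients fold the per-area mass-transfer coefficient and the
interface area into a single mL/min quantity, because only their product is
identifiable; the distributed pairs (1–2, 1–5, 2–5) are totals over the cord,
shared equally by the $N$ element pairs. Fluxes are computed in amount/min and
divided by the receiving volume in each ODE — the only reading under which the
same flux added in compartments of different volume conserves mass. Apart from
$D$ (and the anatomical dimensions), the shipped exchange, clearance and
partition values are stand-ins chosen once in plausible NHP ranges, intended
to be overridden per drug and subject; none of the package's verification
depends on their particular values.

## What the synthetic-data generator emulates

`generate_synthetic()` simulates a protocol, samples named observables
(`lumbar_csf`, `plasma`, `pons`, ...) at a design's time points, and applies
multiplicative lognormal noise with a chosen CV (mean-one, so noise does not
bias the level). This emulates sparse preclinical PK sampling of CSF, plasma
and tissue compartments with assay noise that is roughly proportional on the
log scale. It does **not** emulate inter-animal variability, assay limits of
quantification beyond a simple floor, digitization error, or model
misspecification — recovery tests on synthetic data therefore demonstrate that
the calibration machinery inverts the model correctly (self-consistency), not
that the model is true of any given animal.

## Calibration choices

PK trajectories span several decades, so `objective()` sums squared residuals
in log10 concentration above a quantification floor (default $10^{-6}$ µg/mL);
records below the floor are excluded and model predictions are clamped at it.
Positive parameters are fitted on the log10 scale under box bounds with
Levenberg–Marquardt (`minpack.lm::nls.lm`), optionally multi-started from
seeded draws. The finite-difference step (`epsfcn = 1e-6`) is chosen so
Jacobian steps dominate integrator-tolerance noise in the residuals.
Simulation failure at a candidate yields a large finite penalty, not an
exception, so the optimizer can retreat. Partition coefficients are estimated
by the linear regression described above followed by Euclidean projection onto
the probability simplex, which leaves exact solutions untouched and guarantees
$\phi_i \ge 0$, $\sum \phi_i = 1$ for noisy ones. Which parameters are free
versus fixed is always explicit in the `fit_spec()`, never implicit.

## Regimen sweeps

`regimen_sweep()` maps cranial and spinal delivery over the infusion-regimen
plane at fixed dose: volume sampled uniformly over 1–5 mL and duration
log-uniformly over 0.1–100 min (the duration axis spans three decades), one
simulation per sample, reproducible from the seed, with per-row error capture
so a failed corner never aborts a sweep. The package's own sweeps reproduce
the qualitative structure reported for this model class: cranial-tissue
exposure rises steeply with infusion volume, is comparatively insensitive to
duration, and the volume effect dominates above ~1.5 mL. Exposure fractions
(`exposure_fraction()`) take an explicit threshold argument — what counts as a
"significant" tissue dose is drug-specific, and the package deliberately ships
no hidden default.

## Problem sizes used in verification

The shipped test suite runs the reference protocol (12 mg in 1 mL over 1 min
at the lumbar site, followed by a 0.25 mL, 1-min flush) on the $N = 100$
reference grid over 7-day horizons; dispersion-recovery calibration uses 24
lumbar-CSF samples; the analytic-oracle comparisons run at $N = 200$ with a
cosine-series reference truncated at 300 modes; convergence studies span
$N \in \{50, 100, 200, 400\}$; and the regimen-sweep checks use a
5 × 5 factorial grid plus a 400-sample random sweep. These sizes were chosen
to exercise every code path at full reference resolution while keeping a
complete verification run in the minutes range on a single core.

## Known limitations

* One spatial dimension: no radial gradients, no microanatomical detail of the
  subarachnoid space; dispersion is an effective, calibrated quantity, not a
  first-principles prediction.
* Steady plug flow only — the oscillatory CSF velocity component is *not*
  simulated; its net mixing effect is what $D$ stands for.
* Rigid CSF spaces: no compliance or deformation of the spinal compartment.
* The brain is well-stirred; sub-region heterogeneity enters only through the
  static partition rule.
* All kinetics are linear (first-order); saturable binding or target-mediated
  disposition would need a different flux closure.

## A worked example

```{r example, eval = FALSE}
params <- reference_parameters()
schedule <- build_schedule(dose_ug = 12000, volume_ml = 1, duration_min = 1,
                           site_cm = 3, flush_volume_ml = 0.25,
                           horizon_min = 10080)
sim <- simulate(params, schedule, t_end = 10080)
lumbar <- sample_region(sim, "spinal_csf", "lumbar")
pk_metrics(lumbar)
brain <- brain_trajectories(sim)
sweep <- regimen_sweep(params, dose_ug = 12000, n_samples = 400, seed = 1)
```
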
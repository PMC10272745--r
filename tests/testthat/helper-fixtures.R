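# Shared fixtures: parameter sets with selected couplings switched off, so
# individual transport mechanisms can be tested against closed-form oracles.

# All exchange, clearance and dispersion off; everything else physiological.
quiet_params <- function(n_elements = 10L, dispersion = 0, ...) {
  model_parameters(
    geometry = spinal_geometry(length_cm = 20, area_csf_cm2 = 0.35,
                               area_tissue_cm2 = 0.3,
                               n_elements = n_elements),
    transport = transport_params(dispersion_cm2_min = dispersion),
    exchange = exchange_params(),
    ...
  )
}

# Single 12 mg / 1 mL / 1 min lumbar dose with the standard 0.25 mL flush.
reference_schedule <- function(horizon_min = 10080, volume_ml = 1) {
  build_schedule(dose_ug = 12000, volume_ml = volume_ml, duration_min = 1,
                 site_cm = 3, flush_volume_ml = 0.25,
                 horizon_min = horizon_min)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), .Machine$double.eps)),
            tol)
}
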
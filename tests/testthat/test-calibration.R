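p_ref <- reference_parameters()
sch_ref <- reference_schedule(horizon_min = 10080)
design_times <- seq(420, 10080, by = 420)

test_that("noise-free synthetic data equal the simulator output exactly", {
  ds <- generate_synthetic(p_ref, sch_ref, design_times,
                           c("lumbar_csf", "plasma", "pons"), noise_cv = 0)
  sim <- simulate(p_ref, sch_ref, 10080,
                  output_times = sort(unique(c(0, design_times))))
  for (obs in c("lumbar_csf", "plasma", "pons")) {
    tr <- extract_observable(sim, obs)
    expect_equal(ds$concentration_ug_ml[ds$observable == obs],
                 tr$concentration_ug_ml[tr$time_min %in% design_times])
  }
})

test_that("synthetic noise is reproducible and carries the requested CV", {
  d1 <- generate_synthetic(p_ref, sch_ref, design_times, "lumbar_csf",
                           noise_cv = 0.2, seed = 42)
  d2 <- generate_synthetic(p_ref, sch_ref, design_times, "lumbar_csf",
                           noise_cv = 0.2, seed = 42)
  expect_equal(d1$concentration_ug_ml, d2$concentration_ug_ml)
  d3 <- generate_synthetic(p_ref, sch_ref, design_times, "lumbar_csf",
                           noise_cv = 0.2, seed = 43)
  expect_false(identical(d1$concentration_ug_ml, d3$concentration_ug_ml))

  # moment check on ~1000 multiplicative draws: sample CV within [0.17, 0.23]
  times_many <- seq(60, 10080, length.out = 500)
  clean <- generate_synthetic(p_ref, sch_ref, times_many,
                              c("lumbar_csf", "plasma"), noise_cv = 0)
  noisy <- generate_synthetic(p_ref, sch_ref, times_many,
                              c("lumbar_csf", "plasma"), noise_cv = 0.2,
                              seed = 7)
  ratio <- noisy$concentration_ug_ml / clean$concentration_ug_ml
  cv <- stats::sd(ratio) / mean(ratio)
  expect_gt(cv, 0.17); expect_lt(cv, 0.23)
})

test_that("the log-space objective is zero at truth and grows away from it", {
  ds <- generate_synthetic(p_ref, sch_ref, design_times, "lumbar_csf",
                           noise_cv = 0)
  fs <- fit_spec("dispersion", lower = c(dispersion = 1e-3),
                 upper = c(dispersion = 10))
  at_truth <- objective(fs, c(dispersion = 0.1), ds, p_ref, sch_ref)
  expect_lt(at_truth, 1e-10)
  expect_gt(objective(fs, c(dispersion = 0.2), ds, p_ref, sch_ref), at_truth)

  # additive across datasets
  ds2 <- generate_synthetic(p_ref, sch_ref, design_times, "plasma",
                            noise_cv = 0)
  l1 <- objective(fs, c(dispersion = 0.2), ds, p_ref, sch_ref)
  l2 <- objective(fs, c(dispersion = 0.2), ds2, p_ref, sch_ref)
  l12 <- objective(fs, c(dispersion = 0.2), list(ds, ds2), p_ref, sch_ref)
  expect_equal(l12, l1 + l2)
})

test_that("dispersion is recovered from noise-free lumbar CSF data", {
  ds <- generate_synthetic(p_ref, sch_ref, design_times, "lumbar_csf",
                           noise_cv = 0)
  fs <- fit_spec("dispersion", lower = c(dispersion = 1e-3),
                 upper = c(dispersion = 10))
  res <- fit(fs, ds, p_ref, sch_ref, start = c(dispersion = 0.5))
  expect_true(res$converged)
  expect_lt(abs(res$par[["dispersion"]] - 0.1) / 0.1, 0.01)
  expect_lt(abs(res$recovery[["dispersion"]]), 0.01)
})

test_that("partition coefficients are recovered exactly from noise-free region data", {
  spec <- brain_partition(
    partition_phi = c(pons = 0.1, hippocampus = 0.2, cerebellum = 0.3,
                      cortex = 0.4),
    volume_c4 = 70)
  p <- p_ref
  p$partition <- spec
  sim <- simulate(p, sch_ref, 10080,
                  output_times = sort(unique(c(0, design_times))))
  ds <- generate_synthetic(p, sch_ref, design_times,
                           spec$region_names, noise_cv = 0)
  c4 <- extract_observable(sim, "cranial_tissue")
  phi <- fit_partition(ds, c4, spec)
  expect_rel_equal(phi, c(pons = 0.1, hippocampus = 0.2, cerebellum = 0.3,
                          cortex = 0.4), 1e-6)

  # symmetric case
  spec_eq <- brain_partition(
    region_volume_ml = c(pons = 17.5, hippocampus = 17.5, cerebellum = 17.5,
                         cortex = 17.5),
    partition_phi = c(pons = 0.25, hippocampus = 0.25, cerebellum = 0.25,
                      cortex = 0.25),
    volume_c4 = 70)
  p2 <- p_ref; p2$partition <- spec_eq
  ds2 <- generate_synthetic(p2, sch_ref, design_times, spec_eq$region_names,
                            noise_cv = 0)
  phi2 <- fit_partition(ds2, c4, spec_eq)
  expect_rel_equal(phi2, rep(0.25, 4), 1e-6)

  # estimates always live on the simplex, even from noisy data
  ds_noisy <- generate_synthetic(p, sch_ref, design_times, spec$region_names,
                                 noise_cv = 0.3, seed = 5)
  phi3 <- fit_partition(ds_noisy, c4, spec)
  expect_equal(sum(phi3), 1, tolerance = 1e-12)
  expect_true(all(phi3 >= 0))
})

test_that("recovery degrades gracefully with noise and stays identifiable", {
  # refit D under 20% noise for several seeds: median |rel err| < 15%
  fs <- fit_spec("dispersion", lower = c(dispersion = 1e-3),
                 upper = c(dispersion = 10))
  errs <- vapply(1:5, function(sd_) {
    ds <- generate_synthetic(p_ref, sch_ref, design_times, "lumbar_csf",
                             noise_cv = 0.2, seed = sd_)
    res <- fit(fs, ds, p_ref, sch_ref, start = c(dispersion = 0.5))
    abs(res$par[["dispersion"]] - 0.1) / 0.1
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
})
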
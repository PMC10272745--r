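# A small fake simulation object lets the extraction operations be tested
# against exactly known profiles without running the solver.
fake_sim <- function(C1, C2, times = seq_len(nrow(C1)) - 1,
                     params = reference_parameters(n_elements = ncol(C1))) {
  structure(list(times = times, C1 = C1, C2 = C2,
                 C3 = numeric(length(times)),
                 C4 = seq_along(times) - 1,
                 C5 = numeric(length(times)), C6 = numeric(length(times)),
                 grid = build_grid(params$geometry), params = params,
                 schedule = NULL), class = "it_simulation")
}

test_that("landmark sampling picks the cell containing the landmark", {
  N <- 100
  lin <- matrix(rep(seq_len(N), each = 3), nrow = 3)   # value = cell index
  sim <- fake_sim(lin, lin)
  # landmark at 0.5 L = 10 cm on a 0.2 cm grid lies in cell 50
  th <- sample_region(sim, "spinal_csf", "thoracic")
  expect_equal(th$concentration_ug_ml, rep(50, 3))
  # uniform profile: every landmark returns the uniform value
  uni <- fake_sim(matrix(3.3, 2, N), matrix(1.1, 2, N))
  for (lm in c("lumbar", "thoracic", "cervical"))
    expect_equal(sample_region(uni, "spinal_tissue", lm)$concentration_ug_ml,
                 rep(1.1, 2))
  # window mean over 3 cells of a linear profile equals the centre cell
  expect_equal(sample_region(sim, "spinal_csf", "thoracic",
                             window_cells = 3)$concentration_ug_ml,
               rep(50, 3))
  expect_error(sample_region(sim, "spinal_csf", 25), "outside")
  expect_error(sample_region(sim, "spinal_csf", "sacral"), "unknown landmark")
})

test_that("brain trajectories apply the partition rule at every time point", {
  sim <- fake_sim(matrix(0, 4, 10), matrix(0, 4, 10),
                  params = reference_parameters(n_elements = 10L))
  bt <- brain_trajectories(sim)
  spec <- sim$params$partition
  for (i in seq_len(4)) {
    expect_equal(unname(unlist(bt[i, spec$region_names])),
                 unname(brain_region_concentrations(sim$C4[i], spec)))
    expect_rel_equal(sum(unlist(bt[i, spec$region_names]) * spec$region_volume_ml) +
                       1e-300,
                     spec$volume_c4 * sim$C4[i] + 1e-300, 1e-9)
  }
})

test_that("exposure fraction counts cells at or above the threshold", {
  N <- 100
  prof <- c(rep(2, 40), rep(0.5, N - 40))   # step profile: 40 cells above 1
  sim <- fake_sim(matrix(0, 1, N), matrix(prof, 1, N), times = 7)
  expect_equal(exposure_fraction(sim, 1, at_time = 7), 0.40)
  expect_equal(exposure_fraction(sim, 0, at_time = 7), 1.0)
  expect_equal(exposure_fraction(sim, 10, at_time = 7), 0.0)
  # non-increasing in the threshold
  ths <- seq(0, 3, by = 0.25)
  fr <- vapply(ths, function(th) exposure_fraction(sim, th, 7), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(exposure_fraction(sim, 1, at_time = 3), "output times")
})

test_that("PK metrics match closed forms", {
  # constant concentration: AUC = c * T
  cst <- data.frame(time_min = seq(0, 100, by = 1),
                    concentration_ug_ml = rep(2, 101))
  m <- pk_metrics(cst)
  expect_equal(m$cmax, 2); expect_equal(m$auc, 200)

  # mono-exponential on a dense grid: AUC ~ c0/k (1 - exp(-kT)) within 0.1%
  t <- seq(0, 100, by = 0.05); k <- 0.05; c0 <- 10
  mexp <- pk_metrics(data.frame(time_min = t,
                                concentration_ug_ml = c0 * exp(-k * t)))
  expect_rel_equal(mexp$auc, c0 / k * (1 - exp(-k * 100)), 1e-3)
  expect_equal(mexp$tmax, 0)

  one <- pk_metrics(data.frame(time_min = 5, concentration_ug_ml = 3))
  expect_equal(one$auc, 0); expect_equal(one$cmax, 3)
})

test_that("regimen sweeps are deterministic and reduce to single runs", {
  p <- reference_parameters(n_elements = 40L)
  s1 <- regimen_sweep(p, dose_ug = 12000, n_samples = 3, seed = 7,
                      t_end = 1440, at_times = 1440, n_output = 97)
  s2 <- regimen_sweep(p, dose_ug = 12000, n_samples = 3, seed = 7,
                      t_end = 1440, at_times = 1440, n_output = 97)
  expect_identical(s1, s2)
  expect_true(all(s1$status == "ok"))

  # n = 1 equals a direct simulate + metric evaluation
  s3 <- regimen_sweep(p, dose_ug = 12000, n_samples = 1, seed = 3,
                      t_end = 1440, at_times = 1440, n_output = 97)
  sch <- build_schedule(dose_ug = 12000, volume_ml = s3$volume_ml,
                        duration_min = s3$duration_min, site_cm = 3,
                        horizon_min = 1440)
  sim <- simulate(p, sch, 1440,
                  output_times = sort(unique(c(seq(0, 1440, length.out = 97),
                                               1440))))
  direct <- pk_metrics(data.frame(time_min = sim$times,
                                  concentration_ug_ml = sim$C4))
  expect_equal(s3$cranial_cmax, direct$cmax)
  expect_equal(s3$cranial_auc, direct$auc)

  # failed rows are recorded, the sweep continues
  s4 <- regimen_sweep(p, dose_ug = 12000, volumes = c(1, 2),
                      durations = c(1, 2000), t_end = 1440, at_times = 1440,
                      n_output = 49)
  expect_true(any(s4$status != "ok"))      # 2000-min infusion exceeds horizon
  expect_true(any(s4$status == "ok"))
  expect_true(all(is.na(s4$cranial_cmax[s4$status != "ok"])))
})
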
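test_that("the finite-volume grid partitions the channel exactly", {
  g100 <- build_grid(spinal_geometry(length_cm = 20, n_elements = 100))
  expect_equal(g100$dx, 0.2)
  g4 <- build_grid(spinal_geometry(length_cm = 20, n_elements = 4))
  expect_equal(g4$x, c(2.5, 7.5, 12.5, 17.5))
  expect_rel_equal(g4$n * g4$vol_csf_ml, 0.35 * 20, 1e-12)
  g <- build_grid(spinal_geometry(length_cm = 17.3, area_csf_cm2 = 0.41,
                                  n_elements = 37))
  expect_rel_equal(g$n * g$vol_csf_ml, 0.41 * 17.3, 1e-12)
  expect_error(build_grid(spinal_geometry(n_elements = 2)), NA)
  expect_error(spinal_geometry(n_elements = 1), "n_elements")
})

test_that("the assembled derivative respects trivial structure", {
  p <- reference_parameters(n_elements = 20L)
  sch <- reference_schedule()
  N <- 20; n_state <- 2 * N + 4

  # zero state, no active infusion -> zero derivative
  expect_equal(assemble_rhs(500, numeric(n_state), p, sch),
               numeric(n_state))

  # uniform C1, no flow/exchange/clearance: discrete Laplacian of a constant
  q <- quiet_params(n_elements = 20L, dispersion = 0.3)
  y <- c(rep(2.5, N), numeric(N + 4))
  expect_equal(assemble_rhs(0, y, q, NULL), numeric(n_state))

  # single-cell pulse under pure diffusion: the discrete divergence
  # telescopes, so total C1 amount is conserved
  y2 <- numeric(n_state); y2[7] <- 4
  d <- assemble_rhs(0, y2, q, NULL)
  expect_lt(abs(sum(d[1:N])), 1e-12)
  expect_equal(d[(N + 1):n_state], numeric(N + 4))
})

test_that("a zero-dose schedule leaves the system identically zero", {
  p <- reference_parameters(n_elements = 10L)
  sch <- build_schedule(dose_ug = 0, volume_ml = 1, duration_min = 1,
                        site_cm = 3, horizon_min = 100)
  sim <- simulate(p, sch, 100)
  expect_equal(max(abs(c(sim$C1, sim$C2, sim$C3, sim$C4, sim$C5, sim$C6))), 0)
})

test_that("with clearances off, total mass equals total dosed mass", {
  p <- reference_parameters()
  p$transport$clearance_per_min[] <- 0
  for (sch in list(reference_schedule(horizon_min = 3000),
                   build_schedule(dose_ug = 5000, volume_ml = 4,
                                  duration_min = 20, site_cm = 10,
                                  n_doses = 2, interval_min = 1000,
                                  horizon_min = 3000))) {
    sim <- simulate(p, sch, 3000, rtol = 1e-8, atol = 1e-10)
    ends <- vapply(sch$events, function(e) e$start_min + e$duration_min,
                   numeric(1))
    post <- sim$ledger$time_min >= max(ends)
    dosed <- max(sim$ledger$dosed_mass_ug)
    expect_rel_equal(sim$ledger$total_mass_ug[post], dosed, 1e-6)
  }
})

test_that("pure dispersion matches the reflecting-boundary cosine-series solution", {
  L <- 20; D <- 0.1; N <- 200; t_end <- 200
  q <- quiet_params(n_elements = N, dispersion = D)
  bump <- function(x) ifelse(abs(x - 8) < 4, (1 + cos(pi * (x - 8) / 4)) / 2, 0)
  g <- build_grid(q$geometry)
  sim <- simulate(q, NULL, t_end, output_times = c(0, t_end),
                  init = list(c1 = bump(g$x)), rtol = 1e-10, atol = 1e-12)

  # independent eigenfunction-series oracle (coefficients by fine quadrature)
  xq <- seq(0, L, length.out = 40001)
  xm <- (xq[-1] + xq[-length(xq)]) / 2; dxq <- diff(xq)[1]
  c0 <- bump(xm)
  series <- rep(sum(c0) * dxq / L, N)
  for (n in 1:300) {
    an <- (2 / L) * sum(c0 * cos(n * pi * xm / L)) * dxq
    series <- series + an * cos(n * pi * g$x / L) * exp(-D * (n * pi / L)^2 * t_end)
  }
  err <- max(abs(sim$C1[2, ] - series)) / max(abs(series))
  expect_lt(err, 1e-3)
})

test_that("an isolated compartment decays mono-exponentially", {
  p <- quiet_params(n_elements = 4L)
  p$transport$clearance_per_min[["k5"]] <- 0.05
  times <- seq(0, 60, by = 5)
  sim <- simulate(p, NULL, 60, output_times = times,
                  init = list(c5 = 8), rtol = 1e-10, atol = 1e-14)
  expect_rel_equal(sim$C5, 8 * exp(-0.05 * times), 1e-6)
  # C5(20 min) = 8 * exp(-1) = 2.943...
  expect_equal(sim$C5[times == 20], 8 * exp(-1), tolerance = 1e-6)
})

test_that("a closed CSF/tissue element pair matches a brute-force 2-ODE oracle and equilibrates at C1/C2 = beta", {
  beta <- 0.4; U <- 0.03
  p <- quiet_params(n_elements = 2L)
  p$exchange$U[["1_2"]] <- U
  p$exchange$beta[["1_2"]] <- beta
  times <- c(seq(0, 900, by = 100), 5000, 20000)
  sim <- simulate(p, NULL, 20000, output_times = times,
                  init = list(c1 = c(5, 5)), rtol = 1e-10, atol = 1e-13)

  # independent oracle: the two-box ODE integrated directly
  V1 <- 0.35 * 10; V2 <- 0.3 * 10; u_pc <- U / 2   # per-element share
  oracle <- deSolve::lsoda(
    c(c1 = 5, c2 = 0), times,
    function(t, y, parms) {
      m <- u_pc * (y[1] - beta * y[2])
      list(c(-m / V1, m / V2))
    }, parms = NULL, rtol = 1e-11, atol = 1e-14)
  expect_rel_equal(sim$C1[, 1], oracle[, "c1"], 1e-6)
  expect_rel_equal(sim$C2[, 1], oracle[, "c2"], 1e-6)

  # equilibrium: concentration ratio beta, level fixed by the amount balance
  n <- length(times)
  expect_rel_equal(sim$C1[n, 1] / sim$C2[n, 1], beta, 1e-6)
  expect_rel_equal(sim$C2[n, 1], 5 * V1 / (beta * V1 + V2), 1e-6)
})

test_that("the model is linear: doubling the dose doubles every concentration", {
  p <- reference_parameters(n_elements = 30L)
  sch1 <- build_schedule(dose_ug = 6000, volume_ml = 1, duration_min = 1,
                         site_cm = 3, horizon_min = 2000)
  sch2 <- build_schedule(dose_ug = 12000, volume_ml = 1, duration_min = 1,
                         site_cm = 3, horizon_min = 2000)
  s1 <- simulate(p, sch1, 2000, rtol = 1e-9, atol = 1e-12)
  s2 <- simulate(p, sch2, 2000, rtol = 1e-9, atol = 1e-12)
  sel <- s1$C1 > 1e-8
  expect_rel_equal(s2$C1[sel], 2 * s1$C1[sel], 1e-5)
  expect_rel_equal(s2$C4, 2 * s1$C4, 1e-5)
})

test_that("concentrations stay non-negative to within solver tolerance", {
  p <- reference_parameters()
  sim <- simulate(p, reference_schedule(volume_ml = 4, horizon_min = 10080),
                  10080)
  peak <- max(sim$C1)
  expect_gte(sim$diagnostics$min_concentration, -1e-9 * peak)
})

test_that("total mass sums element and compartment amounts", {
  p <- quiet_params(n_elements = 50L)
  expect_equal(total_mass(numeric(104), p), 0)
  y <- c(rep(1, 50), numeric(54))
  expect_equal(total_mass(y, p), 0.35 * 20)   # c * A * L = 7 ug
  # after a complete infusion with k = 0 the system holds the dose
  p0 <- reference_parameters()
  p0$transport$clearance_per_min[] <- 0
  sch <- build_schedule(dose_ug = 12000, volume_ml = 1, duration_min = 1,
                        site_cm = 3, horizon_min = 10)
  sim <- simulate(p0, sch, 10, output_times = c(0, 2, 10),
                  rtol = 1e-9, atol = 1e-11)
  expect_rel_equal(total_mass(c(sim$C1[3, ], sim$C2[3, ], sim$C3[3],
                                sim$C4[3], sim$C5[3], sim$C6[3]), p0),
                   12000, 1e-6)
})

test_that("grid refinement converges at the expected orders", {
  # diffusion-dominated: ~2nd order (central differences)
  qd <- quiet_params(dispersion = 0.1)
  bump <- function(x) ifelse(abs(x - 8) < 4, (1 + cos(pi * (x - 8) / 4)) / 2, 0)
  tab_d <- convergence_study(qd, NULL, c(25, 50, 100, 200), t_end = 100,
                             init = bump, rtol = 1e-10, atol = 1e-12)
  expect_true(all(diff(tab_d$l2_error) < 0))          # refinement helps
  expect_gt(mean(tab_d$order[-1]), 1.7)

  # advection-dominated: ~1st order (upwind)
  qa <- quiet_params(dispersion = 1e-3)
  sch <- build_schedule(dose_ug = 1000, volume_ml = 4, duration_min = 2,
                        site_cm = 3, horizon_min = 4)
  tab_a <- convergence_study(qa, sch, c(25, 50, 100, 200), t_end = 4,
                             rtol = 1e-10, atol = 1e-12)
  expect_true(all(diff(tab_a$l2_error) < 0))
  expect_gt(mean(tab_a$order[-1]), 0.6)
  expect_lt(mean(tab_a$order[-1]), 1.5)
})
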
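# Method-of-lines solver.
#
# The spinal CSF PDE (advection + effective dispersion + clearance + local
# exchange) is discretized by finite volumes on a uniform cell-centred grid:
# first-order upwind advection (the infusion-driven flow is unidirectional and
# rostral; monotone, positivity-preserving), central second differences for
# dispersion with a reflecting condition at the closed sacral end, and a
# boundary exchange with cranial CSF at the cervical end. Together with the N
# spinal-tissue cells and the four lumped compartments this yields a linear
# system of 2N + 4 ODEs, y' = A y + b, whose coefficients are constant between
# infusion-event boundaries. Integration proceeds segment by segment with
# deSolve::lsoda, supplying A as the analytic Jacobian.

# State layout: y = (C1[1..N], C2[1..N], C3, C4, C5, C6).

#' Finite-volume grid for the spinal channel
#'
#' @param geometry an [spinal_geometry()].
#' @return An object of class `it_grid` with cell centres `x` (cm), width
#'   `dx`, faces (N+1 positions), and per-cell CSF/tissue volumes (mL).
#' @export
build_grid <- function(geometry) {
  msgs <- validate_geometry(geometry)
  if (length(msgs)) stop(paste(msgs, collapse = "; "))
  N <- geometry$n_elements
  dx <- geometry$length_cm / N
  structure(list(
    n = N,
    dx = dx,
    x = (seq_len(N) - 0.5) * dx,
    faces = (0:N) * dx,
    vol_csf_ml = geometry$area_csf_cm2 * dx,
    vol_tissue_ml = geometry$area_tissue_cm2 * dx
  ), class = "it_grid")
}

state_index <- function(N) {
  list(c1 = 1:N, c2 = N + 1:N, c3 = 2 * N + 1, c4 = 2 * N + 2,
       c5 = 2 * N + 3, c6 = 2 * N + 4)
}

# Assemble y' = A y + b for a fixed set of active events.
assemble_system <- function(params, grid, active_events,
                            advective_boundary = TRUE) {
  N <- grid$n
  dx <- grid$dx
  ix <- state_index(N)
  n_state <- 2 * N + 4
  A <- matrix(0, n_state, n_state)

  g <- params$geometry
  tr <- params$transport
  ex <- params$exchange
  V <- params$volumes$volume
  V1 <- grid$vol_csf_ml
  V2 <- grid$vol_tissue_ml
  D <- tr$dispersion_cm2_min
  k <- tr$clearance_per_min

  # Face velocities and per-cell source rates from the active events.
  u_face <- numeric(N + 1)
  src <- numeric(N)             # drug amount rate per CSF cell (ug/min)
  for (e in active_events) {
    cdf <- psf_kernel_cdf(grid$faces, e, g$length_cm)
    u_face <- u_face + e$rate_ml_min * cdf / g$area_csf_cm2
    w <- diff(cdf)              # cell weights, sum to 1
    src <- src + e$rate_ml_min * (e$dose_ug / e$volume_ml) * w
  }

  c1 <- ix$c1; c2 <- ix$c2
  i3 <- ix$c3; i4 <- ix$c4; i5 <- ix$c5; i6 <- ix$c6

  # Advection: upwind, flow is rostral (u >= 0). Outflow across face i+1
  # leaves cell i; u/dx = A_csf * u / V1.
  out_face <- u_face[2:(N + 1)]
  if (!advective_boundary) out_face[N] <- 0
  A[cbind(c1, c1)] <- A[cbind(c1, c1)] - out_face / dx
  if (N > 1) {
    lower <- cbind(c1[-1], c1[-N])
    A[lower] <- A[lower] + u_face[2:N] / dx
  }

  # Dispersion: central differences, reflecting at both ends of the interior
  # stencil (cranial exchange is a separate boundary flux).
  dD <- D / dx^2
  A[cbind(c1, c1)] <- A[cbind(c1, c1)] - 2 * dD
  A[c1[1], c1[1]] <- A[c1[1], c1[1]] + dD
  A[c1[N], c1[N]] <- A[c1[N], c1[N]] + dD
  if (N > 1) {
    A[cbind(c1[-1], c1[-N])] <- A[cbind(c1[-1], c1[-N])] + dD
    A[cbind(c1[-N], c1[-1])] <- A[cbind(c1[-N], c1[-1])] + dD
  }

  # Clearances.
  A[cbind(c1, c1)] <- A[cbind(c1, c1)] - k[["k1"]]
  A[cbind(c2, c2)] <- A[cbind(c2, c2)] - k[["k2"]]
  A[i3, i3] <- A[i3, i3] - k[["k3"]]
  A[i4, i4] <- A[i4, i4] - k[["k4"]]
  A[i5, i5] <- A[i5, i5] - k[["k5"]]
  A[i6, i6] <- A[i6, i6] - k[["k6"]]

  # Distributed exchange: the lumped coefficients are totals over the whole
  # cord; each of the N element pairs carries an equal share U/N.
  u12 <- ex$U[["1_2"]] / N; b12 <- ex$beta[["1_2"]]
  u15 <- ex$U[["1_5"]] / N; b15 <- ex$beta[["1_5"]]
  u25 <- ex$U[["2_5"]] / N; b25 <- ex$beta[["2_5"]]

  A[cbind(c1, c1)] <- A[cbind(c1, c1)] - (u12 + u15) / V1
  A[cbind(c1, c2)] <- A[cbind(c1, c2)] + u12 * b12 / V1
  A[c1, i5] <- A[c1, i5] + u15 * b15 / V1

  A[cbind(c2, c1)] <- A[cbind(c2, c1)] + u12 / V2
  A[cbind(c2, c2)] <- A[cbind(c2, c2)] - (u12 * b12 + u25) / V2
  A[c2, i5] <- A[c2, i5] + u25 * b25 / V2

  A[i5, c1] <- A[i5, c1] + u15 / V[["c5"]]
  A[i5, c2] <- A[i5, c2] + u25 / V[["c5"]]
  A[i5, i5] <- A[i5, i5] - N * (u15 * b15 + u25 * b25) / V[["c5"]]

  # Cervical boundary: diffusive-type exchange with cranial CSF, plus (by
  # default) advective outflow of the infused volume into C3.
  u13 <- ex$U[["1_3"]]
  A[c1[N], c1[N]] <- A[c1[N], c1[N]] - u13 / V1
  A[c1[N], i3] <- A[c1[N], i3] + u13 / V1
  A[i3, c1[N]] <- A[i3, c1[N]] + u13 / V[["c3"]]
  A[i3, i3] <- A[i3, i3] - u13 / V[["c3"]]
  if (advective_boundary) {
    adv_out <- g$area_csf_cm2 * u_face[N + 1]    # mL/min leaving the channel
    A[i3, c1[N]] <- A[i3, c1[N]] + adv_out / V[["c3"]]
  }

  # Cranial CSF <-> cranial tissue.
  u34 <- ex$U[["3_4"]]; b34 <- ex$beta[["3_4"]]
  A[i3, i3] <- A[i3, i3] - u34 / V[["c3"]]
  A[i3, i4] <- A[i3, i4] + u34 * b34 / V[["c3"]]
  A[i4, i3] <- A[i4, i3] + u34 / V[["c4"]]
  A[i4, i4] <- A[i4, i4] - u34 * b34 / V[["c4"]]

  # Cranial tissue <-> blood (asymmetric trapping form: beta on the tissue
  # side attenuates release).
  u45 <- ex$U[["4_5"]]; b45 <- ex$beta[["4_5"]]
  A[i4, i4] <- A[i4, i4] - u45 * b45 / V[["c4"]]
  A[i4, i5] <- A[i4, i5] + u45 / V[["c4"]]
  A[i5, i4] <- A[i5, i4] + u45 * b45 / V[["c5"]]
  A[i5, i5] <- A[i5, i5] - u45 / V[["c5"]]

  # Blood <-> peripheral.
  u56 <- ex$U[["5_6"]]; b56 <- ex$beta[["5_6"]]
  A[i5, i5] <- A[i5, i5] - u56 / V[["c5"]]
  A[i5, i6] <- A[i5, i6] + u56 * b56 / V[["c5"]]
  A[i6, i5] <- A[i6, i5] + u56 / V[["c6"]]
  A[i6, i6] <- A[i6, i6] - u56 * b56 / V[["c6"]]

  b <- numeric(n_state)
  b[c1] <- src / V1
  list(A = A, b = b)
}

#' Time derivative of the full state
#'
#' Assembles and evaluates the right-hand side of the coupled 2N + 4 ODE
#' system at one time point. Used directly in structural tests; [simulate()]
#' uses the same assembly segment-wise for speed.
#'
#' @param t time (min).
#' @param state numeric state vector of length 2N + 4, ordered
#'   (C1\[1..N\], C2\[1..N\], C3, C4, C5, C6).
#' @param params an `it_parameters` object.
#' @param schedule an `it_schedule` or NULL for no infusion.
#' @param advective_boundary deliver advective outflow at the cervical end to
#'   cranial CSF (default TRUE; FALSE reproduces a purely diffusive boundary
#'   coupling).
#' @return Derivative vector of length 2N + 4.
#' @export
assemble_rhs <- function(t, state, params, schedule,
                         advective_boundary = TRUE) {
  if (any(!is.finite(state)))
    stop("non-finite state passed to assemble_rhs at t = ", t)
  grid <- build_grid(params$geometry)
  active <- if (is.null(schedule)) list()
            else schedule$events[active_at(schedule, t)]
  sys <- assemble_system(params, grid, active, advective_boundary)
  as.vector(sys$A %*% state) + sys$b
}

#' Simulate the intrathecal PK model
#'
#' Integrates the coupled CSF-channel / tissue-rod / lumped-compartment system
#' over `[0, t_end]`. Infusion start and end times are used as integration
#' breakpoints so that short boluses are never stepped over; within each
#' segment the system is linear with constant coefficients and is integrated
#' by `deSolve::lsoda` with the exact Jacobian.
#'
#' @param params an `it_parameters` object.
#' @param schedule an `it_schedule`, or NULL for a source-free run (requires
#'   `init`).
#' @param t_end simulation horizon (min).
#' @param output_times times at which the state is recorded (default 201
#'   evenly spaced points).
#' @param init optional initial state: numeric vector of length 2N + 4 or a
#'   list with elements `c1`, `c2` (length-N) and scalars `c3`..`c6`. Defaults
#'   to all-zero.
#' @param advective_boundary see [assemble_rhs()].
#' @param rtol,atol integrator tolerances.
#' @return An object of class `it_simulation`: `times`, matrices `C1`, `C2`
#'   (time x cell, ug/mL), vectors `C3`..`C6`, the `grid`, `params`,
#'   `schedule`, a mass `ledger` (total and dosed mass at each output time)
#'   and solver `diagnostics`. Negative undershoots within integrator
#'   tolerance are clamped to zero; larger ones raise an error.
#' @export
simulate <- function(params, schedule, t_end, output_times = NULL,
                     init = NULL, advective_boundary = TRUE,
                     rtol = 1e-6, atol = 1e-9) {
  rep_ <- validate_parameters(params)
  if (!rep_$ok)
    stop("invalid parameters: ", paste(rep_$violations, collapse = "; "))
  grid <- build_grid(params$geometry)
  N <- grid$n
  n_state <- 2 * N + 4
  if (is.null(schedule) && is.null(init))
    stop("either a schedule or an initial state is required")
  if (!is.null(schedule)) {
    L <- params$geometry$length_cm
    for (e in schedule$events) {
      if (e$site_cm >= L)
        stop("injection site ", e$site_cm, " cm is outside the channel (L = ",
             L, " cm)")
      if (event_end(e) > t_end + 1e-9)
        stop("t_end must cover every infusion event (last event ends at ",
             event_end(e), " min)")
    }
  }
  y0 <- expand_init(init, N)
  if (any(y0 < 0)) stop("initial state must be non-negative")
  if (is.null(output_times)) output_times <- seq(0, t_end, length.out = 201)
  output_times <- sort(unique(output_times))
  if (min(output_times) < 0 || max(output_times) > t_end + 1e-9)
    stop("output_times must lie within [0, t_end]")

  ev_times <- if (is.null(schedule)) numeric() else
    unlist(lapply(schedule$events, function(e) c(e$start_min, event_end(e))))
  bks <- sort(unique(c(0, ev_times[ev_times > 0 & ev_times < t_end], t_end)))

  times_out <- numeric(0)
  rows <- list()
  y <- y0
  min_raw <- 0
  if (any(abs(output_times - 0) < 1e-9)) {
    times_out <- 0
    rows[[1]] <- y0
  }
  for (s in seq_len(length(bks) - 1)) {
    a <- bks[s]; b_ <- bks[s + 1]
    active <- if (is.null(schedule)) list() else
      schedule$events[vapply(schedule$events, function(e)
        e$start_min <= a + 1e-12 && event_end(e) >= b_ - 1e-12 &&
          e$start_min < b_ && event_end(e) > a, logical(1))]
    sys <- assemble_system(params, grid, active, advective_boundary)
    inner <- output_times[output_times > a + 1e-9 & output_times < b_ - 1e-9]
    ts <- sort(unique(c(a, inner, b_)))
    sol <- deSolve::lsoda(
      y, ts,
      func = function(t, y, parms) list(as.vector(parms$A %*% y) + parms$b),
      parms = sys,
      jacfunc = function(t, y, parms) parms$A,
      jactype = "fullusr", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failed in segment [", a, ", ", b_, "] at t = ",
           sol[nrow(sol), 1])
    y <- as.numeric(sol[nrow(sol), -1])
    min_raw <- min(min_raw, min(sol[, -1]))
    keep <- vapply(sol[, 1], function(tt)
      any(abs(output_times - tt) < 1e-9), logical(1))
    keep[1] <- keep[1] && a > 0   # t = a already recorded by previous segment
    if (any(keep)) {
      times_out <- c(times_out, sol[keep, 1])
      rows <- c(rows, lapply(which(keep), function(r) as.numeric(sol[r, -1])))
    }
  }
  Y <- do.call(rbind, rows)
  if (any(!is.finite(Y))) stop("non-finite concentrations in solution")

  # Negative clamp: undershoots within integrator tolerance go to zero.
  clamp_floor <- -(1e3 * atol + 1e-7 * max(Y, 0))
  if (min(Y) < clamp_floor)
    stop("concentration fell below the negativity tolerance (min = ",
         format(min(Y)), ")")
  Y[Y < 0] <- 0

  ix <- state_index(N)
  dosed <- vapply(times_out, function(tt) dosed_mass(schedule, tt), numeric(1))
  total <- apply(Y, 1, total_mass_vec, params = params, grid = grid)
  structure(list(
    times = times_out,
    C1 = Y[, ix$c1, drop = FALSE],
    C2 = Y[, ix$c2, drop = FALSE],
    C3 = Y[, ix$c3], C4 = Y[, ix$c4], C5 = Y[, ix$c5], C6 = Y[, ix$c6],
    grid = grid, params = params, schedule = schedule,
    advective_boundary = advective_boundary,
    ledger = data.frame(time_min = times_out, total_mass_ug = total,
                        dosed_mass_ug = dosed),
    diagnostics = list(n_state = n_state, n_segments = length(bks) - 1,
                       rtol = rtol, atol = atol, min_concentration = min_raw)
  ), class = "it_simulation")
}

expand_init <- function(init, N) {
  n_state <- 2 * N + 4
  if (is.null(init)) return(numeric(n_state))
  if (is.numeric(init)) {
    if (length(init) != n_state)
      stop("init must have length 2N + 4 = ", n_state)
    return(as.numeric(init))
  }
  y <- numeric(n_state)
  ix <- state_index(N)
  if (!is.null(init$c1)) y[ix$c1] <- init$c1
  if (!is.null(init$c2)) y[ix$c2] <- init$c2
  for (nm in c("c3", "c4", "c5", "c6"))
    if (!is.null(init[[nm]])) y[ix[[nm]]] <- init[[nm]]
  y
}

# Drug mass delivered through time t (analytic: rate is constant per event).
dosed_mass <- function(schedule, t) {
  if (is.null(schedule)) return(0)
  sum(vapply(schedule$events, function(e) {
    frac <- min(max((t - e$start_min) / e$duration_min, 0), 1)
    e$dose_ug * frac
  }, numeric(1)))
}

total_mass_vec <- function(y, params, grid) {
  N <- grid$n
  ix <- state_index(N)
  V <- params$volumes$volume
  sum(y[ix$c1]) * grid$vol_csf_ml + sum(y[ix$c2]) * grid$vol_tissue_ml +
    y[ix$c3] * V[["c3"]] + y[ix$c4] * V[["c4"]] +
    y[ix$c5] * V[["c5"]] + y[ix$c6] * V[["c6"]]
}

#' Total drug amount in the system
#'
#' @param state numeric state vector (length 2N + 4) or a one-row slice of a
#'   simulation.
#' @param params an `it_parameters` object.
#' @return Total amount (ug): spinal element concentrations times element
#'   volumes plus lumped concentrations times compartment volumes.
#' @export
total_mass <- function(state, params) {
  grid <- build_grid(params$geometry)
  total_mass_vec(as.numeric(state), params, grid)
}

#' Grid-refinement convergence study
#'
#' Re-runs a scenario on successively finer grids and reports the L2 distance
#' of the final spinal-CSF profile from the finest-grid solution (interpolated
#' to each coarse grid), together with the observed convergence order from
#' successive error ratios. The scheme is a first-order upwind / second-order
#' central mix, so the observed order is ~2 on diffusion-dominated and ~1 on
#' advection-dominated problems.
#'
#' @param params an `it_parameters` object (its `n_elements` is overridden).
#' @param schedule an `it_schedule` or NULL.
#' @param n_list increasing vector of element counts; the last is the
#'   reference grid.
#' @param t_end comparison time (min).
#' @param init optional initial state builder: `function(x)` returning the C1
#'   profile at cell centres `x`.
#' @param ... passed to [simulate()].
#' @return data.frame with columns `n`, `dx`, `l2_error`, `order` (NA in the
#'   first row).
#' @export
convergence_study <- function(params, schedule, n_list, t_end,
                              init = NULL, ...) {
  n_list <- sort(unique(as.integer(n_list)))
  if (length(n_list) < 3) stop("need at least 3 grid levels")
  run_one <- function(N) {
    p <- params
    p$geometry$n_elements <- as.integer(N)
    g <- build_grid(p$geometry)
    ini <- if (is.null(init)) NULL else list(c1 = init(g$x))
    sim <- simulate(p, schedule, t_end, output_times = c(0, t_end),
                    init = ini, ...)
    list(x = g$x, c1 = sim$C1[nrow(sim$C1), ])
  }
  sols <- lapply(n_list, run_one)
  ref <- sols[[length(sols)]]
  res <- data.frame(n = n_list[-length(n_list)],
                    dx = params$geometry$length_cm / n_list[-length(n_list)],
                    l2_error = NA_real_, order = NA_real_)
  for (i in seq_len(nrow(res))) {
    xi <- sols[[i]]$x
    ref_on_coarse <- stats::approx(ref$x, ref$c1, xout = xi, rule = 2)$y
    res$l2_error[i] <- sqrt(mean((sols[[i]]$c1 - ref_on_coarse)^2))
  }
  if (nrow(res) >= 2)
    res$order[-1] <- log(res$l2_error[-nrow(res)] / res$l2_error[-1]) /
      log(res$n[-1] / res$n[-nrow(res)])
  res
}

#' @export
print.it_simulation <- function(x, ...) {
  cat("intrathecal PK simulation:", length(x$times), "time points,",
      x$grid$n, "axial elements (", x$diagnostics$n_state, "state variables )\n")
  cat(sprintf("  t in [%g, %g] min; dosed %g ug; mass in system at t_end: %g ug\n",
              min(x$times), max(x$times),
              max(x$ledger$dosed_mass_ug),
              x$ledger$total_mass_ug[length(x$times)]))
  invisible(x)
}

#' Tidy data frame of a simulation
#'
#' @param x an `it_simulation`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A long data.frame with columns `time_min`, `compartment`,
#'   `position_cm` (NA for lumped compartments) and `concentration_ug_ml`.
#' @export
as.data.frame.it_simulation <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  N <- x$grid$n
  tn <- length(x$times)
  spinal <- function(mat, label) data.frame(
    time_min = rep(x$times, N),
    compartment = label,
    position_cm = rep(x$grid$x, each = tn),
    concentration_ug_ml = as.vector(mat))
  lumped <- function(v, label) data.frame(
    time_min = x$times, compartment = label, position_cm = NA_real_,
    concentration_ug_ml = v)
  rbind(spinal(x$C1, "spinal_csf"), spinal(x$C2, "spinal_tissue"),
        lumped(x$C3, "cranial_csf"), lumped(x$C4, "cranial_tissue"),
        lumped(x$C5, "blood"), lumped(x$C6, "peripheral"))
}
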
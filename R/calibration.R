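# Calibration: synthetic concentration-time datasets with known ground truth,
# a log10-space least-squares objective, bounded Levenberg-Marquardt fitting
# (minpack.lm), and a direct linear estimator for the brain partition
# coefficients. PK observations span several decades, so residuals are taken
# in log10 concentration above a quantification floor.

OBSERVABLE_LUMPED <- c(cranial_csf = "C3", cranial_tissue = "C4",
                       plasma = "C5", blood = "C5", peripheral = "C6")

#' Extract a named observable from a simulation
#'
#' Observable labels: `<landmark>_csf` / `<landmark>_tissue` for spinal
#' samples (e.g. `lumbar_csf`), `cranial_csf`, `cranial_tissue`, `plasma`
#' (alias `blood`), `peripheral`, or a brain region name from the partition
#' spec (e.g. `pons`).
#'
#' @param result an `it_simulation`.
#' @param observable observable label.
#' @return data.frame `time_min`, `concentration_ug_ml`.
#' @export
extract_observable <- function(result, observable) {
  if (observable %in% names(OBSERVABLE_LUMPED)) {
    return(data.frame(time_min = result$times,
                      concentration_ug_ml = result[[OBSERVABLE_LUMPED[[observable]]]]))
  }
  if (observable %in% result$params$partition$region_names) {
    bt <- brain_trajectories(result)
    return(data.frame(time_min = bt$time_min,
                      concentration_ug_ml = bt[[observable]]))
  }
  m <- regmatches(observable, regexec("^([a-z]+)_(csf|tissue)$", observable))[[1]]
  if (length(m) == 3 && m[2] %in% names(result$params$landmarks)) {
    comp <- if (m[3] == "csf") "spinal_csf" else "spinal_tissue"
    return(sample_region(result, comp, m[2]))
  }
  stop("unknown observable '", observable, "'")
}

#' Construct / validate a PK dataset
#'
#' @param df data.frame with columns `time_min`, `observable`,
#'   `concentration_ug_ml` and optionally `noise_cv`.
#' @param provenance free-text provenance tag (file path or synthetic seed).
#' @return The data.frame with class `it_dataset`.
#' @export
pk_dataset <- function(df, provenance = "unspecified") {
  need <- c("time_min", "observable", "concentration_ug_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$time_min < 0)) stop("dataset times must be >= 0")
  if (any(df$concentration_ug_ml < 0)) stop("dataset concentrations must be >= 0")
  structure(df, class = c("it_dataset", class(df)), provenance = provenance)
}

#' Generate a synthetic concentration-time dataset
#'
#' Simulates the model, samples the requested observables at the requested
#' times, and applies multiplicative lognormal noise with the given
#' coefficient of variation (mean-one noise; `noise_cv = 0` returns the exact
#' model output). The generating parameters are attached so that recovery
#' error can be reported after refitting.
#'
#' @param params generating `it_parameters`.
#' @param schedule an `it_schedule`.
#' @param times sampling times (min).
#' @param observables observable labels (see [extract_observable()]).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed used when `noise_cv > 0`.
#' @param t_end simulation horizon; defaults to `max(times)`.
#' @return An `it_dataset` with attributes `truth_params`, `schedule`, `seed`.
#' @export
generate_synthetic <- function(params, schedule, times, observables,
                               noise_cv = 0, seed = 1L, t_end = max(times)) {
  if (!length(times) || !length(observables)) stop("empty sampling design")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  times <- sort(unique(times))
  sim <- simulate(params, schedule, t_end,
                  output_times = sort(unique(c(0, times))))
  recs <- lapply(observables, function(obs) {
    tr <- extract_observable(sim, obs)
    keep <- vapply(times, function(tt) which.min(abs(tr$time_min - tt)),
                   integer(1))
    data.frame(time_min = tr$time_min[keep], observable = obs,
               concentration_ug_ml = tr$concentration_ug_ml[keep],
               noise_cv = noise_cv)
  })
  df <- do.call(rbind, recs)
  if (noise_cv > 0) {
    set.seed(seed)
    sigma <- sqrt(log(1 + noise_cv^2))
    df$concentration_ug_ml <- df$concentration_ug_ml *
      stats::rlnorm(nrow(df), meanlog = -sigma^2 / 2, sdlog = sigma)
  }
  out <- pk_dataset(df, provenance = paste0("synthetic(seed=", seed, ")"))
  attr(out, "truth_params") <- params
  attr(out, "schedule") <- schedule
  attr(out, "seed") <- seed
  out
}

#' Specify a calibration problem
#'
#' @param free character vector of free flat parameter names (see
#'   [get_param()]).
#' @param lower,upper named bounds on the natural scale (finite,
#'   lower < upper).
#' @param log_scale fit positive parameters on the log10 scale (single
#'   logical, applied to all free parameters; default TRUE).
#' @param floor_ug_ml quantification floor: records (and model predictions)
#'   below this concentration are excluded from / clamped in the log-space
#'   loss.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return An object of class `it_fitspec`.
#' @export
fit_spec <- function(free, lower, upper, log_scale = TRUE,
                     floor_ug_ml = 1e-6, max_iter = 100L) {
  if (!all(free %in% names(lower)) || !all(free %in% names(upper)))
    stop("lower/upper must name every free parameter")
  lo <- lower[free]; up <- upper[free]
  if (any(!is.finite(lo)) || any(!is.finite(up)) || any(lo >= up))
    stop("bounds must be finite with lower < upper")
  if (log_scale && any(lo <= 0))
    stop("log-scale fitting requires strictly positive lower bounds")
  structure(list(free = free, lower = lo, upper = up, log_scale = log_scale,
                 floor_ug_ml = floor_ug_ml, max_iter = as.integer(max_iter)),
            class = "it_fitspec")
}

apply_candidate <- function(params, free, theta) {
  for (i in seq_along(free)) params <- set_param(params, free[i], theta[i])
  params
}

# Residual vector in log10 space for one candidate; large finite residuals on
# simulation failure so the optimizer can back off rather than crash.
fit_residuals <- function(fitspec, theta, datasets, params, schedule) {
  if (inherits(datasets, "it_dataset")) datasets <- list(datasets)
  floor_ <- fitspec$floor_ug_ml
  cand <- tryCatch(apply_candidate(params, fitspec$free, theta),
                   error = function(e) e)
  out <- lapply(datasets, function(ds) {
    keep <- ds$concentration_ug_ml >= floor_
    n <- sum(keep)
    if (inherits(cand, "error")) return(rep(1e3, n))
    res <- tryCatch({
      sim <- simulate(cand, schedule, max(ds$time_min),
                      output_times = sort(unique(c(0, ds$time_min))))
      r <- numeric(n)
      sub <- ds[keep, , drop = FALSE]
      for (obs in unique(sub$observable)) {
        sel <- sub$observable == obs
        tr <- extract_observable(sim, obs)
        idx <- vapply(sub$time_min[sel],
                      function(tt) which.min(abs(tr$time_min - tt)), integer(1))
        r[sel] <- log10(pmax(tr$concentration_ug_ml[idx], floor_)) -
          log10(sub$concentration_ug_ml[sel])
      }
      r
    }, error = function(e) rep(1e3, n))
    res
  })
  unlist(out)
}

#' Calibration objective
#'
#' Sum of squared residuals in log10-concentration space over all dataset
#' records at or above the quantification floor; additive over datasets;
#' deterministic for fixed inputs. Simulation failures at a candidate yield a
#' large finite penalty rather than an exception.
#'
#' @param fitspec an [fit_spec()].
#' @param theta named candidate values for the free parameters (natural
#'   scale).
#' @param datasets an `it_dataset` or list thereof.
#' @param params base `it_parameters` (fixed values for non-free parameters).
#' @param schedule the dosing schedule the data were observed under.
#' @return Scalar loss.
#' @export
objective <- function(fitspec, theta, datasets, params, schedule) {
  sum(fit_residuals(fitspec, theta, datasets, params, schedule)^2)
}

#' Fit free parameters by bounded least squares
#'
#' Minimizes [objective()] with the Levenberg-Marquardt algorithm
#' (`minpack.lm::nls.lm`) under box bounds, optionally on the log10 scale.
#' With `n_starts > 1`, additional seeded random starts are drawn
#' log-uniformly (or uniformly) within the bounds and the best solution is
#' kept.
#'
#' @param fitspec an [fit_spec()].
#' @param datasets an `it_dataset` or list thereof.
#' @param params base `it_parameters`.
#' @param schedule the dosing schedule.
#' @param start named starting values (natural scale); defaults to the
#'   current values in `params`.
#' @param n_starts number of multistart draws (>= 1).
#' @param seed seed for the multistart draws.
#' @return An object of class `it_fit`: `par` (fitted values), `loss`,
#'   `converged`, `message`, `n_eval`, `residuals`, a `covariance` proxy
#'   (inverse of the approximate Hessian on the fitting scale, NA if
#'   singular), and `recovery` (per-parameter relative error) when the
#'   dataset carries generating-truth parameters.
#' @export
fit <- function(fitspec, datasets, params, schedule, start = NULL,
                n_starts = 1L, seed = 1L) {
  if (inherits(datasets, "it_dataset")) datasets <- list(datasets)
  n_rec <- sum(vapply(datasets, function(d)
    sum(d$concentration_ug_ml >= fitspec$floor_ug_ml), integer(1)))
  if (n_rec < length(fitspec$free))
    stop("fewer usable records (", n_rec, ") than free parameters")
  if (is.null(start))
    start <- vapply(fitspec$free, function(nm) get_param(params, nm),
                    numeric(1))
  start <- pmin(pmax(start[fitspec$free], fitspec$lower), fitspec$upper)

  fwd <- if (fitspec$log_scale) log10 else identity
  bwd <- if (fitspec$log_scale) function(z) 10^z else identity
  resid_fn <- function(z) {
    fit_residuals(fitspec, stats::setNames(bwd(z), fitspec$free),
                  datasets, params, schedule)
  }
  starts <- list(fwd(start))
  if (n_starts > 1) {
    set.seed(seed)
    lo <- fwd(fitspec$lower); up <- fwd(fitspec$upper)
    for (i in seq_len(n_starts - 1))
      starts <- c(starts, list(stats::runif(length(lo), lo, up)))
  }
  best <- NULL
  for (z0 in starts) {
    sol <- minpack.lm::nls.lm(
      par = z0, fn = resid_fn,
      lower = fwd(fitspec$lower), upper = fwd(fitspec$upper),
      # epsfcn: finite-difference steps must dominate the integrator's
      # rtol-level noise in the residuals, or the Jacobian is meaningless
      control = minpack.lm::nls.lm.control(maxiter = fitspec$max_iter,
                                           epsfcn = 1e-6))
    if (is.null(best) || sol$deviance < best$deviance) best <- sol
  }
  par <- stats::setNames(bwd(best$par), fitspec$free)
  converged <- best$info %in% 1:4
  covmat <- tryCatch(solve(best$hessian), error = function(e) NULL)
  recovery <- NULL
  truth <- attr(datasets[[1]], "truth_params")
  if (!is.null(truth)) {
    tv <- vapply(fitspec$free, function(nm) get_param(truth, nm), numeric(1))
    recovery <- (par - tv) / tv
  }
  structure(list(par = par, loss = best$deviance, converged = converged,
                 message = best$message, n_eval = best$niter,
                 residuals = best$fvec, covariance = covmat,
                 recovery = recovery, fitspec = fitspec),
            class = "it_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.it_fit <- function(x, ...) {
  cat("least-squares calibration:",
      if (x$converged) "converged" else "DID NOT CONVERGE",
      sprintf("(loss %.4g, %d iterations)\n", x$loss, x$n_eval))
  for (nm in names(x$par)) {
    cat(sprintf("  %-12s = %.6g", nm, x$par[[nm]]))
    if (!is.null(x$recovery))
      cat(sprintf("   (recovery error %+.3g%%)", 100 * x$recovery[[nm]]))
    cat("\n")
  }
  invisible(x)
}

# Euclidean projection onto the probability simplex.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

#' Estimate brain partition coefficients from region data
#'
#' The partition rule is linear in the coefficients:
#' `C_i(t) = phi_i * V4 * C4(t) / V_i`, so each `phi_i` is estimated by a
#' zero-intercept least-squares regression of the region observations on the
#' scaled cranial-tissue trajectory, followed by Euclidean projection onto
#' the probability simplex (which leaves exact noise-free solutions
#' untouched).
#'
#' @param region_data an `it_dataset` whose observables are the four region
#'   names.
#' @param c4_trajectory data.frame `time_min`, `concentration_ug_ml` of the
#'   cranial-tissue compartment.
#' @param spec a [brain_partition()] carrying region names and volumes.
#' @return Named vector of `phi` estimates on the simplex.
#' @export
fit_partition <- function(region_data, c4_trajectory, spec) {
  phi <- vapply(spec$region_names, function(rg) {
    sel <- region_data$observable == rg
    if (!any(sel)) stop("no records for region '", rg, "'")
    y <- region_data$concentration_ug_ml[sel]
    idx <- vapply(region_data$time_min[sel],
                  function(tt) which.min(abs(c4_trajectory$time_min - tt)),
                  integer(1))
    p <- spec$volume_c4 * c4_trajectory$concentration_ug_ml[idx] /
      spec$region_volume_ml[[rg]]
    if (all(p == 0)) stop("degenerate (all-zero) cranial-tissue trajectory")
    sum(y * p) / sum(p^2)
  }, numeric(1))
  if (all(phi == 0)) stop("degenerate (all-zero) region data")
  stats::setNames(project_simplex(phi), spec$region_names)
}
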
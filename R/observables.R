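# Derived quantities: regional samples, brain sub-region trajectories,
# exposure fractions, PK summaries, and the infusion-regimen sweep engine.

#' Sample a spinal compartment at a named landmark
#'
#' Returns the concentration-time series of the grid cell containing the
#' landmark position (lumbar, thoracic or cervical, defined in the parameter
#' set as fractions of L), optionally averaged over a window of cells.
#'
#' @param result an `it_simulation`.
#' @param compartment `"spinal_csf"` or `"spinal_tissue"`.
#' @param landmark landmark name, or a numeric position in cm.
#' @param window_cells odd number of cells to average over (default 1).
#' @return data.frame with columns `time_min`, `concentration_ug_ml`.
#' @export
sample_region <- function(result, compartment = c("spinal_csf", "spinal_tissue"),
                          landmark = "lumbar", window_cells = 1L) {
  compartment <- match.arg(compartment)
  L <- result$params$geometry$length_cm
  pos <- if (is.character(landmark)) {
    if (!landmark %in% names(result$params$landmarks))
      stop("unknown landmark '", landmark, "'")
    result$params$landmarks[[landmark]] * L
  } else as.numeric(landmark)
  if (pos <= 0 || pos > L)
    stop("landmark position ", pos, " cm is outside (0, L]")
  if (window_cells %% 2 != 1) stop("window_cells must be odd")
  grid <- result$grid
  i0 <- min(max(ceiling(pos / grid$dx), 1L), grid$n)
  half <- (window_cells - 1L) / 2
  cells <- max(1L, i0 - half):min(grid$n, i0 + half)
  mat <- if (compartment == "spinal_csf") result$C1 else result$C2
  data.frame(time_min = result$times,
             concentration_ug_ml = rowMeans(mat[, cells, drop = FALSE]))
}

#' Brain sub-region concentration trajectories
#'
#' Applies the volumetric partition rule to the cranial-tissue trajectory at
#' every output time.
#'
#' @param result an `it_simulation`.
#' @param spec a [brain_partition()]; defaults to the one in the result's
#'   parameters.
#' @return data.frame with `time_min` and one concentration column (ug/mL)
#'   per region.
#' @export
brain_trajectories <- function(result, spec = result$params$partition) {
  mat <- vapply(result$C4, brain_region_concentrations, spec = spec,
                numeric(length(spec$region_names)))
  out <- data.frame(time_min = result$times)
  out[spec$region_names] <- t(mat)
  out
}

#' Fraction of the spinal length exposed above a threshold
#'
#' @param result an `it_simulation`.
#' @param threshold concentration threshold (ug/mL), >= 0. There is no
#'   default: what counts as a significant exposure is drug- and
#'   question-specific.
#' @param at_time time (min) at which to evaluate; must be an output time.
#' @param compartment `"spinal_tissue"` (default) or `"spinal_csf"`.
#' @return Fraction in \[0, 1\] of cells at or above the threshold.
#' @export
exposure_fraction <- function(result, threshold, at_time,
                              compartment = c("spinal_tissue", "spinal_csf")) {
  compartment <- match.arg(compartment)
  if (threshold < 0) stop("threshold must be >= 0")
  it <- which(abs(result$times - at_time) < 1e-9)
  if (!length(it))
    stop("at_time = ", at_time, " is not among the recorded output times")
  mat <- if (compartment == "spinal_tissue") result$C2 else result$C1
  mean(mat[it[1], ] >= threshold)
}

#' PK summary metrics of a concentration-time series
#'
#' @param series data.frame with columns `time_min` and
#'   `concentration_ug_ml` (as returned by [sample_region()]).
#' @return List with `cmax` (ug/mL), `tmax` (min) and trapezoidal `auc`
#'   (ug*min/mL) over the sampled grid.
#' @export
pk_metrics <- function(series) {
  t <- series$time_min; c <- series$concentration_ug_ml
  if (!length(t)) stop("empty series")
  i <- which.max(c)
  auc <- if (length(t) < 2) 0 else
    sum(diff(t) * (utils::head(c, -1) + utils::tail(c, -1)) / 2)
  list(cmax = c[i], tmax = t[i], auc = auc)
}

#' Infusion-regimen sweep over volume and duration
#'
#' Runs one simulation per (infusion volume, infusion duration) combination at
#' fixed dose and reports delivery metrics, for mapping the regimen landscape
#' the way the underlying model study does (thousands of random combinations
#' rendered as heatmaps). Sampling is uniform in volume and log-uniform in
#' duration (the duration axis spans three decades); pass explicit `volumes`
#' and `durations` vectors instead to evaluate a full factorial grid.
#'
#' @param params an `it_parameters` object.
#' @param dose_ug dose mass per infusion (ug).
#' @param volume_range,duration_range length-2 ranges, default 1-5 mL and
#'   0.1-100 min.
#' @param n_samples number of random samples.
#' @param seed RNG seed (sweeps are fully reproducible given the seed).
#' @param site_cm injection site (cm).
#' @param t_end horizon (min), default 7 days.
#' @param at_times times (min) at which point metrics are recorded.
#' @param volumes,durations optional explicit vectors; if both given, a full
#'   grid is evaluated instead of random sampling.
#' @param n_output number of output time points per simulation.
#' @return data.frame with one row per simulation: `volume_ml`,
#'   `duration_min`, `cranial_cmax`, `cranial_tmax`, `cranial_auc`,
#'   `thoracic_tissue_at_<t>` for each `at_times`, and `status`
#'   ("ok" or the error message for failed runs, whose metrics are NA).
#' @export
regimen_sweep <- function(params, dose_ug, volume_range = c(1, 5),
                          duration_range = c(0.1, 100), n_samples = 100L,
                          seed = 1L, site_cm = 3, t_end = 10080,
                          at_times = t_end, volumes = NULL, durations = NULL,
                          n_output = 201L) {
  if (is.null(volumes) != is.null(durations))
    stop("give both volumes and durations, or neither")
  if (is.null(volumes)) {
    if (any(volume_range <= 0) || any(duration_range <= 0))
      stop("ranges must be positive")
    if (n_samples < 1) stop("n_samples must be >= 1")
    set.seed(seed)
    vols <- stats::runif(n_samples, volume_range[1], volume_range[2])
    durs <- exp(stats::runif(n_samples, log(duration_range[1]),
                             log(duration_range[2])))
  } else {
    g <- expand.grid(volume_ml = volumes, duration_min = durations)
    vols <- g$volume_ml; durs <- g$duration_min
  }
  out_times <- sort(unique(c(seq(0, t_end, length.out = n_output), at_times)))
  rows <- lapply(seq_along(vols), function(i) {
    row <- data.frame(volume_ml = vols[i], duration_min = durs[i],
                      cranial_cmax = NA_real_, cranial_tmax = NA_real_,
                      cranial_auc = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    for (tt in at_times) row[[paste0("thoracic_tissue_at_", tt)]] <- NA_real_
    res <- tryCatch({
      sch <- build_schedule(dose_ug = dose_ug, volume_ml = vols[i],
                            duration_min = durs[i], site_cm = site_cm,
                            horizon_min = t_end)
      sim <- simulate(params, sch, t_end, output_times = out_times)
      cr <- pk_metrics(data.frame(time_min = sim$times,
                                  concentration_ug_ml = sim$C4))
      th <- sample_region(sim, "spinal_tissue", "thoracic")
      list(cr = cr, th = th)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$status <- conditionMessage(res)
    } else {
      row$cranial_cmax <- res$cr$cmax
      row$cranial_tmax <- res$cr$tmax
      row$cranial_auc <- res$cr$auc
      for (tt in at_times)
        row[[paste0("thoracic_tissue_at_", tt)]] <-
          res$th$concentration_ug_ml[which.min(abs(res$th$time_min - tt))]
    }
    row
  })
  do.call(rbind, rows)
}

#' Heatmap of a sweep metric
#'
#' Renders a sweep table as a filled image over (duration, volume), binning
#' random samples onto a regular grid.
#'
#' @param sweep a [regimen_sweep()] table.
#' @param metric metric column name (default `"cranial_cmax"`).
#' @param n_bins bins per axis.
#' @param ... passed to [graphics::image()].
#' @export
plot_sweep <- function(sweep, metric = "cranial_cmax", n_bins = 20, ...) {
  ok <- sweep$status == "ok"
  d <- log10(sweep$duration_min[ok]); v <- sweep$volume_ml[ok]
  z <- sweep[[metric]][ok]
  db <- seq(min(d), max(d), length.out = n_bins + 1)
  vb <- seq(min(v), max(v), length.out = n_bins + 1)
  zi <- matrix(NA_real_, n_bins, n_bins)
  di <- pmin(findInterval(d, db, rightmost.closed = TRUE), n_bins)
  vi <- pmin(findInterval(v, vb, rightmost.closed = TRUE), n_bins)
  agg <- tapply(z, list(di, vi), mean)
  zi[cbind(as.integer(rep(rownames(agg), ncol(agg))),
           as.integer(rep(colnames(agg), each = nrow(agg))))] <- as.vector(agg)
  graphics::image(x = (db[-1] + db[-length(db)]) / 2,
                  y = (vb[-1] + vb[-length(vb)]) / 2, z = zi,
                  xlab = "log10 infusion duration (min)",
                  ylab = "infusion volume (mL)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(zi)
}
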
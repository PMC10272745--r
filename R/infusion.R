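# Infusion scheduling and the distributed infusate source.
#
# A lumbar bolus is not a point source: the catheter mixes the infusate over a
# small finite zone. Each event therefore deposits volume through a smooth
# point-spread kernel with compact support (default half-width 2 cm) centred
# on the injection site. The volumetric flux density f(t, x) (mL/min/cm)
# integrates over space and the event window to the infusate volume V_inj, and
# drives an axially uniform plug flow u(x, t) = (1/A) * int_0^x f dx' in the
# closed-sacral-end channel.

#' Single infusion event
#'
#' @param start_min event start time (min).
#' @param volume_ml infusate volume V_inj (mL), > 0.
#' @param dose_ug drug mass carried by the infusate (ug); 0 for a flush of
#'   drug-free vehicle.
#' @param site_cm injection position measured from the sacral end (cm).
#' @param duration_min,rate_ml_min give exactly one; the other is derived from
#'   `volume_ml = duration_min * rate_ml_min`.
#' @param spread_cm half-width of the point-spread mixing zone (cm).
#' @return An object of class `it_event` with both `duration_min` and
#'   `rate_ml_min` populated.
#' @export
infusion_event <- function(start_min, volume_ml, dose_ug, site_cm,
                           duration_min = NULL, rate_ml_min = NULL,
                           spread_cm = 2) {
  if (is.null(duration_min) == is.null(rate_ml_min))
    stop("give exactly one of duration_min or rate_ml_min")
  if (!is.finite(volume_ml) || volume_ml <= 0)
    stop("volume_ml must be > 0")
  if (is.null(duration_min)) duration_min <- volume_ml / rate_ml_min
  if (is.null(rate_ml_min)) rate_ml_min <- volume_ml / duration_min
  if (!is.finite(duration_min) || duration_min <= 0)
    stop("duration_min must be > 0")
  if (!is.finite(rate_ml_min) || rate_ml_min <= 0)
    stop("rate_ml_min must be > 0")
  if (abs(duration_min * rate_ml_min - volume_ml) > 1e-12 * volume_ml)
    stop("duration_min * rate_ml_min must equal volume_ml")
  if (!is.finite(dose_ug) || dose_ug < 0) stop("dose_ug must be >= 0")
  if (!is.finite(site_cm) || site_cm <= 0) stop("site_cm must be > 0")
  if (!is.finite(spread_cm) || spread_cm <= 0) stop("spread_cm must be > 0")
  structure(list(start_min = as.numeric(start_min),
                 duration_min = as.numeric(duration_min),
                 rate_ml_min = as.numeric(rate_ml_min),
                 volume_ml = as.numeric(volume_ml),
                 dose_ug = as.numeric(dose_ug),
                 site_cm = as.numeric(site_cm),
                 spread_cm = as.numeric(spread_cm)),
            class = "it_event")
}

event_end <- function(e) e$start_min + e$duration_min

#' Dose schedule
#'
#' @param events list of [infusion_event()] objects; sorted by start time on
#'   construction. Overlapping events superpose: their flow rates add.
#' @param horizon_min simulation horizon (min); defaults to the last event end.
#' @return An object of class `it_schedule`.
#' @export
dose_schedule <- function(events, horizon_min = NULL) {
  if (!length(events)) stop("schedule needs at least one event")
  if (inherits(events, "it_event")) events <- list(events)
  stopifnot(all(vapply(events, inherits, logical(1), "it_event")))
  ord <- order(vapply(events, function(e) e$start_min, numeric(1)))
  events <- events[ord]
  last_end <- max(vapply(events, event_end, numeric(1)))
  if (is.null(horizon_min)) horizon_min <- last_end
  structure(list(events = events, horizon_min = as.numeric(horizon_min)),
            class = "it_schedule")
}

#' Build a (possibly repeated) dosing schedule
#'
#' Constructs `n_doses` copies of a dose bolus, each optionally followed
#' immediately by a flush of drug-free vehicle, repeated at a fixed interval.
#'
#' @param dose_ug drug mass per dose (ug), e.g. 12000 for a 12 mg dose.
#' @param volume_ml infusate volume per dose (mL).
#' @param duration_min,rate_ml_min give exactly one (see [infusion_event()]).
#' @param site_cm injection site (cm from the sacral end).
#' @param n_doses number of repeated doses.
#' @param interval_min repeat interval (min); e.g. 2 weeks = 20160 min.
#' @param flush_volume_ml if non-NULL, each dose is followed by a flush of
#'   this volume with zero drug mass.
#' @param flush_duration_min flush duration (min), default 1.
#' @param spread_cm point-spread half-width (cm), default 2.
#' @param horizon_min optional simulation horizon.
#' @return An `it_schedule`.
#' @export
build_schedule <- function(dose_ug, volume_ml, duration_min = NULL,
                           rate_ml_min = NULL, site_cm = 3,
                           n_doses = 1L, interval_min = 0,
                           flush_volume_ml = NULL, flush_duration_min = 1,
                           spread_cm = 2, horizon_min = NULL) {
  if (n_doses < 1) stop("n_doses must be >= 1")
  if (n_doses > 1 && interval_min <= 0)
    stop("interval_min must be > 0 for repeated doses")
  events <- list()
  for (i in seq_len(n_doses)) {
    t0 <- (i - 1) * interval_min
    dose <- infusion_event(t0, volume_ml, dose_ug, site_cm,
                           duration_min = duration_min,
                           rate_ml_min = rate_ml_min, spread_cm = spread_cm)
    events <- c(events, list(dose))
    if (!is.null(flush_volume_ml)) {
      events <- c(events, list(
        infusion_event(event_end(dose), flush_volume_ml, 0, site_cm,
                       duration_min = flush_duration_min,
                       spread_cm = spread_cm)))
    }
  }
  dose_schedule(events, horizon_min = horizon_min)
}

# Raised-cosine (Hann) bump on [site - h, site + h], clipped to [0, L] and
# renormalized so it always integrates to exactly 1 over the channel.
kernel_raw <- function(x, site, h) {
  d <- x - site
  ifelse(abs(d) < h, (1 + cos(pi * d / h)) / (2 * h), 0)
}

# Antiderivative of the unclipped kernel, anchored so cdf(site - h) = 0.
kernel_cdf_raw <- function(x, site, h) {
  d <- pmin(pmax(x - site, -h), h)
  0.5 + d / (2 * h) + sin(pi * d / h) / (2 * pi)
}

kernel_norm <- function(event, length_cm) {
  lo <- max(0, event$site_cm - event$spread_cm)
  hi <- min(length_cm, event$site_cm + event$spread_cm)
  if (hi <= lo) stop("point-spread support lies outside the channel")
  kernel_cdf_raw(hi, event$site_cm, event$spread_cm) -
    kernel_cdf_raw(lo, event$site_cm, event$spread_cm)
}

#' Point-spread kernel of an infusion event
#'
#' Spatial weight (1/cm) with which an event's volumetric flow is distributed
#' along the channel: symmetric about the injection site, identically zero at
#' and beyond the spread half-width, and integrating to 1 over \[0, L\]
#' (after clipping at the domain boundaries and renormalizing).
#'
#' @param x position(s) from the sacral end (cm).
#' @param event an [infusion_event()].
#' @param length_cm channel length L (cm).
#' @return Kernel density values (1/cm).
#' @export
psf_kernel <- function(x, event, length_cm) {
  w <- kernel_raw(x, event$site_cm, event$spread_cm) /
    kernel_norm(event, length_cm)
  w[x < 0 | x > length_cm] <- 0
  w
}

# Integral of the clipped, renormalized kernel from 0 to x.
psf_kernel_cdf <- function(x, event, length_cm) {
  lo <- max(0, event$site_cm - event$spread_cm)
  x <- pmin(pmax(x, 0), length_cm)
  (kernel_cdf_raw(x, event$site_cm, event$spread_cm) -
     kernel_cdf_raw(lo, event$site_cm, event$spread_cm)) /
    kernel_norm(event, length_cm)
}

active_at <- function(schedule, t) {
  vapply(schedule$events,
         function(e) t >= e$start_min && t < event_end(e), logical(1))
}

#' Volumetric infusion flux density f(t, x)
#'
#' Sum over active events of the event flow rate times its point-spread
#' kernel. The double integral of `f` over an event's time window and the
#' channel equals that event's infusate volume.
#'
#' @param t time (min, scalar).
#' @param x position(s) (cm).
#' @param schedule an `it_schedule`.
#' @param length_cm channel length L (cm).
#' @return Flux density (mL/min/cm) at each `x`.
#' @export
infusion_flux <- function(t, x, schedule, length_cm) {
  f <- numeric(length(x))
  for (e in schedule$events[active_at(schedule, t)])
    f <- f + e$rate_ml_min * psf_kernel(x, e, length_cm)
  f
}

#' Plug-flow bulk velocity u(x, t)
#'
#' The closed sacral end and incompressibility make the infusion-induced flow
#' unidirectional and rostral: `u(x, t) = (1/A) * int_0^x f(t, x') dx'`. The
#' velocity is zero at the sacral end, zero everywhere when no event is
#' active, non-decreasing in x, and equals F(t)/A rostral of every active
#' kernel's support.
#'
#' @param t time (min, scalar).
#' @param x position(s) (cm).
#' @param schedule an `it_schedule`.
#' @param geometry an [spinal_geometry()].
#' @return Velocity (cm/min) at each `x`.
#' @export
bulk_velocity <- function(t, x, schedule, geometry) {
  u <- numeric(length(x))
  for (e in schedule$events[active_at(schedule, t)])
    u <- u + e$rate_ml_min *
      psf_kernel_cdf(x, e, geometry$length_cm) / geometry$area_csf_cm2
  u
}
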
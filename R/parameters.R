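#' Spinal channel geometry
#'
#' Describes the one-dimensional spinal subarachnoid CSF channel and the
#' spinal-tissue rod it is coupled to. The channel runs from the closed sacral
#' end at x = 0 to the open cervical end at x = L, with uniform cross-section;
#' both distributed compartments are discretized into `n_elements` uniform
#' axial volume elements.
#'
#' @param length_cm channel length L (cm).
#' @param area_csf_cm2 cross-sectional area of the CSF channel (cm^2).
#' @param area_tissue_cm2 cross-sectional area of the spinal-tissue rod (cm^2).
#' @param n_elements number of axial volume elements N (>= 2).
#' @return An object of class `it_geometry`.
#' @export
spinal_geometry <- function(length_cm = 20, area_csf_cm2 = 0.35,
                            area_tissue_cm2 = 0.3, n_elements = 100L) {
  g <- structure(list(
    length_cm = as.numeric(length_cm),
    area_csf_cm2 = as.numeric(area_csf_cm2),
    area_tissue_cm2 = as.numeric(area_tissue_cm2),
    n_elements = as.integer(n_elements)
  ), class = "it_geometry")
  stop_on_fail(validate_geometry(g))
  g
}

validate_geometry <- function(g) {
  msgs <- character()
  if (!is.finite(g$length_cm) || g$length_cm <= 0)
    msgs <- c(msgs, "geometry: length_cm must be > 0")
  if (!is.finite(g$area_csf_cm2) || g$area_csf_cm2 <= 0)
    msgs <- c(msgs, "geometry: area_csf_cm2 must be > 0")
  if (!is.finite(g$area_tissue_cm2) || g$area_tissue_cm2 <= 0)
    msgs <- c(msgs, "geometry: area_tissue_cm2 must be > 0")
  if (is.na(g$n_elements) || g$n_elements < 2)
    msgs <- c(msgs, "geometry: n_elements must be >= 2")
  msgs
}

#' Axial transport and clearance parameters
#'
#' @param dispersion_cm2_min effective dispersion coefficient D (cm^2/min) in
#'   spinal CSF. This is an apparent dispersion produced by pulsatile
#'   geometry-induced mixing, orders of magnitude above molecular diffusion.
#' @param clearance_per_min named numeric vector `k1`..`k6` of first-order
#'   clearance rate constants (1/min) for the six compartments: spinal CSF,
#'   spinal tissue, cranial CSF, cranial tissue, blood, peripheral.
#' @return An object of class `it_transport`.
#' @export
transport_params <- function(dispersion_cm2_min = 0.1,
                             clearance_per_min = c(k1 = 0, k2 = 0, k3 = 0,
                                                   k4 = 0, k5 = 0, k6 = 0)) {
  k <- rep(0, 6)
  names(k) <- paste0("k", 1:6)
  k[names(clearance_per_min)] <- clearance_per_min
  tr <- structure(list(
    dispersion_cm2_min = as.numeric(dispersion_cm2_min),
    clearance_per_min = k
  ), class = "it_transport")
  stop_on_fail(validate_transport(tr))
  tr
}

validate_transport <- function(tr) {
  msgs <- character()
  if (!is.finite(tr$dispersion_cm2_min) || tr$dispersion_cm2_min < 0)
    msgs <- c(msgs, "transport: dispersion_cm2_min must be >= 0")
  bad <- !is.finite(tr$clearance_per_min) | tr$clearance_per_min < 0
  if (any(bad))
    msgs <- c(msgs, paste0("transport: clearance rate ",
                           paste(names(tr$clearance_per_min)[bad], collapse = ", "),
                           " must be >= 0"))
  msgs
}

# Compartment pairs with a reversible exchange law. (1,3) is the cervical
# boundary flux U13*(C1(L) - C3): no trapping coefficient. (2,5) is the
# tissue-to-blood pathway; its law mirrors the other pairwise laws.
EXCHANGE_PAIRS <- c("1_2", "1_5", "1_3", "2_5", "3_4", "4_5", "5_6")
BETA_PAIRS     <- c("1_2", "1_5", "2_5", "3_4", "4_5", "5_6")

#' Inter-compartment exchange parameters
#'
#' Lumped mass-transfer coefficients `U` (mL/min; the transfer coefficient and
#' interface area are folded together) and trapping ("stickiness")
#' coefficients `beta` in \[0, 1\] biasing reversible exchange toward slow
#' tissue release. Pair names use compartment indices, e.g. `"1_2"` for spinal
#' CSF <-> spinal tissue.
#'
#' @param U named numeric vector over pairs
#'   `r paste(EXCHANGE_PAIRS, collapse = ", ")` (mL/min, >= 0).
#' @param beta named numeric vector over pairs
#'   `r paste(BETA_PAIRS, collapse = ", ")`, each in \[0, 1\].
#' @return An object of class `it_exchange`.
#' @export
exchange_params <- function(U = c("1_2" = 0, "1_5" = 0, "1_3" = 0, "2_5" = 0,
                                  "3_4" = 0, "4_5" = 0, "5_6" = 0),
                            beta = c("1_2" = 0, "1_5" = 0, "2_5" = 0,
                                     "3_4" = 0, "4_5" = 0, "5_6" = 0)) {
  u_full <- stats::setNames(rep(0, length(EXCHANGE_PAIRS)), EXCHANGE_PAIRS)
  b_full <- stats::setNames(rep(0, length(BETA_PAIRS)), BETA_PAIRS)
  unknown <- setdiff(names(U), EXCHANGE_PAIRS)
  if (length(unknown))
    stop("unknown exchange pair(s): ", paste(unknown, collapse = ", "))
  unknown_b <- setdiff(names(beta), BETA_PAIRS)
  if (length(unknown_b))
    stop("unknown stickiness pair(s): ", paste(unknown_b, collapse = ", "))
  u_full[names(U)] <- U
  b_full[names(beta)] <- beta
  ex <- structure(list(U = u_full, beta = b_full), class = "it_exchange")
  stop_on_fail(validate_exchange(ex))
  ex
}

validate_exchange <- function(ex) {
  msgs <- character()
  bad_u <- !is.finite(ex$U) | ex$U < 0
  if (any(bad_u))
    msgs <- c(msgs, paste0("exchange: U[", paste(names(ex$U)[bad_u], collapse = ", "),
                           "] must be >= 0"))
  bad_b <- !is.finite(ex$beta) | ex$beta < 0 | ex$beta > 1
  if (any(bad_b))
    msgs <- c(msgs, paste0("exchange: beta[", paste(names(ex$beta)[bad_b], collapse = ", "),
                           "] violates the bound 0 <= beta <= 1"))
  msgs
}

#' Lumped compartment volumes
#'
#' Volumes (mL) of the well-stirred compartments: cranial CSF (C3), cranial
#' tissue (C4), blood (C5) and peripheral (C6). Element volumes of the
#' distributed spinal compartments are derived from [spinal_geometry()].
#'
#' @param c3,c4,c5,c6 volumes in mL, all > 0.
#' @return An object of class `it_volumes`.
#' @export
compartment_volumes <- function(c3 = 4, c4 = 70, c5 = 160, c6 = 2000) {
  v <- structure(list(volume = c(c3 = as.numeric(c3), c4 = as.numeric(c4),
                                 c5 = as.numeric(c5), c6 = as.numeric(c6))),
                 class = "it_volumes")
  stop_on_fail(validate_volumes(v))
  v
}

validate_volumes <- function(v) {
  bad <- !is.finite(v$volume) | v$volume <= 0
  if (any(bad))
    paste0("volumes: ", paste(names(v$volume)[bad], collapse = ", "),
           " must be > 0")
  else character()
}

#' Brain sub-region partition specification
#'
#' The cranial-tissue compartment is split into functional sub-regions by a
#' volumetric partition rule: region i receives the fraction `phi_i` of the
#' cranial-tissue drug amount, giving concentration
#' `C_i = phi_i * V4 * C4 / V_i`. The `phi_i` must sum to 1 and the region
#' volumes must sum to the cranial-tissue volume `V4`.
#'
#' @param region_names ordered region labels.
#' @param region_volume_ml named volumes (mL) per region; must sum to
#'   `volume_c4`.
#' @param partition_phi named partition coefficients, each in \[0, 1\],
#'   summing to 1.
#' @param volume_c4 cranial tissue volume V4 (mL).
#' @return An object of class `it_partition`.
#' @export
brain_partition <- function(region_names = c("pons", "hippocampus",
                                             "cerebellum", "cortex"),
                            region_volume_ml = c(pons = 1.8, hippocampus = 1.2,
                                                 cerebellum = 5.8, cortex = 61.2),
                            partition_phi = c(pons = 0.06, hippocampus = 0.04,
                                              cerebellum = 0.15, cortex = 0.75),
                            volume_c4 = 70) {
  p <- structure(list(
    region_names = as.character(region_names),
    region_volume_ml = region_volume_ml[region_names],
    partition_phi = partition_phi[region_names],
    volume_c4 = as.numeric(volume_c4)
  ), class = "it_partition")
  stop_on_fail(validate_partition(p))
  p
}

validate_partition <- function(p) {
  msgs <- character()
  if (any(!is.finite(p$region_volume_ml)) || any(p$region_volume_ml <= 0))
    msgs <- c(msgs, "partition: region volumes must be > 0")
  if (any(!is.finite(p$partition_phi)) || any(p$partition_phi < 0) ||
      any(p$partition_phi > 1))
    msgs <- c(msgs, "partition: each phi_i must lie in [0, 1]")
  s <- sum(p$partition_phi)
  if (!is.finite(s) || abs(s - 1) > 1e-12)
    msgs <- c(msgs, sprintf(
      "partition: sum(phi_i) = %.6g violates the normalization sum(phi_i) = 1", s))
  sv <- sum(p$region_volume_ml)
  if (!is.finite(sv) || abs(sv - p$volume_c4) > 1e-9 * p$volume_c4)
    msgs <- c(msgs, sprintf(
      "partition: sum of region volumes (%.6g mL) must equal the cranial tissue volume V4 (%.6g mL)",
      sv, p$volume_c4))
  msgs
}

#' Full model parameter set
#'
#' Aggregates geometry, transport, exchange, lumped volumes, brain partition
#' and named axial landmark positions into one validated object used by the
#' solver, observables and calibration machinery.
#'
#' @param geometry an [spinal_geometry()] object.
#' @param transport a [transport_params()] object.
#' @param exchange an [exchange_params()] object.
#' @param volumes a [compartment_volumes()] object.
#' @param partition a [brain_partition()] object.
#' @param landmarks named fractions of L in (0, 1], strictly increasing, for
#'   the lumbar, thoracic and cervical sampling positions.
#' @return An object of class `it_parameters`.
#' @export
model_parameters <- function(geometry = spinal_geometry(),
                             transport = transport_params(),
                             exchange = exchange_params(),
                             volumes = compartment_volumes(),
                             partition = brain_partition(volume_c4 = volumes$volume[["c4"]]),
                             landmarks = c(lumbar = 0.15, thoracic = 0.5,
                                           cervical = 0.9)) {
  p <- structure(list(geometry = geometry, transport = transport,
                      exchange = exchange, volumes = volumes,
                      partition = partition, landmarks = landmarks),
                 class = "it_parameters")
  rep_ <- validate_parameters(p)
  if (!rep_$ok)
    stop("invalid model parameters:\n  ",
         paste(rep_$violations, collapse = "\n  "))
  p
}

#' Validate a full parameter set
#'
#' Checks every invariant of every component and returns a report rather than
#' raising, so that configuration loading can list all violations at once.
#'
#' @param params an `it_parameters` object (possibly hand-edited).
#' @return A list of class `it_validation` with elements `ok` (logical) and
#'   `violations` (character vector naming each violated invariant).
#' @export
validate_parameters <- function(params) {
  msgs <- c(
    validate_geometry(params$geometry),
    validate_transport(params$transport),
    validate_exchange(params$exchange),
    validate_volumes(params$volumes),
    validate_partition(params$partition)
  )
  lm_ <- params$landmarks
  if (any(!is.finite(lm_)) || any(lm_ <= 0) || any(lm_ > 1))
    msgs <- c(msgs, "landmarks: fractions must lie in (0, 1]")
  else if (is.unsorted(lm_, strictly = TRUE))
    msgs <- c(msgs, "landmarks: fractions must be strictly increasing")
  if (abs(params$partition$volume_c4 - params$volumes$volume[["c4"]]) >
      1e-9 * params$volumes$volume[["c4"]])
    msgs <- c(msgs, "partition: volume_c4 must match volumes$c4")
  structure(list(ok = length(msgs) == 0, violations = msgs),
            class = "it_validation")
}

#' @export
print.it_validation <- function(x, ...) {
  if (x$ok) cat("parameter validation: PASS\n")
  else {
    cat("parameter validation: FAIL\n")
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  }
  invisible(x)
}

stop_on_fail <- function(msgs) {
  if (length(msgs)) stop(paste(msgs, collapse = "; "), call. = FALSE)
  invisible(NULL)
}

#' Reference non-human-primate parameter set
#'
#' A complete parameter set in physiological ranges for an adult cynomolgus
#' monkey: a 20 cm spinal channel discretized into 100 volume elements, an
#' effective CSF dispersion of 0.1 cm^2/min, and exchange, clearance and
#' partition values chosen as documented stand-ins in plausible NHP ranges.
#' All values can be overridden through [set_param()] or a configuration file.
#'
#' @param n_elements number of axial volume elements (default 100).
#' @return An `it_parameters` object.
#' @export
reference_parameters <- function(n_elements = 100L) {
  model_parameters(
    geometry = spinal_geometry(length_cm = 20, area_csf_cm2 = 0.35,
                               area_tissue_cm2 = 0.3, n_elements = n_elements),
    transport = transport_params(
      dispersion_cm2_min = 0.1,
      clearance_per_min = c(k1 = 1e-3, k2 = 2e-4, k3 = 1e-3,
                            k4 = 2e-4, k5 = 2e-2, k6 = 1e-3)),
    exchange = exchange_params(
      U = c("1_2" = 0.05, "1_5" = 0.02, "1_3" = 0.05, "2_5" = 0.005,
            "3_4" = 0.02, "4_5" = 0.01, "5_6" = 0.05),
      beta = c("1_2" = 0.1, "1_5" = 0, "2_5" = 0.1, "3_4" = 0.1,
               "4_5" = 0.2, "5_6" = 0.5)),
    volumes = compartment_volumes(c3 = 4, c4 = 70, c5 = 160, c6 = 2000),
    partition = brain_partition(volume_c4 = 70),
    landmarks = c(lumbar = 0.15, thoracic = 0.5, cervical = 0.9)
  )
}

# Flat parameter addressing used by calibration and config I/O -----------------

#' Get or set a scalar model parameter by flat name
#'
#' Flat names: `dispersion` (cm^2/min), `k1`..`k6` (1/min), `u<i>_<j>` and
#' `beta<i>_<j>` (e.g. `u1_2`, `beta4_5`), `length_cm`, `area_csf_cm2`,
#' `area_tissue_cm2`, `v_c3`..`v_c6` (mL).
#'
#' @param params an `it_parameters` object.
#' @param name flat parameter name.
#' @param value replacement value (for `set_param`).
#' @return `get_param`: the numeric value. `set_param`: an updated, revalidated
#'   `it_parameters` object.
#' @export
get_param <- function(params, name) {
  loc <- locate_param(params, name)
  loc$get(params)
}

#' @rdname get_param
#' @export
set_param <- function(params, name, value) {
  loc <- locate_param(params, name)
  params <- loc$set(params, as.numeric(value))
  rep_ <- validate_parameters(params)
  if (!rep_$ok)
    stop("setting ", name, " = ", value, " violates: ",
         paste(rep_$violations, collapse = "; "))
  params
}

locate_param <- function(params, name) {
  if (name == "dispersion")
    return(list(get = function(p) p$transport$dispersion_cm2_min,
                set = function(p, v) { p$transport$dispersion_cm2_min <- v; p }))
  if (grepl("^k[1-6]$", name))
    return(list(get = function(p) p$transport$clearance_per_min[[name]],
                set = function(p, v) { p$transport$clearance_per_min[[name]] <- v; p }))
  if (grepl("^u[1-6]_[1-6]$", name)) {
    pair <- sub("^u", "", name)
    if (!pair %in% EXCHANGE_PAIRS) stop("unknown exchange pair in '", name, "'")
    return(list(get = function(p) p$exchange$U[[pair]],
                set = function(p, v) { p$exchange$U[[pair]] <- v; p }))
  }
  if (grepl("^beta[1-6]_[1-6]$", name)) {
    pair <- sub("^beta", "", name)
    if (!pair %in% BETA_PAIRS) stop("unknown stickiness pair in '", name, "'")
    return(list(get = function(p) p$exchange$beta[[pair]],
                set = function(p, v) { p$exchange$beta[[pair]] <- v; p }))
  }
  if (name %in% c("length_cm", "area_csf_cm2", "area_tissue_cm2"))
    return(list(get = function(p) p$geometry[[name]],
                set = function(p, v) { p$geometry[[name]] <- v; p }))
  if (grepl("^v_c[3-6]$", name)) {
    key <- sub("^v_", "", name)
    return(list(get = function(p) p$volumes$volume[[key]],
                set = function(p, v) { p$volumes$volume[[key]] <- v; p }))
  }
  stop("unknown parameter name '", name, "'")
}

#' Convert mass concentration to molar concentration
#'
#' Figure axes in the intrathecal ASO literature are commonly in nM while the
#' model works in ug/mL; the conversion needs the drug's molecular weight,
#' which is compound-specific and therefore a required argument.
#'
#' @param conc_ug_ml concentration in ug/mL.
#' @param mw_g_mol molecular weight in g/mol.
#' @return Concentration in nmol/L (nM).
#' @export
ugml_to_nM <- function(conc_ug_ml, mw_g_mol) {
  if (!is.finite(mw_g_mol) || mw_g_mol <= 0) stop("mw_g_mol must be > 0")
  conc_ug_ml / mw_g_mol * 1e6
}
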
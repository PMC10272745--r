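# Algebraic flux laws shared by the solver and by unit-level reasoning.

#' Reversible inter-compartment exchange flux
#'
#' Computes the signed amount-rate (ug/min) transferred between two connected
#' compartments. For most pairs the law is `U * (C_from - beta * C_to)`; the
#' cervical boundary pair (1,3) has no trapping term, `U * (C_from - C_to)`;
#' and the cranial-tissue-to-blood pair (4,5) uses the asymmetric form
#' `U * (beta * C4 - C5)`, with the trapping coefficient attenuating the
#' donor side.
#'
#' @param pair length-2 integer vector `c(i, j)` or string `"i_j"` naming a
#'   connected pair: (1,2), (1,5), (1,3), (2,5), (3,4), (4,5), (5,6).
#' @param c_from concentration (ug/mL) in the first member of the pair.
#' @param c_to concentration (ug/mL) in the second member.
#' @param params an [exchange_params()] object.
#' @return Signed amount-rate (ug/min); positive means net transfer from the
#'   first to the second member.
#' @export
exchange_flux <- function(pair, c_from, c_to, params) {
  key <- pair_key(pair)
  if (!key %in% EXCHANGE_PAIRS)
    stop("unknown compartment pair '", key,
         "'; connected pairs are: ", paste(EXCHANGE_PAIRS, collapse = ", "))
  U <- params$U[[key]]
  if (key == "1_3") return(U * (c_from - c_to))
  if (key == "4_5") return(U * (params$beta[[key]] * c_from - c_to))
  U * (c_from - params$beta[[key]] * c_to)
}

pair_key <- function(pair) {
  if (is.character(pair)) return(pair)
  paste(as.integer(pair), collapse = "_")
}

#' First-order clearance rate
#'
#' @param compartment compartment index 1-6.
#' @param c concentration (ug/mL), >= 0.
#' @param params a [transport_params()] object.
#' @return The elimination rate `k_i * c` (ug/mL/min), to be subtracted from
#'   the concentration derivative.
#' @export
clearance_rate <- function(compartment, c, params) {
  compartment <- as.integer(compartment)
  if (compartment < 1 || compartment > 6) stop("compartment index must be 1-6")
  params$clearance_per_min[[paste0("k", compartment)]] * c
}

#' Brain sub-region concentrations from the volumetric partition rule
#'
#' Distributes the cranial-tissue drug amount `V4 * C4` over the brain
#' sub-regions: region i receives the fraction `phi_i`, giving
#' `C_i = phi_i * V4 * C4 / V_i`. The amounts are conserved exactly:
#' `sum_i C_i V_i = V4 * C4`.
#'
#' @param c4 cranial-tissue concentration (ug/mL), >= 0.
#' @param spec a [brain_partition()] object.
#' @return Named numeric vector of region concentrations (ug/mL).
#' @export
brain_region_concentrations <- function(c4, spec) {
  msgs <- validate_partition(spec)
  if (length(msgs)) stop(paste(msgs, collapse = "; "))
  stats::setNames(
    spec$partition_phi * spec$volume_c4 * c4 / spec$region_volume_ml,
    spec$region_names)
}
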
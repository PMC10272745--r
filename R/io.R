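# Configuration and result serialization. Configurations are YAML with two
# top-level sections, `parameters` and `schedule`; loading validates the whole
# file and reports every violation at once rather than failing at the first.

#' Load a model configuration
#'
#' @param path YAML configuration file (see the shipped
#'   `inst/extdata/reference_config.yaml` for the dialect).
#' @param strict if TRUE (default), raise an error listing every violation;
#'   if FALSE return the partially built objects plus the validation report.
#' @return List with `params` (`it_parameters`), `schedule` (`it_schedule` or
#'   NULL) and `validation` (an `it_validation`).
#' @export
load_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  msgs <- character()
  pc <- cfg$parameters
  if (is.null(pc)) stop("config has no 'parameters' section")

  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  geom <- structure(list(
    length_cm = num(pc$geometry$length_cm, 20),
    area_csf_cm2 = num(pc$geometry$area_csf_cm2, 0.35),
    area_tissue_cm2 = num(pc$geometry$area_tissue_cm2, 0.3),
    n_elements = as.integer(num(pc$geometry$n_elements, 100))
  ), class = "it_geometry")

  k <- stats::setNames(rep(0, 6), paste0("k", 1:6))
  kc <- unlist(pc$transport$clearance_per_min)
  bad_k <- setdiff(names(kc), names(k))
  if (length(bad_k)) msgs <- c(msgs, paste0("transport: unknown clearance key ",
                                            paste(bad_k, collapse = ", ")))
  k[intersect(names(kc), names(k))] <- kc[intersect(names(kc), names(k))]
  transport <- structure(list(
    dispersion_cm2_min = num(pc$transport$dispersion_cm2_min, 0),
    clearance_per_min = k), class = "it_transport")

  U <- stats::setNames(rep(0, length(EXCHANGE_PAIRS)), EXCHANGE_PAIRS)
  B <- stats::setNames(rep(0, length(BETA_PAIRS)), BETA_PAIRS)
  uc <- unlist(pc$exchange$U); bc <- unlist(pc$exchange$beta)
  bad_u <- setdiff(names(uc), names(U))
  if (length(bad_u)) msgs <- c(msgs, paste0("exchange: unknown pair ",
                                            paste(bad_u, collapse = ", ")))
  bad_b <- setdiff(names(bc), names(B))
  if (length(bad_b)) msgs <- c(msgs, paste0("exchange: unknown stickiness pair ",
                                            paste(bad_b, collapse = ", ")))
  U[intersect(names(uc), names(U))] <- uc[intersect(names(uc), names(U))]
  B[intersect(names(bc), names(B))] <- bc[intersect(names(bc), names(B))]
  exchange <- structure(list(U = U, beta = B), class = "it_exchange")

  volumes <- structure(list(volume = c(
    c3 = num(pc$volumes$c3, 4), c4 = num(pc$volumes$c4, 70),
    c5 = num(pc$volumes$c5, 160), c6 = num(pc$volumes$c6, 2000))),
    class = "it_volumes")

  regions <- pc$partition$regions
  rn <- names(regions)
  partition <- structure(list(
    region_names = rn,
    region_volume_ml = stats::setNames(
      vapply(regions, function(r) num(r$volume_ml, NA_real_), numeric(1)), rn),
    partition_phi = stats::setNames(
      vapply(regions, function(r) num(r$phi, NA_real_), numeric(1)), rn),
    volume_c4 = volumes$volume[["c4"]]), class = "it_partition")

  lmk <- unlist(pc$landmarks)
  if (is.null(lmk)) lmk <- c(lumbar = 0.15, thoracic = 0.5, cervical = 0.9)
  params <- structure(list(geometry = geom, transport = transport,
                           exchange = exchange, volumes = volumes,
                           partition = partition, landmarks = lmk),
                      class = "it_parameters")
  vrep <- validate_parameters(params)
  msgs <- c(msgs, vrep$violations)

  schedule <- NULL
  if (!is.null(cfg$schedule)) {
    events <- list()
    for (i in seq_along(cfg$schedule$events)) {
      ev <- cfg$schedule$events[[i]]
      res <- tryCatch(
        infusion_event(start_min = num(ev$start_min, 0),
                       volume_ml = num(ev$volume_ml, NA_real_),
                       dose_ug = num(ev$dose_ug, 0),
                       site_cm = num(ev$site_cm, NA_real_),
                       duration_min = if (is.null(ev$duration_min)) NULL
                                      else as.numeric(ev$duration_min),
                       rate_ml_min = if (is.null(ev$rate_ml_min)) NULL
                                     else as.numeric(ev$rate_ml_min),
                       spread_cm = num(ev$spread_cm, 2)),
        error = function(e) conditionMessage(e))
      if (is.character(res)) msgs <- c(msgs, paste0("event ", i, ": ", res))
      else events <- c(events, list(res))
    }
    if (length(events))
      schedule <- dose_schedule(events,
                                horizon_min = if (is.null(cfg$schedule$horizon_min))
                                  NULL else as.numeric(cfg$schedule$horizon_min))
  }
  validation <- structure(list(ok = length(msgs) == 0, violations = msgs),
                          class = "it_validation")
  if (strict && !validation$ok)
    stop("configuration invalid:\n  ", paste(msgs, collapse = "\n  "))
  list(params = params, schedule = schedule, validation = validation)
}

#' Write a configuration file
#'
#' Serializes a parameter set and optional schedule to the YAML dialect read
#' by [load_config()]; `load_config(write_config(...))` round-trips to equal
#' objects.
#'
#' @param params an `it_parameters`.
#' @param schedule an `it_schedule` or NULL.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, schedule = NULL, path) {
  as_plain <- function(v) as.list(stats::setNames(as.numeric(v), names(v)))
  pt <- params$partition
  cfg <- list(parameters = list(
    geometry = list(length_cm = params$geometry$length_cm,
                    area_csf_cm2 = params$geometry$area_csf_cm2,
                    area_tissue_cm2 = params$geometry$area_tissue_cm2,
                    n_elements = params$geometry$n_elements),
    transport = list(dispersion_cm2_min = params$transport$dispersion_cm2_min,
                     clearance_per_min = as_plain(params$transport$clearance_per_min)),
    exchange = list(U = as_plain(params$exchange$U),
                    beta = as_plain(params$exchange$beta)),
    volumes = as_plain(params$volumes$volume),
    partition = list(regions = stats::setNames(lapply(pt$region_names, function(rg)
      list(volume_ml = pt$region_volume_ml[[rg]],
           phi = pt$partition_phi[[rg]])), pt$region_names)),
    landmarks = as_plain(params$landmarks)))
  if (!is.null(schedule)) {
    cfg$schedule <- list(
      horizon_min = schedule$horizon_min,
      events = lapply(schedule$events, function(e)
        list(start_min = e$start_min, volume_ml = e$volume_ml,
             dose_ug = e$dose_ug, site_cm = e$site_cm,
             duration_min = e$duration_min, spread_cm = e$spread_cm)))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Path to the shipped reference configuration
#' @return File path of the reference NHP configuration inside the installed
#'   package.
#' @export
reference_config_path <- function() {
  system.file("extdata", "reference_config.yaml", package = "itpk",
              mustWork = TRUE)
}

#' Write simulation results as tidy CSV
#'
#' @param result an `it_simulation`.
#' @param path output CSV path.
#' @param mw_g_mol optional molecular weight; adds a `concentration_nM`
#'   column.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(result, path, mw_g_mol = NULL) {
  df <- as.data.frame(result)
  if (!is.null(mw_g_mol))
    df$concentration_nM <- ugml_to_nM(df$concentration_ug_ml, mw_g_mol)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# itpk simulation results, schema v1 (time_min, compartment, position_cm, concentration_ug_ml[, concentration_nM])",
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to re-execute a run: the full parameter and
#' schedule serialization, solver settings, seed, package version and an MD5
#' digest of any input files.
#'
#' @param path output JSON path.
#' @param params an `it_parameters`.
#' @param schedule an `it_schedule` or NULL.
#' @param seed the run seed (or NA).
#' @param solver named list of solver settings.
#' @param extra named list merged into the manifest.
#' @param input_files character vector of input file paths to digest.
#' @return `path`, invisibly.
#' @export
run_manifest <- function(path, params, schedule = NULL, seed = NA,
                         solver = list(), extra = list(),
                         input_files = character()) {
  tmp <- tempfile(fileext = ".yaml")
  write_config(params, schedule, tmp)
  man <- c(list(
    package = "itpk",
    version = tryCatch(as.character(utils::packageVersion("itpk")),
                       error = function(e) "unversioned"),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    solver = solver,
    config = yaml::read_yaml(tmp),
    input_md5 = if (length(input_files))
      as.list(tools::md5sum(input_files)) else NULL
  ), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
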
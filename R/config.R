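#' Pipeline run configuration
#'
#' Aggregates the constants and cutoffs of the whole analysis so a bare
#' default run mirrors the published protocol: `RT` from
#' `R = 1.986e-3 kcal/mol/K` at 298 K, the 200 uM assay ceiling, the
#' 1 kcal/mol single-mutant selection threshold, the 0.5 kcal/mol
#' coupling significance band, and the 4 C thermal-stability cutoff.
#'
#' @param temperature_k Temperature, kelvin.
#' @param gas_constant Gas constant, kcal/mol/K.
#' @param assay_ceiling_molar Kd assay ceiling, molar.
#' @param selection_threshold Single-mutant ddG selection threshold,
#'   kcal/mol.
#' @param significance Coupling significance band, kcal/mol.
#' @param tm_cutoff Thermal-stability exclusion cutoff, degrees C.
#' @param seed Integer seed for stochastic stages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(temperature_k = 298, gas_constant = 1.986e-3,
                       assay_ceiling_molar = 2e-4,
                       selection_threshold = 1.0, significance = 0.5,
                       tm_cutoff = 4.0, seed = 1L) {
  cfg <- list(temperature_k = temperature_k, gas_constant = gas_constant,
              assay_ceiling_molar = assay_ceiling_molar,
              selection_threshold = selection_threshold,
              significance = significance, tm_cutoff = tm_cutoff,
              seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), "seed")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(unlist(num) <= 0))
    stop("invalid run configuration: all thresholds must be positive numbers")
  structure(cfg, class = "run_config")
}

#' Serialize / deserialize a run configuration
#'
#' YAML (`.yml`/`.yaml`) and JSON (`.json`) are both accepted; the round
#' trip is lossless and the result is re-validated on read.
#'
#' @param config A `run_config`.
#' @param path File path ending in `.yml`, `.yaml` or `.json`.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(unclass(config), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA)
  } else stop("unsupported config format: .", ext)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  do.call(run_config, raw)
}
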
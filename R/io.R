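#' Write a sensorgram set to CSV
#'
#' Long-form schema: `cycle_id`, `concentration_molar`, `phase`
#' (`assoc`/`dissoc`), `time_s`, `response_ru`; immobilization metadata
#' is preserved in `#`-prefixed header lines so a round trip is
#' lossless.
#'
#' @param sgs A `sensorgram_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensorgrams <- function(sgs, path) {
  stopifnot(inherits(sgs, "sensorgram_set"))
  d <- sgs$data
  cycle_id <- match(d$concentration, sort(unique(d$concentration)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# t_assoc=%.10g", sgs$t_assoc),
    sprintf("# r_immobilized=%.10g", sgs$r_immobilized),
    sprintf("# mw_analyte=%.10g", sgs$mw_analyte),
    sprintf("# mw_ligand=%.10g", sgs$mw_ligand),
    sprintf("# stoichiometry_n=%.10g", sgs$stoichiometry_n)
  ), con)
  utils::write.csv(
    data.frame(cycle_id = cycle_id, concentration_molar = d$concentration,
               phase = d$phase, time_s = d$time, response_ru = d$response),
    con, row.names = FALSE)
  invisible(path)
}

#' Read a sensorgram set from CSV
#'
#' @param path File written by [write_sensorgrams()].
#' @return A `sensorgram_set`.
#' @export
read_sensorgrams <- function(path) {
  header <- grep("^#", readLines(path, n = 20), value = TRUE)
  meta <- list(t_assoc = NA, r_immobilized = NA, mw_analyte = NA,
               mw_ligand = NA, stoichiometry_n = 1)
  for (h in header) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] %in% names(meta))
      meta[[kv[1]]] <- as.numeric(kv[2])
  }
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("concentration_molar", "phase", "time_s", "response_ru")
  if (!all(need %in% names(d)))
    stop("sensorgram CSV must have columns ", paste(need, collapse = ", "))
  out <- list(
    data = data.frame(concentration = d$concentration_molar,
                      phase = d$phase, time = d$time_s,
                      response = d$response_ru),
    t_assoc = if (is.na(meta$t_assoc))
      max(d$time_s[d$phase == "assoc"]) else meta$t_assoc,
    r_immobilized = meta$r_immobilized,
    mw_analyte = meta$mw_analyte,
    mw_ligand = meta$mw_ligand,
    stoichiometry_n = meta$stoichiometry_n
  )
  class(out) <- "sensorgram_set"
  out
}

#' Write / read a pairwise Kd panel
#'
#' Schema: `yap_variant`, `tead_variant`, `kd_molar`, `kd_se_molar`,
#' `censored` (0/1). Censored rows carry empty Kd fields.
#'
#' @param panel A pairwise Kd table.
#' @param path File path.
#' @return `path` (write) or the panel data frame (read).
#' @export
write_panel <- function(panel, path) {
  out <- panel[, c("yap_variant", "tead_variant", "kd_molar",
                   "kd_se_molar", "censored")]
  out$censored <- as.integer(out$censored)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("yap_variant", "tead_variant", "kd_molar", "kd_se_molar",
            "censored")
  if (!all(need %in% names(d)))
    stop("panel CSV must have columns ", paste(need, collapse = ", "))
  d$censored <- as.logical(d$censored)
  d
}

#' Read melt curves from CSV
#'
#' Schema: `variant`, `temperature_c`, `intensity`; returns one
#' `melt_curve` per variant.
#'
#' @param path File path.
#' @return Named list of `melt_curve` data frames.
#' @export
read_melt_curves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant", "temperature_c", "intensity")
  if (!all(need %in% names(d)))
    stop("melt CSV must have columns ", paste(need, collapse = ", "))
  lapply(split(d, d$variant), function(g) {
    g <- g[order(g$temperature_c), ]
    out <- data.frame(temperature = g$temperature_c,
                      intensity = g$intensity)
    attr(out, "label") <- g$variant[1]
    class(out) <- c("melt_curve", "data.frame")
    out
  })
}
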
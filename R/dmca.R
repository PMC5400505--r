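#' Collapse replicate rows of a pairwise Kd table
#'
#' Duplicate (YAP variant, TEAD variant) rows are averaged; their SEs are
#' pooled as `sqrt(sum(se^2)) / n`. A pair is censored only if all its
#' replicates are censored.
#' @keywords internal
.aggregate_panel <- function(panel) {
  key <- interaction(panel$yap_variant, panel$tead_variant, drop = TRUE)
  if (!anyDuplicated(key)) return(panel)
  out <- lapply(split(panel, key), function(g) {
    meas <- g[!g$censored & !is.na(g$kd_molar), , drop = FALSE]
    if (nrow(meas) == 0) {
      g[1, c("kd_molar", "kd_se_molar")] <- NA_real_
      g$censored[1] <- TRUE
      return(g[1, ])
    }
    data.frame(yap_variant = g$yap_variant[1],
               tead_variant = g$tead_variant[1],
               kd_molar = mean(meas$kd_molar),
               kd_se_molar = sqrt(sum(meas$kd_se_molar^2)) / nrow(meas),
               censored = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.panel_lookup <- function(panel, yap, tead) {
  i <- which(panel$yap_variant == yap & panel$tead_variant == tead)
  if (length(i) == 0) return(NULL)
  panel[i[1], ]
}

#' Single-mutant binding energies from a pairwise Kd table
#'
#' Extracts the rows where the partner protein is wild type, converts Kd
#' to dG, and expresses each variant as a ddG against the wild-type pair.
#'
#' @param panel Pairwise Kd table (columns `yap_variant`, `tead_variant`,
#'   `kd_molar`, `kd_se_molar`, `censored`).
#' @param side `"yap"` or `"tead"`: which protein's variants to extract.
#' @param wt_label Label of the wild-type rows.
#' @param rt Thermal energy, kcal/mol.
#' @return Data frame with columns `variant`, `kd_molar`, `kd_se_molar`,
#'   `dg`, `dg_se`, `ddg`, `ddg_se`, `measured`.
#' @export
single_mutant_energies <- function(panel, side = c("yap", "tead"),
                                   wt_label = "wt", rt = rt_kcal()) {
  side <- match.arg(side)
  panel <- .aggregate_panel(panel)
  ww <- .panel_lookup(panel, wt_label, wt_label)
  if (is.null(ww) || ww$censored)
    stop("pairwise table must contain a measured ", wt_label, ":",
         wt_label, " row")
  dg_ww <- delta_g(ww$kd_molar, ww$kd_se_molar, rt)

  rows <- if (side == "yap") {
    panel[panel$tead_variant == wt_label & panel$yap_variant != wt_label, ]
  } else {
    panel[panel$yap_variant == wt_label & panel$tead_variant != wt_label, ]
  }
  variant <- if (side == "yap") rows$yap_variant else rows$tead_variant
  measured <- !rows$censored & !is.na(rows$kd_molar)
  dg <- dd <- energy(rep(0, nrow(rows)), 0)
  dg$value <- dg$se <- dd$value <- dd$se <- NA_real_
  if (any(measured)) {
    dgi <- delta_g(rows$kd_molar[measured], rows$kd_se_molar[measured], rt)
    ddi <- ddg(dgi, dg_ww)
    dg$value[measured] <- dgi$value; dg$se[measured] <- dgi$se
    dd$value[measured] <- ddi$value; dd$se[measured] <- ddi$se
  }
  data.frame(variant = variant,
             kd_molar = rows$kd_molar, kd_se_molar = rows$kd_se_molar,
             dg = dg$value, dg_se = dg$se,
             ddg = dd$value, ddg_se = dd$se,
             measured = measured, row.names = NULL)
}

#' Select destabilizing mutants for double-mutant-cycle analysis
#'
#' Retains the variants whose single-mutation ddG exceeds the selection
#' threshold (default 1 kcal/mol); variants without a measured Kd are
#' excluded regardless of threshold.
#'
#' @param singles A single-mutant table (see [single_mutant_energies()],
#'   or any data frame with columns `variant`, `ddg`, `measured`).
#' @param threshold Selection threshold, kcal/mol.
#' @return The retained subset of `singles`.
#' @export
select_mutants <- function(singles, threshold = 1.0) {
  stopifnot(is.data.frame(singles),
            all(c("variant", "ddg") %in% names(singles)))
  if (nrow(singles) == 0) stop("empty single-mutant table")
  measured <- if ("measured" %in% names(singles)) singles$measured
              else !is.na(singles$ddg)
  keep <- measured & !is.na(singles$ddg) & singles$ddg > threshold
  singles[keep, , drop = FALSE]
}

#' Enumerate double mutant cycles from a pairwise Kd table
#'
#' Builds one cycle per (YAP variant, TEAD variant) pair: the four binding
#' energies of wt:wt, mutY:wt, wt:mutT and mutY:mutT. A censored or absent
#' mutY:mutT measurement makes the cycle not measurable (`mm_censored`);
#' a missing single-mutant or wild-type row is a data-integrity error.
#'
#' @inheritParams single_mutant_energies
#' @param yap_variants,tead_variants Character vectors of variant labels
#'   (typically from [select_mutants()]).
#' @return Data frame with one row per cycle: `yap`, `tead`, the four
#'   `dg_*`/`se_*` columns and `mm_censored`. The number of distinct Kd
#'   measurements consumed (wild-type pair + singles + double-mutant rows
#'   present, censored included) is attached as attribute
#'   `n_kd_consumed`.
#' @export
enumerate_cycles <- function(panel, yap_variants, tead_variants,
                             wt_label = "wt", rt = rt_kcal()) {
  panel <- .aggregate_panel(panel)
  ww <- .panel_lookup(panel, wt_label, wt_label)
  if (is.null(ww) || ww$censored)
    stop("missing measured wild-type pair ", wt_label, ":", wt_label)
  dg_ww <- delta_g(ww$kd_molar, ww$kd_se_molar, rt)

  need_single <- function(yap, tead) {
    row <- .panel_lookup(panel, yap, tead)
    if (is.null(row) || row$censored || is.na(row$kd_molar))
      stop("missing measured single-mutant row ", yap, ":", tead)
    delta_g(row$kd_molar, row$kd_se_molar, rt)
  }
  dg_mw <- lapply(yap_variants, need_single, tead = wt_label)
  dg_wm <- lapply(tead_variants, function(t) need_single(wt_label, t))
  names(dg_mw) <- yap_variants
  names(dg_wm) <- tead_variants

  n_mm_present <- 0L
  rows <- list()
  for (y in yap_variants) for (t in tead_variants) {
    mm <- .panel_lookup(panel, y, t)
    present <- !is.null(mm)
    if (present) n_mm_present <- n_mm_present + 1L
    censored <- !present || mm$censored || is.na(mm$kd_molar)
    dg_mm <- if (censored) energy(0, 0)[0, ] else
      delta_g(mm$kd_molar, mm$kd_se_molar, rt)
    rows[[length(rows) + 1L]] <- data.frame(
      yap = y, tead = t,
      dg_ww = dg_ww$value, se_ww = dg_ww$se,
      dg_mw = dg_mw[[y]]$value, se_mw = dg_mw[[y]]$se,
      dg_wm = dg_wm[[t]]$value, se_wm = dg_wm[[t]]$se,
      dg_mm = if (censored) NA_real_ else dg_mm$value,
      se_mm = if (censored) NA_real_ else dg_mm$se,
      mm_censored = censored
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "n_kd_consumed") <-
    1L + length(yap_variants) + length(tead_variants) + n_mm_present
  out
}

#' Coupling energy of double mutant cycles
#'
#' For each measurable cycle computes the coupling energy
#' `ddG_int = dG_mm + dG_ww - dG_mw - dG_wm`, its standard error (root
#' sum of squares of the four dG SEs), and the four cycle legs:
#' `ddG_1 = dG_mw - dG_ww` (YAP mutation on wild-type TEAD),
#' `ddG_2 = dG_mm - dG_wm` (YAP mutation on mutant TEAD),
#' `ddG_3 = dG_wm - dG_ww` (TEAD mutation on wild-type YAP),
#' `ddG_4 = dG_mm - dG_mw` (TEAD mutation on mutant YAP).
#' Algebraically `ddG_int = ddG_2 - ddG_1 = ddG_4 - ddG_3`.
#'
#' @param cycles A cycle table from [enumerate_cycles()] (or any data
#'   frame with the `dg_*`/`se_*` columns and `mm_censored`).
#' @return `cycles` with columns `ddg_int`, `ddg_int_se`, `ddg_1` ...
#'   `ddg_4` appended; all NA for not-measurable cycles.
#' @export
coupling_energy <- function(cycles) {
  stopifnot(all(c("dg_ww", "dg_mw", "dg_wm", "dg_mm", "mm_censored")
                %in% names(cycles)))
  ok <- !cycles$mm_censored
  cycles$ddg_int <- with(cycles,
                         ifelse(ok, dg_mm + dg_ww - dg_mw - dg_wm, NA_real_))
  cycles$ddg_int_se <- with(cycles,
    ifelse(ok, sqrt(se_mm^2 + se_ww^2 + se_mw^2 + se_wm^2), NA_real_))
  cycles$ddg_1 <- with(cycles, dg_mw - dg_ww)
  cycles$ddg_3 <- with(cycles, dg_wm - dg_ww)
  cycles$ddg_2 <- with(cycles, ifelse(ok, dg_mm - dg_wm, NA_real_))
  cycles$ddg_4 <- with(cycles, ifelse(ok, dg_mm - dg_mw, NA_real_))
  cycles
}

#' Classify coupling energies
#'
#' Couplings within `significance` of zero are additive (the two residues
#' act independently); `ddG_int < -significance` is a favorable coupling,
#' `ddG_int > +significance` unfavorable. Not-measurable cycles are
#' classed `"not_measurable"`.
#'
#' @param cycles Output of [coupling_energy()].
#' @param significance Significance band, kcal/mol (default 0.5, the
#'   assay's conservative choice; the 2SE-derived bound is 0.36).
#' @return `cycles` with a `coupling_class` factor column appended.
#' @export
classify_coupling <- function(cycles, significance = 0.5) {
  stopifnot(significance >= 0, "ddg_int" %in% names(cycles))
  cls <- ifelse(is.na(cycles$ddg_int), "not_measurable",
         ifelse(cycles$ddg_int < -significance, "favorable",
         ifelse(cycles$ddg_int > significance, "unfavorable", "additive")))
  cycles$coupling_class <- factor(cls, levels = c("additive", "favorable",
                                                  "unfavorable",
                                                  "not_measurable"))
  cycles
}

#' Back-predict double-mutant affinities for unmeasurable pairs
#'
#' For a cycle whose mutY:mutT Kd could not be measured, assumes a
#' coupling energy (default -0.5 kcal/mol, the minimum significant
#' coupling) and predicts
#' `dG_mm = ddG_int_assumed + dG_mw + dG_wm - dG_ww`, hence
#' `Kd_calc = exp(dG_mm / RT)`. `within_assay` flags predictions at or
#' below the assay ceiling, i.e. pairs whose Kd would have been
#' measurable had the residues been coupled at least that strongly.
#'
#' @param cycles A cycle table (needs `dg_ww`, `dg_mw`, `dg_wm`).
#' @param assumed_ddg_int Assumed coupling energy, kcal/mol.
#' @param ceiling_molar Assay ceiling, molar.
#' @param rt Thermal energy, kcal/mol.
#' @return Data frame with columns `yap`, `tead`, `assumed_ddg_int`,
#'   `dg_mm_calc`, `kd_calc_molar`, `within_assay`.
#' @export
predict_kd_calc <- function(cycles, assumed_ddg_int = -0.5,
                            ceiling_molar = 2e-4, rt = rt_kcal()) {
  stopifnot(all(c("dg_ww", "dg_mw", "dg_wm") %in% names(cycles)))
  dg_mm <- assumed_ddg_int + cycles$dg_mw + cycles$dg_wm - cycles$dg_ww
  kd <- kd_from_delta_g(dg_mm, rt)
  data.frame(yap = cycles$yap, tead = cycles$tead,
             assumed_ddg_int = assumed_ddg_int,
             dg_mm_calc = dg_mm, kd_calc_molar = kd,
             within_assay = kd <= ceiling_molar)
}

#' Coupling-energy matrix
#'
#' Lays classified cycles out as a TEAD x YAP matrix of
#' `ddG_int +/- SE` strings, with `"n. m."` for not-measurable cells.
#'
#' @param cycles Output of [classify_coupling()].
#' @return A list with numeric matrices `value` and `se` and a character
#'   matrix `formatted` (rows: TEAD variants, columns: YAP variants).
#' @export
coupling_matrix <- function(cycles) {
  yaps <- unique(cycles$yap)
  teads <- unique(cycles$tead)
  shape <- function(col) {
    m <- matrix(NA_real_, length(teads), length(yaps),
                dimnames = list(teads, yaps))
    m[cbind(match(cycles$tead, teads), match(cycles$yap, yaps))] <-
      cycles[[col]]
    m
  }
  value <- shape("ddg_int")
  se <- shape("ddg_int_se")
  formatted <- ifelse(is.na(value), "n. m.",
                      sprintf("%.2f ± %.2f", value, se))
  dimnames(formatted) <- dimnames(value)
  list(value = value, se = se, formatted = formatted)
}

#' Double mutant cycle analysis of a pairwise Kd table
#'
#' The package's main fitting function. Starting from a pairwise mutant
#' Kd table it (i) converts affinities to binding free energies, (ii)
#' selects the variants whose single mutation destabilizes the complex by
#' more than `threshold` kcal/mol, (iii) enumerates every double mutant
#' cycle in the selected panel, (iv) computes coupling energies with
#' propagated standard errors and classifies them against the
#' `significance` band, and (v) back-predicts Kd for the cycles whose
#' double-mutant affinity fell outside the assay (`Kd > 200 uM`).
#'
#' @param panel Pairwise Kd table: data frame with columns
#'   `yap_variant`, `tead_variant`, `kd_molar`, `kd_se_molar`,
#'   `censored`. Wild-type rows are keyed by `wt_label`; replicate rows
#'   are averaged with SE pooling.
#' @param wt_label Label of the wild-type rows.
#' @param threshold Single-mutant selection threshold, kcal/mol.
#' @param significance Coupling significance band, kcal/mol.
#' @param assumed_ddg_int Coupling energy assumed when back-predicting
#'   unmeasurable pairs, kcal/mol.
#' @param ceiling_molar Assay ceiling, molar.
#' @param rt Thermal energy, kcal/mol.
#' @return An object of class `dmca`; see [print.dmca()],
#'   [summary.dmca()], [coef.dmca()], [predict.dmca()], [plot.dmca()].
#' @export
#' @examples
#' panel <- simulate_panel(
#'   dg_wt = -10.56,
#'   ddg_yap = c(R89A = 4.34, L91A = 4.40),
#'   ddg_tead = c(D272A = 3.53),
#'   ddg_int = data.frame(yap = "R89A", tead = "D272A", ddg_int = -3.49),
#'   rel_se = 0, seed = 1)
#' fit <- dmca(panel)
#' coef(fit)
dmca <- function(panel, wt_label = "wt", threshold = 1.0,
                 significance = 0.5, assumed_ddg_int = -0.5,
                 ceiling_molar = 2e-4, rt = rt_kcal()) {
  stopifnot(is.data.frame(panel),
            all(c("yap_variant", "tead_variant", "kd_molar",
                  "kd_se_molar", "censored") %in% names(panel)))
  panel <- .aggregate_panel(panel)

  singles_yap <- single_mutant_energies(panel, "yap", wt_label, rt)
  singles_tead <- single_mutant_energies(panel, "tead", wt_label, rt)
  sel_yap <- select_mutants(singles_yap, threshold)
  sel_tead <- select_mutants(singles_tead, threshold)
  if (nrow(sel_yap) == 0 || nrow(sel_tead) == 0)
    stop("no variants pass the selection threshold on one or both sides")

  cycles <- enumerate_cycles(panel, sel_yap$variant, sel_tead$variant,
                             wt_label, rt)
  n_kd <- attr(cycles, "n_kd_consumed")
  cycles <- classify_coupling(coupling_energy(cycles), significance)

  nm <- cycles[cycles$mm_censored, , drop = FALSE]
  predictions <- if (nrow(nm) > 0)
    predict_kd_calc(nm, assumed_ddg_int, ceiling_molar, rt)
  else NULL

  structure(list(
    call = match.call(),
    panel = panel,
    singles = list(yap = singles_yap, tead = singles_tead),
    selected = list(yap = sel_yap, tead = sel_tead),
    cycles = cycles,
    matrix = coupling_matrix(cycles),
    predictions = predictions,
    n_kd_consumed = n_kd,
    params = list(wt_label = wt_label, threshold = threshold,
                  significance = significance,
                  assumed_ddg_int = assumed_ddg_int,
                  ceiling_molar = ceiling_molar, rt = rt)
  ), class = "dmca")
}

#' @describeIn dmca Compact display: panel size, cycle count, class
#'   tally and the strongest couplings.
#' @param x,object A `dmca` object.
#' @param ... Unused.
#' @export
print.dmca <- function(x, ...) {
  cat("Double mutant cycle analysis\n")
  cat(sprintf("  %d YAP x %d TEAD variants (ddG > %.2g kcal/mol), %d cycles, %d Kd values consumed\n",
              nrow(x$selected$yap), nrow(x$selected$tead),
              x$params$threshold, nrow(x$cycles), x$n_kd_consumed))
  print(table(x$cycles$coupling_class))
  meas <- x$cycles[!is.na(x$cycles$ddg_int), ]
  if (nrow(meas) > 0) {
    top <- meas[order(meas$ddg_int)[1:min(3, nrow(meas))], ]
    cat("  strongest couplings (kcal/mol):\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s : %s  ddG_int = %.2f ± %.2f (%s)\n",
                  top$yap[i], top$tead[i], top$ddg_int[i],
                  top$ddg_int_se[i], top$coupling_class[i]))
  }
  invisible(x)
}

#' @describeIn dmca Full coupling matrix plus the single-mutant tables.
#' @export
summary.dmca <- function(object, ...) {
  structure(list(matrix = object$matrix, singles = object$singles,
                 selected = object$selected,
                 class_table = table(object$cycles$coupling_class),
                 n_kd_consumed = object$n_kd_consumed,
                 predictions = object$predictions,
                 params = object$params),
            class = "summary.dmca")
}

#' @export
print.summary.dmca <- function(x, ...) {
  cat("Coupling energies ddG_int (kcal/mol), TEAD rows x YAP columns:\n")
  print(x$matrix$formatted, quote = FALSE)
  cat("\nCycle classes:\n")
  print(x$class_table)
  if (!is.null(x$predictions)) {
    cat("\nBack-predicted Kd for unmeasurable pairs (assumed ddG_int =",
        x$params$assumed_ddg_int, "kcal/mol):\n")
    p <- x$predictions
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %s : %s  Kd_calc = %.3g uM (%s)\n", p$yap[i],
                  p$tead[i], 1e6 * p$kd_calc_molar[i],
                  if (p$within_assay[i]) "within assay" else "beyond assay"))
  }
  invisible(x)
}

#' @describeIn dmca Numeric coupling-energy matrix (TEAD rows, YAP
#'   columns).
#' @export
coef.dmca <- function(object, ...) {
  object$matrix$value
}

#' @describeIn dmca Back-predict double-mutant Kd values. By default the
#'   not-measurable cycles are predicted; supply `newdata` (a cycle
#'   table) to predict others.
#' @param newdata Optional cycle table to predict from.
#' @param assumed_ddg_int Assumed coupling energy, kcal/mol.
#' @export
predict.dmca <- function(object, newdata = NULL,
                         assumed_ddg_int = object$params$assumed_ddg_int,
                         ...) {
  cycles <- if (is.null(newdata))
    object$cycles[object$cycles$mm_censored, , drop = FALSE]
  else newdata
  if (nrow(cycles) == 0) return(NULL)
  predict_kd_calc(cycles, assumed_ddg_int,
                  object$params$ceiling_molar, object$params$rt)
}

#' @describeIn dmca Heat-map of the coupling-energy matrix.
#' @export
plot.dmca <- function(x, ...) {
  m <- x$matrix$value
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  axes = FALSE, xlab = "YAP variant", ylab = "TEAD variant",
                  main = "Coupling energy ddG_int (kcal/mol)", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 1,
                 cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
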
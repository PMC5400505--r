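.fixture_md5 <- c(
  "yap_single_mutants.csv" = "413b367d30d01f9e5bed8027ddfc7b21",
  "tead_single_mutants.csv" = "d4aafd5af62cc1be6f02af8abdbef245",
  "coupling_energies.csv" = "dfe7b61de9e3b9fe33699e9c5f5daa11",
  "toy_interface_synthetic.pdb" = "4e2e69c4b5d46b9c0108bdf02088fcb0"
)

#' Path to a packaged fixture, with integrity check
#'
#' @param name File name under the package's `extdata` directory.
#' @return Absolute path to the fixture.
#' @export
fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "dmcycle")
  if (path == "") stop("no packaged fixture named ", name)
  if (name %in% names(.fixture_md5)) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(.fixture_md5[name])))
      stop("fixture integrity error: checksum mismatch for ", name)
  }
  path
}

#' Published YAP single-mutant affinity table
#'
#' Equilibrium dissociation constants (with SE) of alanine mutants of the
#' YAP TEAD-binding domain against wild-type TEAD, as printed (whole
#' nanomolar), together with the printed dG/ddG columns for
#' cross-checking. Region annotates the secondary-structure element
#' (alpha-helix or omega-loop) carrying the residue.
#'
#' @return Data frame with columns `variant`, `region`, `kd_nm`,
#'   `kd_se_nm` and the printed energy columns.
#' @export
yap_table <- function() {
  utils::read.csv(fixture_path("yap_single_mutants.csv"),
                  stringsAsFactors = FALSE)
}

#' Published TEAD single-mutant stability and affinity table
#'
#' Melting temperatures (thermal-shift assay) and, for the variants
#' stable enough to be studied, equilibrium dissociation constants
#' against wild-type YAP. Variants excluded by the stability cutoff have
#' no Kd (NA).
#'
#' @return Data frame with columns `variant`, `region`, `tm_c`,
#'   `tm_se_c`, the printed delta-Tm columns, `kd_nm`, `kd_se_nm` and
#'   the printed energy columns.
#' @export
tead_table <- function() {
  utils::read.csv(fixture_path("tead_single_mutants.csv"),
                  stringsAsFactors = FALSE)
}

#' Published coupling-energy matrix (long form)
#'
#' The printed coupling energies `ddG_int` (kcal/mol, with SE) for every
#' (YAP variant, TEAD variant) pair of the selected panel;
#' `measurable = 0` marks the pairs whose double-mutant Kd exceeded the
#' assay ceiling ("n. m.").
#'
#' @return Data frame with columns `yap_variant`, `tead_variant`,
#'   `ddg_int`, `ddg_int_se`, `measurable`.
#' @export
printed_couplings <- function() {
  utils::read.csv(fixture_path("coupling_energies.csv"),
                  stringsAsFactors = FALSE)
}

#' Pairwise Kd panel reconstructed from the printed tables
#'
#' The raw 80-entry pairwise Kd table behind the published analysis is
#' not redistributable, so this function reconstructs a synthetic
#' stand-in from printed numbers only: wild-type and single-mutant rows
#' come directly from the printed Kd tables, and each double-mutant Kd is
#' back-derived from the printed coupling energy via
#' `dG_mm = ddG_int + dG_mw + dG_wm - dG_ww`. Pairs printed "n. m." are
#' emitted censored. Coupling energies recomputed from this panel
#' reproduce the printed matrix by construction, so it validates the
#' cycle arithmetic and the combinatorics, not the published raw data.
#'
#' @param rt Thermal energy, kcal/mol.
#' @return A pairwise Kd table (columns `yap_variant`, `tead_variant`,
#'   `kd_molar`, `kd_se_molar`, `censored`).
#' @export
reconstructed_panel <- function(rt = rt_kcal()) {
  yap <- yap_table()
  tead <- tead_table()
  cpl <- printed_couplings()
  tead <- tead[!is.na(tead$kd_nm), ]

  base <- rbind(
    data.frame(yap_variant = "wt", tead_variant = "wt",
               kd_nm = yap$kd_nm[yap$variant == "wt"],
               kd_se_nm = yap$kd_se_nm[yap$variant == "wt"]),
    data.frame(yap_variant = yap$variant[yap$variant != "wt"],
               tead_variant = "wt",
               kd_nm = yap$kd_nm[yap$variant != "wt"],
               kd_se_nm = yap$kd_se_nm[yap$variant != "wt"]),
    data.frame(yap_variant = "wt",
               tead_variant = tead$variant[tead$variant != "wt"],
               kd_nm = tead$kd_nm[tead$variant != "wt"],
               kd_se_nm = tead$kd_se_nm[tead$variant != "wt"])
  )
  base <- data.frame(base[, 1:2], kd_molar = base$kd_nm * 1e-9,
                     kd_se_molar = base$kd_se_nm * 1e-9,
                     censored = FALSE)

  dg_of <- function(y, t) {
    row <- base[base$yap_variant == y & base$tead_variant == t, ]
    delta_g(row$kd_molar, row$kd_se_molar, rt)
  }
  dg_ww <- dg_of("wt", "wt")
  mm <- lapply(seq_len(nrow(cpl)), function(i) {
    y <- cpl$yap_variant[i]; t <- cpl$tead_variant[i]
    if (!cpl$measurable[i]) {
      return(data.frame(yap_variant = y, tead_variant = t,
                        kd_molar = NA_real_, kd_se_molar = NA_real_,
                        censored = TRUE))
    }
    dg_mw <- dg_of(y, "wt"); dg_wm <- dg_of("wt", t)
    dg_mm <- cpl$ddg_int[i] + dg_mw$value + dg_wm$value - dg_ww$value
    kd <- kd_from_delta_g(dg_mm, rt)
    # SE of dG_mm implied by the printed coupling SE and the other legs
    se2 <- cpl$ddg_int_se[i]^2 - dg_ww$se^2 - dg_mw$se^2 - dg_wm$se^2
    kd_se <- kd * sqrt(max(se2, 0)) / rt
    data.frame(yap_variant = y, tead_variant = t, kd_molar = kd,
               kd_se_molar = kd_se, censored = FALSE)
  })
  out <- rbind(base, do.call(rbind, mm))
  rownames(out) <- NULL
  out
}
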
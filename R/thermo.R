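#' Thermal energy RT in kcal/mol
#'
#' All free-energy arithmetic in the package uses `RT = R * T` with the gas
#' constant `R = 1.986e-3 kcal mol^-1 K^-1` and `T = 298 K` unless stated
#' otherwise, giving `RT = 0.591828 kcal/mol`.
#'
#' @param temperature_k Absolute temperature in kelvin.
#' @param gas_constant Gas constant in kcal mol^-1 K^-1.
#' @return RT in kcal/mol.
#' @export
#' @examples
#' rt_kcal() # 0.591828
rt_kcal <- function(temperature_k = 298, gas_constant = 1.986e-3) {
  stopifnot(temperature_k > 0, gas_constant > 0)
  gas_constant * temperature_k
}

#' Construct an energy value with a standard error
#'
#' A minimal value/SE pair used throughout the free-energy calculus. Both
#' arguments are recycled to a common length.
#'
#' @param value Energy in kcal/mol.
#' @param se Standard error in kcal/mol (non-negative).
#' @return A data frame with columns `value` and `se`.
#' @export
energy <- function(value, se = 0) {
  if (any(!is.finite(value))) stop("energy values must be finite")
  if (any(se < 0, na.rm = TRUE)) stop("standard errors must be non-negative")
  data.frame(value = value, se = rep_len(se, length(value)))
}

#' Binding free energy from an equilibrium dissociation constant
#'
#' Computes `dG = RT ln(Kd)` with the first-order propagated standard error
#' `SE_dG = RT * (SE_Kd / Kd)`. `Kd` must be expressed in molar units so that
#' sub-molar affinities give negative free energies.
#'
#' @param kd_molar Equilibrium dissociation constant(s), molar.
#' @param kd_se_molar Standard error(s) on `kd_molar`, molar.
#' @param rt Thermal energy in kcal/mol (see [rt_kcal()]).
#' @return An [energy()] data frame (kcal/mol).
#' @export
#' @examples
#' delta_g(18e-9)            # wild-type YAP:TEAD, about -10.55 kcal/mol
#' delta_g(6447e-9, 400e-9)  # Phe69Ala
delta_g <- function(kd_molar, kd_se_molar = 0, rt = rt_kcal()) {
  if (any(!is.finite(kd_molar)) || any(kd_molar <= 0))
    stop("kd_molar must be strictly positive")
  if (any(kd_se_molar < 0)) stop("kd_se_molar must be non-negative")
  energy(rt * log(kd_molar), rt * (kd_se_molar / kd_molar))
}

#' Dissociation constant from a binding free energy
#'
#' Inverse of [delta_g()]: `Kd = exp(dG / RT)` in molar units.
#'
#' @param dg Binding free energy in kcal/mol.
#' @inheritParams delta_g
#' @return Kd in molar.
#' @export
kd_from_delta_g <- function(dg, rt = rt_kcal()) {
  exp(dg / rt)
}

#' Mutational change in binding free energy
#'
#' `ddG = dG_mutant - dG_wt` with the standard error propagated as the root
#' sum of squares of the two input SEs.
#'
#' @param mutant,wt [energy()] data frames (kcal/mol).
#' @return An [energy()] data frame (kcal/mol).
#' @export
ddg <- function(mutant, wt) {
  stopifnot(is.data.frame(mutant), is.data.frame(wt))
  energy(mutant$value - wt$value, sqrt(mutant$se^2 + wt$se^2))
}

#' Worst-case propagated standard error on a free-energy combination
#'
#' With every Kd measured at a relative standard error `rel_kd_se`, each dG
#' carries `SE_dG = RT * rel_kd_se`, and a combination of `n_terms`
#' independent dG values carries `RT * rel_kd_se * sqrt(n_terms)`. At the
#' assay's 15% ceiling this gives 0.09 kcal/mol for a single dG and
#' 0.18 kcal/mol for a four-term coupling energy.
#'
#' @param rel_kd_se Relative standard error on Kd, as a fraction in (0, 1).
#' @param n_terms Number of independent dG terms combined.
#' @inheritParams delta_g
#' @return Standard error in kcal/mol.
#' @export
max_propagated_se <- function(rel_kd_se, n_terms = 1, rt = rt_kcal()) {
  stopifnot(rel_kd_se >= 0, rel_kd_se < 1, n_terms >= 1)
  rt * rel_kd_se * sqrt(n_terms)
}
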
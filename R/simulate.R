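#' Simulate a 1:1 Langmuir SPR sensorgram set
#'
#' Generates time-resolved response curves for a series of analyte
#' concentrations under the pseudo-first-order 1:1 interaction model. The
#' association phase follows the closed form
#' `R(t) = Req * (1 - exp(-(ka*C + kd_off)*t))` with
#' `Req = C * rmax / (C + Kd)`, and the dissociation phase decays as
#' `R(t') = R(t_assoc) * exp(-kd_off * t')`. Gaussian response noise and a
#' linear baseline drift can be added.
#'
#' If `r_immobilized` is not supplied it is chosen so that the theoretical
#' maximum binding capacity of the surface equals `rmax`, i.e. a fully
#' active surface.
#'
#' @param ka Association rate constant, per molar per second.
#' @param kd_off Dissociation rate constant, per second.
#' @param rmax Saturating response, response units (RU).
#' @param concentrations Analyte concentrations, molar; strictly positive.
#' @param t_assoc,t_dissoc Durations of the injection (association) and
#'   dissociation phases, seconds.
#' @param dt Sampling interval, seconds.
#' @param ru_sd Additive Gaussian response noise, RU.
#' @param drift_rate Linear baseline drift, RU per second.
#' @param seed Optional integer seed for reproducibility.
#' @param r_immobilized Immobilized ligand level, RU.
#' @param mw_analyte,mw_ligand Molecular weights of analyte and immobilized
#'   ligand, daltons.
#' @param stoichiometry_n Binding stoichiometry (default 1).
#' @return A `sensorgram_set` object: a list with a `data` data frame
#'   (columns `concentration`, `phase`, `time`, `response`), immobilization
#'   metadata, and the true kinetic parameters as attribute `truth`.
#' @seealso [fit_kinetics()], [determine_kd()]
#' @export
#' @examples
#' sgs <- simulate_sensorgram(ka = 1e5, kd_off = 1.8e-3, rmax = 60,
#'                            concentrations = c(5, 20, 80, 320) * 1e-9)
simulate_sensorgram <- function(ka, kd_off, rmax, concentrations,
                                t_assoc = 230, t_dissoc = 120, dt = 2,
                                ru_sd = 0, drift_rate = 0, seed = NULL,
                                r_immobilized = NULL,
                                mw_analyte = 14000, mw_ligand = 25000,
                                stoichiometry_n = 1) {
  if (ka <= 0 || kd_off <= 0 || rmax <= 0)
    stop("ka, kd_off and rmax must be positive")
  if (length(concentrations) == 0 || any(concentrations <= 0))
    stop("concentrations must be non-empty and strictly positive")
  if (anyDuplicated(concentrations))
    stop("concentrations must be distinct")
  if (t_assoc <= 0 || t_dissoc <= 0 || dt <= 0)
    stop("t_assoc, t_dissoc and dt must be positive")
  if (ru_sd < 0) stop("ru_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  kd_eq <- kd_off / ka
  if (is.null(r_immobilized))
    r_immobilized <- rmax * mw_ligand / (mw_analyte * stoichiometry_n)

  t_a <- seq(dt, t_assoc, by = dt)
  t_d <- seq(dt, t_dissoc, by = dt)
  curves <- lapply(concentrations, function(conc) {
    kobs <- ka * conc + kd_off
    req <- conc * rmax / (conc + kd_eq)
    r_assoc <- req * (1 - exp(-kobs * t_a))
    r_end <- req * (1 - exp(-kobs * t_assoc))
    r_dissoc <- r_end * exp(-kd_off * t_d)
    df <- rbind(
      data.frame(concentration = conc, phase = "assoc", time = t_a,
                 response = r_assoc),
      data.frame(concentration = conc, phase = "dissoc", time = t_d,
                 response = r_dissoc)
    )
    # drift accumulates over the whole cycle; noise is per sample
    elapsed <- c(t_a, t_assoc + t_d)
    df$response <- df$response + drift_rate * elapsed
    if (ru_sd > 0)
      df$response <- df$response + stats::rnorm(nrow(df), sd = ru_sd)
    df
  })

  out <- list(
    data = do.call(rbind, curves),
    t_assoc = t_assoc,
    r_immobilized = r_immobilized,
    mw_analyte = mw_analyte,
    mw_ligand = mw_ligand,
    stoichiometry_n = stoichiometry_n
  )
  attr(out, "truth") <- list(ka = ka, kd_off = kd_off, rmax = rmax,
                             kd_eq = kd_eq)
  class(out) <- "sensorgram_set"
  out
}

#' @export
print.sensorgram_set <- function(x, ...) {
  concs <- unique(x$data$concentration)
  cat("SPR sensorgram set:", length(concs), "concentrations,",
      format(min(concs), digits = 3), "-", format(max(concs), digits = 3),
      "M\n")
  cat("  immobilized ligand:", format(x$r_immobilized, digits = 4), "RU;",
      "MW analyte/ligand:", x$mw_analyte, "/", x$mw_ligand, "Da\n")
  invisible(x)
}

#' @export
plot.sensorgram_set <- function(x, ...) {
  d <- x$data
  elapsed <- ifelse(d$phase == "assoc", d$time, x$t_assoc + d$time)
  graphics::plot(elapsed, d$response, type = "n",
                 xlab = "time (s)", ylab = "response (RU)", ...)
  for (conc in unique(d$concentration)) {
    i <- d$concentration == conc
    graphics::lines(elapsed[i][order(elapsed[i])],
                    d$response[i][order(elapsed[i])])
  }
  graphics::abline(v = x$t_assoc, lty = 3)
  invisible(x)
}

#' Simulate an equilibrium binding isotherm
#'
#' Steady-state responses `Req(C) = rmax * C / (Kd + C) + background`,
#' optionally perturbed by multiplicative noise.
#'
#' @param kd_eq Equilibrium dissociation constant, molar.
#' @param rmax Saturating response, RU.
#' @param background Constant background response, RU.
#' @param concentrations Analyte concentrations, molar.
#' @param rel_noise Multiplicative noise, relative standard deviation.
#' @param seed Optional integer seed.
#' @return A data frame with columns `concentration` and `response`.
#' @export
simulate_isotherm <- function(kd_eq, rmax, background = 0, concentrations,
                              rel_noise = 0, seed = NULL) {
  if (kd_eq <= 0) stop("kd_eq must be positive")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (rel_noise < 0) stop("rel_noise must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  r <- rmax * concentrations / (kd_eq + concentrations) + background
  if (rel_noise > 0)
    r <- r * exp(stats::rnorm(length(r), sd = sqrt(log1p(rel_noise^2))))
  data.frame(concentration = concentrations, response = r)
}

#' Simulate a full pairwise mutant-panel Kd table
#'
#' Builds the substrate of a double-mutant-cycle analysis: one Kd per
#' (YAP variant, TEAD variant) pair, including wild type. The true pair
#' energy is `dG = dG_wt + ddG_yap + ddG_tead + ddG_int`, inverted to
#' `Kd = exp(dG / RT)`. Reported Kd values are perturbed by a
#' median-preserving multiplicative log-normal whose relative standard
#' deviation equals `rel_se`, and carry a matching SE column
#' (`rel_se * Kd`). Pairs whose true Kd exceeds the assay ceiling are
#' emitted censored with no numeric Kd, mirroring the 200 uM limit of the
#' SPR assay.
#'
#' @param dg_wt Wild-type:wild-type binding free energy, kcal/mol
#'   (negative).
#' @param ddg_yap,ddg_tead Named numeric vectors of single-mutant ddG
#'   values, kcal/mol; names are variant labels.
#' @param ddg_int Optional data frame with columns `yap`, `tead`,
#'   `ddg_int` giving injected coupling energies (kcal/mol) for specific
#'   pairs; pairs not listed are additive (coupling 0).
#' @param rel_se Relative standard error applied to simulated Kd, in
#'   \[0, 0.15\] (the assay's stated maximum).
#' @param seed Optional integer seed.
#' @param ceiling_molar Assay ceiling for Kd determination, molar.
#' @param wt_label Label used for the wild-type rows.
#' @param rt Thermal energy, kcal/mol.
#' @return A pairwise Kd table: data frame with columns `yap_variant`,
#'   `tead_variant`, `kd_molar`, `kd_se_molar`, `censored`; the noiseless
#'   truth is kept as attribute `truth`.
#' @seealso [dmca()]
#' @export
simulate_panel <- function(dg_wt, ddg_yap, ddg_tead, ddg_int = NULL,
                           rel_se = 0.15, seed = NULL,
                           ceiling_molar = 2e-4, wt_label = "wt",
                           rt = rt_kcal()) {
  if (dg_wt >= 0) stop("dg_wt must be negative (sub-molar wild-type Kd)")
  if (rel_se < 0 || rel_se > 0.15)
    stop("rel_se must lie in [0, 0.15]")
  if (is.null(names(ddg_yap)) || is.null(names(ddg_tead)))
    stop("ddg_yap and ddg_tead must be named vectors")
  if (!is.null(seed)) set.seed(seed)

  coupling <- function(y, t) {
    if (is.null(ddg_int)) return(0)
    hit <- ddg_int$yap == y & ddg_int$tead == t
    if (any(hit)) ddg_int$ddg_int[which(hit)[1]] else 0
  }
  if (!is.null(ddg_int)) {
    stopifnot(all(c("yap", "tead", "ddg_int") %in% names(ddg_int)))
    bad <- !(ddg_int$yap %in% names(ddg_yap)) |
      !(ddg_int$tead %in% names(ddg_tead))
    if (any(bad))
      stop("ddg_int refers to variants absent from ddg_yap/ddg_tead")
  }

  yaps <- c(wt_label, names(ddg_yap))
  teads <- c(wt_label, names(ddg_tead))
  grid <- expand.grid(yap_variant = yaps, tead_variant = teads,
                      stringsAsFactors = FALSE)
  dg_true <- apply(grid, 1, function(row) {
    y <- row[["yap_variant"]]; t <- row[["tead_variant"]]
    dy <- if (y == wt_label) 0 else ddg_yap[[y]]
    dt_ <- if (t == wt_label) 0 else ddg_tead[[t]]
    di <- if (y == wt_label || t == wt_label) 0 else coupling(y, t)
    dg_wt + dy + dt_ + di
  })
  kd_true <- exp(dg_true / rt)
  sdlog <- sqrt(log1p(rel_se^2))
  kd_obs <- kd_true * exp(stats::rnorm(length(kd_true), sd = sdlog))
  censored <- kd_true > ceiling_molar

  out <- data.frame(
    yap_variant = grid$yap_variant,
    tead_variant = grid$tead_variant,
    kd_molar = ifelse(censored, NA_real_, kd_obs),
    kd_se_molar = ifelse(censored, NA_real_, rel_se * kd_obs),
    censored = censored
  )
  attr(out, "truth") <- data.frame(grid, dg_true = dg_true,
                                   kd_true = kd_true)
  out
}

#' Simulate a fluorescence thermal-denaturation curve
#'
#' Two-state melt with linearly sloping pre- and post-transition baselines:
#' `F(T) = low(T) + (high(T) - low(T)) / (1 + exp((tm - T)/width))` plus
#' additive Gaussian noise.
#'
#' @param tm Melting temperature, degrees C; must lie inside the scan
#'   range.
#' @param transition_width Transition width, degrees C.
#' @param baseline_low,baseline_high Numeric `c(intercept, slope)` of the
#'   folded and unfolded baselines (intensity, intensity per degree C).
#' @param t_min,t_max,dt Temperature scan range and step, degrees C. The
#'   defaults mirror a 25-85 degree C scan in 0.5 degree increments.
#' @param noise_sd Additive intensity noise (SD).
#' @param seed Optional integer seed.
#' @param label Variant label carried on the curve.
#' @return A `melt_curve` data frame with columns `temperature` and
#'   `intensity`; the true Tm is kept as attribute `truth`.
#' @seealso [fit_tm()]
#' @export
simulate_melt_curve <- function(tm, transition_width = 1.5,
                                baseline_low = c(100, 0.2),
                                baseline_high = c(900, -1.0),
                                t_min = 25, t_max = 85, dt = 0.5,
                                noise_sd = 0, seed = NULL,
                                label = "variant") {
  if (transition_width <= 0) stop("transition_width must be positive")
  if (tm <= t_min || tm >= t_max)
    stop("tm must lie strictly inside the temperature range")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  temp <- seq(t_min, t_max, by = dt)
  low <- baseline_low[1] + baseline_low[2] * temp
  high <- baseline_high[1] + baseline_high[2] * temp
  f <- low + (high - low) / (1 + exp((tm - temp) / transition_width))
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), sd = noise_sd)
  out <- data.frame(temperature = temp, intensity = f)
  attr(out, "truth") <- list(tm = tm, transition_width = transition_width)
  attr(out, "label") <- label
  class(out) <- c("melt_curve", "data.frame")
  out
}
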
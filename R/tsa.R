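#' Fit a melting temperature to a thermal-denaturation curve
#'
#' Fits a two-state Boltzmann sigmoid with linearly sloping baselines,
#' `F(T) = (a1 + b1*T) + (a2 + b2*T - a1 - b1*T) / (1 + exp((Tm - T)/w))`,
#' to a fluorescence melt curve; `Tm` is the transition midpoint
#' (inflection) and its standard error comes from the fit covariance.
#' The post-transition aggregation/quench region, where SYPRO-type dye
#' fluorescence decays again, is trimmed by fitting only up to the global
#' intensity maximum. The fit is invariant to affine rescaling of the
#' intensity axis.
#'
#' @param curve A `melt_curve` (see [simulate_melt_curve()]) or a data
#'   frame with columns `temperature` (degrees C, strictly increasing)
#'   and `intensity`.
#' @return An object of class `tm_fit` with components `tm`, `tm_se`,
#'   `width`, `coef`, `fit` and the (trimmed) data.
#' @export
fit_tm <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("temperature", "intensity") %in% names(curve)))
  temp <- curve$temperature
  intensity <- curve$intensity
  if (length(temp) < 8) stop("melt curve too short to fit")
  if (any(diff(temp) <= 0))
    stop("temperatures must be strictly increasing")

  # trim the post-transition decay: keep everything up to the global max
  imax <- which.max(intensity)
  if (imax < 8) stop("no detectable unfolding transition before decay")
  temp <- temp[1:imax]
  intensity <- intensity[1:imax]

  amp <- max(intensity) - min(intensity)
  if (amp <= .Machine$double.eps)
    stop("no detectable transition: flat curve")
  # noise estimate from second differences; transition must rise above it
  noise <- stats::mad(diff(intensity, differences = 2)) / sqrt(6)
  if (amp < 5 * noise)
    stop("no detectable transition: amplitude below noise")

  # initial Tm from the steepest (smoothed) rise
  n <- length(temp)
  k <- max(3L, min(9L, as.integer(n / 10)))
  sm <- stats::filter(intensity, rep(1 / k, k), sides = 2)
  dsm <- diff(sm) / diff(temp)
  tm0 <- temp[which.max(dsm)]
  w0 <- max(diff(range(temp)) / 40, 0.5)
  nlow <- max(3L, ceiling(n / 10))
  a1_0 <- intensity[1]; b1_0 <- 0
  a2_0 <- intensity[n]; b2_0 <- 0

  d <- data.frame(temperature = temp, intensity = intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ (a1 + b1 * temperature) +
        ((a2 + b2 * temperature) - (a1 + b1 * temperature)) /
        (1 + exp((tm - temperature) / exp(lw))),
      data = d,
      start = list(a1 = a1_0, b1 = b1_0, a2 = a2_0, b2 = b2_0,
                   tm = tm0, lw = log(w0)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) stop("Tm fit failed: ", conditionMessage(e))
  )
  cf <- stats::coef(fit)
  if (cf[["tm"]] < min(temp) || cf[["tm"]] > max(temp))
    stop("Tm fit failed: midpoint outside the scanned range")
  v <- stats::vcov(fit)
  structure(list(tm = cf[["tm"]], tm_se = sqrt(max(0, v["tm", "tm"])),
                 width = exp(cf[["lw"]]), coef = cf, fit = fit, data = d,
                 label = attr(curve, "label")),
            class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("Boltzmann melt fit%s: Tm = %.2f C (SE %.3f C), width %.2f C\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$tm, x$tm_se, x$width))
  invisible(x)
}

#' @export
coef.tm_fit <- function(object, ...) object$coef

#' @export
plot.tm_fit <- function(x, ...) {
  graphics::plot(x$data$temperature, x$data$intensity,
                 xlab = "temperature (C)", ylab = "fluorescence", ...)
  graphics::lines(x$data$temperature, stats::fitted(x$fit), col = 2)
  graphics::abline(v = x$tm, lty = 3)
  invisible(x)
}

#' Derivative-based Tm estimate
#'
#' Midpoint taken as the temperature of the steepest smoothed rise; a
#' model-free cross-check of [fit_tm()].
#'
#' @inheritParams fit_tm
#' @param k Smoothing window (points).
#' @return Tm in degrees C.
#' @export
tm_derivative <- function(curve, k = 5) {
  temp <- curve$temperature
  intensity <- curve$intensity
  imax <- which.max(intensity)
  temp <- temp[1:imax]; intensity <- intensity[1:imax]
  sm <- stats::filter(intensity, rep(1 / k, k), sides = 2)
  d1 <- diff(sm) / diff(temp)
  mid <- (temp[-1] + temp[-length(temp)]) / 2
  mid[which.max(d1)]
}

#' Thermal-stability shift of a mutant against wild type
#'
#' `dTm = Tm_mutant - Tm_wt`, SE by root sum of squares. The mutant is
#' flagged `excluded` when `|dTm|` exceeds the cutoff (default 4 C),
#' the criterion used to discard mutations that destabilize the protein
#' fold too much for meaningful binding measurements.
#'
#' @param mutant,wt `tm_fit` objects, or lists with elements `tm` and
#'   `tm_se`.
#' @param cutoff Exclusion cutoff on `|dTm|`, degrees C.
#' @return A list with `delta_tm`, `delta_tm_se` and `excluded`.
#' @export
delta_tm <- function(mutant, wt, cutoff = 4.0) {
  stopifnot(cutoff >= 0)
  d <- mutant$tm - wt$tm
  se <- sqrt(mutant$tm_se^2 + wt$tm_se^2)
  list(delta_tm = d, delta_tm_se = se, excluded = abs(d) > cutoff)
}

#' Partition mutants by the thermal-stability cutoff
#'
#' @param tm_table Data frame with columns `variant` and `delta_tm`
#'   (degrees C).
#' @param cutoff Exclusion cutoff on `|delta_tm|`, degrees C.
#' @return A list with data frames `retained` and `excluded`.
#' @export
exclude_destabilized <- function(tm_table, cutoff = 4.0) {
  stopifnot(is.data.frame(tm_table),
            all(c("variant", "delta_tm") %in% names(tm_table)),
            cutoff >= 0)
  out <- abs(tm_table$delta_tm) > cutoff
  out[is.na(out)] <- FALSE
  list(retained = tm_table[!out, , drop = FALSE],
       excluded = tm_table[out, , drop = FALSE])
}

#' Mean residue ellipticity from an observed CD signal
#'
#' `[theta]_MRW = MRW * theta / (10 * d * c)` with the mean residue
#' weight `MRW = M / (N - 1)` (M: molecular mass in daltons, N: number
#' of residues), `theta` the observed ellipticity in degrees, `d` the
#' path length in cm and `c` the protein concentration in g/ml.
#'
#' @param theta_obs Observed ellipticity, degrees.
#' @param mw Protein molecular mass, daltons.
#' @param n_residues Number of amino acids (>= 2).
#' @param path_cm Cell path length, cm.
#' @param conc_g_per_ml Protein concentration, g/ml.
#' @return Mean residue ellipticity, deg cm^2 dmol^-1.
#' @export
cd_mean_residue_ellipticity <- function(theta_obs, mw, n_residues,
                                        path_cm, conc_g_per_ml) {
  if (n_residues < 2) stop("n_residues must be at least 2")
  if (mw <= 0 || path_cm <= 0 || conc_g_per_ml <= 0)
    stop("mw, path_cm and conc_g_per_ml must be positive")
  mrw <- mw / (n_residues - 1)
  mrw * theta_obs / (10 * path_cm * conc_g_per_ml)
}
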
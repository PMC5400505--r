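test_that("rmax_theo follows the mass-ratio formula", {
  expect_equal(rmax_theo(100, mw_analyte = 25000, mw_ligand = 25000), 100)
  expect_equal(rmax_theo(1000, mw_analyte = 14000, mw_ligand = 25000), 560)
  expect_equal(rmax_theo(1000, mw_analyte = 14000, mw_ligand = 25000,
                         stoichiometry_n = 2), 1120)
  expect_error(rmax_theo(1000, mw_analyte = 14000, mw_ligand = 0),
               "mw_ligand")
})

test_that("step-3 fit-quality gate applies the 20% SE and 70% Rmax bounds", {
  expect_true(qc_fit_quality(fake_fit(1e-7, 0.19e-7, rmax = 75), 100)$pass)
  q1 <- qc_fit_quality(fake_fit(1e-7, 0.21e-7, rmax = 75), 100)
  expect_false(q1$pass)
  expect_true("kd_se_above_20pct" %in% q1$reasons)
  q2 <- qc_fit_quality(fake_fit(1e-7, 0.1e-7, rmax = 69), 100)
  expect_false(q2$pass)
  expect_true("rmax_below_70pct_theo" %in% q2$reasons)
})

test_that("step-4 saturation requires the top concentration above 10x Kd", {
  sgs <- clean_sensorgrams(18e-9, top_factor = 16)
  expect_true(check_saturation(sgs, fake_fit(18e-9)))   # 288 > 180 nM
  expect_false(check_saturation(sgs, fake_fit(30e-9)))  # 288 < 300 nM
  sgs2 <- clean_sensorgrams(30e-6, top_factor = 16.7)   # top 501 uM
  expect_true(check_saturation(sgs2, fake_fit(30e-6)))
})

test_that("rmax_sat scales the theoretical capacity by surface activity", {
  expect_equal(rmax_sat(560, 100, 100), 560)
  expect_equal(rmax_sat(560, 50, 100), 280)
  expect_error(rmax_sat(560, 100, 0), "positive")
  # a surface with 60% active ligand, estimated from a saturating
  # wild-type run
  kd <- 18e-9
  sgs <- simulate_sensorgram(ka = 0.02 / kd, kd_off = 0.02, rmax = 36,
                             concentrations = kd * c(1, 10, 100, 1000),
                             r_immobilized = 60 * 25000 / 14000)
  rt_theo <- rmax_theo(sgs)  # 60 RU if fully active
  rmax_meas <- fit_kinetics(sgs)$rmax
  expect_equal(rmax_sat(rt_theo, rmax_meas, rt_theo), 0.6 * rt_theo,
               tolerance = 0.02)
})

test_that("global kinetic fit recovers the generating parameters", {
  sgs <- clean_sensorgrams(18e-9)
  fit <- fit_kinetics(sgs)
  expect_equal(fit$kd_eq, 18e-9, tolerance = 1e-3)
  expect_equal(fit$rmax, 60, tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-6)
  # degenerate: flat zero response
  flat <- clean_sensorgrams(18e-9)
  flat$data$response <- 0
  expect_error(fit_kinetics(flat), "fit failed")
  # too narrow a concentration series
  narrow <- simulate_sensorgram(1e5, 1e-3, 60, c(1e-7, 2e-7, 3e-7))
  expect_error(fit_kinetics(narrow), "order of magnitude")
})

test_that("kinetic fit stays within 5% under 1% RU noise", {
  errs <- vapply(1:25, function(i) {
    sgs <- clean_sensorgrams(18e-9, ru_sd = 0.6, seed = 500 + i)
    abs(fit_kinetics(sgs)$kd_eq - 18e-9) / 18e-9
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("automated inspection flags drift, bulk jumps and bad ranges", {
  clean <- clean_sensorgrams(18e-9, ru_sd = 0.6, seed = 21)
  fit <- fit_kinetics(clean)
  expect_true(qc_inspect(clean, fit)$pass)

  drifty <- clean_sensorgrams(18e-9, drift_rate = 0.5)
  q <- qc_inspect(drifty, fit_kinetics(drifty))
  expect_false(q$pass)
  expect_true("unstable_equilibrium" %in% q$reasons)

  bulk <- clean_sensorgrams(18e-9)
  bulk$data$response[bulk$data$phase == "assoc"] <-
    bulk$data$response[bulk$data$phase == "assoc"] + 25
  qb <- qc_inspect(bulk, fit_kinetics(bulk))
  expect_false(qb$pass)
  expect_true("bulk_effect" %in% qb$reasons)

  # concentration-range proxy against a Kd far above the series
  qr <- qc_inspect(clean, fake_fit(1e-5))
  expect_false(qr$pass)
  expect_true("inappropriate_conc_range" %in% qr$reasons)
})

test_that("QC failures are monotone in increasing drift", {
  passes <- vapply(c(0, 0.05, 0.2, 0.5, 1), function(dr) {
    sgs <- clean_sensorgrams(18e-9, drift_rate = dr)
    qc_inspect(sgs, fit_kinetics(sgs))$pass
  }, logical(1))
  expect_true(all(diff(as.integer(passes)) <= 0))
})

test_that("anchored isotherm fit recovers Kd from truncated data", {
  # noiseless, points only up to 20x Kd, exact Rmax_sat
  iso <- simulate_isotherm(5e-6, 60, 0, c(0.5, 1, 2, 5, 10, 25, 100) * 1e-6)
  f <- fit_isotherm(iso, rmax_sat = 60, kd_init = 6e-6)
  expect_true(f$anchored)
  expect_equal(f$kd_eq, 5e-6, tolerance = 0.01)
  expect_lt(f$kd_se / f$kd_eq, 0.10)
  # when data already span 50x Kd the anchor must not bias the fit
  full <- simulate_isotherm(5e-6, 60, 3, 5e-6 * c(0.2, 1, 5, 20, 50, 100))
  fa <- fit_isotherm(full, rmax_sat = 60, kd_init = 5e-6)
  fu <- fit_isotherm(full)
  expect_equal(fa$kd_eq, fu$kd_eq, tolerance = 5e-3)
  expect_error(fit_isotherm(iso[1:3, ]), "at least 4")
  expect_error(fit_isotherm(iso, rmax_sat = 60), "kd_init")
})

test_that("determine_kd routes strong binders through the direct method", {
  sgs <- clean_sensorgrams(18e-9, ru_sd = 0.6, seed = 31)
  res <- determine_kd(sgs)
  expect_s3_class(res, "kd_result")
  expect_identical(res$method, "saturation_direct")
  expect_false(res$censored)
  expect_equal(res$kd_eq, 18e-9, tolerance = 0.05)
  expect_true(res$qc$step2_pass && res$qc$step3_pass && res$qc$step4_pass)
})

test_that("determine_kd routes weak binders through the anchored method", {
  kd <- 80e-6
  sgs <- simulate_sensorgram(ka = 0.02 / kd, kd_off = 0.02, rmax = 60,
                             concentrations = c(2, 10, 50, 150, 500) * 1e-6,
                             ru_sd = 0.6, seed = 32)
  ref <- list(rmax_meas = 60, rmax_theo = rmax_theo(sgs))
  res <- determine_kd(sgs, wt_reference = ref)
  expect_identical(res$method, "rmax_sat_anchored")
  expect_equal(res$kd_eq, kd, tolerance = 0.10)
  expect_false(res$qc$step4_pass)
  expect_true(res$qc$step5_pass)
  # without the wild-type reference the weak pair cannot be analyzed
  res2 <- determine_kd(sgs)
  expect_true(is.na(res2$kd_eq))
  expect_true("no_wt_reference_for_rmax_sat" %in% res2$qc$reasons)
})

test_that("determine_kd censors pairs beyond the 200 uM ceiling", {
  kd <- 4e-4
  sgs <- simulate_sensorgram(ka = 0.02 / kd, kd_off = 0.02, rmax = 60,
                             concentrations = c(2, 10, 50, 150, 500) * 1e-6,
                             ru_sd = 0.6, seed = 33)
  ref <- list(rmax_meas = 60, rmax_theo = rmax_theo(sgs))
  res <- determine_kd(sgs, wt_reference = ref)
  expect_true(res$censored)
  expect_true(is.na(res$kd_eq))
})

test_that("sensorgram CSV round trip preserves data and metadata", {
  sgs <- clean_sensorgrams(18e-9, ru_sd = 0.6, seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensorgrams(sgs, path)
  back <- read_sensorgrams(path)
  expect_equal(back$data$response, sgs$data$response)
  expect_equal(back$r_immobilized, sgs$r_immobilized)
  expect_equal(back$t_assoc, sgs$t_assoc)
  expect_equal(rmax_theo(back), rmax_theo(sgs))
})
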
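test_that("noiseless sensorgrams obey the 1:1 closed-form identities", {
  kd <- 18e-9
  # at C = Kd the association plateau is Rmax/2
  sgs <- simulate_sensorgram(ka = 1e5, kd_off = 1.8e-3, rmax = 80,
                             concentrations = kd, t_assoc = 20000,
                             t_dissoc = 100, dt = 50)
  a <- sgs$data[sgs$data$phase == "assoc", ]
  expect_equal(max(a$response), 40, tolerance = 1e-6)
  # one dissociation half-life halves the end-of-injection response
  koff <- 1.8e-3
  sgs2 <- simulate_sensorgram(ka = 1e5, kd_off = koff, rmax = 80,
                              concentrations = 1e-6, t_assoc = 10000,
                              t_dissoc = 2 * log(2) / koff,
                              dt = log(2) / koff)
  d <- sgs2$data[sgs2$data$phase == "dissoc", ]
  r_end <- max(sgs2$data$response[sgs2$data$phase == "assoc"])
  expect_equal(d$response[d$time == log(2) / koff], r_end / 2,
               tolerance = 1e-9)
})

test_that("closed-form association matches numerical integration of the ODE", {
  skip_if_not_installed("deSolve")
  ka <- 1e5; koff <- 1.8e-3; rmax <- 60; conc <- 500e-9
  sgs <- simulate_sensorgram(ka, koff, rmax, conc, t_assoc = 200,
                             t_dissoc = 50, dt = 1)
  a <- sgs$data[sgs$data$phase == "assoc", ]
  ode <- deSolve::lsoda(
    c(R = 0), times = c(0, a$time),
    func = function(t, y, p) list(ka * conc * (rmax - y[1]) - koff * y[1]),
    parms = NULL, rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(a$response - ode[-1, "R"])), 1e-6)
  # high above Kd the plateau approaches Rmax
  sat <- simulate_sensorgram(ka, koff, rmax, 1000 * koff / ka,
                             t_assoc = 5000, t_dissoc = 10, dt = 10)
  expect_equal(max(sat$data$response), rmax, tolerance = 2e-3)
})

test_that("simulated isotherms follow one-site binding with background", {
  iso <- simulate_isotherm(1e-7, 50, 5, c(1e-9, 1e-7))
  expect_equal(iso$response[2], 30)           # C = Kd: Rmax/2 + bg
  expect_equal(iso$response[1], 5, tolerance = 0.5)  # C -> 0: background
  expect_error(simulate_isotherm(1e-7, 50, 5, 1e-7, rel_noise = -0.1),
               "non-negative")
})

test_that("simulators are deterministic under a fixed seed", {
  s1 <- simulate_sensorgram(1e5, 1e-2, 60, c(1e-7, 1e-6), ru_sd = 1,
                            seed = 42)
  s2 <- simulate_sensorgram(1e5, 1e-2, 60, c(1e-7, 1e-6), ru_sd = 1,
                            seed = 42)
  expect_identical(s1$data, s2$data)
  p1 <- simulate_panel(-10, c(a = 2), c(b = 2), rel_se = 0.15, seed = 7)
  p2 <- simulate_panel(-10, c(a = 2), c(b = 2), rel_se = 0.15, seed = 7)
  expect_identical(p1$kd_molar, p2$kd_molar)
  m1 <- simulate_melt_curve(54, noise_sd = 3, seed = 9)
  m2 <- simulate_melt_curve(54, noise_sd = 3, seed = 9)
  expect_identical(m1$intensity, m2$intensity)
})

test_that("additive noiseless panels are exactly multiplicative in Kd", {
  panel <- simulate_panel(-10.56,
                          ddg_yap = c(y1 = 2.2, y2 = 1.4, y3 = 2.6),
                          ddg_tead = c(t1 = 1.2, t2 = 2.2),
                          rel_se = 0, seed = 1)
  kd <- function(y, t) panel$kd_molar[panel$yap_variant == y &
                                        panel$tead_variant == t]
  for (y in c("y1", "y2", "y3")) for (t in c("t1", "t2")) {
    expect_equal(kd(y, t) * kd("wt", "wt"), kd(y, "wt") * kd("wt", t),
                 tolerance = 1e-12)
  }
  cycles <- coupling_energy(enumerate_cycles(panel, c("y1", "y2", "y3"),
                                             c("t1", "t2")))
  expect_true(all(abs(cycles$ddg_int) < 1e-9))
})

test_that("panels censor pairs whose true Kd exceeds the assay ceiling", {
  # 4.4 + 4.4 puts the double mutant near millimolar
  panel <- simulate_panel(-10.56, c(y = 4.4), c(t = 4.4), rel_se = 0.1,
                          seed = 3)
  mm <- panel[panel$yap_variant == "y" & panel$tead_variant == "t", ]
  expect_true(mm$censored)
  expect_true(is.na(mm$kd_molar))
  truth <- attr(panel, "truth")
  expect_true(all((truth$kd_true > 2e-4) ==
                    panel$censored[match(paste(truth$yap_variant,
                                               truth$tead_variant),
                                         paste(panel$yap_variant,
                                               panel$tead_variant))]))
})

test_that("an injected coupling is recovered exactly at zero noise", {
  panel <- simulate_panel(-10.56, c(R89A = 4.34), c(D272A = 3.53),
                          ddg_int = data.frame(yap = "R89A",
                                               tead = "D272A",
                                               ddg_int = -3.49),
                          rel_se = 0, seed = 1)
  cyc <- coupling_energy(enumerate_cycles(panel, "R89A", "D272A"))
  expect_equal(cyc$ddg_int, -3.49, tolerance = 1e-9)
  expect_error(simulate_panel(-10, c(a = 1), c(b = 1), rel_se = 0.2),
               "0.15")
  expect_error(simulate_panel(10, c(a = 1), c(b = 1)), "negative")
})

test_that("panel noise propagates to the analytic coupling SE", {
  ests <- vapply(1:100, function(i) {
    panel <- simulate_panel(-10.56, c(y = 2.0), c(t = 2.0),
                            rel_se = 0.15, seed = 100 + i)
    coupling_energy(enumerate_cycles(panel, "y", "t"))$ddg_int
  }, numeric(1))
  # analytic propagation: RT * 0.15 * sqrt(4) = 0.178 kcal/mol
  expect_equal(sd(ests), 0.178, tolerance = 0.2)
  expect_equal(mean(ests), 0, tolerance = 0.06)
})

test_that("melt curves hit the baseline midpoint at Tm and validate inputs", {
  mc <- simulate_melt_curve(55, 1.5, baseline_low = c(100, 0),
                            baseline_high = c(900, 0), dt = 0.5)
  expect_equal(mc$intensity[mc$temperature == 55], 500)
  expect_error(simulate_melt_curve(90), "range")
  expect_error(simulate_melt_curve(54, transition_width = -1), "positive")
})
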
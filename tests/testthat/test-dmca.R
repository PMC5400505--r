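test_that("mutant selection applies the 1 kcal/mol rule to the printed tables", {
  yap <- single_mutant_energies(reconstructed_panel(), "yap")
  tead <- single_mutant_energies(reconstructed_panel(), "tead")
  expect_equal(nrow(select_mutants(yap)), 9)
  sel_t <- select_mutants(tead)
  expect_equal(nrow(sel_t), 7)
  expect_false(any(c("Tyr429Phe", "Phe373Ala", "Val414Ala")
                   %in% sel_t$variant))
  # negative-ddG variants stay excluded even at threshold 0
  sel0 <- select_mutants(tead, threshold = 0)
  expect_false(any(c("Phe373Ala", "Val414Ala") %in% sel0$variant))
  expect_true("Tyr429Phe" %in% sel0$variant)
  expect_equal(nrow(select_mutants(yap, threshold = Inf)), 0)
  expect_error(select_mutants(yap[0, ]), "empty")
})

test_that("cycle enumeration reproduces the published combinatorics", {
  panel <- reconstructed_panel()
  yaps <- select_mutants(single_mutant_energies(panel, "yap"))$variant
  teads <- select_mutants(single_mutant_energies(panel, "tead"))$variant
  cycles <- enumerate_cycles(panel, yaps, teads)
  expect_equal(nrow(cycles), 63)
  expect_equal(attr(cycles, "n_kd_consumed"), 80)
  expect_equal(sum(cycles$mm_censored), 7)
  # a single pair consumes 4 Kd values
  one <- enumerate_cycles(panel, "Arg89Ala", "Asp272Ala")
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "n_kd_consumed"), 4)
  expect_error(enumerate_cycles(panel, "NoSuchMutant", "Asp272Ala"),
               "NoSuchMutant")
})

test_that("coupling energy satisfies the leg identities exactly", {
  set.seed(11)
  for (i in 1:20) {
    kds <- 10^runif(4, -8, -4)
    panel <- data.frame(
      yap_variant = c("wt", "mY", "wt", "mY"),
      tead_variant = c("wt", "wt", "mT", "mT"),
      kd_molar = kds, kd_se_molar = 0.1 * kds, censored = FALSE)
    cyc <- coupling_energy(enumerate_cycles(panel, "mY", "mT"))
    expect_equal(cyc$ddg_2 - cyc$ddg_1, cyc$ddg_int, tolerance = 1e-12)
    expect_equal(cyc$ddg_4 - cyc$ddg_3, cyc$ddg_int, tolerance = 1e-12)
    # independent brute-force recomputation straight from the Kd values
    expect_equal(cyc$ddg_int,
                 brute_force_coupling(kds[1], kds[2], kds[3], kds[4]),
                 tolerance = 1e-10)
    expect_equal(cyc$ddg_int_se,
                 rt_kcal() * 0.1 * 2, tolerance = 1e-10)
  }
})

test_that("coupling energy is symmetric in which protein is mutated first", {
  panel <- simulate_panel(-10.56, c(y1 = 2.5, y2 = 3.2), c(t1 = 1.8),
                          ddg_int = data.frame(yap = "y1", tead = "t1",
                                               ddg_int = -1.2),
                          rel_se = 0.1, seed = 5)
  fwd <- coupling_energy(enumerate_cycles(panel, c("y1", "y2"), "t1"))
  swapped <- data.frame(yap_variant = panel$tead_variant,
                        tead_variant = panel$yap_variant,
                        panel[, c("kd_molar", "kd_se_molar", "censored")])
  rev <- coupling_energy(enumerate_cycles(swapped, "t1", c("y1", "y2")))
  expect_equal(sort(fwd$ddg_int), sort(rev$ddg_int), tolerance = 1e-12)
})

test_that("the Arg89:Asp272 cycle matches the published coupling", {
  cyc <- arg89_asp272_cycle()
  expect_equal(cyc$ddg_int, -3.49, tolerance = 0.02)
  expect_equal(cyc$ddg_2, 0.85, tolerance = 0.02)
  expect_equal(cyc$ddg_4, 0.04, tolerance = 1e-9)
  expect_identical(as.character(cyc$coupling_class), "favorable")
})

test_that("classification uses the 0.5 kcal/mol significance band", {
  mk <- function(v) data.frame(ddg_int = v, mm_censored = is.na(v))
  cls <- function(v, sig = 0.5)
    as.character(classify_coupling(mk(v), sig)$coupling_class)
  expect_identical(cls(-3.49), "favorable")
  expect_identical(cls(-0.44), "additive")
  expect_identical(cls(0), "additive")
  expect_identical(cls(0.5), "additive")    # band is exclusive
  expect_identical(cls(-0.5), "additive")
  expect_identical(cls(0.51), "unfavorable")
  expect_identical(cls(NA_real_), "not_measurable")
})

test_that("back-prediction flags which censored pairs were decidable", {
  fit <- dmca(reconstructed_panel())
  pred <- predict(fit)
  expect_equal(nrow(pred), 7)
  key <- paste(pred$yap, pred$tead)
  named <- c("Leu91Ala Phe337Ala", "Phe95Ala Phe337Ala",
             "Leu65Ala Asp272Ala")
  expect_true(all(pred$kd_calc_molar[key %in% named] <= 150e-6))
  expect_true(all(pred$within_assay[key %in% named]))
  # Phe69:Asp272 and Leu91:Val389 predict beyond the ceiling
  expect_false(pred$within_assay[key == "Phe69Ala Asp272Ala"])
  expect_false(pred$within_assay[key == "Leu91Ala Val389Ala"])
  # neutral assumption on an all-wild-type-like cycle returns wt Kd
  wtish <- data.frame(yap = "y", tead = "t", dg_ww = -10.554,
                      dg_mw = -10.554, dg_wm = -10.554)
  expect_equal(predict_kd_calc(wtish, assumed_ddg_int = 0)$kd_calc_molar,
               kd_from_delta_g(-10.554), tolerance = 1e-12)
})

test_that("replicate panel rows are averaged with pooled SEs", {
  panel <- data.frame(
    yap_variant = c("wt", "wt", "mY", "wt", "mY"),
    tead_variant = c("wt", "wt", "wt", "mT", "mT"),
    kd_molar = c(16e-9, 20e-9, 800e-9, 400e-9, 8e-6),
    kd_se_molar = c(2e-9, 2e-9, 40e-9, 20e-9, 4e-7),
    censored = FALSE)
  cyc <- enumerate_cycles(panel, "mY", "mT")
  dg_ww <- delta_g(18e-9, sqrt(2 * 4e-18) / 2)
  expect_equal(cyc$dg_ww, dg_ww$value, tolerance = 1e-12)
  expect_equal(cyc$se_ww, dg_ww$se, tolerance = 1e-12)
})

test_that("the coupling matrix lays out cycles with n.m. markers", {
  fit <- dmca(reconstructed_panel())
  m <- coef(fit)
  expect_equal(dim(m), c(7, 9))
  expect_equal(m["Asp272Ala", "Arg89Ala"], -3.49, tolerance = 0.02)
  expect_identical(fit$matrix$formatted["Asp272Ala", "Leu65Ala"], "n. m.")
  expect_equal(sum(is.na(m)), 7)
  # printed couplings are reproduced from the reconstructed panel
  # (a consistency check of the cycle arithmetic, not a validation of
  # the raw data, which the packaged panel is back-derived from)
  cpl <- printed_couplings()
  for (i in which(cpl$measurable == 1)) {
    expect_equal(m[cpl$tead_variant[i], cpl$yap_variant[i]],
                 cpl$ddg_int[i], tolerance = 0.02)
  }
})

test_that("dmca methods print, summarize and plot without error", {
  fit <- dmca(reconstructed_panel())
  expect_output(print(fit), "63 cycles")
  expect_output(print(summary(fit)), "n. m.")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
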
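panel <- builtin_panel()

test_that("normalized response and single-point quantification are exact ratios", {
  expect_equal(normalized_response(1000, 2000), 0.5)
  expect_equal(normalized_response(0, 2000), 0)
  expect_error(normalized_response(100, 0), class = "evmrm_normalization_error")

  expect_equal(quantify_single_point(0.5, 10), 5)
  expect_equal(quantify_single_point(1.0, 0.2), 0.2)
  expect_error(quantify_single_point(1, 0), class = "evmrm_normalization_error")

  # noiseless simulation: exact recovery of a known concentration
  prm <- noiseless_params()
  inj <- simulate_injection(panel, sample_spec("qEV35", endogenous = c(CANX = 0.37)),
                            prm, chromatograms = FALSE)
  a <- inj$areas
  light <- a$area[a$analyte_id == "CANX" & a$form == "light" & a$role == "quantifier"]
  sil <- a$area[a$analyte_id == "CANX" & a$form == "SIL" & a$role == "quantifier"]
  expect_equal(quantify_single_point(normalized_response(light, sil), 0.2),
               0.37, tolerance = 1e-12)
})

test_that("calibration fit is unweighted OLS with r-squared", {
  lv <- data.frame(nominal_conc = c(1, 2, 3), normalized_response = c(1, 2, 3))
  fit <- fit_calibration(lv)
  expect_equal(unname(coef(fit)), c(0, 1))
  expect_equal(fit$r2, 1)
  expect_equal(fit$uloq, 3)

  # matches lm on noisy points
  set.seed(2)
  lv2 <- data.frame(nominal_conc = rep(1:8, each = 3))
  lv2$normalized_response <- 0.05 + 0.3 * lv2$nominal_conc + rnorm(24, 0, 0.02)
  fit2 <- fit_calibration(lv2, analyte_id = "ALB")
  ref <- lm(normalized_response ~ nominal_conc, lv2)
  expect_equal(coef(fit2)[["slope"]], unname(coef(ref)[2]))
  expect_equal(fit2$r2, summary(ref)$r.squared)
  expect_equal(unname(residuals(fit2)), unname(residuals(ref)))
  expect_equal(predict(fit2, 10), unname(predict(ref, data.frame(nominal_conc = 10))))

  expect_error(fit_calibration(lv[1:2, ]), class = "evmrm_insufficient_data")
  expect_error(fit_calibration(data.frame(nominal_conc = c(1, 1, 1),
                                          normalized_response = 1:3)),
               class = "evmrm_insufficient_data")

  s <- summary(fit2)
  expect_s3_class(s, "summary.ev_calibration")
  expect_equal(nrow(s$back_calculated), 24)
})

test_that("quantification from the curve censors against LOD/LLOQ/ULOQ", {
  curve <- structure(list(analyte_id = "ALB", matrix_id = "qEV70",
                          slope = 0.1, intercept = 0, r2 = 1, uloq = 80,
                          levels = data.frame(), weighting = "none"),
                     class = "ev_calibration")
  q <- quantify_from_curve(curve, 1.0, lod = 0.02, lloq = 0.1)
  expect_equal(q$concentration, 10)
  expect_equal(q$censor, "quantified")

  # response at 4x LOD with LLOQ = 5x LOD: detected but below quantification
  q2 <- quantify_from_curve(curve, 0.1 * 4 * 0.02, lod = 0.02, lloq = 0.1)
  expect_equal(q2$concentration, 4 * 0.02)
  expect_equal(q2$censor, "below_LLOQ")

  q3 <- quantify_from_curve(curve, 0.1 * 100, lod = 0.02, lloq = 0.1)
  expect_equal(q3$censor, "above_ULOQ")
  expect_equal(q3$concentration, 100)  # numeric kept despite the flag

  q4 <- quantify_from_curve(curve, 0.1 * 0.001, lod = 0.02, lloq = 0.1)
  expect_equal(q4$censor, "below_LOD")

  bad <- curve; bad$slope <- -1
  expect_error(quantify_from_curve(bad, 1, 0.02, 0.1),
               class = "evmrm_invalid_curve")
  expect_error(quantify_from_curve(curve, 1, 0.1, 0.02),
               class = "evmrm_invalid_curve")
})

test_that("censor labels partition concentration monotonically", {
  curve <- structure(list(analyte_id = "X", matrix_id = NA, slope = 1,
                          intercept = 0, r2 = 1, uloq = 10,
                          levels = data.frame(), weighting = "none"),
                     class = "ev_calibration")
  concs <- c(0.001, 0.0199, 0.02, 0.05, 0.0999, 0.1, 5, 10, 10.0001, 50)
  labels <- quantify_from_curve(curve, concs, lod = 0.02, lloq = 0.1)$censor
  order_map <- c(below_LOD = 1, below_LLOQ = 2, quantified = 3, above_ULOQ = 4)
  expect_true(all(diff(order_map[labels]) >= 0))
  expect_equal(labels[3], "below_LLOQ")   # conc == LOD leaves the LOD bin
  expect_equal(labels[6], "quantified")   # conc == LLOQ is quantifiable
  expect_equal(labels[8], "quantified")   # conc == ULOQ still quantifiable
})

test_that("curve quantification inverts simulated truth in any matrix", {
  prm <- noiseless_params()
  for (m in c("qEV70", "ExoQuick")) {
    ser <- simulate_calibration_series(panel, matrix_id = m, replicates = 1,
                                       params = prm, analytes = "CD9")
    fit <- fit_calibration_series(ser)$CD9
    for (conc in c(0.05, 0.2, 0.6)) {
      resp <- fit$intercept + fit$slope * conc
      q <- quantify_from_curve(fit, resp, lod = 0.005, lloq = 0.025)
      expect_lt(abs(q$concentration - conc) / conc, 0.02)
      # single-point agrees with the curve when the intercept vanishes
      sp <- quantify_single_point(resp, 0.1)
      expect_lt(abs(sp - q$concentration) / q$concentration, 0.05)
    }
  }
})

test_that("quantify_areas applies per-method sensitivity limits", {
  st <- simulate_replicate_study(study_design(), params = noiseless_params())
  sens <- do.call(rbind, lapply(c("qEV70", "qEV35", "ExoQuick"), function(m)
    sens_table(c("ALB", "CD81", "CD9", "CANX", "TSG101"),
               c(0.004, 0.05, 0.005, 0.007, 0.006), method = m)))
  q <- quantify_areas(st$areas, sens)
  expect_true(all(q$concentration[q$analyte_id == "ALB"] > 0))
  # TSG101 in SEC isolates sits below LLOQ; quantifiable in precipitation
  expect_true(all(q$censor[q$analyte_id == "TSG101" & q$method == "qEV70"] ==
                    "below_LLOQ"))
  expect_true(all(q$censor[q$analyte_id == "TSG101" & q$method == "ExoQuick"] ==
                    "quantified"))
})
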
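panel <- builtin_panel()

test_that("LOD comes from the 3:1 S/N rule and LLOQ is five times it", {
  # closed form: snr(c) = 600 c -> lod = 3/600 = 0.005, lloq = 0.025
  tab <- data.frame(nominal_conc = rep(c(0.02, 0.04, 0.06), each = 3))
  tab$snr <- 600 * tab$nominal_conc
  sens <- estimate_lod_lloq(tab, analyte_id = "CD9")
  expect_equal(sens$lod, 0.005)
  expect_equal(sens$lloq, 0.025)
  expect_equal(sens$lloq / sens$lod, 5)

  # the rule reproduces the published ALB pair
  expect_equal(5 * 0.004, 0.020)

  # levels above the lowest three never enter the fit
  tab2 <- rbind(tab, data.frame(nominal_conc = 10, snr = 1))
  expect_equal(estimate_lod_lloq(tab2)$lod, 0.005)

  expect_error(estimate_lod_lloq(data.frame(nominal_conc = c(1, 2), snr = c(0, 0))),
               class = "evmrm_sensitivity_indeterminate")
  expect_error(estimate_lod_lloq(data.frame(nominal_conc = 1, snr = 5)),
               class = "evmrm_insufficient_data")
})

test_that("doubling the instrument noise doubles the estimated LOD", {
  lod_at_noise <- function(noise_sd, seed) {
    prm <- sim_params(noise_sd = noise_sd, rt_jitter_sd = 0, cv_injection = 0)
    lv <- default_calibrators(panel)$CD9[1:3]
    set.seed(seed)
    rows <- list()
    for (conc in lv) for (r in 1:3) {
      tr <- quant_transition(panel, "CD9")
      area <- prm$response_factor[["CD9"]] * conc * 0.57  # qEV70 suppression
      ch <- simulate_chromatogram(tr, area, prm)
      pk <- detect_and_integrate(ch, 24.3)
      rows[[length(rows) + 1]] <- data.frame(nominal_conc = conc, snr = pk$snr)
    }
    estimate_lod_lloq(do.call(rbind, rows))$lod
  }
  l1 <- lod_at_noise(10, 21)
  l2 <- lod_at_noise(20, 22)
  expect_gt(l2 / l1, 1.6)
  expect_lt(l2 / l1, 2.6)
  # and the absolute scale matches the validated CD9 limit
  expect_lt(abs(l1 - 0.005) / 0.005, 0.35)
})

test_that("slope precision splits within-day and between-day variability", {
  sl <- data.frame(day = rep(1:3, each = 3), slope = rep(c(9, 10, 11), 3))
  pr <- slope_precision(sl)
  expect_equal(unname(pr$intraday_rsd), rep(10, 3))  # SD 1, mean 10
  expect_equal(pr$interday_rsd, 0)                   # day means identical

  sl2 <- data.frame(day = rep(1:3, each = 2),
                    slope = c(10, 10, 12, 12, 8, 8))
  pr2 <- slope_precision(sl2)
  expect_equal(unname(pr2$intraday_rsd), rep(0, 3))
  expect_equal(pr2$interday_rsd, 20)

  expect_error(slope_precision(data.frame(day = 1, slope = 1)),
               class = "evmrm_precision_indeterminate")
  expect_error(slope_precision(data.frame(day = c(1, 1, 1), slope = c(1, 2, 3))),
               class = "evmrm_precision_indeterminate")
})

test_that("repeatability is the %RSD of five consecutive injections", {
  expect_equal(repeatability_rsd(rep(2, 5)), 0)
  expect_equal(repeatability_rsd(c(1, 1, 1, 1, 2)),
               100 * sd(c(1, 1, 1, 1, 2)) / 1.2)  # 37.27, sample SD
  expect_warning(r <- repeatability_rsd(c(1, 2, 3)), "5 consecutive")
  expect_equal(r, pct_rsd(1:3))
})

test_that("%RSD is scale invariant", {
  x <- c(3.1, 2.8, 3.4, 2.9, 3.2)
  for (k in c(0.01, 1, 250)) {
    expect_equal(pct_rsd(k * x), pct_rsd(x), tolerance = 1e-12)
  }
})

test_that("accuracy reproduces the published % True worked examples", {
  expect_equal(accuracy_percent_true(0.2, 0.232)$percent_true, 116)
  expect_equal(accuracy_percent_true(0.06, 0.063)$percent_true, 105)
  expect_equal(accuracy_percent_true(0.2, 0.212)$percent_true, 106)
  expect_equal(accuracy_percent_true(7, 7)$percent_true, 100)
  expect_error(accuracy_percent_true(0, 1), class = "evmrm_config_error")
})

test_that("carryover classification follows the three-bin rule", {
  sens <- list(analyte_id = "ALB", lod = 0.004, lloq = 0.020)
  blanks <- data.frame(analyte_id = "ALB", blank_index = 1:3,
                       conc_equivalent = c(4 * 0.004, 0, 0.020))
  res <- assess_carryover(blanks, sens)
  expect_equal(res$classification, c("detectable", "none", "quantifiable"))

  # monotone in response; decaying carryover never escalates the class
  rank <- c(none = 1, detectable = 2, quantifiable = 3)
  seqres <- assess_carryover(data.frame(
    analyte_id = "ALB", blank_index = 1:2,
    conc_equivalent = c(0.016, 0.016 * 2e-4 / 1)), sens)
  expect_true(rank[seqres$classification[2]] <= rank[seqres$classification[1]])

  # end-to-end: default carryover puts ALB blank 1 at 4x LOD -> detectable
  sq <- simulate_carryover_sequence(panel, n_blanks = 2,
                                    params = sim_params(cv_injection = 0))
  alb <- sq[sq$analyte_id == "ALB" & sq$injection > 0, ]
  res2 <- assess_carryover(data.frame(analyte_id = "ALB",
                                      blank_index = alb$injection,
                                      conc_equivalent = alb$conc_equivalent),
                           sens)
  expect_equal(res2$conc_equivalent[1], 4 * sens$lod)
  expect_equal(res2$classification, c("detectable", "none"))
})

test_that("stability applies the strict 20% change rule on duplicate means", {
  tc <- data.frame(analyte_id = "ALB", temperature = 15,
                   timepoint_h = rep(c(0, 6, 24), each = 2),
                   concentration = c(1, 1, 1.02, 0.98, 1.26, 1.26))
  st <- assess_stability(tc)
  expect_equal(st$stable, c(TRUE, TRUE, FALSE))
  expect_equal(st$percent_change_from_baseline[3], 26, tolerance = 1e-9)

  # exactly -20% is NOT stable (rule is strictly below 20)
  tc2 <- data.frame(analyte_id = "X", temperature = 4,
                    timepoint_h = rep(c(0, 48), each = 2),
                    concentration = c(1, 1, 0.8, 0.8))
  st2 <- assess_stability(tc2)
  expect_false(st2$stable[st2$timepoint_h == 48])
  expect_equal(st2$percent_change_from_baseline[2], -20)
  expect_equal(st2$duplicate_rsd, c(0, 0))

  expect_error(assess_stability(data.frame(analyte_id = "X", temperature = 4,
                                           timepoint_h = 6, concentration = 1)),
               class = "evmrm_stability_indeterminate")
})

test_that("matrix recovery is the slope ratio with the right reference type", {
  mk_curve <- function(slope, matrix_id, aid = "TSG101")
    structure(list(analyte_id = aid, matrix_id = matrix_id, slope = slope,
                   intercept = 0, r2 = 1, uloq = 1, levels = data.frame(),
                   weighting = "none"), class = "ev_calibration")
  expect_equal(recovery_percent(mk_curve(1, "qEV70"),
                                mk_curve(1, "mobile_phase"))$recovery_percent, 100)
  r <- recovery_percent(mk_curve(1.64, "qEV35"), mk_curve(1.0, "qEV70"))
  expect_equal(r$recovery_percent, 164)
  expect_equal(r$reference_type, "relative")
  expect_equal(recovery_percent(mk_curve(0.38, "qEV70"),
                                mk_curve(1, "mobile_phase"))$reference_type,
               "absolute")
  expect_error(recovery_percent(mk_curve(1, "qEV35"), mk_curve(0, "qEV70")),
               class = "evmrm_invalid_reference")
  expect_error(recovery_percent(mk_curve(1, "qEV35", "ALB"),
                                mk_curve(1, "qEV70", "CD9")),
               class = "evmrm_config_error")
})

test_that("recovery estimation is unbiased over seeded simulations", {
  # 500-seed Monte Carlo: mean estimated absolute recovery within 2 points
  # of the configured suppression for CD81 in ExoQuick (13%)
  prm <- sim_params(cv_injection = 0.02)
  set.seed(77)
  recs <- replicate(500, {
    mat <- simulate_sil_recovery_series(panel, matrix_id = "ExoQuick",
                                        params = prm, analytes = "CD81")
    ref <- simulate_sil_recovery_series(panel, matrix_id = "mobile_phase",
                                        params = prm, analytes = "CD81")
    recovery_percent(fit_sil_response_curves(mat)$CD81,
                     fit_sil_response_curves(ref)$CD81)$recovery_percent
  })
  expect_lt(abs(mean(recs) - 13), 2)
})

test_that("matrix-adjusted limits rescale only beyond the 20% band", {
  sens <- structure(list(analyte_id = "CD81", matrix_id = "qEV70",
                         lod = 0.05, lloq = 0.25, snr_slope = 60),
                    class = "ev_sensitivity")
  # within band (91% relative recovery in qEV35): unchanged
  same <- adjust_limits_for_matrix(sens, 91)
  expect_equal(same$lod, 0.05)
  expect_false(same$adjusted)
  expect_equal(adjust_limits_for_matrix(sens, 100)$lod, 0.05)

  # 22% relative recovery (ExoQuick): limits scale up by 1/0.22
  adj <- adjust_limits_for_matrix(sens, 22)
  expect_true(adj$adjusted)
  expect_equal(adj$lod, 0.05 / 0.22, tolerance = 1e-12)
  expect_equal(adj$lod, 0.227, tolerance = 0.01)
  expect_equal(adj$lloq / adj$lod, 5)

  expect_error(adjust_limits_for_matrix(sens, 0), class = "evmrm_config_error")
})

test_that("simulated slope precision sits in the validated range", {
  # triplicate curves on three days at the default injection noise
  prm <- sim_params(cv_injection = 0.02)
  set.seed(55)
  ok <- replicate(20, {
    slopes <- do.call(rbind, lapply(1:3, function(day) {
      data.frame(day = day, slope = vapply(1:3, function(r) {
        ser <- simulate_calibration_series(panel, replicates = 1, params = prm,
                                           analytes = "CD81")
        fit_calibration_series(ser)$CD81$slope
      }, numeric(1)))
    }))
    pr <- slope_precision(slopes)
    pr$intraday_rsd_pooled <= 13 && pr$interday_rsd <= 8
  })
  expect_gte(mean(ok), 0.9)
})
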
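panel <- builtin_panel()

test_that("simulated chromatograms have the configured signal model", {
  tr <- quant_transition(panel, "ALB")
  prm <- sim_params(rt_jitter_sd = 0)

  # zero area: trace is baseline + noise
  ch <- simulate_chromatogram(tr, 0, prm, seed = 11)
  n <- length(ch$times)
  expect_lt(abs(mean(ch$intensities) - prm$baseline),
            3 * prm$noise_sd / sqrt(n))
  expect_lt(abs(stats::sd(ch$intensities) - prm$noise_sd), 3)

  # noiseless trace integrates to the true area (analytic Gaussian oracle)
  prm0 <- noiseless_params()
  ch0 <- simulate_chromatogram(tr, 100, prm0, seed = 1)
  riemann <- sum((ch0$intensities - prm0$baseline)[-1] * diff(ch0$times))
  expect_lt(abs(riemann - 100) / 100, 0.001)

  # determinism
  a <- simulate_chromatogram(tr, 50, prm, seed = 99)
  b <- simulate_chromatogram(tr, 50, prm, seed = 99)
  expect_identical(a, b)
})

test_that("injection areas follow response x concentration x suppression", {
  prm <- noiseless_params()

  # mobile phase, no suppression: area = response_factor x conc exactly
  inj <- simulate_injection(panel, sample_spec("mobile_phase",
                                               endogenous = c(ALB = 5)),
                            prm, seed = 1, chromatograms = FALSE)
  a <- inj$areas
  alb_quant <- a[a$analyte_id == "ALB" & a$form == "light" &
                   a$role == "quantifier", ]
  expect_equal(alb_quant$area, prm$response_factor[["ALB"]] * 5)

  # ExoQuick suppresses CD81 to 13% of the mobile-phase response
  spec_mp <- sample_spec("mobile_phase", endogenous = c(CD81 = 1))
  spec_eq <- sample_spec("ExoQuick", endogenous = c(CD81 = 1))
  sil_mp <- simulate_injection(panel, spec_mp, prm, chromatograms = FALSE)$areas
  sil_eq <- simulate_injection(panel, spec_eq, prm, chromatograms = FALSE)$areas
  pick <- function(a) a$area[a$analyte_id == "CD81" & a$form == "SIL" &
                               a$role == "quantifier"]
  expect_equal(pick(sil_eq) / pick(sil_mp), 0.13)

  # zero endogenous and supplement: light quantifier carries no signal
  inj0 <- simulate_injection(panel, sample_spec("qEV70"), prm,
                             chromatograms = FALSE)
  l0 <- inj0$areas[inj0$areas$form == "light", ]
  expect_true(all(l0$area == 0))
  s0 <- inj0$areas[inj0$areas$form == "SIL" & inj0$areas$role == "quantifier", ]
  expect_true(all(s0$area > 0))

  # qualifier areas are the configured fractions of the quantifier
  alb_light <- a[a$analyte_id == "ALB" & a$form == "light", ]
  expect_equal(sort(alb_light$area[alb_light$role == "qualifier"] /
                      alb_light$area[alb_light$role == "quantifier"]),
               sort(prm$qualifier_ratios$ALB))

  expect_error(simulate_injection(panel, structure(
    list(matrix_id = "vacuum", endogenous = c(), sil = NULL,
         light_supplement = c()), class = "ev_sample_spec"), prm,
    chromatograms = FALSE), class = "evmrm_config_error")
})

test_that("SIL normalization cancels matrix suppression (noiseless identity)", {
  prm <- noiseless_params()
  for (m in c("mobile_phase", "qEV70", "qEV35", "ExoQuick")) {
    inj <- simulate_injection(panel, sample_spec(m, endogenous = c(CD9 = 0.1)),
                              prm, chromatograms = FALSE)
    a <- inj$areas
    light <- a$area[a$analyte_id == "CD9" & a$form == "light" &
                      a$role == "quantifier"]
    sil <- a$area[a$analyte_id == "CD9" & a$form == "SIL" &
                    a$role == "quantifier"]
    # CD9 endogenous equals the CD9 SIL spike -> ratio exactly 1 in any matrix
    expect_equal(normalized_response(light, sil), 1, tolerance = 1e-12,
                 info = m)
  }
})

test_that("calibration series has the designed layout and noiseless slope", {
  prm <- noiseless_params()
  ser <- simulate_calibration_series(panel, replicates = 3, params = prm,
                                     analytes = "ALB")
  # 8 levels x 3 replicates = 24 injection contexts (one light + one SIL row)
  expect_equal(nrow(ser), 24 * 2)
  expect_equal(max(ser$nominal_conc) / min(ser$nominal_conc), 40)

  fit <- fit_calibration_series(simulate_calibration_series(
    panel, replicates = 1, params = prm, analytes = "ALB"))$ALB
  # normalized response = conc / SIL spike -> slope = 1/spike, intercept 0
  expect_equal(fit$slope, 1 / 10, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  expect_error(simulate_calibration_series(panel, levels = c(2, 1, 3),
                                           analytes = "ALB"),
               class = "evmrm_config_error")
})

test_that("replicate study propagates hierarchical CVs and is seeded", {
  des <- study_design()
  st <- simulate_replicate_study(des, seed = 7)
  # 3 donors x 3 isolations x 2 digests x 3 methods = 54 injections/analyte
  expect_equal(nrow(st$areas), 54 * 5)

  st2 <- simulate_replicate_study(des, seed = 7)
  expect_identical(st$areas, st2$areas)

  # all CVs zero: every digest hits the method truth exactly
  st0 <- simulate_replicate_study(des, params = noiseless_params(), seed = 1)
  truth <- default_method_truth()
  for (m in names(truth)) {
    sub <- st0$areas[st0$areas$method == m, ]
    expect_equal(sub$true_conc,
                 unname(truth[[m]][sub$analyte_id]), tolerance = 1e-12)
  }

  # isolation-level CV shows up as ~cv_isolation %RSD of isolation means
  # (Monte-Carlo oracle at 500 repetitions, donor level switched off)
  prm <- sim_params(cv_donor = 0, cv_isolation = 0.2, cv_digest = 0,
                    cv_injection = 0)
  des1 <- study_design(methods = "qEV70")
  set.seed(123)
  rsds <- replicate(500, {
    st <- simulate_replicate_study(des1, truth_conc = list(qEV70 = c(
      ALB = 34, CD81 = 10, CD9 = 10, CANX = 10, TSG101 = 10)), params = prm)
    q <- quantify_areas(st$areas)
    iso_means <- tapply(q$concentration[q$analyte_id == "CD81"],
                        paste(q$donor, q$isolation)[q$analyte_id == "CD81"],
                        mean)
    pct_rsd(as.numeric(iso_means))
  })
  expect_lt(abs(mean(rsds) - 20), 3)
})

test_that("carryover sequence decays geometrically", {
  prm <- noiseless_params()
  seq0 <- simulate_carryover_sequence(panel, n_blanks = 2,
                                      params = sim_params(carryover_fraction = 0,
                                                          cv_injection = 0),
                                      seed = 1)
  expect_true(all(seq0$area[seq0$injection > 0] == 0))

  prm2 <- sim_params(carryover_fraction = 0.01, cv_injection = 0)
  sq <- simulate_carryover_sequence(panel, n_blanks = 2, params = prm2)
  alb <- sq[sq$analyte_id == "ALB", ]
  expect_equal(alb$area[alb$injection == 2],
               0.01^2 * alb$area[alb$injection == 0])
  expect_equal(alb$conc_equivalent, 80 * c(1, 0.01, 1e-4))

  expect_error(sim_params(carryover_fraction = 0.2),
               class = "evmrm_config_error")
})

test_that("stability series applies first-order loss per form and temperature", {
  base <- sample_spec("qEV70", endogenous = c(ALB = 5, CD81 = 1, CD9 = 0.1,
                                              CANX = 0.2, TSG101 = 0.2))
  # no degradation: all timepoints equal baseline
  st0 <- simulate_stability_series(panel, base, params = noiseless_params())
  expect_equal(length(unique(round(st0$light_area[st0$analyte_id == "ALB"], 9))), 1)

  # rate log(1/0.8)/48 -> exactly 20% loss at 48 h
  rate <- log(1 / 0.8) / 48
  deg <- data.frame(analyte_id = "ALB", form = "light", temperature = 15,
                    rate = rate)
  prm <- noiseless_params(degradation_rate = deg)
  st <- simulate_stability_series(panel, base, temperatures = 15,
                                  timepoints_h = c(0, 48), params = prm)
  alb <- st[st$analyte_id == "ALB", ]
  expect_equal(alb$true_conc[alb$timepoint_h == 48][1] /
                 alb$true_conc[alb$timepoint_h == 0][1], 0.8)

  # SIL degrading faster than light inflates the measured concentration
  deg2 <- data.frame(analyte_id = "CD81", form = "SIL", temperature = 15,
                     rate = log(1.26) / 24)
  prm2 <- noiseless_params(degradation_rate = deg2)
  st2 <- simulate_stability_series(panel, base, temperatures = 15,
                                   timepoints_h = c(0, 24), params = prm2)
  cd <- quantify_areas(st2[st2$analyte_id == "CD81", ])
  conc0 <- mean(cd$concentration[cd$timepoint_h == 0])
  conc24 <- mean(cd$concentration[cd$timepoint_h == 24])
  expect_equal(conc24 / conc0, 1.26, tolerance = 1e-9)

  expect_error(simulate_stability_series(panel, base, timepoints_h = c(6, 24)),
               class = "evmrm_config_error")
})

test_that("chromatogram long-format files round trip", {
  inj <- simulate_injection(panel, sample_spec("qEV70", endogenous = c(ALB = 5)),
                            sim_params(), seed = 3, sample_id = "s1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_chromatograms(inj$chromatograms, f)
  back <- read_chromatograms(f)
  expect_equal(length(back), length(inj$chromatograms))
  orig <- inj$chromatograms[["ALB|light|y8+"]]
  got <- back[["s1|ALB|light|y8+"]]
  expect_equal(got$intensities, orig$intensities, tolerance = 1e-8)
  expect_equal(got$times, orig$times, tolerance = 1e-8)
})
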
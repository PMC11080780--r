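#' Simulation parameters for the MRM signal and study model
#'
#' The simulator draws each transition as a single Gaussian chromatographic
#' peak on a flat baseline with additive white noise, multiplies true
#' quantifier areas by a per-matrix ionization-suppression factor applied
#' equally to light and SIL forms (the physical basis of SIL
#' normalization), and propagates hierarchical lognormal variability from
#' donor to isolation to digest to injection.
#'
#' Defaults define the desk-scale study conditions: peak SD 0.05 min on a
#' 0.01-min grid, baseline 50 counts, noise SD 10 counts, retention-time
#' jitter SD 0.015 min (matching low-fraction-of-a-percent RT
#' reproducibility), absolute-recovery suppression factors per matrix taken
#' from the validated assay (mobile phase 1.0 for all analytes), carryover
#' fraction 2e-4 (which puts the albumin blank-1 response at 4x its LOD
#' after the top calibrator), and CVs of 0.30 (donor), 0.20 (isolation),
#' 0.05 (digest) and 0.02 (injection). Response factors (counts*min per
#' pmol/ml) are fixed so that the signal-to-noise in qEV70 matrix yields
#' the panel's validated detection limits.
#'
#' @param peak_sigma chromatographic peak SD, minutes.
#' @param grid_step sampling interval of simulated traces, minutes.
#' @param baseline flat baseline level, counts.
#' @param noise_sd additive baseline noise SD, counts.
#' @param rt_jitter_sd retention-time jitter SD, minutes.
#' @param response_factor named per-analyte vector, counts*min per pmol/ml.
#' @param qualifier_ratios named list; per analyte the two qualifier/
#'   quantifier area fractions.
#' @param suppression named list: matrix_id -> named per-analyte factor in
#'   (0, 1] (or slightly above 1 for matrix enhancement).
#' @param carryover_fraction fraction of the previous injection's area
#'   carried into the next, in `[0, 0.05]`.
#' @param degradation_rate data.frame(analyte_id, form, temperature, rate)
#'   of first-order loss rates per hour; empty means no degradation.
#' @param cv_donor,cv_isolation,cv_digest,cv_injection fractional CVs of
#'   the hierarchical lognormal noise levels.
#' @return list of class `ev_sim_params`.
#' @export
sim_params <- function(peak_sigma = 0.05,
                       grid_step = 0.01,
                       baseline = 50,
                       noise_sd = 10,
                       rt_jitter_sd = 0.015,
                       response_factor = c(ALB = 1709, CD81 = 130, CD9 = 1319,
                                           CANX = 778, TSG101 = 1649),
                       qualifier_ratios = NULL,
                       suppression = default_suppression(),
                       carryover_fraction = 2e-4,
                       degradation_rate = NULL,
                       cv_donor = 0.30,
                       cv_isolation = 0.20,
                       cv_digest = 0.05,
                       cv_injection = 0.02) {
  stopifnot(peak_sigma > 0, grid_step > 0, noise_sd >= 0,
            cv_donor >= 0, cv_isolation >= 0, cv_digest >= 0,
            cv_injection >= 0)
  if (carryover_fraction < 0 || carryover_fraction > 0.05)
    stop_evmrm("carryover_fraction must lie in [0, 0.05]", "evmrm_config_error")
  for (m in names(suppression)) {
    s <- suppression[[m]]
    if (any(s <= 0)) stop_evmrm("suppression factors must be > 0",
                                "evmrm_config_error")
  }
  if (is.null(qualifier_ratios)) {
    qualifier_ratios <- lapply(names(response_factor), function(a) c(0.6, 0.3))
    names(qualifier_ratios) <- names(response_factor)
  }
  if (is.null(degradation_rate)) {
    degradation_rate <- data.frame(analyte_id = character(), form = character(),
                                   temperature = numeric(), rate = numeric(),
                                   stringsAsFactors = FALSE)
  }
  structure(list(peak_sigma = peak_sigma, grid_step = grid_step,
                 baseline = baseline, noise_sd = noise_sd,
                 rt_jitter_sd = rt_jitter_sd,
                 response_factor = response_factor,
                 qualifier_ratios = qualifier_ratios,
                 suppression = suppression,
                 carryover_fraction = carryover_fraction,
                 degradation_rate = degradation_rate,
                 cv_donor = cv_donor, cv_isolation = cv_isolation,
                 cv_digest = cv_digest, cv_injection = cv_injection),
            class = "ev_sim_params")
}

#' Default per-matrix ionization-suppression factors
#'
#' Absolute SIL recoveries of the validated assay, expressed as fractions
#' of the mobile-phase response: the EV matrices suppress each analyte to a
#' different degree (strongest for CD81 and ALB in precipitation matrix).
#' Serum and microsomal (HLM) digests, used only as positive controls, get
#' a uniform nominal factor.
#'
#' @return named list: matrix_id -> named per-analyte factor.
#' @export
default_suppression <- function() {
  list(
    mobile_phase = c(ALB = 1.00, CD81 = 1.00, CD9 = 1.00, CANX = 1.00, TSG101 = 1.00),
    qEV70    = c(ALB = 0.55, CD81 = 0.58, CD9 = 0.57, CANX = 0.69, TSG101 = 0.38),
    qEV35    = c(ALB = 0.59, CD81 = 0.52, CD9 = 0.84, CANX = 0.88, TSG101 = 0.54),
    ExoQuick = c(ALB = 0.22, CD81 = 0.13, CD9 = 0.76, CANX = 0.87, TSG101 = 0.57),
    serum    = c(ALB = 0.50, CD81 = 0.50, CD9 = 0.50, CANX = 0.50, TSG101 = 0.50),
    HLM      = c(ALB = 0.50, CD81 = 0.50, CD9 = 0.50, CANX = 0.50, TSG101 = 0.50)
  )
}

matrix_ids <- function() c("mobile_phase", "qEV70", "qEV35", "ExoQuick", "serum", "HLM")

suppression_factor <- function(params, matrix_id, analyte_id) {
  s <- params$suppression[[matrix_id]]
  if (is.null(s)) stop_evmrm(paste0("unknown matrix_id '", matrix_id, "'"),
                             "evmrm_config_error")
  if (!analyte_id %in% names(s))
    stop_evmrm(paste0("no suppression factor for ", analyte_id, " in ", matrix_id),
               "evmrm_config_error")
  as.numeric(s[[analyte_id]])
}

degradation_lookup <- function(params, analyte_id, form, temperature) {
  d <- params$degradation_rate
  hit <- d$analyte_id == analyte_id & d$form == form &
    d$temperature == temperature
  if (any(hit)) d$rate[which(hit)[1]] else 0
}

#' Describe one sample to be injected
#'
#' @param matrix_id one of `mobile_phase`, `qEV70`, `qEV35`, `ExoQuick`,
#'   `serum`, `HLM`.
#' @param endogenous named per-analyte endogenous (light) concentration,
#'   pmol/ml; analytes omitted default to 0.
#' @param sil named per-analyte SIL spike concentration, pmol/ml; `NULL`
#'   means "use the panel spike levels" wherever the sample is simulated.
#' @param light_supplement named per-analyte synthetic light peptide spiked
#'   on top of the endogenous level (used for validation samples), pmol/ml.
#' @return list of class `ev_sample_spec`.
#' @export
sample_spec <- function(matrix_id, endogenous = numeric(), sil = NULL,
                        light_supplement = numeric()) {
  if (!matrix_id %in% matrix_ids())
    stop_evmrm(paste0("unknown matrix_id '", matrix_id, "'"),
               "evmrm_config_error")
  stopifnot(all(endogenous >= 0), all(light_supplement >= 0),
            is.null(sil) || all(sil >= 0))
  structure(list(matrix_id = matrix_id, endogenous = endogenous,
                 sil = sil, light_supplement = light_supplement),
            class = "ev_sample_spec")
}

# concentration of one analyte in a named map (vector or list); 0 if absent
conc_of <- function(map, analyte_id) {
  if (is.null(map) || length(map) == 0) return(0)
  if (!analyte_id %in% names(map)) return(0)
  as.numeric(map[[analyte_id]])
}

#' Replicate-study design
#'
#' The default mirrors the validated reproducibility protocol: EVs isolated
#' in triplicate from the serum of three donors by each of three isolation
#' methods, with duplicate peptide digests (18 injections per method).
#'
#' @param donors number of donors.
#' @param methods character vector of isolation-matrix ids.
#' @param isolations_per_donor,digests_per_isolation replicate counts.
#' @param calibrator_levels named list: analyte -> increasing concentrations
#'   (pmol/ml); default is the panel's 8-calibrator series.
#' @param qc_levels named list: analyte -> c(low, mid, high) pmol/ml.
#' @param stability_temperatures,stability_timepoints_h stability grid.
#' @param panel panel used to derive default calibrators.
#' @return list of class `ev_study_design`.
#' @export
study_design <- function(donors = 3,
                         methods = c("qEV70", "qEV35", "ExoQuick"),
                         isolations_per_donor = 3,
                         digests_per_isolation = 2,
                         calibrator_levels = default_calibrators(panel),
                         qc_levels = default_qc_levels(),
                         stability_temperatures = c(-20, 4, 15),
                         stability_timepoints_h = c(0, 6, 24, 48),
                         panel = builtin_panel()) {
  stopifnot(donors >= 1, isolations_per_donor >= 1, digests_per_isolation >= 1)
  for (a in names(qc_levels)) {
    q <- qc_levels[[a]]
    if (!(q[1] < q[2] && q[2] < q[3]))
      stop_evmrm(paste0("QC levels for ", a, " must satisfy low < mid < high"),
                 "evmrm_config_error")
  }
  structure(list(donors = donors, methods = methods,
                 isolations_per_donor = isolations_per_donor,
                 digests_per_isolation = digests_per_isolation,
                 calibrator_levels = calibrator_levels,
                 qc_levels = qc_levels,
                 stability_temperatures = stability_temperatures,
                 stability_timepoints_h = stability_timepoints_h),
            class = "ev_study_design")
}

#' Default 8-calibrator series per analyte
#'
#' Calibrators 1-6 span the concentration range of healthy-donor serum EV
#' isolates; calibrators 7 and 8 sit at two and four times the top of that
#' range, giving each analyte a 40-fold validated span.
#'
#' @param panel an [ev_panel].
#' @return named list: analyte -> 8 increasing concentrations (pmol/ml).
#' @export
default_calibrators <- function(panel = builtin_panel()) {
  mult <- c(1, 2, 3, 5, 7.5, 10, 20, 40)
  out <- lapply(seq_len(nrow(panel$calibration_ranges)), function(i)
    panel$calibration_ranges$low[i] * mult)
  names(out) <- panel$calibration_ranges$analyte_id
  out
}

#' Default QC concentrations (low, mid, high) per analyte
#'
#' @return named list of length-3 vectors, pmol/ml.
#' @export
default_qc_levels <- function() {
  list(ALB = c(6, 10, 18), CD81 = c(0.6, 1.0, 1.8), CD9 = c(0.06, 0.1, 0.18),
       CANX = c(0.12, 0.2, 0.36), TSG101 = c(0.12, 0.2, 0.36))
}

#' Mean analyte concentrations per isolation method
#'
#' Method-level ground-truth concentrations used as defaults for the
#' replicate-study simulator: a high-recovery low-purity precipitation
#' matrix carries far more albumin and tetraspanin signal than the
#' size-exclusion matrices, and TSG101/CANX sit near or below the
#' quantification limit in SEC isolates.
#'
#' @return named list: method -> named per-analyte pmol/ml.
#' @export
default_method_truth <- function() {
  list(
    qEV70 = c(ALB = 34, CD81 = 0.25, CD9 = 0.04, CANX = 0.02, TSG101 = 0.015),
    qEV35 = c(ALB = 122, CD81 = 0.38, CD9 = 0.16, CANX = 0.19, TSG101 = 0.02),
    ExoQuick = c(ALB = 27984, CD81 = 8.54, CD9 = 0.24, CANX = 0.54, TSG101 = 1.55)
  )
}

#' Simulate one transition chromatogram
#'
#' The trace is `baseline + A * exp(-(t - rt')^2 / (2 sigma^2)) + eps` with
#' `A = true_area / (sigma * sqrt(2*pi))`, `rt'` the expected retention
#' time plus Gaussian jitter, and `eps` iid Gaussian noise, sampled on a
#' fixed grid over expected RT +/- 1.5 min.
#'
#' @param transition one row of a panel transition table (or any list with
#'   `expected_rt` and identification fields).
#' @param true_area true peak area, counts*min (>= 0).
#' @param params an [sim_params()] object.
#' @param seed optional integer seed; identical inputs and seed give
#'   identical traces.
#' @param sample_id label stored on the chromatogram.
#' @return an `ev_chromatogram`.
#' @export
simulate_chromatogram <- function(transition, true_area, params = sim_params(),
                                  seed = NULL, sample_id = "sim") {
  stopifnot(true_area >= 0)
  maybe_set_seed(seed)
  rt <- as.numeric(transition$expected_rt)
  times <- seq(rt - 1.5, rt + 1.5, by = params$grid_step)
  rt_actual <- rt + if (params$rt_jitter_sd > 0)
    stats::rnorm(1, 0, params$rt_jitter_sd) else 0
  amp <- true_area / (params$peak_sigma * sqrt(2 * pi))
  sig <- amp * exp(-(times - rt_actual)^2 / (2 * params$peak_sigma^2))
  eps <- if (params$noise_sd > 0) stats::rnorm(length(times), 0, params$noise_sd) else 0
  chromatogram(times, params$baseline + sig + eps,
               analyte_id = transition$analyte_id %||% NA_character_,
               form = transition$form %||% NA_character_,
               role = transition$role %||% NA_character_,
               product_label = transition$product_label %||% NA_character_,
               sample_id = sample_id, expected_rt = rt)
}

# true quantifier area for one analyte/form in one injection
true_quant_area <- function(params, matrix_id, analyte_id, conc) {
  params$response_factor[[analyte_id]] * conc *
    suppression_factor(params, matrix_id, analyte_id)
}

#' Simulate a full injection of a sample against a panel
#'
#' Every transition of every analyte is drawn: the light-form
#' concentration is endogenous + light supplement, the SIL form is the
#' spike concentration, and both forms see the same matrix suppression
#' factor -- which is why SIL normalization cancels matrix effects.
#' Quantifier areas get independent lognormal injection noise; qualifier
#' areas are fixed fractions of their quantifier.
#'
#' @param panel an [ev_panel].
#' @param sample an [sample_spec()].
#' @param params an [sim_params()].
#' @param seed optional integer seed.
#' @param sample_id label for the injection.
#' @param chromatograms simulate full traces (`TRUE`) or return the
#'   pre-integrated area table only (`FALSE`, much faster; this is the
#'   "results-table" route of downstream processing).
#' @return list with `areas` (data.frame: sample_id, matrix_id, analyte_id,
#'   form, role, product_label, true_conc, area), `truth` (one row per
#'   quantifier transition) and, when requested, `chromatograms` (named
#'   list keyed `analyte|form|product_label`).
#' @export
simulate_injection <- function(panel, sample, params = sim_params(),
                               seed = NULL, sample_id = "inj1",
                               chromatograms = TRUE) {
  maybe_set_seed(seed)
  rows <- list()
  chroms <- list()
  for (i in seq_len(nrow(panel$analytes))) {
    aid <- panel$analytes$analyte_id[i]
    sil_spike <- if (is.null(sample$sil)) panel$analytes$sil_spike_conc[i]
                 else conc_of(sample$sil, aid)
    concs <- c(light = conc_of(sample$endogenous, aid) +
                 conc_of(sample$light_supplement, aid),
               SIL = sil_spike)
    for (form in c("light", "SIL")) {
      conc <- concs[[form]]
      qarea <- true_quant_area(params, sample$matrix_id, aid, conc) *
        rlnorm_cv(1, params$cv_injection)
      tr <- panel$transitions[panel$transitions$analyte_id == aid &
                                panel$transitions$form == form, ]
      qual_i <- 0L
      for (j in seq_len(nrow(tr))) {
        role <- tr$role[j]
        if (role == "quantifier") {
          area <- qarea
        } else {
          qual_i <- qual_i + 1L
          area <- qarea * params$qualifier_ratios[[aid]][qual_i]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, matrix_id = sample$matrix_id,
          analyte_id = aid, form = form, role = role,
          product_label = tr$product_label[j],
          true_conc = conc, area = area, stringsAsFactors = FALSE)
        if (chromatograms) {
          key <- paste(aid, form, tr$product_label[j], sep = "|")
          chroms[[key]] <- simulate_chromatogram(tr[j, ], area, params,
                                                 seed = NULL,
                                                 sample_id = sample_id)
        }
      }
    }
  }
  areas <- do.call(rbind, rows)
  truth <- areas[areas$role == "quantifier", ]
  out <- list(areas = areas, truth = truth)
  if (chromatograms) out$chromatograms <- chroms
  out
}

#' Simulate a calibration series
#'
#' One injection per calibrator level and replicate: the light form sits at
#' the calibrator concentration (synthetic light peptide), the SIL form at
#' the panel spike concentration, in the requested matrix.
#'
#' @param panel an [ev_panel].
#' @param levels named list analyte -> strictly increasing concentrations,
#'   or a single numeric vector applied to every analyte.
#' @param matrix_id matrix the calibrators are prepared in.
#' @param replicates injections per level.
#' @param params an [sim_params()].
#' @param seed optional integer seed.
#' @param analytes subset of analyte ids to simulate (default all).
#' @return data.frame of quantifier areas: analyte_id, matrix_id, level,
#'   replicate, nominal_conc, form, area (one light and one SIL row per
#'   injection context).
#' @export
simulate_calibration_series <- function(panel, levels = default_calibrators(panel),
                                        matrix_id = "qEV70", replicates = 3,
                                        params = sim_params(), seed = NULL,
                                        analytes = panel$analytes$analyte_id) {
  maybe_set_seed(seed)
  if (!is.list(levels)) {
    levels <- stats::setNames(rep(list(levels), length(analytes)), analytes)
  }
  rows <- list()
  for (aid in analytes) {
    lv <- levels[[aid]]
    if (is.null(lv)) stop_evmrm(paste0("no calibrator levels for ", aid),
                                "evmrm_config_error")
    if (any(diff(lv) <= 0))
      stop_evmrm("calibrator levels must be strictly increasing",
                 "evmrm_config_error")
    sil_spike <- panel_analyte(panel, aid)$sil_spike_conc
    for (k in seq_along(lv)) {
      for (r in seq_len(replicates)) {
        a_light <- true_quant_area(params, matrix_id, aid, lv[k]) *
          rlnorm_cv(1, params$cv_injection)
        a_sil <- true_quant_area(params, matrix_id, aid, sil_spike) *
          rlnorm_cv(1, params$cv_injection)
        rows[[length(rows) + 1L]] <- data.frame(
          analyte_id = aid, matrix_id = matrix_id, level = k, replicate = r,
          nominal_conc = lv[k],
          form = c("light", "SIL"), area = c(a_light, a_sil),
          sil_spike_conc = sil_spike, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate the hierarchical replicate (reproducibility) study
#'
#' Per-donor, per-isolation and per-digest concentrations are the method
#' truth multiplied by independent lognormal factors at the configured CVs
#' (donor > isolation > digest); each digest is then injected once with
#' injection-level noise on light and SIL areas independently.
#'
#' @param design an [study_design()].
#' @param truth_conc named list: method -> named per-analyte pmol/ml
#'   (default [default_method_truth()]).
#' @param panel an [ev_panel].
#' @param params an [sim_params()].
#' @param seed optional integer seed.
#' @return list with `areas` (quantifier light/SIL areas per digest) and
#'   `truth` (true digest-level concentration per analyte).
#' @export
simulate_replicate_study <- function(design = study_design(),
                                     truth_conc = default_method_truth(),
                                     panel = builtin_panel(),
                                     params = sim_params(), seed = NULL) {
  maybe_set_seed(seed)
  rows <- list()
  analytes <- panel$analytes$analyte_id
  for (m in design$methods) {
    tm <- truth_conc[[m]]
    if (is.null(tm)) stop_evmrm(paste0("no truth concentrations for method ", m),
                                "evmrm_config_error")
    for (d in seq_len(design$donors)) {
      f_donor <- rlnorm_cv(length(analytes), params$cv_donor)
      for (iso in seq_len(design$isolations_per_donor)) {
        f_iso <- rlnorm_cv(length(analytes), params$cv_isolation)
        for (dig in seq_len(design$digests_per_isolation)) {
          f_dig <- rlnorm_cv(length(analytes), params$cv_digest)
          for (ai in seq_along(analytes)) {
            aid <- analytes[ai]
            conc <- (tm[[aid]] %||% 0) * f_donor[ai] * f_iso[ai] * f_dig[ai]
            sil_spike <- panel$analytes$sil_spike_conc[ai]
            a_light <- true_quant_area(params, m, aid, conc) *
              rlnorm_cv(1, params$cv_injection)
            a_sil <- true_quant_area(params, m, aid, sil_spike) *
              rlnorm_cv(1, params$cv_injection)
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sprintf("%s_D%d_I%d_G%d", m, d, iso, dig),
              donor = d, method = m, isolation = iso, digest = dig,
              analyte_id = aid, true_conc = conc,
              light_area = a_light, sil_area = a_sil,
              sil_spike_conc = sil_spike, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  areas <- do.call(rbind, rows)
  list(areas = areas,
       truth = areas[, c("sample_id", "donor", "method", "isolation",
                         "digest", "analyte_id", "true_conc")])
}

#' Simulate a carryover assessment sequence
#'
#' One injection of the highest calibration standard followed by blank
#' injections of mobile phase; blank k carries `carryover_fraction^k` of
#' the standard's peak area. Blank responses are expressed as
#' concentration equivalents against the standard (area ratio times the
#' standard concentration), the scale on which they are compared to
#' LOD/LLOQ.
#'
#' @param panel an [ev_panel].
#' @param high_standard an [sample_spec()]; its light-form concentrations
#'   are the top-calibrator levels (default: panel top calibrators in
#'   mobile phase).
#' @param n_blanks number of consecutive blanks (>= 1).
#' @param params an [sim_params()].
#' @param seed optional integer seed.
#' @return data.frame: analyte_id, injection (0 = standard, 1..n blanks),
#'   area, conc_equivalent (pmol/ml).
#' @export
simulate_carryover_sequence <- function(panel, high_standard = NULL,
                                        n_blanks = 2, params = sim_params(),
                                        seed = NULL) {
  stopifnot(n_blanks >= 1)
  maybe_set_seed(seed)
  if (is.null(high_standard)) {
    tops <- stats::setNames(panel$calibration_ranges$high,
                            panel$calibration_ranges$analyte_id)
    high_standard <- sample_spec("mobile_phase", endogenous = tops)
  }
  rows <- list()
  for (i in seq_len(nrow(panel$analytes))) {
    aid <- panel$analytes$analyte_id[i]
    conc0 <- conc_of(high_standard$endogenous, aid) +
      conc_of(high_standard$light_supplement, aid)
    a0 <- true_quant_area(params, high_standard$matrix_id, aid, conc0) *
      rlnorm_cv(1, params$cv_injection)
    rows[[length(rows) + 1L]] <- data.frame(
      analyte_id = aid, injection = 0L, area = a0, conc_equivalent = conc0,
      stringsAsFactors = FALSE)
    for (k in seq_len(n_blanks)) {
      ak <- params$carryover_fraction^k * a0
      rows[[length(rows) + 1L]] <- data.frame(
        analyte_id = aid, injection = k, area = ak,
        conc_equivalent = ak / a0 * conc0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a short-term stability series
#'
#' Light and SIL forms decay first-order at (possibly different) rates per
#' analyte and storage temperature; because the SIL standard is spiked once
#' at baseline, faster SIL decay inflates the apparent concentration over
#' time. Duplicate injections per timepoint.
#'
#' @param panel an [ev_panel].
#' @param sample an [sample_spec()] giving the baseline endogenous
#'   concentrations.
#' @param temperatures storage temperatures, degrees C.
#' @param timepoints_h analysis times in hours; must include 0 (baseline).
#' @param params an [sim_params()]; degradation rates come from
#'   `params$degradation_rate`.
#' @param seed optional integer seed.
#' @param duplicates injections per (temperature, timepoint).
#' @return data.frame: analyte_id, temperature, timepoint_h, duplicate,
#'   light_area, sil_area, sil_spike_conc, true_conc.
#' @export
simulate_stability_series <- function(panel, sample,
                                      temperatures = c(-20, 4, 15),
                                      timepoints_h = c(0, 6, 24, 48),
                                      params = sim_params(), seed = NULL,
                                      duplicates = 2) {
  if (!0 %in% timepoints_h)
    stop_evmrm("timepoints must include 0 (baseline)", "evmrm_config_error")
  maybe_set_seed(seed)
  rows <- list()
  for (i in seq_len(nrow(panel$analytes))) {
    aid <- panel$analytes$analyte_id[i]
    conc0 <- conc_of(sample$endogenous, aid) +
      conc_of(sample$light_supplement, aid)
    sil0 <- if (is.null(sample$sil)) panel$analytes$sil_spike_conc[i]
            else conc_of(sample$sil, aid)
    for (temp in temperatures) {
      r_light <- degradation_lookup(params, aid, "light", temp)
      r_sil <- degradation_lookup(params, aid, "SIL", temp)
      for (t in timepoints_h) {
        conc_t <- conc0 * exp(-r_light * t)
        sil_t <- sil0 * exp(-r_sil * t)
        for (dup in seq_len(duplicates)) {
          a_light <- true_quant_area(params, sample$matrix_id, aid, conc_t) *
            rlnorm_cv(1, params$cv_injection)
          a_sil <- true_quant_area(params, sample$matrix_id, aid, sil_t) *
            rlnorm_cv(1, params$cv_injection)
          rows[[length(rows) + 1L]] <- data.frame(
            analyte_id = aid, temperature = temp, timepoint_h = t,
            duplicate = dup, light_area = a_light, sil_area = a_sil,
            sil_spike_conc = sil0, true_conc = conc_t,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate SIL spike curves for matrix-effect assessment
#'
#' For recovery studies the SIL peptides themselves are spiked at several
#' concentrations (the first and sixth calibrator plus a mid QC level)
#' into each matrix, and the raw SIL response curves are compared between
#' matrices.
#'
#' @param panel an [ev_panel].
#' @param levels named list analyte -> SIL spike concentrations, or a
#'   single numeric vector applied to all analytes; default calibrators
#'   1 and 6 plus the mid QC.
#' @param matrix_id matrix the spikes are prepared in.
#' @param replicates injections per level.
#' @param params an [sim_params()].
#' @param seed optional integer seed.
#' @param analytes subset of analyte ids (default all).
#' @return data.frame: analyte_id, matrix_id, level, replicate,
#'   nominal_conc, area.
#' @export
simulate_sil_recovery_series <- function(panel, levels = NULL,
                                         matrix_id = "qEV70", replicates = 3,
                                         params = sim_params(), seed = NULL,
                                         analytes = panel$analytes$analyte_id) {
  maybe_set_seed(seed)
  if (is.null(levels)) {
    cal <- default_calibrators(panel)
    qc <- default_qc_levels()
    levels <- lapply(analytes, function(a) sort(c(cal[[a]][c(1, 6)], qc[[a]][2])))
    names(levels) <- analytes
  } else if (!is.list(levels)) {
    levels <- stats::setNames(rep(list(levels), length(analytes)), analytes)
  }
  rows <- list()
  for (aid in analytes) {
    lv <- levels[[aid]]
    for (k in seq_along(lv)) {
      for (r in seq_len(replicates)) {
        a <- true_quant_area(params, matrix_id, aid, lv[k]) *
          rlnorm_cv(1, params$cv_injection)
        rows[[length(rows) + 1L]] <- data.frame(
          analyte_id = aid, matrix_id = matrix_id, level = k, replicate = r,
          nominal_conc = lv[k], area = a, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
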
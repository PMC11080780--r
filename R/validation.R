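#' Estimate LOD and LLOQ from low-level calibration injections
#'
#' The limit of detection is the concentration at which the quantifier
#' signal-to-noise ratio reaches 3:1 and the lower limit of quantification
#' is five times the LOD. The S/N-versus-concentration relationship is
#' estimated by an origin-constrained least-squares fit over the lowest
#' three calibrator levels (where the linear S/N approximation is safest),
#' so `lod = 3 / slope`.
#'
#' @param snr_table data.frame with columns `nominal_conc` and `snr` (one
#'   row per calibration injection); at least two distinct low-end levels
#'   with measurable S/N are required.
#' @param analyte_id,matrix_id labels stored on the result.
#' @param n_levels number of lowest levels used in the fit (default 3).
#' @return list of class `ev_sensitivity`: `lod`, `lloq` (= 5 x lod),
#'   `snr_slope`, all in pmol/ml.
#' @export
estimate_lod_lloq <- function(snr_table, analyte_id = NA_character_,
                              matrix_id = NA_character_, n_levels = 3) {
  if (all(snr_table$snr == 0))
    stop_evmrm("all S/N values are zero: sensitivity indeterminate",
               "evmrm_sensitivity_indeterminate")
  lv <- sort(unique(snr_table$nominal_conc))
  if (length(lv) < 2L)
    stop_evmrm("need >= 2 distinct low-end levels", "evmrm_insufficient_data")
  use <- snr_table[snr_table$nominal_conc %in% lv[seq_len(min(n_levels, length(lv)))], ]
  slope <- sum(use$snr * use$nominal_conc) / sum(use$nominal_conc^2)
  if (!is.finite(slope) || slope <= 0)
    stop_evmrm("non-positive fitted S/N slope: sensitivity indeterminate",
               "evmrm_sensitivity_indeterminate")
  lod <- 3 / slope
  structure(list(analyte_id = analyte_id, matrix_id = matrix_id,
                 lod = lod, lloq = 5 * lod, snr_slope = slope),
            class = "ev_sensitivity")
}

#' @export
print.ev_sensitivity <- function(x, ...) {
  cat(sprintf("sensitivity [%s%s]: LOD %.4g, LLOQ %.4g pmol/ml (S/N slope %.3g)\n",
              x$analyte_id,
              if (!is.na(x$matrix_id)) paste0(" in ", x$matrix_id) else "",
              x$lod, x$lloq, x$snr_slope))
  invisible(x)
}

#' Intra- and inter-day precision of calibration slopes
#'
#' Within-run precision is the \%RSD of same-day replicate slopes (reported
#' per day; the pooled figure is the worst day); between-run precision is
#' the \%RSD of the day-average slopes.
#'
#' @param slopes data.frame with columns `day` and `slope` (one row per
#'   replicate calibration curve); >= 2 slopes per day and >= 2 days.
#' @return list of class `ev_precision`: `intraday_rsd` (named per day),
#'   `intraday_rsd_pooled` (max over days), `interday_rsd`.
#' @export
slope_precision <- function(slopes) {
  days <- split(slopes$slope, slopes$day)
  if (length(slopes$slope) < 2L)
    stop_evmrm("a single curve cannot yield precision", "evmrm_precision_indeterminate")
  intraday <- vapply(days, function(s) {
    if (length(s) < 2L)
      stop_evmrm("need >= 2 slopes per day for intraday precision",
                 "evmrm_precision_indeterminate")
    pct_rsd(s)
  }, numeric(1))
  if (length(days) < 2L)
    stop_evmrm("need >= 2 days for interday precision",
               "evmrm_precision_indeterminate")
  interday <- pct_rsd(vapply(days, mean, numeric(1)))
  structure(list(intraday_rsd = intraday,
                 intraday_rsd_pooled = max(intraday),
                 interday_rsd = interday),
            class = "ev_precision")
}

#' @export
print.ev_precision <- function(x, ...) {
  cat(sprintf("precision: intraday %%RSD %s (pooled %.2g), interday %%RSD %.2g\n",
              paste(signif(x$intraday_rsd, 2), collapse = "/"),
              x$intraday_rsd_pooled, x$interday_rsd))
  invisible(x)
}

#' Repeatability from five consecutive injections
#'
#' \%RSD of the concentrations measured in five consecutive injections of
#' the same mid-QC sample. A different replicate count is computed anyway
#' but flagged with a design-mismatch warning.
#'
#' @param concs numeric concentrations.
#' @return \%RSD.
#' @export
repeatability_rsd <- function(concs) {
  if (length(concs) != 5L)
    warning("repeatability design expects exactly 5 consecutive injections; ",
            "computed over ", length(concs), call. = FALSE)
  pct_rsd(concs)
}

#' Accuracy as percent of nominal (\% True)
#'
#' @param nominal nominal QC concentration, pmol/ml (> 0).
#' @param measured measured concentration, pmol/ml.
#' @param qc_level optional label (`"low"`, `"mid"`, `"high"`).
#' @param analyte_id optional label.
#' @return data.frame: analyte_id, qc_level, nominal, measured,
#'   percent_true (100 x measured/nominal, reported to 3 significant
#'   figures).
#' @export
accuracy_percent_true <- function(nominal, measured, qc_level = NA_character_,
                                  analyte_id = NA_character_) {
  if (any(nominal <= 0))
    stop_evmrm("nominal concentration must be > 0", "evmrm_config_error")
  data.frame(analyte_id = analyte_id, qc_level = qc_level,
             nominal = nominal, measured = measured,
             percent_true = signif(100 * measured / nominal, 3),
             stringsAsFactors = FALSE)
}

#' Classify carryover in blank injections
#'
#' Each blank injection after the top calibration standard is classified by
#' its response (in concentration equivalents) against the assay limits:
#' `none` (< LOD), `detectable` (>= LOD but < LLOQ), `quantifiable`
#' (>= LLOQ; boundary inclusive).
#'
#' @param blanks data.frame with columns `blank_index` (1 = first blank)
#'   and `conc_equivalent` (pmol/ml), ordered by injection; an
#'   `analyte_id` column is carried through.
#' @param sensitivity an `ev_sensitivity` (or list with `lod`, `lloq`).
#' @return data.frame: analyte_id, blank_index, conc_equivalent,
#'   classification.
#' @export
assess_carryover <- function(blanks, sensitivity) {
  cls <- ifelse(blanks$conc_equivalent < sensitivity$lod, "none",
                ifelse(blanks$conc_equivalent < sensitivity$lloq,
                       "detectable", "quantifiable"))
  data.frame(analyte_id = blanks$analyte_id %||% sensitivity$analyte_id,
             blank_index = blanks$blank_index,
             conc_equivalent = blanks$conc_equivalent,
             classification = cls, stringsAsFactors = FALSE)
}

#' Assess short-term stability against the 20\% rule
#'
#' Per (analyte, temperature, timepoint): percent change of the duplicate
#' mean concentration from the baseline (t = 0) mean, plus the duplicate
#' \%RSD. A timepoint is stable only when the absolute change is strictly
#' less than 20\%.
#'
#' @param timecourse data.frame with columns `analyte_id`, `temperature`,
#'   `timepoint_h`, `concentration` (one row per duplicate injection).
#' @return data.frame: analyte_id, temperature, timepoint_h,
#'   mean_concentration, percent_change_from_baseline, duplicate_rsd,
#'   stable. Baseline rows report 0 change. A series without a baseline
#'   raises a stability-indeterminate error.
#' @export
assess_stability <- function(timecourse) {
  out <- list()
  for (g in split(timecourse,
                  paste(timecourse$analyte_id, timecourse$temperature))) {
    if (!0 %in% g$timepoint_h)
      stop_evmrm(paste0("no baseline (t = 0) for ", g$analyte_id[1], " at ",
                        g$temperature[1], " degC: stability indeterminate"),
                 "evmrm_stability_indeterminate")
    base_mean <- mean(g$concentration[g$timepoint_h == 0])
    for (t in sort(unique(g$timepoint_h))) {
      ct <- g$concentration[g$timepoint_h == t]
      change <- 100 * (mean(ct) - base_mean) / base_mean
      out[[length(out) + 1L]] <- data.frame(
        analyte_id = g$analyte_id[1], temperature = g$temperature[1],
        timepoint_h = t, mean_concentration = mean(ct),
        percent_change_from_baseline = change,
        duplicate_rsd = if (length(ct) >= 2) pct_rsd(ct) else NA_real_,
        # strict "< 20": a change at the boundary (to within numerical
        # round-off of the percent computation) is not stable
        stable = abs(change) < 20 - 1e-9, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Matrix-effect recovery from calibration-slope ratio
#'
#' Recovery of the SIL response in a matrix, as a percentage of the slope
#' of the same SIL standard curve in a reference: mobile phase for
#' absolute recovery, the primary EV matrix (qEV70) for relative recovery.
#'
#' @param curve_matrix,curve_reference `ev_calibration` fits for the same
#'   analyte at the same nominal levels.
#' @return list of class `ev_recovery`: `analyte_id`, `matrix_id`,
#'   `reference`, `reference_type` (`"absolute"` for mobile phase,
#'   `"relative"` otherwise), `recovery_percent`.
#' @export
recovery_percent <- function(curve_matrix, curve_reference) {
  if (!is.na(curve_matrix$analyte_id) && !is.na(curve_reference$analyte_id) &&
      curve_matrix$analyte_id != curve_reference$analyte_id)
    stop_evmrm("recovery compares curves of the same analyte",
               "evmrm_config_error")
  if (curve_reference$slope <= 0)
    stop_evmrm("reference slope must be > 0", "evmrm_invalid_reference")
  structure(list(
    analyte_id = curve_matrix$analyte_id,
    matrix_id = curve_matrix$matrix_id,
    reference = curve_reference$matrix_id,
    reference_type = if (identical(curve_reference$matrix_id, "mobile_phase"))
      "absolute" else "relative",
    recovery_percent = 100 * curve_matrix$slope / curve_reference$slope),
    class = "ev_recovery")
}

#' @export
print.ev_recovery <- function(x, ...) {
  cat(sprintf("%s recovery [%s]: %s is %.3g%% of %s\n", x$reference_type,
              x$analyte_id, x$matrix_id, x$recovery_percent, x$reference))
  invisible(x)
}

#' Adjust LOD/LLOQ for matrix effects on relative recovery
#'
#' When the relative recovery in an alternate EV matrix deviates from
#' 100\% by more than a threshold (default 20 percentage points), the
#' detection and quantification limits validated in the reference matrix
#' are rescaled: `adjusted_lod = lod_ref / (recovery/100)` and
#' `adjusted_lloq = 5 x adjusted_lod`. Within the threshold the limits are
#' unchanged.
#'
#' @param sensitivity_ref `ev_sensitivity` validated in the reference
#'   matrix.
#' @param relative_recovery_percent relative recovery, \% (> 0).
#' @param threshold deviation (percentage points) beyond which limits are
#'   adjusted.
#' @return list of class `ev_sensitivity` with `lod`/`lloq` adjusted and
#'   an `adjusted` flag.
#' @export
adjust_limits_for_matrix <- function(sensitivity_ref, relative_recovery_percent,
                                     threshold = 20) {
  if (relative_recovery_percent <= 0)
    stop_evmrm("relative recovery must be > 0", "evmrm_config_error")
  adjust <- abs(relative_recovery_percent - 100) > threshold
  lod <- if (adjust) sensitivity_ref$lod / (relative_recovery_percent / 100)
         else sensitivity_ref$lod
  structure(list(analyte_id = sensitivity_ref$analyte_id,
                 matrix_id = sensitivity_ref$matrix_id,
                 lod = lod, lloq = 5 * lod,
                 snr_slope = sensitivity_ref$snr_slope %||% NA_real_,
                 adjusted = adjust,
                 relative_recovery_percent = relative_recovery_percent),
            class = "ev_sensitivity")
}

#' Fit one calibration curve per analyte from a simulated series
#'
#' Helper that normalizes the light/SIL quantifier areas of
#' [simulate_calibration_series()] output and fits [fit_calibration()]
#' per analyte.
#'
#' @param series data.frame from [simulate_calibration_series()].
#' @param weighting passed to [fit_calibration()].
#' @return named list of `ev_calibration`.
#' @export
fit_calibration_series <- function(series, weighting = "none") {
  out <- list()
  for (aid in unique(series$analyte_id)) {
    sub <- series[series$analyte_id == aid, ]
    wide <- merge(
      sub[sub$form == "light",
          c("level", "replicate", "nominal_conc", "area", "matrix_id")],
      sub[sub$form == "SIL", c("level", "replicate", "area")],
      by = c("level", "replicate"), suffixes = c("_light", "_sil"))
    lv <- data.frame(nominal_conc = wide$nominal_conc,
                     normalized_response = normalized_response(
                       wide$area_light, wide$area_sil),
                     replicate = wide$replicate)
    out[[aid]] <- fit_calibration(lv, analyte_id = aid,
                                  matrix_id = wide$matrix_id[1],
                                  weighting = weighting)
  }
  out
}

#' SIL-only calibration slope per analyte (for matrix-effect studies)
#'
#' Matrix-effect recovery compares raw SIL response curves between
#' matrices, so the fit here regresses the raw SIL quantifier area on the
#' spiked SIL concentration (no normalization).
#'
#' @param series data.frame with columns `analyte_id`, `matrix_id`,
#'   `nominal_conc`, `area` (one row per injection), e.g. from
#'   [simulate_sil_recovery_series()].
#' @return named list of `ev_calibration` on the raw-area scale.
#' @export
fit_sil_response_curves <- function(series) {
  out <- list()
  for (aid in unique(series$analyte_id)) {
    rows <- series[series$analyte_id == aid, ]
    lv <- data.frame(nominal_conc = rows$nominal_conc,
                     normalized_response = rows$area)
    out[[aid]] <- fit_calibration(lv, analyte_id = aid,
                                  matrix_id = rows$matrix_id[1])
  }
  out
}
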
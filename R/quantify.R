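#' SIL-normalized response
#'
#' The quantity regressed against concentration: endogenous (light) peak
#' area divided by the SIL internal-standard peak area from the same
#' injection. Because matrix suppression attenuates both forms equally,
#' the ratio is invariant to matrix effects.
#'
#' @param light_area light-form quantifier area, counts*min.
#' @param sil_area SIL quantifier area, counts*min; must be > 0.
#' @return dimensionless normalized response.
#' @export
normalized_response <- function(light_area, sil_area) {
  if (any(sil_area <= 0))
    stop_evmrm("SIL peak area must be > 0 (SIL peak missing?)",
               "evmrm_normalization_error")
  light_area / sil_area
}

#' Single-point quantification against the SIL spike
#'
#' Concentration = normalized response x known SIL spike concentration;
#' exact when the response is linear through the origin.
#'
#' @param norm_resp SIL-normalized response.
#' @param sil_conc SIL spike concentration, pmol/ml; must be > 0.
#' @return concentration in pmol/ml.
#' @export
quantify_single_point <- function(norm_resp, sil_conc) {
  if (any(sil_conc <= 0))
    stop_evmrm("SIL concentration must be > 0", "evmrm_normalization_error")
  norm_resp * sil_conc
}

#' Fit a linear calibration curve
#'
#' Ordinary (unweighted) least-squares regression of SIL-normalized
#' response on nominal concentration, with fitted intercept;
#' `r2 = 1 - SS_res/SS_tot`. Optional 1/x weighting is available for
#' real-data use where response variance grows with concentration.
#'
#' @param levels data.frame with columns `nominal_conc` (pmol/ml, > 0) and
#'   `normalized_response`; an optional `replicate` column is carried
#'   through.
#' @param uloq upper limit of quantification, pmol/ml; defaults to the top
#'   calibrator.
#' @param analyte_id,matrix_id labels stored on the fit.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return object of class `ev_calibration` with components `slope`,
#'   `intercept`, `r2`, `uloq`, `levels`, usable with `coef`, `predict`,
#'   `residuals`, `summary` and `plot` methods and with
#'   [quantify_from_curve()].
#' @examples
#' fit <- fit_calibration(data.frame(nominal_conc = 1:3,
#'                                   normalized_response = 1:3))
#' coef(fit)   # intercept 0, slope 1
#' @export
fit_calibration <- function(levels, uloq = max(levels$nominal_conc),
                            analyte_id = NA_character_,
                            matrix_id = NA_character_,
                            weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  if (is.null(levels$nominal_conc) || is.null(levels$normalized_response))
    stop_evmrm("levels needs nominal_conc and normalized_response columns",
               "evmrm_insufficient_data")
  if (any(levels$nominal_conc <= 0))
    stop_evmrm("nominal concentrations must be > 0", "evmrm_insufficient_data")
  x <- levels$nominal_conc
  y <- levels$normalized_response
  if (length(unique(x)) < 3L)
    stop_evmrm("at least 3 distinct concentrations required",
               "evmrm_insufficient_data")
  if (stats::var(x) == 0)
    stop_evmrm("zero concentration variance: degenerate design",
               "evmrm_degenerate_design")
  w <- if (weighting == "1/x") 1 / x else rep(1, length(x))
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  ss_res <- sum((y - stats::fitted(fit))^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(analyte_id = analyte_id, matrix_id = matrix_id,
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 r2 = 1 - ss_res / ss_tot, uloq = uloq,
                 levels = levels, weighting = weighting, lm_fit = fit),
            class = "ev_calibration")
}

#' @export
print.ev_calibration <- function(x, ...) {
  cat(sprintf("calibration curve%s%s\n",
              if (!is.na(x$analyte_id)) paste0(" [", x$analyte_id, "]") else "",
              if (!is.na(x$matrix_id)) paste0(" in ", x$matrix_id) else ""))
  cat(sprintf("  response = %.4g + %.4g * conc   (r2 = %.4f, n = %d, ULOQ = %g pmol/ml)\n",
              x$intercept, x$slope, x$r2, nrow(x$levels), x$uloq))
  invisible(x)
}

#' @export
summary.ev_calibration <- function(object, ...) {
  s <- summary(object$lm_fit)
  out <- list(analyte_id = object$analyte_id, matrix_id = object$matrix_id,
              slope = object$slope, intercept = object$intercept,
              r2 = object$r2, uloq = object$uloq,
              n_levels = length(unique(object$levels$nominal_conc)),
              n_points = nrow(object$levels),
              slope_se = s$coefficients[2, 2],
              back_calculated = data.frame(
                nominal_conc = object$levels$nominal_conc,
                back_calc = (object$levels$normalized_response -
                               object$intercept) / object$slope))
  out$back_calculated$percent_true <-
    100 * out$back_calculated$back_calc / out$back_calculated$nominal_conc
  class(out) <- "summary.ev_calibration"
  out
}

#' @export
print.summary.ev_calibration <- function(x, ...) {
  cat(sprintf("calibration [%s in %s]: slope %.4g (SE %.2g), intercept %.4g, r2 %.4f\n",
              x$analyte_id, x$matrix_id, x$slope, x$slope_se, x$intercept, x$r2))
  cat(sprintf("  %d points over %d levels, ULOQ %g pmol/ml\n",
              x$n_points, x$n_levels, x$uloq))
  cat("  back-calculated accuracy (% true) per point:\n")
  print(data.frame(nominal = x$back_calculated$nominal_conc,
                   pct_true = signif(x$back_calculated$percent_true, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.ev_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.ev_calibration <- function(object, ...) {
  stats::residuals(object$lm_fit)
}

#' Predicted normalized response at given concentrations
#' @param object an `ev_calibration`.
#' @param newdata numeric concentrations (pmol/ml) or a data.frame with a
#'   `nominal_conc` column; default: the calibrator levels.
#' @param ... unused.
#' @export
predict.ev_calibration <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$levels$nominal_conc
       else if (is.data.frame(newdata)) newdata$nominal_conc
       else as.numeric(newdata)
  object$intercept + object$slope * x
}

#' @export
plot.ev_calibration <- function(x, ...) {
  graphics::plot(x$levels$nominal_conc, x$levels$normalized_response,
                 xlab = "nominal concentration (pmol/ml)",
                 ylab = "normalized response",
                 main = paste("Calibration", x$analyte_id), ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("r2 = %.4f", x$r2))
  invisible(x)
}

censor_label <- function(conc, lod, lloq, uloq) {
  ifelse(conc < lod, "below_LOD",
         ifelse(conc < lloq, "below_LLOQ",
                ifelse(conc > uloq, "above_ULOQ", "quantified")))
}

#' Quantify a response against a calibration curve, with censoring
#'
#' Concentration = (response - intercept)/slope, flagged against the
#' assay's limits: `below_LOD` (< LOD), `below_LLOQ` (in [LOD, LLOQ)),
#' `quantified` (in [LLOQ, ULOQ]) or `above_ULOQ` (> ULOQ). Censored
#' values keep their numeric estimate -- downstream reproducibility rules
#' need the number, not an NA.
#'
#' @param curve an `ev_calibration` with positive slope.
#' @param norm_resp SIL-normalized response(s).
#' @param lod,lloq detection and quantification limits, pmol/ml, with
#'   `lod < lloq <= uloq`.
#' @param sample_id optional label(s).
#' @param identity_confirmed optional logical flag(s) carried through.
#' @return data.frame of class `ev_quant`: sample_id, analyte_id,
#'   normalized_response, concentration, censor, identity_confirmed.
#' @export
quantify_from_curve <- function(curve, norm_resp, lod, lloq,
                                sample_id = NA_character_,
                                identity_confirmed = NA) {
  if (curve$slope <= 0)
    stop_evmrm("calibration slope must be > 0", "evmrm_invalid_curve")
  if (!(lod < lloq && lloq <= curve$uloq))
    stop_evmrm("limits must satisfy lod < lloq <= uloq", "evmrm_invalid_curve")
  conc <- (norm_resp - curve$intercept) / curve$slope
  out <- data.frame(sample_id = sample_id, analyte_id = curve$analyte_id,
                    normalized_response = norm_resp, concentration = conc,
                    censor = censor_label(conc, lod, lloq, curve$uloq),
                    identity_confirmed = identity_confirmed,
                    stringsAsFactors = FALSE)
  class(out) <- c("ev_quant", class(out))
  out
}

#' Quantify a replicate-study area table by single-point SIL normalization
#'
#' Converts the light/SIL quantifier areas of [simulate_replicate_study()]
#' (or any table with `light_area`, `sil_area`, `sil_spike_conc` columns)
#' into concentrations, optionally censored against per-method sensitivity
#' limits.
#'
#' @param areas data.frame with at least `analyte_id`, `light_area`,
#'   `sil_area`, `sil_spike_conc`; replicate-coordinate columns (donor,
#'   method, isolation, digest, sample_id) are carried through.
#' @param sensitivity optional data.frame with `analyte_id`, `lod`, `lloq`
#'   and optionally `method`/`matrix_id` columns used for the censor flag;
#'   a `uloq` column may cap the range.
#' @return the input with `normalized_response`, `concentration` and
#'   (when sensitivity is given) `censor` columns appended.
#' @export
quantify_areas <- function(areas, sensitivity = NULL) {
  areas$normalized_response <- normalized_response(areas$light_area,
                                                   areas$sil_area)
  areas$concentration <- quantify_single_point(areas$normalized_response,
                                               areas$sil_spike_conc)
  if (!is.null(sensitivity)) {
    by_method <- !is.null(sensitivity$method) && !is.null(areas$method)
    key_s <- if (by_method) paste(sensitivity$analyte_id, sensitivity$method)
             else sensitivity$analyte_id
    key_a <- if (by_method) paste(areas$analyte_id, areas$method)
             else areas$analyte_id
    i <- match(key_a, key_s)
    if (anyNA(i))
      stop_evmrm("sensitivity table does not cover all analytes/methods",
                 "evmrm_config_error")
    lod <- sensitivity$lod[i]
    lloq <- sensitivity$lloq[i]
    uloq <- if (!is.null(sensitivity$uloq)) sensitivity$uloq[i] else Inf
    areas$censor <- censor_label(areas$concentration, lod, lloq, uloq)
  }
  areas
}
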
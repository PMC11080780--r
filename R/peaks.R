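flank_region <- function(chrom, flank_frac = 0.15) {
  t0 <- min(chrom$times); t1 <- max(chrom$times)
  span <- t1 - t0
  eps <- 1e-9 * max(1, abs(t1))  # grid-robust boundary comparisons
  idx <- which(chrom$times <= t0 + flank_frac * span + eps |
                 chrom$times >= t1 - flank_frac * span - eps)
  idx
}

# linear baseline fitted over the flanking regions of the window
flank_baseline_fit <- function(chrom, flank_frac = 0.15) {
  idx <- flank_region(chrom, flank_frac)
  if (length(idx) < 6L)
    stop_evmrm("fewer than 6 flank points for noise/baseline estimation",
               "evmrm_insufficient_data")
  fit <- stats::lm.fit(cbind(1, chrom$times[idx]), chrom$intensities[idx])
  list(idx = idx, coef = fit$coefficients, residuals = fit$residuals)
}

#' Estimate baseline noise of a chromatogram
#'
#' A robust noise SD taken from the peak-free flanking regions (first and
#' last 15\% of the time window): a linear baseline is fitted over the
#' flanks and the noise is 1.4826 x the median absolute deviation of the
#' residuals. The median-based estimator is insensitive to any peak tail
#' leaking into the flanks.
#'
#' @param chrom an `ev_chromatogram`.
#' @param flank_frac fraction of the window treated as flank at each end.
#' @return noise SD in counts.
#' @export
estimate_noise <- function(chrom, flank_frac = 0.15) {
  fb <- flank_baseline_fit(chrom, flank_frac)
  stats::mad(fb$residuals, center = stats::median(fb$residuals))
}

#' Detect and integrate the peak nearest an expected retention time
#'
#' The trace is smoothed with a fixed-width moving average and the apex is
#' the smoothed maximum inside `expected_rt +/- rt_window` (earliest time
#' wins on ties). The peak width is estimated as the half-width at 60.65\%
#' of the baseline-subtracted apex height (the 1-sigma level of a
#' Gaussian); integration runs over apex +/- 4 sigma (99.99\% of a
#' Gaussian), clipped to the search window, by trapezoid on the
#' baseline-subtracted raw trace, floored at zero. A peak is "detected"
#' when the signal-to-noise ratio (baseline-subtracted height over the
#' flank noise SD) reaches 3 -- the assay's LOD criterion. Undetected
#' results still report their area and height so that downstream averaging
#' over replicates is unbiased.
#'
#' @param chrom an `ev_chromatogram`.
#' @param expected_rt expected retention time, minutes; must lie inside the
#'   trace.
#' @param rt_window half-width of the apex search window, minutes.
#' @param smooth_width moving-average width in points (odd).
#' @param flank_frac flank fraction for baseline/noise estimation.
#' @return list of class `ev_peak`: `rt_apex`, `area` (counts*min,
#'   baseline-subtracted), `height` (counts, baseline-subtracted),
#'   `noise_sd`, `snr`, `detected`, `sigma_est`.
#' @export
detect_and_integrate <- function(chrom, expected_rt, rt_window = 0.5,
                                 smooth_width = 5, flank_frac = 0.15) {
  if (expected_rt < min(chrom$times) || expected_rt > max(chrom$times))
    stop_evmrm("expected_rt outside chromatogram time range", "evmrm_bounds_error")
  lo <- expected_rt - rt_window
  hi <- expected_rt + rt_window
  eps <- 1e-9 * max(1, abs(hi))
  win <- which(chrom$times >= lo - eps & chrom$times <= hi + eps)
  if (length(win) < 3L)
    stop_evmrm("search window contains too few points", "evmrm_bounds_error")

  fb <- flank_baseline_fit(chrom, flank_frac)
  noise_sd <- stats::mad(fb$residuals, center = stats::median(fb$residuals))
  bl <- fb$coef[1] + fb$coef[2] * chrom$times
  y <- chrom$intensities - bl

  k <- rep(1 / smooth_width, smooth_width)
  ys <- stats::filter(y, k, sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)

  apex_i <- win[which.max(ys[win])]  # which.max: earliest index on ties
  rt_apex <- chrom$times[apex_i]
  height <- y[apex_i]

  # Gaussian sigma from half-width at exp(-1/2) of apex height
  thr <- 0.6065 * max(ys[apex_i], 0)
  sigma_est <- NA_real_
  if (thr > 0) {
    left <- apex_i
    while (left > 1 && ys[left] > thr) left <- left - 1L
    right <- apex_i
    n <- length(ys)
    while (right < n && ys[right] > thr) right <- right + 1L
    half_l <- rt_apex - chrom$times[left]
    half_r <- chrom$times[right] - rt_apex
    sigma_est <- (half_l + half_r) / 2
  }
  if (!is.finite(sigma_est) || sigma_est <= 0) {
    sigma_est <- (hi - lo) / 8  # degenerate peak: fall back to window scale
  }

  b_lo <- max(lo, rt_apex - 4 * sigma_est)
  b_hi <- min(hi, rt_apex + 4 * sigma_est)
  bi <- which(chrom$times >= b_lo - eps & chrom$times <= b_hi + eps)
  area <- max(0, trapz(chrom$times[bi], y[bi]))

  snr <- if (noise_sd > 0) max(0, height) / noise_sd else
    if (height > 0) Inf else 0
  structure(list(rt_apex = rt_apex, area = area, height = height,
                 noise_sd = noise_sd, snr = snr, detected = snr >= 3,
                 sigma_est = sigma_est),
            class = "ev_peak")
}

#' @export
print.ev_peak <- function(x, ...) {
  cat(sprintf(
    "peak: apex %.3f min, area %.1f counts*min, height %.1f, S/N %.1f (%s)\n",
    x$rt_apex, x$area, x$height, x$snr,
    if (x$detected) "detected" else "not detected"))
  invisible(x)
}

#' Confirm endogenous peptide identity against the SIL standard
#'
#' Identity of the endogenous (light) peptide is confirmed when its
#' quantifier apex co-elutes with the SIL quantifier (|RT delta| within
#' tolerance) and every qualifier/quantifier area ratio matches the SIL
#' reference ratio within a relative tolerance. A light qualifier that is
#' undetected while the light quantifier is far above the quantification
#' limit (S/N at least `missing_qualifier_snr_gate`) also fails
#' confirmation; at low signal a missing qualifier is expected and not
#' penalised.
#'
#' @param light_peaks named list of `ev_peak` for the light form, with a
#'   `quantifier` element and one element per qualifier product label.
#' @param sil_peaks same structure for the SIL form (the reference).
#' @param rt_tolerance maximum |RT delta| in minutes (default 0.3).
#' @param ratio_tolerance maximum relative ratio deviation (default 0.30).
#' @param missing_qualifier_snr_gate light-quantifier S/N above which a
#'   missing light qualifier vetoes confirmation; default 45, i.e. three
#'   times the S/N that defines the LLOQ (S/N 15 = 5 x the LOD criterion).
#' @return list of class `ev_identity`: `rt_delta`, `ratio_deviations`
#'   (named per qualifier), `confirmed`.
#' @export
confirm_identity <- function(light_peaks, sil_peaks, rt_tolerance = 0.3,
                             ratio_tolerance = 0.30,
                             missing_qualifier_snr_gate = 45) {
  if (is.null(sil_peaks$quantifier))
    stop_evmrm("SIL quantifier peak missing: identity reference unavailable",
               "evmrm_reference_unavailable")
  if (is.null(light_peaks$quantifier))
    stop_evmrm("light quantifier peak missing", "evmrm_reference_unavailable")
  quals <- setdiff(intersect(names(light_peaks), names(sil_peaks)), "quantifier")
  if (length(quals) < 1L)
    stop_evmrm("at least one qualifier required in both forms",
               "evmrm_reference_unavailable")

  rt_delta <- light_peaks$quantifier$rt_apex - sil_peaks$quantifier$rt_apex
  q_snr <- light_peaks$quantifier$snr
  devs <- stats::setNames(numeric(length(quals)), quals)
  confirmed <- abs(rt_delta) <= rt_tolerance
  for (q in quals) {
    ref_ratio <- sil_peaks[[q]]$area / sil_peaks$quantifier$area
    if (!light_peaks[[q]]$detected) {
      if (q_snr >= missing_qualifier_snr_gate) {
        devs[q] <- Inf
        confirmed <- FALSE
      } else {
        # near the detection limit a missing qualifier is expected, not a veto
        devs[q] <- NA_real_
      }
      next
    }
    light_ratio <- light_peaks[[q]]$area / light_peaks$quantifier$area
    devs[q] <- abs(light_ratio / ref_ratio - 1)
    if (devs[q] > ratio_tolerance) confirmed <- FALSE
  }
  structure(list(rt_delta = rt_delta, ratio_deviations = devs,
                 confirmed = confirmed),
            class = "ev_identity")
}

#' @export
print.ev_identity <- function(x, ...) {
  cat(sprintf("identity %s: RT delta %+.3f min, max ratio deviation %.0f%%\n",
              if (x$confirmed) "CONFIRMED" else "NOT confirmed",
              x$rt_delta,
              100 * if (all(is.na(x$ratio_deviations))) NA_real_
                    else max(x$ratio_deviations, na.rm = TRUE)))
  invisible(x)
}

#' Integrate every transition of a simulated injection
#'
#' Convenience wrapper: runs [detect_and_integrate()] on each chromatogram
#' of a [simulate_injection()] result (or any named chromatogram list) and
#' returns a results table in the pre-integrated format accepted by the
#' quantification layer.
#'
#' @param chroms named list of `ev_chromatogram` keyed
#'   `analyte|form|product_label`.
#' @param panel an [ev_panel] supplying expected retention times.
#' @param rt_window apex search half-window, minutes.
#' @return data.frame: sample_id, analyte_id, form, role, product_label,
#'   rt_apex, area, height, noise_sd, snr, detected.
#' @export
integrate_injection <- function(chroms, panel, rt_window = 0.5) {
  rows <- lapply(chroms, function(ch) {
    rt <- panel_analyte(panel, ch$analyte_id)$expected_rt
    pk <- detect_and_integrate(ch, rt, rt_window)
    data.frame(sample_id = ch$sample_id, analyte_id = ch$analyte_id,
               form = ch$form, role = ch$role,
               product_label = ch$product_label,
               rt_apex = pk$rt_apex, area = pk$area, height = pk$height,
               noise_sd = pk$noise_sd, snr = pk$snr, detected = pk$detected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
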
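get_sensitivity_limits <- function(sensitivity, analyte_id, method = NULL) {
  if (inherits(sensitivity, "ev_sensitivity"))
    return(list(lod = sensitivity$lod, lloq = sensitivity$lloq))
  if (is.data.frame(sensitivity)) {
    hit <- sensitivity$analyte_id == analyte_id
    if (!is.null(method) && !is.null(sensitivity$method))
      hit <- hit & sensitivity$method == method
    i <- which(hit)
    if (length(i) == 0)
      stop_evmrm(paste0("no sensitivity limits for ", analyte_id,
                        if (!is.null(method)) paste0(" / ", method)),
                 "evmrm_config_error")
    return(list(lod = sensitivity$lod[i[1]], lloq = sensitivity$lloq[i[1]]))
  }
  stop_evmrm("sensitivity must be an ev_sensitivity or a data.frame",
             "evmrm_config_error")
}

#' Detection reproducibility across replicate isolations
#'
#' An isolation counts as "detected" when the mean concentration over its
#' digest replicates exceeds the LOD (equivalent to the mean normalized
#' response exceeding the LOD-equivalent response, since single-point
#' quantification is linear). The percentage is taken over all isolations
#' with donors pooled, rounded to the nearest integer.
#'
#' @param dataset data.frame with columns `analyte_id`, `method`, `donor`,
#'   `isolation`, `digest`, `concentration` (e.g. from [quantify_areas()]
#'   on a [simulate_replicate_study()]).
#' @param sensitivity per-analyte limits: data.frame with `analyte_id`,
#'   `lod`, `lloq` and optionally `method` (matrix-adjusted limits).
#' @return data.frame: analyte_id, method, n_isolations, n_detected,
#'   pct_isolations_above_lod.
#' @export
detection_reproducibility <- function(dataset, sensitivity) {
  out <- list()
  for (g in split(dataset, list(dataset$analyte_id, dataset$method),
                  drop = TRUE)) {
    lim <- get_sensitivity_limits(sensitivity, g$analyte_id[1], g$method[1])
    iso_means <- tapply(g$concentration, paste(g$donor, g$isolation), mean)
    n <- length(iso_means)
    k <- sum(iso_means > lim$lod)
    out[[length(out) + 1L]] <- data.frame(
      analyte_id = g$analyte_id[1], method = g$method[1],
      n_isolations = n, n_detected = k,
      pct_isolations_above_lod = round(100 * k / n),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$analyte_id, res$method), , drop = FALSE]
}

#' Digest-pair detection equivalence rate
#'
#' A duplicate digest pair is "equivalent" when both members fall on the
#' same side of the LOD; the percentage is over all pairs (donors pooled),
#' rounded to the nearest integer. With more than two digests per
#' isolation, pairs are formed by consecutive replicate index and any
#' leftover digest is flagged.
#'
#' @inheritParams detection_reproducibility
#' @return data.frame: analyte_id, method, n_pairs, n_equivalent,
#'   pct_equivalent_digest_pairs, n_unpaired.
#' @export
digest_equivalence_rate <- function(dataset, sensitivity) {
  out <- list()
  for (g in split(dataset, list(dataset$analyte_id, dataset$method),
                  drop = TRUE)) {
    lim <- get_sensitivity_limits(sensitivity, g$analyte_id[1], g$method[1])
    n_pairs <- 0L; n_eq <- 0L; n_unpaired <- 0L
    for (iso in split(g, paste(g$donor, g$isolation))) {
      iso <- iso[order(iso$digest), ]
      m <- nrow(iso)
      if (m %% 2L == 1L) n_unpaired <- n_unpaired + 1L
      for (p in seq_len(m %/% 2L)) {
        a <- iso$concentration[2 * p - 1]
        b <- iso$concentration[2 * p]
        n_pairs <- n_pairs + 1L
        if ((a > lim$lod) == (b > lim$lod)) n_eq <- n_eq + 1L
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      analyte_id = g$analyte_id[1], method = g$method[1],
      n_pairs = n_pairs, n_equivalent = n_eq,
      pct_equivalent_digest_pairs = round(100 * n_eq / n_pairs),
      n_unpaired = n_unpaired, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$analyte_id, res$method), , drop = FALSE]
}

#' Quantification reproducibility (\%RSD) over isolations and digests
#'
#' Digest variability is the root-mean-square of per-pair \%RSDs over
#' pairs in which both members are at or above the LLOQ; isolation
#' variability is the \%RSD of per-isolation mean concentrations (donors
#' pooled) over isolations whose mean is at or above the LLOQ. When every
#' contributing value is below the LLOQ the analyte/method cell is marked
#' censored-reproducible (noise precludes a meaningful \%RSD) rather than
#' given a number.
#'
#' @inheritParams detection_reproducibility
#' @param digest_aggregate `"rms"` (default) or `"mean"` aggregation of
#'   per-pair \%RSDs.
#' @return data.frame: analyte_id, method, mean_concentration,
#'   isolation_rsd, digest_rsd, censored (all values < LLOQ),
#'   n_isolations_used, n_pairs_used.
#' @export
quantification_rsd <- function(dataset, sensitivity,
                               digest_aggregate = c("rms", "mean")) {
  digest_aggregate <- match.arg(digest_aggregate)
  out <- list()
  for (g in split(dataset, list(dataset$analyte_id, dataset$method),
                  drop = TRUE)) {
    lim <- get_sensitivity_limits(sensitivity, g$analyte_id[1], g$method[1])
    censored <- all(g$concentration < lim$lloq)
    iso_means <- tapply(g$concentration, paste(g$donor, g$isolation), mean)
    iso_used <- iso_means[iso_means >= lim$lloq]
    iso_rsd <- if (censored) NA_real_
      else if (length(iso_used) >= 2) pct_rsd(as.numeric(iso_used))
      else NA_real_
    pair_rsds <- c()
    for (iso in split(g, paste(g$donor, g$isolation))) {
      iso <- iso[order(iso$digest), ]
      for (p in seq_len(nrow(iso) %/% 2L)) {
        ab <- iso$concentration[c(2 * p - 1, 2 * p)]
        if (all(ab >= lim$lloq)) pair_rsds <- c(pair_rsds, pct_rsd(ab))
      }
    }
    dig_rsd <- if (censored || length(pair_rsds) == 0) NA_real_
      else if (digest_aggregate == "rms") sqrt(mean(pair_rsds^2))
      else mean(pair_rsds)
    out[[length(out) + 1L]] <- data.frame(
      analyte_id = g$analyte_id[1], method = g$method[1],
      mean_concentration = mean(g$concentration),
      isolation_rsd = iso_rsd, digest_rsd = dig_rsd, censored = censored,
      n_isolations_used = if (censored) 0L else length(iso_used),
      n_pairs_used = if (censored) 0L else length(pair_rsds),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$analyte_id, res$method), , drop = FALSE]
}

#' Fold difference between two concentrations
#'
#' @param conc_a,conc_b concentrations in pmol/ml; `conc_b` must be > 0.
#' @return `conc_a / conc_b`, full precision; use [format_fold()] for the
#'   reported figure (3 significant digits at or above 10-fold, 2 below).
#' @examples
#' format_fold(fold_difference(27984, 34))  # 823
#' format_fold(fold_difference(122, 34))    # 3.6
#' @export
fold_difference <- function(conc_a, conc_b) {
  if (any(conc_b <= 0))
    stop_evmrm("fold difference undefined for non-positive reference",
               "evmrm_undefined_fold")
  conc_a / conc_b
}

#' Scale isolate concentrations to a per-ml-of-serum basis
#'
#' Isolates are concentrated from a larger serum input (default 500 ul of
#' serum yielding 100 ul of isolate); when contaminant depletion is to be
#' reported against the starting material, concentrations are multiplied
#' by isolate volume over serum input volume.
#'
#' @param conc concentration in the isolate, pmol/ml.
#' @param isolate_volume_ml,serum_input_volume_ml volumes in ml.
#' @return serum-equivalent concentration, pmol per ml of serum.
#' @export
serum_equivalent_conc <- function(conc, isolate_volume_ml = 0.1,
                                  serum_input_volume_ml = 0.5) {
  conc * isolate_volume_ml / serum_input_volume_ml
}
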
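#' Render a MISEV-style marker characterization report
#'
#' Per analyte and isolation method: positive EV markers (MISEV categories
#' 1-2) are called "present" when the detection reproducibility across
#' isolations reaches a threshold (default 75\%); contaminant markers
#' (categories 3-4) are reported with their fold difference versus a
#' reference method (and versus the starting material when a serum
#' concentration is supplied). Rows carry censoring and identity flags and
#' are deterministically ordered by MISEV category then analyte id.
#'
#' @param dataset quantified replicate dataset (see
#'   [detection_reproducibility()]); must carry a `censor` column when
#'   above-ULOQ flagging is wanted.
#' @param reproducibility output of [detection_reproducibility()].
#' @param quant_rsd output of [quantification_rsd()].
#' @param panel the [ev_panel] analysed.
#' @param presence_threshold detection percentage at or above which a
#'   positive marker is "present".
#' @param reference_method method used as depletion reference for
#'   contaminants (default `"qEV70"`).
#' @param serum_conc optional named per-analyte concentration in the
#'   starting serum, pmol/ml, for percent-of-serum depletion figures.
#' @return object of class `ev_misev_report`: a data.frame (`rows`) plus
#'   rendering metadata; `print()` and [format_misev_report()] produce the
#'   human-readable document.
#' @export
render_misev_report <- function(dataset, reproducibility, quant_rsd, panel,
                                presence_threshold = 75,
                                reference_method = "qEV70",
                                serum_conc = NULL) {
  methods <- sort(unique(dataset$method))
  an <- panel$analytes[order(panel$analytes$misev_category,
                             panel$analytes$analyte_id), ]
  gap <- setdiff(1:4, unique(an$misev_category))
  rows <- list()
  for (i in seq_len(nrow(an))) {
    aid <- an$analyte_id[i]
    ref_mean <- quant_rsd$mean_concentration[
      quant_rsd$analyte_id == aid & quant_rsd$method == reference_method]
    for (m in methods) {
      det <- reproducibility[reproducibility$analyte_id == aid &
                               reproducibility$method == m, ]
      qr <- quant_rsd[quant_rsd$analyte_id == aid & quant_rsd$method == m, ]
      sub <- dataset[dataset$analyte_id == aid & dataset$method == m, ]
      above_uloq <- !is.null(sub$censor) && any(sub$censor == "above_ULOQ")
      id_fail <- !is.null(sub$identity_confirmed) &&
        any(!sub$identity_confirmed, na.rm = TRUE)
      positive <- an$marker_polarity[i] == "positive_ev"
      pct <- if (nrow(det) == 1) det$pct_isolations_above_lod else NA_real_
      fold_ref <- if (!positive && length(ref_mean) == 1 && ref_mean > 0 &&
                      nrow(qr) == 1)
        format_fold(fold_difference(qr$mean_concentration, ref_mean))
        else NA_real_
      pct_serum <- if (!positive && !is.null(serum_conc) && nrow(qr) == 1 &&
                       conc_of(serum_conc, aid) > 0)
        100 * serum_equivalent_conc(qr$mean_concentration) /
          conc_of(serum_conc, aid) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        analyte_id = aid, misev_category = an$misev_category[i],
        marker_polarity = an$marker_polarity[i], method = m,
        pct_isolations_above_lod = pct,
        verdict = if (positive) {
          if (!is.na(pct) && pct >= presence_threshold) "present"
          else "not reproducibly detected"
        } else "contaminant",
        mean_concentration = if (nrow(qr) == 1) qr$mean_concentration else NA_real_,
        censored_lloq = if (nrow(qr) == 1) qr$censored else NA,
        isolation_rsd = if (nrow(qr) == 1) qr$isolation_rsd else NA_real_,
        fold_vs_reference = fold_ref,
        pct_of_serum = pct_serum,
        flag_above_uloq = above_uloq,
        flag_identity_failure = id_fail,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(rows = do.call(rbind, rows),
                 presence_threshold = presence_threshold,
                 reference_method = reference_method,
                 gap_categories = gap),
            class = "ev_misev_report")
}

#' Format a MISEV report as text lines
#'
#' Deterministic: identical inputs produce byte-identical output.
#'
#' @param report an `ev_misev_report`.
#' @return character vector of report lines.
#' @export
format_misev_report <- function(report) {
  r <- report$rows
  lines <- c("MISEV marker characterization report",
             sprintf("presence threshold: %g%% of isolations above LOD; depletion reference: %s",
                     report$presence_threshold, report$reference_method),
             "")
  if (length(report$gap_categories) > 0)
    lines <- c(lines, sprintf(
      "WARNING: no analyte covers MISEV category %s",
      paste(report$gap_categories, collapse = ", ")), "")
  for (i in seq_len(nrow(r))) {
    conc <- if (isTRUE(r$censored_lloq[i])) "<LLOQ"
            else sprintf("%.3g pmol/ml", r$mean_concentration[i])
    flags <- c(if (r$flag_above_uloq[i]) "above_ULOQ",
               if (r$flag_identity_failure[i]) "identity_failure")
    extra <- if (r$marker_polarity[i] == "contaminant" &&
                 !is.na(r$fold_vs_reference[i]) &&
                 r$method[i] != report$reference_method)
      sprintf(" (%gx vs %s)", r$fold_vs_reference[i], report$reference_method)
      else ""
    pserum <- if (!is.na(r$pct_of_serum[i]))
      sprintf(" [%.3g%% of serum]", r$pct_of_serum[i]) else ""
    lines <- c(lines, sprintf(
      "cat%d %-7s %-9s det %3s%%  %s  %s%s%s%s",
      r$misev_category[i], r$analyte_id[i], r$method[i],
      ifelse(is.na(r$pct_isolations_above_lod[i]), "NA",
             r$pct_isolations_above_lod[i]),
      format(conc, width = 12), r$verdict[i], extra, pserum,
      if (length(flags) > 0) paste0(" FLAGS: ", paste(flags, collapse = ","))
      else ""))
  }
  lines
}

#' @export
print.ev_misev_report <- function(x, ...) {
  cat(paste(format_misev_report(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Write a MISEV report to a text file
#'
#' @param report an `ev_misev_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_misev_report <- function(report, path) {
  writeLines(format_misev_report(report), path)
  invisible(path)
}

#' Write a quantification table as delimited text
#'
#' Tab-separated with a leading comment line naming the units.
#'
#' @param quant data.frame with quantification results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# concentration: pmol/ml; areas: counts*min; rsd: percent", con)
  utils::write.table(quant, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
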
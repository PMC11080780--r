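#' Read an analyte panel from a YAML config document
#'
#' The document holds three tables (`analytes`, `transitions`,
#' `calibration_ranges`) as lists of records plus an optional
#' `instrument_settings` block carried verbatim. Concentrations given in nM
#' are accepted and converted 1:1 to pmol/ml (the units are equivalent);
#' a `units:` block may declare `concentration: nM` to make that explicit,
#' in which case a note is emitted.
#'
#' @param path path to a UTF-8 YAML file.
#' @return an [ev_panel]; parse failures raise a format error naming the
#'   offending field, invariant breaches raise a validation error listing
#'   every violation.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop_evmrm(paste0("panel file not found: ", path),
                                     "evmrm_format_error")
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_evmrm(
                    paste0("cannot parse panel file '", path, "': ",
                           conditionMessage(e)),
                    "evmrm_format_error"))
  for (block in c("analytes", "transitions", "calibration_ranges")) {
    if (is.null(doc[[block]]))
      stop_evmrm(paste0("panel file missing '", block, "' block"),
                 "evmrm_format_error")
  }
  bind_records <- function(recs, block) {
    rows <- lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      if (!is.list(r)) stop_evmrm(
        paste0("record ", i, " of '", block, "' is not a mapping"),
        "evmrm_format_error")
      as.data.frame(r, stringsAsFactors = FALSE)
    })
    need <- switch(block,
      analytes = c("analyte_id", "protein_name", "misev_category",
                   "marker_polarity", "peptide_sequence", "sil_spike_conc"),
      transitions = c("analyte_id", "form", "precursor_mz", "product_mz",
                      "product_label", "role", "collision_energy", "expected_rt"),
      calibration_ranges = c("analyte_id", "low", "high"))
    df <- tryCatch(do.call(rbind, rows), error = function(e) stop_evmrm(
      paste0("inconsistent fields in '", block, "': ", conditionMessage(e)),
      "evmrm_format_error"))
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      stop_evmrm(paste0("'", block, "' records missing field(s): ",
                        paste(miss, collapse = ", ")), "evmrm_format_error")
    df[, need]
  }
  analytes <- bind_records(doc$analytes, "analytes")
  analytes$misev_category <- as.integer(analytes$misev_category)
  if (identical(doc$units$concentration, "nM"))
    message("panel concentrations declared in nM; converted 1:1 to pmol/ml")
  panel <- ev_panel(analytes,
                    bind_records(doc$transitions, "transitions"),
                    bind_records(doc$calibration_ranges, "calibration_ranges"),
                    doc$instrument_settings %||% list())
  viol <- validate_panel(panel)
  if (nrow(viol) > 0) {
    msgs <- paste0(viol$analyte_id, "/", viol$field, ": ", viol$rule)
    stop_evmrm(paste0("panel fails validation:\n  ",
                      paste(msgs, collapse = "\n  ")),
               "evmrm_validation_error")
  }
  panel
}

#' Write an analyte panel to a YAML config document
#'
#' @param panel an [ev_panel].
#' @param path output path; re-reading with [load_panel()] reproduces a
#'   structurally identical panel.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df_to_records <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  doc <- list(
    units = list(concentration = "pmol/ml", time = "minutes",
                 collision_energy = "eV"),
    analytes = df_to_records(panel$analytes),
    transitions = df_to_records(panel$transitions),
    calibration_ranges = df_to_records(panel$calibration_ranges),
    instrument_settings = panel$instrument_settings
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Import a vendor-style delimited transition list
#'
#' Reads a tab- or comma-delimited table with the seven columns
#' `analyte_id`, `form`, `precursor_mz`, `product_mz`, `role`,
#' `collision_energy`, `expected_rt` (a `product_label` column is kept when
#' present) and returns the transition table; combine with analyte metadata
#' via [ev_panel()].
#'
#' @param path delimited text file, dot decimal separator.
#' @param sep field separator, default tab.
#' @return transitions data.frame.
#' @export
read_transition_list <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("analyte_id", "form", "precursor_mz", "product_mz", "role",
            "collision_energy", "expected_rt")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_evmrm(paste0("transition list missing column(s): ",
                      paste(miss, collapse = ", ")), "evmrm_format_error")
  if (is.null(df$product_label)) df$product_label <- NA_character_
  df[, c("analyte_id", "form", "precursor_mz", "product_mz", "product_label",
         "role", "collision_energy", "expected_rt")]
}

#' Export a panel's transition table as a delimited transition list
#'
#' @param panel an [ev_panel].
#' @param path output path.
#' @param sep field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(panel, path, sep = "\t") {
  utils::write.table(panel$transitions, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
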
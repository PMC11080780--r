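#' Construct an analyte panel
#'
#' An analyte panel bundles the peptide analytes of a targeted MRM assay
#' (their proteotypic peptide sequences, MISEV marker categories and SIL
#' internal-standard spike concentrations), the transition table (precursor
#' and product m/z, quantifier/qualifier roles, collision energies, expected
#' retention times for both the light and the stable-isotope-labelled form),
#' the per-analyte validated calibration ranges, and opaque instrument
#' metadata.
#'
#' @param analytes data.frame with columns `analyte_id`, `protein_name`,
#'   `misev_category` (integer 1-4), `marker_polarity`
#'   (`"positive_ev"`/`"contaminant"`), `peptide_sequence`,
#'   `sil_spike_conc` (pmol/ml).
#' @param transitions data.frame with columns `analyte_id`, `form`
#'   (`"SIL"`/`"light"`), `precursor_mz`, `product_mz`, `product_label`,
#'   `role` (`"quantifier"`/`"qualifier"`), `collision_energy` (eV),
#'   `expected_rt` (minutes).
#' @param calibration_ranges data.frame with columns `analyte_id`, `low`,
#'   `high` (pmol/ml). The top calibrator doubles as the upper limit of
#'   quantification (ULOQ).
#' @param instrument_settings optional list of instrument metadata records
#'   (time segments, voltages); carried verbatim, never interpreted.
#' @return an object of class `ev_panel`.
#' @seealso [builtin_panel()], [validate_panel()], [load_panel()]
#' @export
ev_panel <- function(analytes, transitions, calibration_ranges,
                     instrument_settings = list()) {
  analytes <- as.data.frame(analytes, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  calibration_ranges <- as.data.frame(calibration_ranges, stringsAsFactors = FALSE)
  structure(
    list(
      analytes = analytes,
      transitions = transitions,
      calibration_ranges = calibration_ranges,
      instrument_settings = instrument_settings
    ),
    class = "ev_panel"
  )
}

#' @export
print.ev_panel <- function(x, ...) {
  cat("MRM analyte panel:", nrow(x$analytes), "analytes,",
      nrow(x$transitions), "transitions\n")
  pos <- x$analytes$analyte_id[x$analytes$marker_polarity == "positive_ev"]
  neg <- x$analytes$analyte_id[x$analytes$marker_polarity == "contaminant"]
  cat("  positive EV markers:", paste(pos, collapse = ", "), "\n")
  cat("  contaminant markers:", paste(neg, collapse = ", "), "\n")
  v <- validate_panel(x)
  cat(if (nrow(v) == 0) "  panel valid\n"
      else paste0("  INVALID: ", nrow(v), " violation(s); see validate_panel()\n"))
  invisible(x)
}

#' Look up one analyte of a panel
#'
#' @param panel an [ev_panel].
#' @param analyte_id analyte label, e.g. `"CD9"`.
#' @return a list with the analyte row fields plus `expected_rt` (minutes),
#'   `quantifier` rows and the calibration range.
#' @export
panel_analyte <- function(panel, analyte_id) {
  i <- match(analyte_id, panel$analytes$analyte_id)
  if (is.na(i)) stop_evmrm(paste0("unknown analyte '", analyte_id, "'"),
                           "evmrm_unknown_analyte")
  a <- as.list(panel$analytes[i, ])
  tr <- panel$transitions[panel$transitions$analyte_id == analyte_id, ]
  a$expected_rt <- tr$expected_rt[1]
  a$quantifier <- tr[tr$role == "quantifier", ]
  rng <- panel$calibration_ranges[panel$calibration_ranges$analyte_id == analyte_id, ]
  if (nrow(rng) == 1) {
    a$cal_low <- rng$low
    a$cal_high <- rng$high
    a$uloq <- rng$high
  }
  a
}

#' Validate a panel against the assay design rules
#'
#' Checks every panel invariant and reports violations instead of throwing:
#' peptide length 7-22 residues with no methionine or cysteine (both are
#' oxidation/modification liabilities in targeted assays), MISEV category
#' consistent with marker polarity (categories 1-2 are positive EV markers,
#' 3-4 contaminants), positive SIL spike, exactly one quantifier and at
#' least two qualifiers per analyte and form, matched SIL/light retention
#' times and collision energies, SIL precursor above the light precursor,
#' and calibration range low < high.
#'
#' @param panel an [ev_panel].
#' @return data.frame with columns `analyte_id`, `field`, `rule`; zero rows
#'   when the panel is valid.
#' @export
validate_panel <- function(panel) {
  v <- list()
  bad <- function(analyte_id, field, rule) {
    v[[length(v) + 1L]] <<- data.frame(analyte_id = analyte_id, field = field,
                                       rule = rule, stringsAsFactors = FALSE)
  }

  an <- panel$analytes
  for (i in seq_len(nrow(an))) {
    id <- an$analyte_id[i]
    seq_ <- an$peptide_sequence[i]
    n <- nchar(seq_)
    if (n < 7 || n > 22)
      bad(id, "peptide_sequence", "length must be 7-22 residues")
    if (grepl("[MC]", seq_))
      bad(id, "peptide_sequence", "forbidden residue (M or C)")
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seq_))
      bad(id, "peptide_sequence", "non-amino-acid character")
    cat_ <- an$misev_category[i]
    pol <- an$marker_polarity[i]
    if (!cat_ %in% 1:4) {
      bad(id, "misev_category", "category must be 1-4")
    } else if ((cat_ %in% 1:2) != (pol == "positive_ev")) {
      bad(id, "misev_category",
          "categories 1-2 must be positive_ev, 3-4 contaminant")
    }
    if (!is.finite(an$sil_spike_conc[i]) || an$sil_spike_conc[i] <= 0)
      bad(id, "sil_spike_conc", "SIL spike concentration must be > 0")
  }

  tr <- panel$transitions
  orphan <- setdiff(unique(tr$analyte_id), an$analyte_id)
  for (id in orphan) bad(id, "analyte_id", "transition references undeclared analyte")

  for (id in an$analyte_id) {
    sub <- tr[tr$analyte_id == id, ]
    if (nrow(sub) == 0) {
      bad(id, "transitions", "analyte has no transitions")
      next
    }
    for (form in c("SIL", "light")) {
      fs <- sub[sub$form == form, ]
      nq <- sum(fs$role == "quantifier")
      if (nq == 0) bad(id, "role", paste0("missing quantifier (", form, ")"))
      if (nq > 1) bad(id, "role", paste0("duplicate quantifier (", form, ")"))
      if (sum(fs$role == "qualifier") < 2)
        bad(id, "role", paste0("fewer than 2 qualifiers (", form, ")"))
    }
    sil <- sub[sub$form == "SIL", ]
    lig <- sub[sub$form == "light", ]
    if (nrow(sil) > 0 && nrow(lig) > 0) {
      if (length(unique(sub$expected_rt)) > 1)
        bad(id, "expected_rt", "SIL and light retention times must be equal")
      if (length(unique(sub$collision_energy)) > 1)
        bad(id, "collision_energy", "collision energy must match within SIL/light pair")
      if (max(sil$precursor_mz) <= max(lig$precursor_mz) ||
          min(sil$precursor_mz) <= min(lig$precursor_mz)) {
        if (!all(sil$precursor_mz > max(lig$precursor_mz)))
          bad(id, "precursor_mz", "SIL precursor m/z must exceed light precursor m/z")
      }
    }
  }

  cr <- panel$calibration_ranges
  for (i in seq_len(nrow(cr))) {
    if (!(cr$low[i] > 0 && cr$high[i] > cr$low[i]))
      bad(cr$analyte_id[i], "calibration_range", "range must satisfy 0 < low < high")
  }

  if (length(v) == 0)
    data.frame(analyte_id = character(), field = character(), rule = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, v)
}

#' The published five-protein EV marker panel
#'
#' Returns the validated panel of three positive EV markers -- the
#' tetraspanins CD81 (MISEV category 1) and CD9 (category 1) and the
#' cytosolic ESCRT protein TSG101 (category 2) -- and two contaminant
#' markers: serum albumin (ALB, category 3, matrix-associated protein) and
#' the endoplasmic-reticulum protein calnexin (CANX, category 4, marker of
#' cellular debris). Each analyte carries one proteotypic tryptic peptide
#' monitored as one quantifier plus two qualifier transitions in both the
#' light (endogenous) and stable-isotope-labelled (SIL) form, the SIL
#' internal-standard spike concentration (pmol/ml), the validated
#' calibration range (a 40-fold span per analyte), and the instrument time
#' segments and source voltages as opaque metadata.
#'
#' @return an [ev_panel] that passes [validate_panel()] with zero violations.
#' @examples
#' p <- builtin_panel()
#' panel_analyte(p, "TSG101")$expected_rt   # 32.5 min
#' panel_analyte(p, "ALB")$sil_spike_conc   # 10 pmol/ml
#' @export
builtin_panel <- function() {
  analytes <- data.frame(
    analyte_id = c("ALB", "CD81", "CD9", "CANX", "TSG101"),
    protein_name = c("Serum albumin", "CD81 antigen", "CD9 antigen",
                     "Calnexin", "Tumor susceptibility gene 101 protein"),
    misev_category = c(3L, 1L, 1L, 4L, 2L),
    marker_polarity = c("contaminant", "positive_ev", "positive_ev",
                        "contaminant", "positive_ev"),
    peptide_sequence = c("LVNEVTEFAK", "QFYDQALQQAVVDDDANNAK", "DVLETFTVK",
                         "IVDDWANDGWGLK", "GVIDLDVFLK"),
    sil_spike_conc = c(10, 0.4, 0.1, 0.2, 0.2),
    stringsAsFactors = FALSE
  )

  # transition table: analyte, form, precursor, RT, CE, then the three
  # product ions (label; the quantifier flagged TRUE)
  tr1 <- function(id, form, prec, rt, ce, prods) {
    data.frame(
      analyte_id = id, form = form, precursor_mz = prec,
      product_mz = vapply(prods, `[[`, numeric(1), "mz"),
      product_label = vapply(prods, `[[`, character(1), "label"),
      role = ifelse(vapply(prods, `[[`, logical(1), "quant"),
                    "quantifier", "qualifier"),
      collision_energy = ce, expected_rt = rt,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  p <- function(mz, label, quant = FALSE) list(mz = mz, label = label, quant = quant)
  transitions <- rbind(
    tr1("ALB", "SIL", 579.3, 20.7, 18.8,
        list(p(603.3, "y5+"), p(702.4, "y6+"), p(945.5, "y8+", TRUE))),
    tr1("ALB", "light", 575.3, 20.7, 18.8,
        list(p(595.3, "y5+"), p(694.4, "y6+"), p(937.5, "y8+", TRUE))),
    tr1("CD81", "SIL", 754.4, 23.9, 17.3,
        list(p(870.4, "y8+"), p(969.4, "y9+", TRUE), p(1068.5, "y10+"))),
    tr1("CD81", "light", 751.7, 23.9, 17.3,
        list(p(862.4, "y8+"), p(961.4, "y9+", TRUE), p(1060.5, "y10+"))),
    tr1("CD9", "SIL", 530.3, 24.3, 22.3,
        list(p(603.4, "y5+"), p(732.4, "y6+"), p(846.5, "y7+", TRUE))),
    tr1("CD9", "light", 526.3, 24.3, 22.3,
        list(p(595.4, "y5+"), p(724.4, "y6+"), p(837.5, "y7+", TRUE))),
    tr1("CANX", "SIL", 748.9, 27.2, 24.1,
        list(p(797.4, "y7+"), p(868.4, "y8+", TRUE), p(1054.5, "y9+"))),
    tr1("CANX", "light", 744.9, 27.2, 24.1,
        list(p(789.4, "y7+"), p(860.4, "y8+", TRUE), p(1046.5, "y9+"))),
    tr1("TSG101", "SIL", 563.8, 32.5, 18.4,
        list(p(742.5, "y6+"), p(857.5, "y7+", TRUE), p(970.6, "y8+"))),
    tr1("TSG101", "light", 559.8, 32.5, 18.4,
        list(p(734.4, "y6+"), p(849.5, "y7+", TRUE), p(962.6, "y8+")))
  )

  calibration_ranges <- data.frame(
    analyte_id = c("ALB", "CD81", "CD9", "CANX", "TSG101"),
    low = c(2.0, 0.2, 0.02, 0.04, 0.04),
    high = c(80, 8.0, 0.8, 1.6, 1.6),
    stringsAsFactors = FALSE
  )

  instrument_settings <- list(
    time_segments_min = c("0-22", "22-26", "26-30", "30-48"),
    delta_emv_v = c(300, 300, 300, 300),
    capillary_voltage_v = c(3000, 2500, 3000, 3000),
    nebulizer_pressure_psi = c(30, 25, 30, 30),
    nozzle_voltage_v = c(1000, 500, 500, 500),
    cell_accelerator_voltage_v = c(5, 3, 5, 4)
  )

  ev_panel(analytes, transitions, calibration_ranges, instrument_settings)
}
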
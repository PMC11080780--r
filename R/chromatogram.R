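#' Construct a chromatogram
#'
#' An intensity-versus-time trace for one MRM transition in one injection.
#'
#' @param times minutes, strictly increasing, length >= 20.
#' @param intensities counts, finite, same length as `times`.
#' @param analyte_id,form,role,product_label,sample_id transition identity
#'   metadata (optional).
#' @param expected_rt expected retention time, minutes (optional).
#' @return object of class `ev_chromatogram`.
#' @export
chromatogram <- function(times, intensities, analyte_id = NA_character_,
                         form = NA_character_, role = NA_character_,
                         product_label = NA_character_,
                         sample_id = NA_character_, expected_rt = NA_real_) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) < 20L)
    stop_evmrm("chromatogram needs >= 20 points", "evmrm_chromatogram_error")
  if (length(times) != length(intensities))
    stop_evmrm("times and intensities lengths differ", "evmrm_chromatogram_error")
  if (any(diff(times) <= 0))
    stop_evmrm("times must be strictly increasing", "evmrm_chromatogram_error")
  if (any(!is.finite(intensities)))
    stop_evmrm("intensities must be finite", "evmrm_chromatogram_error")
  structure(list(times = times, intensities = intensities,
                 analyte_id = analyte_id, form = form, role = role,
                 product_label = product_label, sample_id = sample_id,
                 expected_rt = expected_rt),
            class = "ev_chromatogram")
}

#' @export
print.ev_chromatogram <- function(x, ...) {
  cat("MRM chromatogram", if (!is.na(x$analyte_id))
    paste0("[", x$analyte_id, " ", x$form, " ", x$product_label, "]") else "",
    "\n  ", length(x$times), " points over ",
    sprintf("%.2f-%.2f", min(x$times), max(x$times)), " min\n", sep = "")
  invisible(x)
}

#' @export
plot.ev_chromatogram <- function(x, ...) {
  graphics::plot(x$times, x$intensities, type = "l",
                 xlab = "retention time (min)", ylab = "intensity (counts)",
                 main = paste(x$analyte_id, x$form, x$product_label), ...)
  if (!is.na(x$expected_rt))
    graphics::abline(v = x$expected_rt, lty = 2, col = "grey50")
  invisible(x)
}

#' Write chromatograms to a long-format delimited file
#'
#' One row per sampled point: `sample_id`, `analyte`, `form`, `role`,
#' `product_label`, `time_min`, `intensity`; tab-separated, UTF-8, dot
#' decimal separator. Re-readable with [read_chromatograms()].
#'
#' @param chroms a single `ev_chromatogram` or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chromatograms <- function(chroms, path) {
  if (inherits(chroms, "ev_chromatogram")) chroms <- list(chroms)
  long <- do.call(rbind, lapply(chroms, function(ch) data.frame(
    sample_id = ch$sample_id, analyte = ch$analyte_id, form = ch$form,
    role = ch$role, product_label = ch$product_label,
    time_min = ch$times, intensity = ch$intensities,
    stringsAsFactors = FALSE)))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read chromatograms from a long-format delimited file
#'
#' @param path file written by [write_chromatograms()] (or any delimited
#'   file with the same seven columns).
#' @return named list of `ev_chromatogram`, keyed
#'   `sample_id|analyte|form|product_label`.
#' @export
read_chromatograms <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "analyte", "form", "role", "product_label",
            "time_min", "intensity")
  miss <- setdiff(need, names(long))
  if (length(miss) > 0)
    stop_evmrm(paste0("chromatogram file missing column(s): ",
                      paste(miss, collapse = ", ")), "evmrm_format_error")
  key <- paste(long$sample_id, long$analyte, long$form, long$product_label,
               sep = "|")
  out <- lapply(split(long, key), function(g) {
    g <- g[order(g$time_min), ]
    chromatogram(g$time_min, g$intensity, analyte_id = g$analyte[1],
                 form = g$form[1], role = g$role[1],
                 product_label = g$product_label[1], sample_id = g$sample_id[1])
  })
  out
}
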
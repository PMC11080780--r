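# deterministic building blocks shared across test files

# a peak result without running detection, for identity-confirmation tests
mk_peak <- function(area, rt = 20, snr = 100, noise_sd = 10,
                    detected = snr >= 3) {
  structure(list(rt_apex = rt, area = area, height = area / (0.05 * sqrt(2 * pi)),
                 noise_sd = noise_sd, snr = snr, detected = detected,
                 sigma_est = 0.05),
            class = "ev_peak")
}

# all stochastic layers off: exact areas, exact traces
noiseless_params <- function(...) {
  sim_params(noise_sd = 0, rt_jitter_sd = 0, cv_donor = 0, cv_isolation = 0,
             cv_digest = 0, cv_injection = 0, ...)
}

# quantifier transition row of the built-in panel
quant_transition <- function(panel, analyte_id, form = "light") {
  tr <- panel$transitions
  tr[tr$analyte_id == analyte_id & tr$form == form & tr$role == "quantifier", ]
}

# hierarchical replicate dataset built directly from concentrations:
# conc_by_iso is a vector of 9 per-isolation concentrations (3 donors x 3
# isolations); each digest duplicate gets the same value unless jitter given
mk_replicate_dataset <- function(conc_by_iso, analyte_id = "CD81",
                                 method = "qEV70", digests = 2,
                                 digest_delta = 0) {
  rows <- list()
  k <- 0
  for (d in 1:3) for (iso in 1:3) {
    k <- k + 1
    for (dig in seq_len(digests)) {
      rows[[length(rows) + 1]] <- data.frame(
        donor = d, method = method, isolation = iso, digest = dig,
        analyte_id = analyte_id,
        concentration = conc_by_iso[k] + (dig - 1) * digest_delta,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

sens_table <- function(analyte_id, lod, method = NULL) {
  df <- data.frame(analyte_id = analyte_id, lod = lod, lloq = 5 * lod,
                   stringsAsFactors = FALSE)
  if (!is.null(method)) df$method <- method
  df
}
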
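# Shared fixtures built in code. Cohorts are cached per test session so
# independent test files can reuse the same generated data cheaply.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(config)
  .cohort_cache[[key]]
}

global_cohort <- function(n = 10, seed = 21, noise = NULL) {
  cached_cohort(sprintf("g_%d_%d_%s", n, seed, deparse(noise)),
                synth_config(n_patients = n, seed = seed,
                             noise_snr_db = noise))
}

perwave_cohort <- function(n = 15, d = 0.2, seed = 22, noise = 20) {
  cached_cohort(sprintf("pw_%d_%g_%d_%s", n, d, seed, deparse(noise)),
                synth_config(n_patients = n, mixing_mode = "per_wave",
                             disparity = d, noise_snr_db = noise,
                             seed = seed))
}

as_entries <- function(cohort) {
  lapply(cohort$entries, function(e)
    list(record = e$record, fiducials = e$fiducials))
}

pooled_xy <- function(cohort, inputs = c("I", "II", "V3"),
                      outputs = c("V1", "V2", "V4", "V5", "V6")) {
  list(X = do.call(rbind, lapply(cohort$entries, function(e)
         e$record$samples[, inputs, drop = FALSE])),
       Y = do.call(rbind, lapply(cohort$entries, function(e)
         e$record$samples[, outputs, drop = FALSE])))
}

run_cv <- function(cohort, variant, fitter = "ols", k = 5, seed = 42, ...) {
  entries <- as_entries(cohort)
  pids <- vapply(entries, function(e) e$record$patient_id, character(1))
  folds <- make_patient_folds(pids, k = k, seed = seed)
  pipeline <- make_pipeline(variant, fitter = fitter, ...)
  suppressWarnings(cross_validate(pipeline, entries, folds))
}

# align detected beats to truth beats by nearest R peak
align_beats <- function(truth, detected) {
  idx <- vapply(truth$r_peak, function(r)
    which.min(abs(detected$r_peak - r)), integer(1))
  detected[idx, ]
}

# fraction of truth beats whose six fiducials are all within tol_ms
fiducial_hit_rate <- function(entries, fs = 500, tol_ms = 10,
                              delineator = delineate) {
  tot <- 0L; hit <- 0L
  for (e in entries) {
    truth <- e$fiducials$beats
    det <- delineator(e$record)$beats
    db <- align_beats(truth, det)
    for (i in seq_len(nrow(truth))) {
      tot <- tot + 1L
      errs <- abs(unlist(db[i, 1:7]) - unlist(truth[i, 1:7])) / fs * 1000
      if (all(!is.na(errs)) && all(errs <= tol_ms)) hit <- hit + 1L
    }
  }
  hit / tot
}

toy_metadata <- function() {
  flags <- c("1dAVb", "RBBB", "LBBB", "SB", "AF", "ST")
  m <- data.frame(patient_id = c("p1", "p1", "p2", "p3", "p4"),
                  is_normal = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                  check.names = FALSE)
  for (f in flags) m[[f]] <- FALSE
  m$AF[4] <- TRUE
  m$has_blank_lead <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  m
}
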
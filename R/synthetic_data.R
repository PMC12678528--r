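#' Default beat morphology
#'
#' Sum-of-Gaussians beat model: each deflection (P, Q, R, S, T) is a
#' Gaussian with a center (seconds relative to the R peak), width (sigma,
#' seconds) and amplitude (mV), truncated at +/- 4 sigma so every wave has
#' an exact, provable support. The defaults describe a normal adult beat
#' at amplitudes typical of limb-lead recordings.
#'
#' @return Data.frame with rows P, Q, R, S, T.
#' @export
beat_morphology <- function() {
  data.frame(row.names = c("P", "Q", "R", "S", "T"),
             center_s = c(-0.160, -0.025, 0.000, 0.025, 0.240),
             sigma_s = c(0.020, 0.008, 0.010, 0.008, 0.030),
             amp_mv = c(0.15, -0.10, 1.00, -0.20, 0.35))
}

#' Default per-lead gains of the single-source mixing model
#'
#' The generator treats the heart as one electrical source whose three
#' wave components project linearly onto the eight independent leads
#' (I, II, V1..V6); the four limb leads III, aVR, aVL, aVF are derived
#' from I and II so the Einthoven/Goldberger identities hold by
#' construction.
#' @export
default_gains <- function() {
  # g_I = 0.6 (not 0.5) keeps the derived aVL = (g_I - g_II/2) s nonzero
  c(I = 0.6, II = 1.0, V1 = 0.4, V2 = 0.7, V3 = 1.1, V4 = 1.3,
    V5 = 1.0, V6 = 0.8)
}

CORE_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Synthetic cohort configuration
#'
#' @param n_patients Number of patients.
#' @param records_per_patient Records per patient (records of one patient
#'   share morphology and heart rate).
#' @param fs Sampling rate, Hz.
#' @param duration_s Record duration, seconds.
#' @param hr_range Heart-rate range in bpm patients are drawn from.
#' @param morphology A [beat_morphology()] table.
#' @param mixing_mode `"global"` (one gain vector for all waves) or
#'   `"per_wave"` (wave-specific gains on the reconstructed leads).
#' @param base_gains Named per-lead gain vector over I, II, V1..V6.
#' @param disparity Per-wave gain disparity `d` (per_wave mode): on leads
#'   V1, V2, V4, V5, V6 the QRS gain is scaled by `1 + d` and the P/T
#'   gains by `1 - d`, while the delineation/input leads I, II, V3 keep
#'   the shared gains. Raw input samples therefore carry no wave
#'   identity, and only the masked wave channels can separate the
#'   wave-specific projections -- the masking premise made literal.
#' @param noise_snr_db Per-lead additive white-noise SNR in dB, or `NULL`
#'   for noiseless records.
#' @param rr_jitter Fractional uniform jitter of each RR interval.
#' @param amp_jitter,width_jitter Per-patient multiplicative morphology
#'   jitter (uniform, +/- fraction) on wave amplitudes and widths.
#' @param inject Named counts of metadata-criteria violations to inject
#'   (for filter tests): `duplicates`, `abnormal`, `condition`, `blank`.
#' @param seed Cohort seed; patient and record seeds derive from it.
#' @export
synth_config <- function(n_patients, records_per_patient = 1, fs = 500,
                         duration_s = 10, hr_range = c(50, 90),
                         morphology = beat_morphology(),
                         mixing_mode = c("global", "per_wave"),
                         base_gains = default_gains(), disparity = 0.2,
                         noise_snr_db = NULL, rr_jitter = 0.05,
                         amp_jitter = 0.2, width_jitter = 0.1,
                         inject = c(duplicates = 0, abnormal = 0,
                                    condition = 0, blank = 0),
                         seed = 1) {
  mixing_mode <- match.arg(mixing_mode)
  if (n_patients < 1 || fs <= 0 || duration_s <= 0)
    wmlr_stop("n_patients, fs and duration_s must be positive",
              "wmlr_config_error")
  if (!all(CORE_LEADS %in% names(base_gains)) ||
      any(!is.finite(base_gains)))
    wmlr_stop("base_gains must name finite gains for I, II, V1..V6",
              "wmlr_config_error")
  inj <- c(duplicates = 0, abnormal = 0, condition = 0, blank = 0)
  inj[names(inject)] <- inject
  list(n_patients = as.integer(n_patients),
       records_per_patient = as.integer(records_per_patient),
       fs = fs, duration_s = duration_s, hr_range = hr_range,
       morphology = morphology, mixing_mode = mixing_mode,
       base_gains = base_gains[CORE_LEADS], disparity = disparity,
       noise_snr_db = noise_snr_db, rr_jitter = rr_jitter,
       amp_jitter = amp_jitter, width_jitter = width_jitter,
       inject = inj, seed = as.integer(seed))
}

#' Wave-by-lead mixing matrix of a configuration
#'
#' @param config A [synth_config()].
#' @return 3 x 8 matrix (rows P, QRS, T; columns I, II, V1..V6).
#' @export
mixing_gains <- function(config) {
  G <- matrix(rep(config$base_gains, each = 3), 3, 8,
              dimnames = list(c("P", "QRS", "T"), CORE_LEADS))
  if (config$mixing_mode == "per_wave") {
    d <- config$disparity
    out_leads <- c("V1", "V2", "V4", "V5", "V6")
    G["QRS", out_leads] <- G["QRS", out_leads] * (1 + d)
    G["P", out_leads] <- G["P", out_leads] * (1 - d)
    G["T", out_leads] <- G["T", out_leads] * (1 - d)
  }
  G
}

#' Render one beat's wave components
#'
#' Evaluates the three source components (P; QRS as Q+R+S; T) on integer
#' sample offsets relative to the R peak, each Gaussian truncated at
#' +/- 4 sigma. Components have disjoint supports whose exact bounds are
#' the returned fiducials (half-open `[on, off)` offsets).
#'
#' @param morphology A [beat_morphology()] table.
#' @param fs Sampling rate, Hz.
#' @return List with per-wave `offsets`/`values` and `fiducials` (relative
#'   offsets: `p_on, p_off, qrs_on, qrs_off, t_on, t_off, r_peak = 0`).
#' @export
generate_beat <- function(morphology, fs) {
  m <- morphology
  if (any(m$sigma_s <= 0))
    wmlr_stop("wave widths must be positive", "wmlr_morphology_error")
  lo <- ceiling((m$center_s - 4 * m$sigma_s) * fs)
  hi <- floor((m$center_s + 4 * m$sigma_s) * fs)
  wave_of <- c(P = "P", Q = "QRS", R = "QRS", S = "QRS", T = "T")
  supp <- lapply(c("P", "QRS", "T"), function(w) {
    rows <- which(wave_of[rownames(m)] == w)
    c(min(lo[rows]), max(hi[rows]))
  })
  names(supp) <- c("P", "QRS", "T")
  if (supp$P[2] >= supp$QRS[1] || supp$QRS[2] >= supp$T[1])
    wmlr_stop("wave supports overlap: morphology too wide for this beat",
              "wmlr_morphology_error")
  comp <- lapply(names(supp), function(w) {
    off <- supp[[w]][1]:supp[[w]][2]
    t <- off / fs
    v <- numeric(length(off))
    for (i in which(wave_of[rownames(m)] == w)) {
      inside <- abs(t - m$center_s[i]) <= 4 * m$sigma_s[i]
      v[inside] <- v[inside] +
        m$amp_mv[i] * exp(-(t[inside] - m$center_s[i])^2 /
                            (2 * m$sigma_s[i]^2))
    }
    list(offsets = off, values = v)
  })
  names(comp) <- names(supp)
  list(P = comp$P, QRS = comp$QRS, T = comp$T,
       fiducials = list(p_on = supp$P[1], p_off = supp$P[2] + 1L,
                        qrs_on = supp$QRS[1], qrs_off = supp$QRS[2] + 1L,
                        t_on = supp$T[1], t_off = supp$T[2] + 1L,
                        r_peak = 0L))
}

jitter_morphology <- function(m, amp_jitter, width_jitter) {
  k <- nrow(m)
  m$amp_mv <- m$amp_mv * (1 + stats::runif(k, -amp_jitter, amp_jitter))
  m$sigma_s <- m$sigma_s * (1 + stats::runif(k, -width_jitter, width_jitter))
  m
}

#' Generate one synthetic 12-lead record with ground truth
#'
#' Concatenates beats at jittered RR intervals, projects the three wave
#' sources onto the eight core leads through the configured mixing,
#' optionally adds white noise at the configured per-lead SNR, and
#' derives the four limb leads from the (noisy) leads I and II so the
#' Einthoven/Goldberger identities hold exactly. Deterministic given
#' `seed`.
#'
#' @param config A [synth_config()].
#' @param patient List with `morphology` and `hr_bpm` (drawn by
#'   [generate_cohort()]; defaults to the config morphology at 60 bpm).
#' @param record_id,patient_id Identifiers.
#' @param seed Record seed.
#' @return A `synth_truth` list: `record` (12-lead [ecg_record()]),
#'   `fiducials` (exact [fiducial_set()]), `sources` (samples x 3 matrix),
#'   `mixing`, `metadata` (one-row data.frame), `patient`.
#' @export
generate_record <- function(config, patient = NULL, record_id = "synth-1",
                            patient_id = record_id, seed = config$seed) {
  patient <- patient %||% list(morphology = config$morphology, hr_bpm = 60)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  beat <- generate_beat(patient$morphology, fs)
  fid_rel <- beat$fiducials
  G <- mixing_gains(config)
  with_seed(seed, {
    rr0 <- 60 / patient$hr_bpm
    t <- 0.35
    r_times <- numeric(0)
    while (t + 0.45 < config$duration_s) {
      r_times <- c(r_times, t)
      t <- t + rr0 * (1 + stats::runif(1, -config$rr_jitter,
                                       config$rr_jitter))
    }
    r_idx <- round(r_times * fs) + 1L
    sources <- matrix(0, n, 3, dimnames = list(NULL, c("P", "QRS", "T")))
    for (ri in r_idx)
      for (w in c("P", "QRS", "T")) {
        idx <- ri + beat[[w]]$offsets
        ok <- idx >= 1L & idx <= n
        sources[idx[ok], w] <- sources[idx[ok], w] + beat[[w]]$values[ok]
      }
    beats <- data.frame(p_on = r_idx + fid_rel$p_on,
                        p_off = r_idx + fid_rel$p_off,
                        qrs_on = r_idx + fid_rel$qrs_on,
                        qrs_off = r_idx + fid_rel$qrs_off,
                        t_on = r_idx + fid_rel$t_on,
                        t_off = r_idx + fid_rel$t_off,
                        r_peak = r_idx)
    core <- sources %*% G
    if (!is.null(config$noise_snr_db)) {
      att <- 10^(-config$noise_snr_db / 20)
      for (j in seq_len(ncol(core))) {
        sdn <- sqrt(mean(core[, j]^2)) * att
        core[, j] <- core[, j] + stats::rnorm(n, 0, sdn)
      }
    }
    limb <- derive_limb_leads(core[, "I"], core[, "II"])
    samples <- cbind(core[, c("I", "II")], limb,
                     core[, c("V1", "V2", "V3", "V4", "V5", "V6")])
    samples <- samples[, STANDARD_LEADS]
    record <- ecg_record(samples, fs = fs, lead_names = STANDARD_LEADS,
                         record_id = record_id, patient_id = patient_id)
    fids <- fiducial_set(record_id, fs, beats, source = "internal",
                         n_samples = n)
    meta <- data.frame(patient_id = patient_id, is_normal = TRUE,
                       check.names = FALSE)
    for (fl in CONDITION_FLAGS) meta[[fl]] <- FALSE
    meta$has_blank_lead <- FALSE
    structure(list(record = record, fiducials = fids, sources = sources,
                   mixing = G, metadata = meta, patient = patient),
              class = "synth_truth")
  })
}

#' Generate a synthetic cohort
#'
#' Draws per-patient morphology (multiplicative amplitude/width jitter)
#' and heart rate, then renders `records_per_patient` records per patient
#' (sharing the patient's morphology). By default every metadata row
#' satisfies the normal-cohort selection criteria; `config$inject` flips
#' rows into duplicates, abnormals, condition-flagged or blank-lead
#' records for testing the metadata filter.
#'
#' @param config A [synth_config()].
#' @return List with `entries` (list of `synth_truth`), `metadata`
#'   (data.frame, one row per record) and `config`.
#' @export
generate_cohort <- function(config) {
  entries <- list()
  for (p in seq_len(config$n_patients)) {
    pseed <- derive_seed(config$seed, p)
    patient <- with_seed(pseed, list(
      morphology = jitter_morphology(config$morphology, config$amp_jitter,
                                     config$width_jitter),
      hr_bpm = stats::runif(1, config$hr_range[1], config$hr_range[2])))
    for (rr in seq_len(config$records_per_patient)) {
      rseed <- derive_seed(pseed, rr)
      rid <- sprintf("rec%04d_%d", p, rr)
      entries[[length(entries) + 1L]] <-
        generate_record(config, patient, record_id = rid,
                        patient_id = sprintf("pat%04d", p), seed = rseed)
    }
  }
  # criteria-violation injections, applied to rows 2, 3, ... in turn
  inj <- config$inject
  row <- 2L
  apply_n <- function(n, fun) {
    for (i in seq_len(n)) {
      if (row > length(entries)) break
      entries[[row]] <<- fun(entries[[row]])
      row <<- row + 1L
    }
  }
  apply_n(inj["duplicates"], function(e) {
    e$metadata$patient_id <- entries[[1]]$metadata$patient_id
    e$record$patient_id <- entries[[1]]$record$patient_id
    e
  })
  apply_n(inj["abnormal"], function(e) {
    e$metadata$is_normal <- FALSE
    e
  })
  apply_n(inj["condition"], function(e) {
    e$metadata$AF <- TRUE
    e
  })
  apply_n(inj["blank"], function(e) {
    e$record$samples[, "V6"] <- 0
    e$metadata$has_blank_lead <- TRUE
    e
  })
  metadata <- do.call(rbind, lapply(entries, `[[`, "metadata"))
  metadata <- cbind(record_id = vapply(entries, function(e)
    e$record$record_id, character(1)), metadata)
  list(entries = entries, metadata = metadata, config = config)
}

#' Write a synthetic cohort to disk
#'
#' Records in the chosen format (per-record CSV, WFDB pairs, or one HDF5
#' container), a `metadata.csv`, per-record truth fiducial CSVs, and a
#' `mixing.json` with the wave-by-lead gains -- format-compatible with
#' the package's readers.
#'
#' @param cohort From [generate_cohort()].
#' @param dir Output directory.
#' @param format `"csv"`, `"wfdb"` or `"hdf5"`.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "wfdb", "hdf5")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(cohort$entries, `[[`, "record")
  if (format == "hdf5") {
    write_cohort_hdf5(recs, file.path(dir, "tracings.h5"))
  } else {
    for (r in recs)
      write_record(r, file.path(dir, paste0(r$record_id,
                                            if (format == "csv") ".csv" else "")),
                   format = format)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  for (e in cohort$entries)
    export_fiducials(e$fiducials,
                     file.path(dir, paste0(e$record$record_id,
                                           "_fiducials.csv")))
  jsonlite::write_json(list(mixing_mode = cohort$config$mixing_mode,
                            gains = as.data.frame(cohort$entries[[1]]$mixing)),
                       file.path(dir, "mixing.json"),
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
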
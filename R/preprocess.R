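#' Select records by the normal-cohort metadata criteria
#'
#' Keeps a metadata row iff (a) its patient has not appeared in an earlier
#' kept row, (b) the record is categorised normal, (c) all six monitored
#' rhythm conditions (first-degree AV block, RBBB, LBBB, sinus bradycardia,
#' atrial fibrillation, sinus tachycardia) are false, and (d) no lead is
#' blank. Order of survivors is preserved; the operation is idempotent.
#'
#' @param meta Data.frame as returned by [read_metadata_csv()].
#' @return Integer indices (1-based rows) of the selected records.
#' @export
filter_metadata <- function(meta) {
  if (is.null(meta) || nrow(as.data.frame(meta)) == 0L) return(integer(0))
  meta <- as.data.frame(meta)
  flags <- as.matrix(meta[CONDITION_FLAGS])
  eligible <- as.logical(meta$is_normal) &
    rowSums(flags, na.rm = FALSE) == 0 &
    !as.logical(meta$has_blank_lead)
  eligible[is.na(eligible)] <- FALSE
  keep <- logical(nrow(meta))
  seen <- character(0)
  for (i in seq_len(nrow(meta))) {
    if (eligible[i] && !(meta$patient_id[i] %in% seen)) {
      keep[i] <- TRUE
      seen <- c(seen, meta$patient_id[i])
    }
  }
  which(keep)
}

#' Trim a record to its first `duration_s` seconds
#'
#' @param record An [ecg_record()].
#' @param duration_s Target duration in seconds; the record must be at
#'   least this long (no padding).
#' @export
trim_record <- function(record, duration_s) {
  n_keep <- round(duration_s * record$fs)
  if (n_keep > n_samples(record))
    wmlr_stop(sprintf("record '%s' is shorter (%d samples) than requested %g s (%d samples)",
                      record$record_id, n_samples(record), duration_s, n_keep),
              "wmlr_length_error")
  record$samples <- record$samples[seq_len(n_keep), , drop = FALSE]
  record
}

# smallest rational p/q approximating `ratio` (denominator <= max_den)
rational_ratio <- function(ratio, max_den = 1000, tol = 1e-9) {
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    if (p > 0 && abs(p / q - ratio) < tol * ratio) return(c(p = p, q = q))
  }
  wmlr_stop(sprintf("sampling-rate ratio %g has no small rational form", ratio),
            "wmlr_value_error")
}

#' Resample a record to a new rate
#'
#' Polyphase rational resampling with anti-aliasing
#' (`signal::resample` with `p/q = target_fs/fs`). Output length is
#' `round(n_in * target_fs / fs)`.
#'
#' @param record An [ecg_record()].
#' @param target_fs Target sampling rate in Hz.
#' @export
resample_record <- function(record, target_fs) {
  if (!is.numeric(target_fs) || length(target_fs) != 1L ||
      !is.finite(target_fs) || target_fs <= 0)
    wmlr_stop("target_fs must be a positive number", "wmlr_value_error")
  if (target_fs == record$fs) return(record)
  pq <- rational_ratio(target_fs / record$fs)
  n_out <- round(n_samples(record) * target_fs / record$fs)
  out <- apply(record$samples, 2, function(x) {
    y <- signal::resample(x, pq["p"], pq["q"])
    length(y) <- n_out  # resample may return a few extra/fewer edge samples
    y[is.na(y)] <- 0
    y
  })
  record$samples <- out
  record$fs <- target_fs
  record
}

#' Denoising configuration
#'
#' @param highpass_hz Baseline-wander cutoff (highpass), Hz.
#' @param lowpass_hz High-frequency cutoff (lowpass), Hz.
#' @param notch_hz Optional mains frequency (50/60) for a band-stop notch;
#'   `NULL` disables it.
#' @param order Butterworth order for each stage.
#' @export
denoise_config <- function(highpass_hz = 0.3, lowpass_hz = 100,
                           notch_hz = NULL, order = 4) {
  list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
       notch_hz = notch_hz, order = order)
}

#' Denoise a record
#'
#' Zero-phase (forward-backward) Butterworth filtering: a highpass removes
#' baseline wander, a lowpass removes high-frequency noise, and an optional
#' notch suppresses mains interference. Zero-phase filtering leaves wave
#' fiducials unshifted; the whole operation is linear in the signal.
#'
#' @param record An [ecg_record()].
#' @param config A [denoise_config()].
#' @export
denoise_record <- function(record, config = denoise_config()) {
  nyq <- record$fs / 2
  cuts <- c(config$highpass_hz, config$lowpass_hz, config$notch_hz)
  if (any(cuts <= 0 | cuts >= nyq))
    wmlr_stop(sprintf("cutoffs must lie in (0, %g) Hz", nyq),
              "wmlr_value_error")
  hp <- signal::butter(config$order, config$highpass_hz / nyq, type = "high")
  lp <- signal::butter(config$order, config$lowpass_hz / nyq, type = "low")
  nf <- if (!is.null(config$notch_hz))
    signal::butter(2, c(config$notch_hz - 1, config$notch_hz + 1) / nyq,
                   type = "stop")
  record$samples <- apply(record$samples, 2, function(x) {
    y <- signal::filtfilt(hp, x)
    y <- signal::filtfilt(lp, y)
    if (!is.null(nf)) y <- signal::filtfilt(nf, y)
    y
  })
  record
}

#' Detect blank leads
#'
#' A lead is blank iff its maximum absolute amplitude over the record is
#' below `tol` millivolts (detects all-zero channels without flagging
#' low-amplitude leads).
#'
#' @param record An [ecg_record()].
#' @param tol Threshold in mV.
#' @return Named logical vector, one entry per lead.
#' @export
detect_blank_leads <- function(record, tol = 1e-6) {
  apply(record$samples, 2, function(x) max(abs(x)) < tol)
}

#' Standard preprocessing chain
#'
#' Trim to `duration_s`, resample to `target_fs`, denoise.
#'
#' @param record An [ecg_record()].
#' @param duration_s,target_fs Conditioning targets (defaults 10 s, 500 Hz).
#' @param config A [denoise_config()].
#' @export
preprocess_record <- function(record, duration_s = 10, target_fs = 500,
                              config = denoise_config()) {
  record <- trim_record(record, duration_s)
  record <- resample_record(record, target_fs)
  denoise_record(record, config)
}
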
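#' @title Multichannel ECG record container
#' @description An `ecg_record` holds a matrix of amplitudes in millivolts
#' (rows = time samples, columns = leads), the sampling rate, ordered lead
#' names, and record/patient identifiers. Sample indices are 1-based; the
#' time of sample `i` is `(i - 1) / fs` seconds plus the start offset `t0`.
#' @name ecg_record
NULL

#' Standard 12-lead labels in conventional order
#' @export
STANDARD_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct an ECG record
#'
#' @param samples Numeric matrix, one row per time sample, one column per
#'   lead, amplitudes in millivolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param lead_names Ordered lead labels; defaults to `colnames(samples)`.
#' @param record_id,patient_id Identifiers (strings).
#' @param t0 Start offset in seconds.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, lead_names = colnames(samples),
                       record_id = "record", patient_id = record_id, t0 = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(lead_names))
    wmlr_stop("lead_names missing and samples has no column names",
              "wmlr_value_error")
  lead_names <- as.character(lead_names)
  if (length(lead_names) != ncol(samples))
    wmlr_stop("lead_names length does not match column count",
              "wmlr_shape_error")
  if (anyDuplicated(lead_names))
    wmlr_stop("lead_names must be unique", "wmlr_value_error")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    wmlr_stop("fs must be a positive finite scalar", "wmlr_value_error")
  colnames(samples) <- lead_names
  structure(list(record_id = as.character(record_id),
                 patient_id = as.character(patient_id),
                 fs = as.numeric(fs),
                 lead_names = lead_names,
                 samples = samples,
                 t0 = as.numeric(t0)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s (patient %s): %d samples x %d leads @ %g Hz (%.3f s)\n",
              x$record_id, x$patient_id, nrow(x$samples), ncol(x$samples),
              x$fs, nrow(x$samples) / x$fs))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of time samples in a record
#' @param record An `ecg_record`.
#' @export
n_samples <- function(record) nrow(record$samples)

#' Extract one lead as a numeric vector
#' @param record An `ecg_record`.
#' @param lead Lead label.
#' @export
get_lead <- function(record, lead) {
  if (!lead %in% record$lead_names)
    wmlr_stop(sprintf("lead '%s' not present in record '%s'",
                      lead, record$record_id), "wmlr_lead_error")
  record$samples[, lead]
}

#' Validate ECG record invariants
#'
#' Checks finiteness, lead-name consistency and positive sampling rate.
#' @param record An `ecg_record`.
#' @return `record`, invisibly; errors on violation.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (any(!is.finite(record$samples)))
    wmlr_stop("samples contain non-finite values", "wmlr_value_error")
  if (length(record$lead_names) != ncol(record$samples))
    wmlr_stop("lead_names do not match sample columns", "wmlr_shape_error")
  if (record$fs <= 0) wmlr_stop("fs must be positive", "wmlr_value_error")
  invisible(record)
}

# Map raw lead labels onto the standard 12-lead names; unknown labels are
# kept verbatim (with a warning at the call site that resolves them).
resolve_lead_names <- function(labels) {
  canon <- toupper(STANDARD_LEADS)
  idx <- match(toupper(trimws(labels)), canon)
  out <- ifelse(is.na(idx), labels, STANDARD_LEADS[idx])
  unknown <- labels[is.na(idx)]
  if (length(unknown))
    warning(sprintf("unknown lead label(s) kept verbatim: %s",
                    paste(unique(unknown), collapse = ", ")),
            call. = FALSE)
  out
}
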
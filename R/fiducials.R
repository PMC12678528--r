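#' Per-beat fiducial container
#'
#' A `fiducial_set` stores, per beat, the R-peak sample and the half-open
#' `[on, off)` sample intervals of the P wave, QRS complex and T wave.
#' Indices are 1-based; `NA` marks a wave that could not be located
#' (ABSENT). The on-disk CSV dialect (see [export_fiducials()]) is 0-based
#' for interoperability with external delineators.
#'
#' @param record_id Record identifier the fiducials belong to.
#' @param fs Sampling rate in Hz.
#' @param beats Data.frame with columns `p_on, p_off, qrs_on, qrs_off,
#'   t_on, t_off, r_peak` (one row per beat, ordered by `r_peak`).
#' @param source `"internal"` (this package's delineator) or `"imported"`.
#' @param n_samples Record length used for range validation (optional).
#' @export
fiducial_set <- function(record_id, fs, beats, source = c("internal", "imported"),
                         n_samples = NULL) {
  source <- match.arg(source)
  cols <- c("p_on", "p_off", "qrs_on", "qrs_off", "t_on", "t_off", "r_peak")
  beats <- as.data.frame(beats)
  missing <- setdiff(cols, names(beats))
  if (length(missing))
    wmlr_stop(paste("beats missing columns:", paste(missing, collapse = ", ")),
              "wmlr_validation_error")
  beats <- beats[cols]
  for (cc in cols) beats[[cc]] <- as.integer(round(beats[[cc]]))
  fs_obj <- structure(list(record_id = as.character(record_id),
                           fs = as.numeric(fs), beats = beats,
                           source = source),
                      class = "fiducial_set")
  validate_fiducials(fs_obj, n_samples = n_samples)
  fs_obj
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %s: %d beats @ %g Hz (%s)\n",
              x$record_id, nrow(x$beats), x$fs, x$source))
  invisible(x)
}

#' Validate fiducial invariants
#'
#' Checks per-beat ordering (`p_on < p_off <= qrs_on < qrs_off <= t_on <
#' t_off`, `qrs_on <= r_peak < qrs_off`), strictly increasing R peaks,
#' non-overlapping consecutive beats and (optionally) index range.
#'
#' @param fids A [fiducial_set()].
#' @param n_samples Optional record length for range checks.
#' @return `fids`, invisibly; a validation error names the offending beat.
#' @export
validate_fiducials <- function(fids, n_samples = NULL) {
  b <- fids$beats
  bad <- function(i, what)
    wmlr_stop(sprintf("fiducial validation failed at beat %d: %s", i, what),
              "wmlr_validation_error")
  if (nrow(b) == 0L) return(invisible(fids))
  for (i in seq_len(nrow(b))) {
    r <- b[i, ]
    if (is.na(r$r_peak) || is.na(r$qrs_on) || is.na(r$qrs_off))
      bad(i, "r_peak/qrs_on/qrs_off must be present")
    if (xor(is.na(r$p_on), is.na(r$p_off))) bad(i, "partial P interval")
    if (xor(is.na(r$t_on), is.na(r$t_off))) bad(i, "partial T interval")
    if (!(r$qrs_on < r$qrs_off)) bad(i, "qrs_on < qrs_off violated")
    if (!(r$qrs_on <= r$r_peak && r$r_peak < r$qrs_off))
      bad(i, "r_peak outside QRS interval")
    if (!is.na(r$p_on) &&
        !(r$p_on < r$p_off && r$p_off <= r$qrs_on))
      bad(i, "P interval ordering violated")
    if (!is.na(r$t_on) &&
        !(r$qrs_off <= r$t_on && r$t_on < r$t_off))
      bad(i, "T interval ordering violated")
    if (!is.null(n_samples)) {
      lo <- min(r$p_on, r$qrs_on, na.rm = TRUE)
      hi <- max(r$t_off - 1L, r$qrs_off - 1L, na.rm = TRUE)
      if (lo < 1L || hi > n_samples) bad(i, "index out of record range")
    }
  }
  if (nrow(b) > 1L) {
    if (any(diff(b$r_peak) <= 0))
      bad(which(diff(b$r_peak) <= 0)[1] + 1L, "r_peaks not strictly increasing")
    ends <- pmax(b$qrs_off, b$t_off, na.rm = FALSE)
    ends[is.na(ends)] <- b$qrs_off[is.na(ends)]
    starts <- pmin(b$p_on, b$qrs_on, na.rm = TRUE)
    if (any(ends[-nrow(b)] > starts[-1]))
      bad(which(ends[-nrow(b)] > starts[-1])[1] + 1L,
          "consecutive beats overlap")
  }
  invisible(fids)
}

#' Export fiducials to the CSV dialect
#'
#' Header `beat,p_on,p_off,qrs_on,qrs_off,t_on,t_off,r_peak`; indices are
#' written 0-based, absent waves as empty fields, one file per record.
#'
#' @param fids A [fiducial_set()].
#' @param path Output CSV path.
#' @export
export_fiducials <- function(fids, path) {
  b <- fids$beats
  fmt <- function(v) ifelse(is.na(v), "", as.character(v - 1L))
  lines <- vapply(seq_len(nrow(b)), function(i)
    paste(c(i - 1L, fmt(b$p_on[i]), fmt(b$p_off[i]), fmt(b$qrs_on[i]),
            fmt(b$qrs_off[i]), fmt(b$t_on[i]), fmt(b$t_off[i]),
            fmt(b$r_peak[i])), collapse = ","), character(1))
  writeLines(c("beat,p_on,p_off,qrs_on,qrs_off,t_on,t_off,r_peak", lines),
             path)
  invisible(path)
}

#' Import externally produced fiducials
#'
#' Reads the documented CSV dialect (0-based indices, empty field =
#' absent), converts to the package's 1-based indexing and validates all
#' fiducial invariants against the record.
#'
#' @param path CSV path in the dialect written by [export_fiducials()].
#' @param record The [ecg_record()] the fiducials describe.
#' @return A [fiducial_set()] with `source = "imported"`.
#' @export
import_fiducials <- function(path, record) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "integer", na.strings = "")
  need <- c("beat", "p_on", "p_off", "qrs_on", "qrs_off", "t_on", "t_off",
            "r_peak")
  if (!all(need %in% names(df)))
    wmlr_stop("fiducial CSV header does not match the documented dialect",
              "wmlr_validation_error")
  df <- df[order(df$beat), ]
  beats <- df[c("p_on", "p_off", "qrs_on", "qrs_off", "t_on", "t_off",
                "r_peak")] + 1L
  fiducial_set(record$record_id, record$fs, beats, source = "imported",
               n_samples = n_samples(record))
}
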
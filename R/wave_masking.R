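#' Zero-mask a signal outside given segments
#'
#' Everything outside the half-open `[on, off)` segments is replaced with
#' zeros; inside them the signal passes through unchanged. This is the
#' core wave-isolation primitive: masking the complement of a delineated
#' wave leaves only that wave in the channel.
#'
#' @param x Single-lead samples.
#' @param segments Two-column matrix (or data.frame) of half-open 1-based
#'   `[on, off)` intervals; must be pairwise disjoint and within the
#'   signal.
#' @return Masked samples, same length as `x`.
#' @export
mask_wave <- function(x, segments) {
  n <- length(x)
  seg <- as.matrix(segments)
  if (length(seg) == 0L) return(numeric(n))
  if (ncol(seg) != 2L)
    wmlr_stop("segments must have two columns [on, off)", "wmlr_segment_error")
  storage.mode(seg) <- "integer"
  if (any(is.na(seg)))
    wmlr_stop("segments contain NA", "wmlr_segment_error")
  if (any(seg[, 1] < 1L) || any(seg[, 2] > n + 1L) || any(seg[, 1] >= seg[, 2]))
    wmlr_stop("segment out of range or empty", "wmlr_segment_error")
  o <- order(seg[, 1])
  seg <- seg[o, , drop = FALSE]
  if (nrow(seg) > 1L && any(seg[-nrow(seg), 2] > seg[-1, 1]))
    wmlr_stop("segments overlap", "wmlr_segment_error")
  out <- numeric(n)
  for (i in seq_len(nrow(seg))) {
    idx <- seg[i, 1]:(seg[i, 2] - 1L)
    out[idx] <- x[idx]
  }
  out
}

#' Extract one wave's segments from a fiducial set
#'
#' Collects the half-open `[on, off)` intervals of the requested wave over
#' all beats; beats with the wave absent contribute no segment. Segments
#' are clipped to `[1, n]` when `n` is given.
#'
#' @param fids A [fiducial_set()].
#' @param wave `"P"`, `"QRS"` or `"T"`.
#' @param n Record length for clipping (optional).
#' @return Integer matrix with columns `on`, `off`.
#' @export
wave_segments <- function(fids, wave = c("P", "QRS", "T"), n = NULL) {
  wave <- match.arg(wave)
  b <- fids$beats
  on <- switch(wave, P = b$p_on, QRS = b$qrs_on, T = b$t_on)
  off <- switch(wave, P = b$p_off, QRS = b$qrs_off, T = b$t_off)
  keep <- !is.na(on) & !is.na(off)
  on <- on[keep]; off <- off[keep]
  if (!is.null(n)) {
    on <- pmax(on, 1L)
    off <- pmin(off, n + 1L)
    keep2 <- on < off
    on <- on[keep2]; off <- off[keep2]
  }
  cbind(on = as.integer(on), off = as.integer(off))
}

#' Fixed channel names of the augmented input
#' @export
AUGMENTED_CHANNELS <- c("P_masked", "QRS_masked", "T_masked", "I", "II", "V3")

#' Build the wave-masked augmented input
#'
#' Assembles the six-channel input stack used by the wave-masked linear
#' reconstruction: the P wave isolated from one lead, the QRS complex from
#' another, the T wave from a third (default mapping P from II, QRS from
#' V3, T from I), followed by the three raw leads I, II, V3. Raw channels
#' pass through bit-exactly; beats whose wave is absent contribute zeros.
#'
#' @param record An [ecg_record()] containing leads I, II and V3.
#' @param fiducials A [fiducial_set()] for the record.
#' @param wave_leads Named character vector mapping waves to source leads.
#' @return An `augmented_input`: list with `record_id`, `channels`
#'   (samples x 6 matrix) and `channel_names`.
#' @export
build_augmented_input <- function(record, fiducials,
                                  wave_leads = c(P = "II", QRS = "V3", T = "I")) {
  need <- unique(c("I", "II", "V3", unname(wave_leads)))
  miss <- setdiff(need, record$lead_names)
  if (length(miss))
    wmlr_stop(paste("record lacks required lead(s):",
                    paste(miss, collapse = ", ")), "wmlr_lead_error")
  n <- n_samples(record)
  b <- fiducials$beats
  hi <- suppressWarnings(max(c(b$qrs_off, b$t_off), na.rm = TRUE))
  if (nrow(b) && is.finite(hi) && hi > n + 1L)
    wmlr_stop("fiducials extend past the record", "wmlr_validation_error")
  ch <- matrix(0, n, 6, dimnames = list(NULL, AUGMENTED_CHANNELS))
  ch[, "P_masked"] <- mask_wave(get_lead(record, wave_leads[["P"]]),
                                wave_segments(fiducials, "P", n))
  ch[, "QRS_masked"] <- mask_wave(get_lead(record, wave_leads[["QRS"]]),
                                  wave_segments(fiducials, "QRS", n))
  ch[, "T_masked"] <- mask_wave(get_lead(record, wave_leads[["T"]]),
                                wave_segments(fiducials, "T", n))
  ch[, "I"] <- get_lead(record, "I")
  ch[, "II"] <- get_lead(record, "II")
  ch[, "V3"] <- get_lead(record, "V3")
  structure(list(record_id = record$record_id, channels = ch,
                 channel_names = AUGMENTED_CHANNELS),
            class = "augmented_input")
}

#' @export
print.augmented_input <- function(x, ...) {
  cat(sprintf("<augmented_input> %s: %d samples x %d channels\n",
              x$record_id, nrow(x$channels), ncol(x$channels)))
  invisible(x)
}

#' Write an augmented input in the record CSV dialect
#' @param aug An augmented input from [build_augmented_input()].
#' @param path Output CSV path.
#' @export
write_augmented_csv <- function(aug, path) {
  rec <- ecg_record(aug$channels, fs = 500, lead_names = aug$channel_names,
                    record_id = aug$record_id)
  write_record_csv(rec, path)
}
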
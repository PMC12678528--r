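#' Delineation parameters
#'
#' Tunables of the classical delineator. Boundary fractions are relative
#' amplitudes at which a wave's on/offset is declared: scanning outward
#' from the wave peak, the boundary is placed where the rectified signal
#' stays below `frac * peak` for `min_below_ms`. The fractions default to
#' deep-tail values (0.05% for P/T against the wave's own peak, 0.05% for
#' QRS against the R amplitude) so boundaries land close to the true limits
#' of compact waves.
#'
#' @param bandpass_hz QRS detection band (Pan-Tompkins style), Hz.
#' @param mwi_ms Moving-window-integration width, ms.
#' @param refractory_ms Minimum separation of detected R peaks, ms.
#' @param qrs_window_ms Maximum QRS half-width searched around R, ms.
#' @param p_window_ms PR search window length before QRS onset, ms.
#' @param t_frac Fraction of the RR interval searched after QRS offset.
#' @param boundary_frac_pt Boundary fraction for P and T waves.
#' @param boundary_frac_qrs Boundary fraction for the QRS complex.
#' @param presence_frac Minimum wave peak (relative to R amplitude) for a
#'   P/T wave to count as present.
#' @param min_below_ms Run length that must stay sub-threshold at a
#'   boundary (rejects instantaneous zero-crossings inside a wave), ms.
#' @param match_ms Maximum R-peak distance when fusing leads, ms.
#' @export
delineation_params <- function(bandpass_hz = c(5, 15), mwi_ms = 150,
                               refractory_ms = 200, qrs_window_ms = 150,
                               p_window_ms = 200, t_frac = 0.6,
                               boundary_frac_pt = 5e-4,
                               boundary_frac_qrs = 5e-4,
                               presence_frac = 0.02, min_below_ms = 6,
                               match_ms = 150) {
  list(bandpass_hz = bandpass_hz, mwi_ms = mwi_ms,
       refractory_ms = refractory_ms, qrs_window_ms = qrs_window_ms,
       p_window_ms = p_window_ms, t_frac = t_frac,
       boundary_frac_pt = boundary_frac_pt,
       boundary_frac_qrs = boundary_frac_qrs,
       presence_frac = presence_frac, min_below_ms = min_below_ms,
       match_ms = match_ms)
}

#' Detect R peaks in a single lead
#'
#' Pan-Tompkins-style detector: zero-phase band-pass (default 5-15 Hz),
#' derivative, squaring, centered moving-window integration, adaptive
#' thresholding with a refractory period, then refinement to the absolute
#' extremum of the raw signal near each detection.
#'
#' @param x Single-lead samples (mV).
#' @param fs Sampling rate, Hz.
#' @param params A [delineation_params()].
#' @return Integer vector of R-peak sample indices (1-based, increasing).
#'   An all-constant signal yields an empty vector with a warning.
#' @export
detect_r_peaks <- function(x, fs, params = delineation_params()) {
  n <- length(x)
  if (n < 2 * fs)
    wmlr_stop("signal shorter than 2 s", "wmlr_length_error")
  if (diff(range(x)) == 0) {
    warning("constant signal: no R peaks detected", call. = FALSE)
    return(integer(0))
  }
  nyq <- fs / 2
  bp <- signal::butter(3, params$bandpass_hz / nyq, type = "pass")
  y <- signal::filtfilt(bp, x)
  d <- c(0, diff(y)) * fs
  sq <- d^2
  w <- max(3L, round(params$mwi_ms / 1000 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi <- as.numeric(mwi)
  mwi[is.na(mwi)] <- 0
  thr <- 0.5 * stats::quantile(mwi, 0.99, names = FALSE)
  if (!is.finite(thr) || thr <= 0) {
    warning("no QRS energy found", call. = FALSE)
    return(integer(0))
  }
  rf <- round(params$refractory_ms / 1000 * fs)
  above <- which(mwi >= thr)
  cand <- integer(0)
  i <- 1L
  while (i <= length(above)) {
    j <- i
    while (j < length(above) && above[j + 1] - above[j] <= rf) j <- j + 1L
    seg <- above[i]:above[j]
    cand <- c(cand, seg[which.max(mwi[seg])])
    i <- j + 1L
  }
  # refine to the absolute QRS extremum of the raw signal
  b <- estimate_baseline(x)
  half <- round(0.075 * fs)
  peaks <- vapply(cand, function(cc) {
    lo <- max(1L, cc - half); hi <- min(n, cc + half)
    as.integer(lo + which.max(abs(x[lo:hi] - b)) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce refractory on the refined locations
  if (length(peaks) > 1L) {
    keep <- logical(length(peaks)); keep[1] <- TRUE
    last <- peaks[1]
    for (k in 2:length(peaks)) {
      if (peaks[k] - last >= rf) { keep[k] <- TRUE; last <- peaks[k] }
      else if (abs(x[peaks[k]] - b) > abs(x[last] - b)) {
        keep[which(peaks == last)] <- FALSE; keep[k] <- TRUE; last <- peaks[k]
      }
    }
    peaks <- peaks[keep]
  }
  peaks
}

# isoelectric baseline as the mode of the amplitude histogram: the
# baseline level occupies the most samples in any ECG-like signal, while
# a plain median drifts with wave occupancy at high heart rates.
estimate_baseline <- function(x, nbins = 101L) {
  rng <- range(x)
  if (diff(rng) == 0) return(x[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- findInterval(x, br, rightmost.closed = TRUE)
  top <- which.max(tabulate(bin, nbins))
  sel <- x[bin >= top - 1L & bin <= top + 1L]
  stats::median(sel)
}

# boundary scan: from `start`, step `dir` (+1/-1); boundary is the last
# supra-threshold sample before `m` consecutive sub-threshold samples.
scan_boundary <- function(ax, start, dir, thr, m, limit) {
  i <- start; run <- 0L; last_supra <- start
  while ((dir < 0 && i >= limit) || (dir > 0 && i <= limit)) {
    if (ax[i] < thr) {
      run <- run + 1L
      if (run >= m) return(last_supra)
    } else {
      run <- 0L
      last_supra <- i
    }
    i <- i + dir
  }
  last_supra
}

# delineate one lead given its R peaks; returns a beats data.frame
delineate_lead <- function(x, fs, r_peaks, params) {
  n <- length(x)
  b <- estimate_baseline(x)
  ax <- abs(x - b)
  m <- max(1L, round(params$min_below_ms / 1000 * fs))
  wq <- round(params$qrs_window_ms / 1000 * fs)
  wp <- round(params$p_window_ms / 1000 * fs)
  out <- lapply(seq_along(r_peaks), function(k) {
    r <- r_peaks[k]
    ramp <- ax[r]
    thr_q <- params$boundary_frac_qrs * ramp
    qrs_on <- scan_boundary(ax, r, -1L, thr_q, m, max(1L, r - wq))
    qrs_off_in <- scan_boundary(ax, r, +1L, thr_q, m, min(n, r + wq))
    qrs_off <- qrs_off_in + 1L
    # P wave: dominant extremum in the PR window before QRS onset
    p_on <- p_off <- NA_integer_
    plo <- max(1L, qrs_on - wp); phi <- qrs_on - 1L
    if (phi - plo > m) {
      pk <- plo + which.max(ax[plo:phi]) - 1L
      if (ax[pk] >= params$presence_frac * ramp) {
        thr_p <- params$boundary_frac_pt * ax[pk]
        p_on <- scan_boundary(ax, pk, -1L, thr_p, m, plo)
        p_off <- min(scan_boundary(ax, pk, +1L, thr_p, m, phi) + 1L, qrs_on)
        if (p_on >= p_off) { p_on <- p_off <- NA_integer_ }
      }
    }
    # T wave: dominant extremum after QRS offset, up to t_frac of RR
    t_on <- t_off <- NA_integer_
    rr <- if (k < length(r_peaks)) r_peaks[k + 1] - r
          else if (k > 1) r - r_peaks[k - 1] else round(0.8 * fs)
    tlo <- qrs_off
    thi <- min(n, r + round(params$t_frac * rr))
    if (k < length(r_peaks)) thi <- min(thi, r_peaks[k + 1] - wq)
    if (thi - tlo > m) {
      pk <- tlo + which.max(ax[tlo:thi]) - 1L
      if (ax[pk] >= params$presence_frac * ramp) {
        thr_t <- params$boundary_frac_pt * ax[pk]
        t_on <- max(scan_boundary(ax, pk, -1L, thr_t, m, tlo), qrs_off)
        t_off <- scan_boundary(ax, pk, +1L, thr_t, m, thi) + 1L
        if (t_on >= t_off) { t_on <- t_off <- NA_integer_ }
      }
    }
    data.frame(p_on = p_on, p_off = p_off, qrs_on = qrs_on,
               qrs_off = qrs_off, t_on = t_on, t_off = t_off, r_peak = r)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Delineate P/QRS/T waves from the reduced lead set
#'
#' Each of the input leads (default I, II, V3 -- the leads assumed
#' available during reduced recording) is delineated independently; beats
#' are matched across leads by nearest R peak and each fiducial is fused as
#' the across-lead median. QRS has priority in overlap repair: a P offset
#' past the QRS onset is clipped to it, a T onset before the QRS offset is
#' clipped to it.
#'
#' @param record A preprocessed [ecg_record()] containing the input leads.
#' @param input_leads Leads used for delineation.
#' @param params A [delineation_params()].
#' @return A [fiducial_set()] with `source = "internal"`.
#' @export
delineate <- function(record, input_leads = c("I", "II", "V3"),
                      params = delineation_params()) {
  miss <- setdiff(input_leads, record$lead_names)
  if (length(miss))
    wmlr_stop(paste("record lacks required lead(s):",
                    paste(miss, collapse = ", ")), "wmlr_lead_error")
  fs <- record$fs
  n <- n_samples(record)
  per_lead <- lapply(input_leads, function(ld) {
    x <- get_lead(record, ld)
    rp <- suppressWarnings(detect_r_peaks(x, fs, params))
    if (!length(rp)) return(NULL)
    delineate_lead(x, fs, rp, params)
  })
  per_lead <- Filter(Negate(is.null), per_lead)
  if (!length(per_lead))
    return(fiducial_set(record$record_id, fs,
                        data.frame(p_on = integer(0), p_off = integer(0),
                                   qrs_on = integer(0), qrs_off = integer(0),
                                   t_on = integer(0), t_off = integer(0),
                                   r_peak = integer(0)),
                        source = "internal", n_samples = n))
  # reference = lead with most beats (ties: first listed)
  ref <- per_lead[[which.max(vapply(per_lead, nrow, integer(1)))]]
  tol <- round(params$match_ms / 1000 * fs)
  cols <- c("p_on", "p_off", "qrs_on", "qrs_off", "t_on", "t_off", "r_peak")
  fused <- lapply(seq_len(nrow(ref)), function(i) {
    rows <- lapply(per_lead, function(dl) {
      j <- which.min(abs(dl$r_peak - ref$r_peak[i]))
      if (abs(dl$r_peak[j] - ref$r_peak[i]) <= tol) dl[j, ] else NULL
    })
    rows <- do.call(rbind, Filter(Negate(is.null), rows))
    med <- vapply(cols, function(cc) {
      v <- rows[[cc]][!is.na(rows[[cc]])]
      if (!length(v)) NA_real_ else stats::median(v)
    }, numeric(1))
    as.data.frame(as.list(round(med)))
  })
  beats <- do.call(rbind, fused)
  names(beats) <- cols
  beats <- repair_beats(beats, n)
  fiducial_set(record$record_id, fs, beats, source = "internal",
               n_samples = n)
}

# enforce fiducial invariants after fusion (QRS has priority)
repair_beats <- function(beats, n) {
  if (!nrow(beats)) return(beats)
  beats <- beats[order(beats$r_peak), , drop = FALSE]
  beats <- beats[!duplicated(beats$r_peak), , drop = FALSE]
  for (i in seq_len(nrow(beats))) {
    bb <- beats[i, ]
    bb$qrs_on <- max(1, min(bb$qrs_on, bb$r_peak))
    bb$qrs_off <- min(n + 1, max(bb$qrs_off, bb$r_peak + 1))
    if (!is.na(bb$p_on)) {
      bb$p_off <- min(bb$p_off, bb$qrs_on)
      bb$p_on <- max(bb$p_on, 1)
      if (bb$p_on >= bb$p_off) bb$p_on <- bb$p_off <- NA
    }
    if (!is.na(bb$t_on)) {
      bb$t_on <- max(bb$t_on, bb$qrs_off)
      bb$t_off <- min(bb$t_off, n + 1)
      if (bb$t_on >= bb$t_off) bb$t_on <- bb$t_off <- NA
    }
    beats[i, ] <- bb
  }
  # consecutive beats must not overlap: clip this beat's tail at the next
  # beat's earliest onset
  if (nrow(beats) > 1) {
    for (i in seq_len(nrow(beats) - 1)) {
      nxt <- min(beats$p_on[i + 1], beats$qrs_on[i + 1], na.rm = TRUE)
      if (!is.na(beats$t_off[i]) && beats$t_off[i] > nxt) {
        beats$t_off[i] <- nxt
        if (beats$t_on[i] >= beats$t_off[i])
          beats$t_on[i] <- beats$t_off[i] <- NA
      }
      if (beats$qrs_off[i] > nxt) beats$qrs_off[i] <- nxt
    }
  }
  beats
}
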
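# Signal conditioning: zero-phase filtering, pulse segmentation with beat
# normalisation, Pan-Tompkins QRS detection, signal-quality indices and
# pulse arrival time.

# Zero-phase application of a cascade of IIR sections via the frequency
# domain: the signal is reflection-padded, its spectrum multiplied by the
# cascade's squared magnitude response (the steady-state forward-backward
# gain), and trimmed. Exactly zero-phase, exactly symmetric under time
# reversal, and numerically safe for high-order sections at very low
# normalized cut-offs.
.zero_phase <- function(sections, x, fs, pad_s = 5) {
  n <- length(x)
  pad <- min(n - 1, max(16L, as.integer(round(pad_s * fs))))
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  N <- length(xp)
  w <- 2 * pi * (seq_len(N) - 1) / N
  z <- exp(-1i * w)
  gain <- rep(1, N)
  for (s in sections) {
    H <- .polyval_z(s$b, z) / .polyval_z(s$a, z)
    gain <- gain * Mod(H)^2
  }
  y <- Re(fft(fft(xp) * gain, inverse = TRUE)) / N
  y[(pad + 1):(pad + n)]
}

.polyval_z <- function(coefs, z) {
  out <- rep(0 + 0i, length(z))
  for (c in coefs) out <- out * z + c
  out
}

#' Band-pass filter a raw PPG signal
#'
#' 8th-order Butterworth band-pass (0.5-10 Hz by default), realised as a
#' cascade of 4th-order high- and low-pass sections and applied zero-phase
#' (squared magnitude response, as forward-backward filtering), so fiducial
#' timing is preserved.
#'
#' @param raw numeric samples.
#' @param fs sampling rate, Hz; must exceed twice the upper cut-off.
#' @param band lower/upper cut-off frequencies, Hz.
#' @return Filtered samples, same length as the input.
#' @export
filter_ppg <- function(raw, fs, band = c(0.5, 10)) {
  if (fs <= 2 * band[2]) {
    stop("sampling rate must exceed twice the upper cut-off (filter unrealizable)")
  }
  hp <- signal::butter(4, band[1] * 2 / fs, type = "high")
  lp <- signal::butter(4, band[2] * 2 / fs, type = "low")
  .zero_phase(list(hp, lp), raw, fs)
}

# 2nd-order IIR notch biquad.
.notch_coefs <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + al),
       a = c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al)))
}

#' High-pass and notch filter a raw ECG signal
#'
#' 8th-order Butterworth high-pass at 0.5 Hz (cascade of two 4th-order
#' sections) to suppress baseline wander, followed by a 2nd-order IIR notch
#' at the mains frequency; both zero-phase.
#'
#' @param raw numeric samples.
#' @param fs sampling rate, Hz.
#' @param mains_hz mains interference frequency (50 Hz default).
#' @param highpass_hz baseline-wander cut-off.
#' @return Filtered samples, same length as the input.
#' @export
filter_ecg <- function(raw, fs, mains_hz = 50, highpass_hz = 0.5) {
  if (fs <= 2 * mains_hz) {
    stop("sampling rate must exceed twice the mains frequency (filter unrealizable)")
  }
  hp <- signal::butter(4, highpass_hz * 2 / fs, type = "high")
  nf <- .notch_coefs(mains_hz, fs)
  .zero_phase(list(hp, hp, nf), raw, fs)
}

# Local maxima of x satisfying a minimum value and minimum spacing (samples).
.find_peaks <- function(x, min_height = -Inf, min_dist = 1L) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  sel <- integer()
  for (i in cand) {
    if (!length(sel) || all(abs(sel - i) >= min_dist)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Segment a PPG signal into normalized beats
#'
#' Pulse onsets are detected from maxima of the first derivative (the
#' systolic upslope) with an adaptive amplitude threshold; each onset is the
#' signal minimum in the window preceding the upslope. Beats are delimited
#' onset-to-onset, resampled to a fixed length by cubic splines, min-max
#' normalized to exactly \[0, 1\], and differentiated twice by a
#' Savitzky-Golay filter to yield the velocity (VPG) and acceleration (APG)
#' plethysmograms. A per-beat quality index (SQI) is the Pearson correlation
#' against a running template (mean of the last accepted beats), clipped to
#' \[0, 1\].
#'
#' @param ppg filtered samples.
#' @param fs sampling rate, Hz.
#' @param beat_len number of samples per normalized beat.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window.
#' @param template_n running-template depth (beats).
#' @return An object of class `ppgbp_beats`: list with matrices `zeta`,
#'   `vpg`, `apg` (one row per beat) and vectors `onset_time`, `duration`,
#'   `sqi`.
#' @export
segment_beats <- function(ppg, fs, beat_len = 100L, sg_order = 7L,
                          sg_window = 11L, template_n = 20L) {
  if (length(ppg) < 5 * fs) stop("need at least 5 s of signal")
  empty <- structure(list(zeta = matrix(numeric(), 0, beat_len),
                          vpg = matrix(numeric(), 0, beat_len),
                          apg = matrix(numeric(), 0, beat_len),
                          onset_time = numeric(), duration = numeric(),
                          sqi = numeric()),
                     class = "ppgbp_beats")
  dx <- c(0, diff(ppg)) * fs
  thr <- 0.25 * quantile(dx[dx > 0], 0.95, na.rm = TRUE)
  if (!is.finite(thr) || thr <= 0) {
    warning("no detectable pulses")
    return(empty)
  }
  # two-pass: a first pass estimates the beat period, a second enforces a
  # spacing of 0.6 periods so secondary (diastolic) upslopes are not taken
  # as onsets
  pk1 <- .find_peaks(dx, min_height = thr,
                     min_dist = as.integer(round(0.3 * fs)))
  if (length(pk1) < 2) {
    warning("no detectable pulses")
    return(empty)
  }
  rr_est <- median(diff(pk1)) / fs
  slope_pk <- .find_peaks(dx, min_height = thr,
                          min_dist = as.integer(round(max(0.3, 0.6 * rr_est) * fs)))
  if (length(slope_pk) < 2) {
    warning("no detectable pulses")
    return(empty)
  }
  onsets <- vapply(slope_pk, function(i) {
    w0 <- max(1L, i - as.integer(round(0.3 * fs)))
    w0 + which.min(ppg[w0:i]) - 1L
  }, integer(1))
  onsets <- unique(onsets)
  nb <- length(onsets) - 1L
  zeta <- vpg <- apg <- matrix(NA_real_, nb, beat_len)
  onset_time <- duration <- sqi <- rep(NA_real_, nb)
  u <- seq(0, 1, length.out = beat_len)
  keep <- logical(nb)
  for (k in seq_len(nb)) {
    i0 <- onsets[k]; i1 <- onsets[k + 1]
    dur <- (i1 - i0) / fs
    if (dur < 0.3 || dur > 2.0) next
    seg <- ppg[i0:i1]
    ts <- seq(0, 1, length.out = length(seg))
    z <- spline(ts, seg, xout = u)$y
    rng <- max(z) - min(z)
    if (rng <= 0) next
    z <- (z - min(z)) / rng
    zeta[k, ] <- z
    du <- u[2] - u[1]
    vpg[k, ] <- signal::sgolayfilt(z, p = sg_order, n = sg_window, m = 1,
                                   ts = du)
    apg[k, ] <- signal::sgolayfilt(z, p = sg_order, n = sg_window, m = 2,
                                   ts = du)
    onset_time[k] <- (i0 - 1) / fs
    duration[k] <- dur
    keep[k] <- TRUE
  }
  zeta <- zeta[keep, , drop = FALSE]
  vpg <- vpg[keep, , drop = FALSE]
  apg <- apg[keep, , drop = FALSE]
  onset_time <- onset_time[keep]; duration <- duration[keep]
  # running-template SQI
  nb <- nrow(zeta)
  sqi <- numeric(nb)
  buf <- list()
  for (k in seq_len(nb)) {
    if (!length(buf)) {
      sqi[k] <- 1
    } else {
      tmpl <- colMeans(do.call(rbind, buf))
      r <- suppressWarnings(cor(zeta[k, ], tmpl))
      sqi[k] <- if (is.finite(r)) min(max(r, 0), 1) else 0
    }
    if (sqi[k] > 0.8) {
      buf[[length(buf) + 1L]] <- zeta[k, ]
      if (length(buf) > template_n) buf <- buf[-1L]
    }
  }
  structure(list(zeta = zeta, vpg = vpg, apg = apg,
                 onset_time = onset_time, duration = duration, sqi = sqi),
            class = "ppgbp_beats")
}

#' @export
#' @method print ppgbp_beats
print.ppgbp_beats <- function(x, ...) {
  cat("<ppgbp_beats> ", nrow(x$zeta), " beats, ", ncol(x$zeta),
      " samples each; median SQI ",
      round(median(x$sqi), 3), "\n", sep = "")
  invisible(x)
}

#' Detect QRS complexes (Pan-Tompkins)
#'
#' Classic stages: 5-15 Hz band-pass, five-point derivative, squaring,
#' 150-ms moving-window integration and adaptive signal/noise thresholds
#' with a search-back for missed beats. R peaks are refined to the local
#' maximum of the band-passed signal. An ECG quality index per 10-s block is
#' the agreement fraction (within 50 ms) between this detector and an
#' independent fixed-threshold peak picker.
#'
#' @param ecg filtered samples.
#' @param fs sampling rate, Hz.
#' @return list of class `ppgbp_qrs`: `r_peak_times` (seconds, strictly
#'   increasing), `block_t` (block centres) and `sqi_ecg` per 10-s block.
#' @export
detect_qrs <- function(ecg, fs) {
  if (length(ecg) < 5 * fs) stop("need at least 5 s of signal")
  n <- length(ecg)
  if (sd(ecg) < 1e-12) {
    nb <- max(1L, floor(n / fs / 10))
    return(structure(list(r_peak_times = numeric(),
                          block_t = (seq_len(nb) - 0.5) * 10,
                          sqi_ecg = rep(0, nb)), class = "ppgbp_qrs"))
  }
  bp <- signal::butter(2, c(5, 15) * 2 / fs)
  xf <- as.numeric(signal::filtfilt(bp, ecg))
  dx <- c(0, diff(xf))
  sq <- dx^2
  w <- max(1L, as.integer(round(0.15 * fs)))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  integ[is.na(integ)] <- 0
  pk <- .find_peaks(integ, min_dist = as.integer(round(0.2 * fs)))
  if (!length(pk)) {
    return(structure(list(r_peak_times = numeric(), block_t = numeric(),
                          sqi_ecg = numeric()), class = "ppgbp_qrs"))
  }
  spki <- max(integ[seq_len(min(n, 2 * fs))]) * 0.5
  npki <- mean(integ[seq_len(min(n, 2 * fs))]) * 0.5
  qrs <- integer()
  rr_hist <- numeric()
  for (i in pk) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] > thr) {
      qrs <- c(qrs, i)
      spki <- 0.125 * integ[i] + 0.875 * spki
      if (length(qrs) > 1) rr_hist <- c(rr_hist, i - qrs[length(qrs) - 1])
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
      # search-back: accept at half threshold if the expected beat is overdue
      if (length(qrs) && length(rr_hist)) {
        rr_avg <- mean(tail(rr_hist, 8))
        if ((i - qrs[length(qrs)]) > 1.66 * rr_avg && integ[i] > thr / 2) {
          qrs <- c(qrs, i)
          spki <- 0.25 * integ[i] + 0.75 * spki
          rr_hist <- c(rr_hist, i - qrs[length(qrs) - 1])
        }
      }
    }
  }
  # refine to the band-passed R peak (window compensates integration delay)
  half <- as.integer(round(0.15 * fs))
  r_idx <- vapply(qrs, function(i) {
    w0 <- max(1L, i - 2L * half); w1 <- min(n, i)
    w0 + which.max(xf[w0:w1]) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # drop double detections inside the refractory period
  if (length(r_idx) > 1) {
    keep <- c(TRUE, diff(r_idx) > 0.25 * fs)
    r_idx <- r_idx[keep]
  }
  r_times <- (r_idx - 1) / fs
  # independent detector for the quality index
  alt <- .find_peaks(xf, min_height = 0.4 * quantile(xf, 0.99),
                     min_dist = as.integer(round(0.25 * fs)))
  alt_times <- (alt - 1) / fs
  nb <- max(1L, floor(n / fs / 10))
  block_t <- (seq_len(nb) - 0.5) * 10
  sqi <- vapply(seq_len(nb), function(b) {
    lo <- (b - 1) * 10; hi <- b * 10
    a <- r_times[r_times >= lo & r_times < hi]
    bb <- alt_times[alt_times >= lo & alt_times < hi]
    if (length(a) < 4 || !length(bb)) return(0)
    m <- sum(vapply(a, function(ti) any(abs(bb - ti) <= 0.05), logical(1)))
    agree <- m / max(length(a), length(bb))
    # detections on noise pass the agreement check by chance but have
    # irregular inter-peak intervals; true rhythms within a 10-s block are
    # nearly constant-rate
    rr <- diff(a)
    cv <- sd(rr) / mean(rr)
    agree * max(0, 1 - 2.5 * cv)
  }, numeric(1))
  structure(list(r_peak_times = r_times, block_t = block_t, sqi_ecg = sqi),
            class = "ppgbp_qrs")
}

#' Pulse arrival time per beat
#'
#' PAT is the delay from the nearest preceding ECG R peak to the pulse foot
#' (beat onset). Beats with no preceding R peak are excluded; values outside
#' the physiological range are flagged with `sqi_pat = 0`.
#'
#' @param qrs a `ppgbp_qrs` annotation.
#' @param beats a `ppgbp_beats` object.
#' @param range admissible PAT range, seconds.
#' @return data.frame with `onset_time`, `pat` (s) and `sqi_pat`.
#' @export
compute_pat <- function(qrs, beats, range = c(0.05, 0.8)) {
  r <- qrs$r_peak_times
  out <- lapply(seq_along(beats$onset_time), function(k) {
    t0 <- beats$onset_time[k]
    prev <- r[r <= t0]
    if (!length(prev)) return(NULL)
    pat <- t0 - max(prev)
    sqi <- if (pat >= range[1] && pat <= range[2]) beats$sqi[k] else 0
    data.frame(onset_time = t0, pat = pat, sqi_pat = sqi)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(onset_time = numeric(), pat = numeric(),
                      sqi_pat = numeric())
  }
  out
}
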
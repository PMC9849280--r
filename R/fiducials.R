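# Fiducial-point detection on normalized beats: max-slope point W, systolic
# peak S, dicrotic notch N, diastolic peak D and the a-e waves of the APG.
# With rising arterial stiffness the tidal wave can overtake the first
# systolic peak, so S is the *first* turning point above the pulse midpoint,
# not the global maximum; a vanished notch is inferred from the APG.

# All local maxima/minima (interior) of a vector, as indices; two-sample
# plateaus (possible on symmetric pulses sampled at even length) count once.
.local_max <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  cand <- which(x[i] >= x[i - 1] & x[i] >= x[i + 1] &
                  (x[i] > x[i - 1] | x[i] > x[i + 1])) + 1L
  if (!length(cand)) return(integer())
  cand[c(TRUE, diff(cand) > 1)]
}
.local_min <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  cand <- which(x[i] <= x[i - 1] & x[i] <= x[i + 1] &
                  (x[i] < x[i - 1] | x[i] < x[i + 1])) + 1L
  if (!length(cand)) return(integer())
  cand[c(TRUE, diff(cand) > 1)]
}

# Prominence of a peak: height above the higher of the two flanking minima
# (window-bounded).
.prominence <- function(x, i) {
  lmin <- if (i > 1) min(x[1:i]) else x[i]
  rmin <- if (i < length(x)) min(x[i:length(x)]) else x[i]
  x[i] - max(lmin, rmin)
}

#' Detect the systolic peak of a normalized beat
#'
#' The systolic peak is the first turning point of the pulse above its
#' midpoint (amplitude 0.5 on the normalized beat) with prominence at least
#' `prominence`; when the tidal wave exceeds the original systolic peak this
#' still returns the first peak. If no such turning point exists the global
#' maximum is returned with `valid = FALSE`.
#'
#' @param zeta normalized beat (min 0, max 1).
#' @param prominence minimum peak prominence guarding numerical ripple.
#' @return list `t_s`, `amp_s` (normalized time/amplitude), `valid`.
#' @export
detect_systolic_peak <- function(zeta, prominence = 0.01) {
  n <- length(zeta)
  u <- seq(0, 1, length.out = n)
  cand <- .local_max(zeta)
  cand <- cand[zeta[cand] > 0.5]
  cand <- cand[vapply(cand, function(i) .prominence(zeta, i) >= prominence,
                      logical(1))]
  if (length(cand)) {
    i <- cand[1]
    list(t_s = u[i], amp_s = zeta[i], valid = TRUE)
  } else {
    i <- which.max(zeta)
    list(t_s = u[i], amp_s = zeta[i], valid = FALSE)
  }
}

#' Detect the dicrotic notch and diastolic peak
#'
#' The notch is the first local minimum of the pulse after the systolic peak
#' within `notch_window` beat fractions (equivalently a positive-going VPG
#' zero crossing); the diastolic peak is the first local maximum after the
#' notch. For stiff, notchless pulses the notch is inferred from the local
#' maximum of the APG in the search window and flagged `inferred`.
#'
#' @param zeta,apg normalized beat and its second derivative.
#' @param t_s systolic peak time.
#' @param notch_window search window length after `t_s`, beat fractions.
#' @return list `t_n`, `amp_n`, `t_d`, `amp_d`, `valid_n`, `valid_d`,
#'   `inferred`.
#' @export
detect_notch_diastolic <- function(zeta, apg, t_s, notch_window = 0.5) {
  n <- length(zeta)
  u <- seq(0, 1, length.out = n)
  win <- which(u > t_s & u <= min(t_s + notch_window, 0.98))
  inferred <- FALSE
  t_n <- amp_n <- NA_real_
  valid_n <- FALSE
  mins <- .local_min(zeta)
  mins <- mins[mins %in% win]
  if (length(mins)) {
    i_n <- mins[1]
    t_n <- u[i_n]; amp_n <- zeta[i_n]; valid_n <- TRUE
  } else {
    # no distinct notch: infer from curvature (APG local maximum after the
    # systolic peak marks the residual inflection)
    apg_max <- .local_max(apg)
    apg_max <- apg_max[apg_max %in% win & u[apg_max] > t_s + 0.08]
    if (length(apg_max)) {
      i_n <- apg_max[which.max(apg[apg_max])]
      t_n <- u[i_n]; amp_n <- zeta[i_n]; valid_n <- TRUE; inferred <- TRUE
    }
  }
  t_d <- amp_d <- NA_real_
  valid_d <- FALSE
  if (valid_n) {
    maxs <- .local_max(zeta)
    maxs <- maxs[u[maxs] > t_n]
    if (length(maxs)) {
      i_d <- maxs[1]
      t_d <- u[i_d]; amp_d <- zeta[i_d]; valid_d <- TRUE
    } else {
      # plateaued diastole: the notch location doubles as the reference
      t_d <- t_n; amp_d <- amp_n; valid_d <- inferred <- TRUE
    }
  }
  list(t_n = t_n, amp_n = amp_n, t_d = t_d, amp_d = amp_d,
       valid_n = valid_n, valid_d = valid_d, inferred = inferred)
}

#' Detect the a-e waves of the APG
#'
#' `a` is the global APG maximum in early systole, `b` the first minimum
#' after it, and `c`, `d`, `e` the subsequent alternating extrema up to
#' `t_n + e_margin`. Missing later waves are flagged invalid.
#'
#' @param apg second derivative of the normalized beat.
#' @param t_s systolic peak time (bounds early systole).
#' @param t_n notch time (`NA` allowed; limits the e-wave search).
#' @param e_margin beat fraction past the notch searched for later waves.
#' @return list with times `t_a`..`t_e`, amplitudes `a`..`e`, and a logical
#'   `valid` vector named a-e.
#' @export
detect_apg_waves <- function(apg, t_s = NA, t_n = NA, e_margin = 0.1) {
  n <- length(apg)
  u <- seq(0, 1, length.out = n)
  out <- list(t_a = NA_real_, t_b = NA_real_, t_c = NA_real_,
              t_d = NA_real_, t_e = NA_real_,
              a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
              e = NA_real_,
              valid = c(a = FALSE, b = FALSE, c = FALSE, d = FALSE,
                        e = FALSE))
  early_end <- if (is.finite(t_s)) max(t_s, 0.15) else 0.3
  sel <- which(u <= early_end)
  if (length(sel) < 3) return(out)
  i_a <- sel[which.max(apg[sel])]
  out$t_a <- u[i_a]; out$a <- apg[i_a]; out$valid["a"] <- TRUE
  limit <- if (is.finite(t_n)) min(t_n + e_margin, 1) else 0.8
  maxs <- .local_max(apg); mins <- .local_min(apg)
  nxt_min <- function(after) { i <- mins[u[mins] > after]; if (length(i)) i[1] else NA }
  nxt_max <- function(after) { i <- maxs[u[maxs] > after]; if (length(i)) i[1] else NA }
  i_b <- nxt_min(out$t_a)
  if (is.na(i_b)) return(out)
  out$t_b <- u[i_b]; out$b <- apg[i_b]; out$valid["b"] <- TRUE
  i_c <- nxt_max(out$t_b)
  if (is.na(i_c) || u[i_c] > limit) return(out)
  out$t_c <- u[i_c]; out$c <- apg[i_c]; out$valid["c"] <- TRUE
  i_d <- nxt_min(out$t_c)
  if (is.na(i_d) || u[i_d] > limit) return(out)
  out$t_d <- u[i_d]; out$d <- apg[i_d]; out$valid["d"] <- TRUE
  i_e <- nxt_max(out$t_d)
  if (is.na(i_e) || u[i_e] > limit) return(out)
  out$t_e <- u[i_e]; out$e <- apg[i_e]; out$valid["e"] <- TRUE
  out
}

#' Full fiducial set for one normalized beat
#'
#' Combines the max-slope point W (VPG maximum before S), the systolic peak,
#' the notch/diastolic pair and the APG waves.
#'
#' @param zeta,vpg,apg normalized beat and its first two derivatives.
#' @param prominence,notch_window,e_margin see the individual detectors.
#' @return list of class `ppgbp_fiducials`.
#' @export
detect_fiducials <- function(zeta, vpg, apg, prominence = 0.01,
                             notch_window = 0.5, e_margin = 0.1) {
  n <- length(zeta)
  u <- seq(0, 1, length.out = n)
  s <- detect_systolic_peak(zeta, prominence)
  nd <- detect_notch_diastolic(zeta, apg, s$t_s, notch_window)
  w_sel <- which(u < s$t_s)
  if (length(w_sel) >= 2) {
    i_w <- w_sel[which.max(vpg[w_sel])]
    t_w <- u[i_w]; valid_w <- TRUE
  } else {
    t_w <- NA_real_; valid_w <- FALSE
  }
  waves <- detect_apg_waves(apg, s$t_s, nd$t_n, e_margin)
  structure(list(
    t_w = t_w, t_s = s$t_s, t_n = nd$t_n, t_d = nd$t_d,
    amp_s = s$amp_s, amp_n = nd$amp_n, amp_d = nd$amp_d,
    apg_waves = waves,
    valid = c(w = valid_w, s = s$valid, n = nd$valid_n, d = nd$valid_d),
    notch_inferred = nd$inferred
  ), class = "ppgbp_fiducials")
}
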
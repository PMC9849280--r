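# Reference blood pressure from sparse, noisy cuff readings. A natural cubic
# smoothing spline f minimises
#
#     p * sum_i (y_i - f(t_i))^2 + int f''(t)^2 dt
#
# so large p approaches the interpolating cubic spline and small p the
# ordinary least-squares line. The penalty weight is shared across the
# cohort per channel and selected by leave-one-out RMSE over a log-spaced
# grid. Implementation follows the standard banded formulation of the
# natural-spline roughness penalty (K = Q R^-1 Q').

# roughness penalty matrix for knots t (n >= 3)
.penalty_K <- function(t) {
  n <- length(t)
  h <- diff(t)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    c <- j - 1
    Q[j - 1, c] <- 1 / h[j - 1]
    Q[j, c] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, c] <- 1 / h[j]
    R[c, c] <- (h[j - 1] + h[j]) / 3
    if (j < n - 1) {
      R[c, c + 1] <- R[c + 1, c] <- h[j] / 6
    }
  }
  list(Q = Q, R = R, K = Q %*% solve(R, t(Q)))
}

#' Fit a penalized cubic smoothing spline to cuff readings
#'
#' Minimises `p * RSS + roughness` exactly (natural cubic smoothing
#' spline); the fitted function is twice continuously differentiable at the
#' knots. With two observations the fit is the straight line through them.
#'
#' @param t observation times, strictly increasing (duplicates are an
#'   error).
#' @param y observed values, mmHg.
#' @param p penalty weight on the residual sum of squares (larger fits the
#'   data more closely).
#' @param time_scale divisor applied to `t` before fitting, so the
#'   roughness integral (and hence the meaning of `p`) is expressed in
#'   these units; with once-per-minute cuff readings a scale of 60 puts
#'   unit spacing between knots, which makes the canonical `p` grid span
#'   the full linear-to-interpolating range.
#' @return Object of class `ppgbp_spline` with knots, fitted values,
#'   second derivatives, and `p`.
#' @export
fit_smoothing_spline <- function(t, y, p, time_scale = 1) {
  fit <- .fit_spline_scaled(t / time_scale, y, p)
  fit$t <- fit$t * time_scale   # knot times in original units
  fit$time_scale <- time_scale
  fit
}

# core fit; knots in (possibly rescaled) time units
.fit_spline_scaled <- function(t, y, p) {
  if (anyDuplicated(t)) stop("duplicate observation times")
  o <- order(t)
  t <- t[o]; y <- y[o]
  n <- length(t)
  if (n < 2) stop("need at least 2 observations")
  if (n == 2) {
    return(structure(list(t = t, f = y, gamma = rep(0, n), p = p),
                     class = "ppgbp_spline"))
  }
  mats <- .penalty_K(t)
  # solve (pI + K) f = p y through the eigensystem of K: exact projection
  # onto the linear null space as p -> 0 and interpolation as p -> inf,
  # without the conditioning loss of a direct solve at extreme p
  eg <- eigen(mats$K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  lam[lam < 1e-12 * max(lam)] <- 0   # numerically null (linear) directions
  shrink <- p / (p + lam)
  f <- eg$vectors %*% (shrink * crossprod(eg$vectors, y))
  f <- as.numeric(f)
  gam <- c(0, solve(mats$R, crossprod(mats$Q, f)), 0)
  structure(list(t = t, f = f, gamma = gam, p = p), class = "ppgbp_spline")
}

#' Evaluate a fitted smoothing spline
#'
#' Natural cubic spline evaluation between knots; outside the knot range the
#' extension is linear (zero second derivative), but see [resample_spline()]
#' which refuses extrapolation.
#'
#' @param object a `ppgbp_spline`.
#' @param newdata evaluation times.
#' @param ... unused.
#' @return Numeric vector of f(newdata).
#' @export
predict.ppgbp_spline <- function(object, newdata, ...) {
  sc <- if (is.null(object$time_scale)) 1 else object$time_scale
  t <- object$t / sc; f <- object$f; M <- object$gamma
  newdata <- newdata / sc
  n <- length(t)
  vapply(newdata, function(x) {
    if (x <= t[1]) {
      h <- t[2] - t[1]
      slope <- (f[2] - f[1]) / h - h * M[2] / 6
      return(f[1] + slope * (x - t[1]))
    }
    if (x >= t[n]) {
      h <- t[n] - t[n - 1]
      slope <- (f[n] - f[n - 1]) / h + h * M[n - 1] / 6
      return(f[n] + slope * (x - t[n]))
    }
    i <- findInterval(x, t)
    h <- t[i + 1] - t[i]
    a <- (t[i + 1] - x) / h; b <- (x - t[i]) / h
    a * f[i] + b * f[i + 1] +
      ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1]) * h^2 / 6
  }, numeric(1))
}

#' Objective value of the smoothing-spline loss
#'
#' Evaluates `p * RSS + int f''^2` for a fitted spline against its data
#' (used by the local-optimality checks; the roughness integral of a
#' natural cubic spline is `f' K f`).
#'
#' @param fit a `ppgbp_spline`.
#' @param y the observations at the fit's knots.
#' @param f_values optional alternative knot values (a competitor spline).
#' @return Scalar objective value.
#' @export
spline_objective <- function(fit, y, f_values = NULL) {
  f <- if (is.null(f_values)) fit$f else f_values
  sc <- if (is.null(fit$time_scale)) 1 else fit$time_scale
  tk <- fit$t / sc
  n <- length(tk)
  K <- if (n >= 3) .penalty_K(tk)$K else matrix(0, n, n)
  fit$p * sum((y - f)^2) + as.numeric(t(f) %*% K %*% f)
}

#' Select the penalty weight by cohort leave-one-out error
#'
#' For each candidate `p`, each participant's series is refitted leaving out
#' one observation at a time; the RMSE of the predictions at the left-out
#' times is averaged per participant and then across the cohort, and the
#' `p` minimising this average is returned. Participants with fewer than 4
#' readings are excluded from that candidate's average.
#'
#' @param series list of data.frames with columns `t` and `y`, one per
#'   participant.
#' @param grid candidate penalty weights (log-spaced; default one per
#'   decade over 1e-3..1e8).
#' @param time_scale passed to [fit_smoothing_spline()].
#' @return list with `p` (selected), `loo` (named vector of cohort LOO RMSE
#'   per candidate).
#' @export
select_p <- function(series, grid = 10^seq(-3, 8), time_scale = 1) {
  if (!length(grid)) stop("empty penalty grid")
  loo <- vapply(grid, function(p) {
    per_part <- vapply(series, function(s) {
      n <- nrow(s)
      if (n < 4) return(NA_real_)
      errs <- vapply(seq_len(n), function(i) {
        fit <- fit_smoothing_spline(s$t[-i], s$y[-i], p,
                                    time_scale = time_scale)
        predict(fit, s$t[i]) - s$y[i]
      }, numeric(1))
      sqrt(mean(errs^2))
    }, numeric(1))
    mean(per_part, na.rm = TRUE)
  }, numeric(1))
  names(loo) <- signif(grid, 3)
  if (all(is.na(loo))) stop("no participant had enough readings for LOO")
  list(p = grid[which.min(loo)], loo = loo)
}

#' Resample a fitted spline on a regular grid
#'
#' Evaluates the spline at `1/f_bp`-spaced times within the data support;
#' extrapolation beyond the first or last cuff time is an error.
#'
#' @param fit a `ppgbp_spline`.
#' @param f_bp sampling frequency, Hz (1/60 for once per minute).
#' @param span optional c(from, to) in seconds; defaults to the full knot
#'   range.
#' @return data.frame with `t` and `y`.
#' @export
resample_spline <- function(fit, f_bp, span = range(fit$t)) {
  if (span[1] < fit$t[1] - 1e-9 || span[2] > fit$t[length(fit$t)] + 1e-9) {
    stop("resampling span extends beyond the cuff-data support")
  }
  tt <- seq(span[1], span[2], by = 1 / f_bp)
  data.frame(t = tt, y = predict(fit, tt))
}
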
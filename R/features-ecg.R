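# ECG complexity and entropy features, computed on windows of the filtered
# waveform: Hjorth mobility and complexity, Higuchi fractal dimension,
# Shannon entropy of the amplitude histogram, approximate and sample
# entropy, and multiscale sample entropy at coarse-graining scales 2-8.

#' Hjorth mobility and complexity
#'
#' Mobility estimates the signal's mean frequency as
#' `sqrt(var(dx) / var(x))` with `dx` the first difference; complexity
#' estimates the bandwidth as the ratio of the mobility of `dx` to the
#' mobility of `x`.
#'
#' @param x numeric window (>= 3 samples).
#' @return c(mobility, complexity); `NA` for zero-variance input.
#' @export
hjorth <- function(x) {
  v0 <- var(x)
  if (!is.finite(v0) || v0 <= 0) {
    return(c(mobility = NA_real_, complexity = NA_real_))
  }
  d1 <- diff(x); d2 <- diff(d1)
  mob <- sqrt(var(d1) / v0)
  mob_d <- sqrt(var(d2) / var(d1))
  c(mobility = mob, complexity = mob_d / mob)
}

#' Higuchi fractal dimension
#'
#' Slope of log mean curve length against log(1/k) over lags k = 1..k_max.
#'
#' @param x numeric window.
#' @param k_max maximum lag.
#' @return Fractal dimension (about 1 for smooth curves, about 2 for white
#'   noise); `NA` for constant input.
#' @export
higuchi_fd <- function(x, k_max = 17L) {
  n <- length(x)
  if (n < 10 * k_max) stop("window too short for k_max")
  if (sd(x) < 1e-14) return(NA_real_)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lm_k <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx)
      if (ni < 2) { lm_k[m] <- NA; next }
      lm_k[m] <- sum(abs(diff(x[idx]))) * (n - 1) / ((ni - 1) * k) / k
    }
    lk[k] <- mean(lm_k, na.rm = TRUE)
  }
  stats::coef(lm(log(lk) ~ log(1 / seq_len(k_max))))[[2]]
}

#' Shannon entropy of the amplitude distribution
#'
#' `-sum(p * log2(p))` over an equal-width amplitude histogram.
#'
#' @param x numeric window.
#' @param n_bins number of histogram bins (>= 2).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x, n_bins = 16L) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Approximate entropy
#'
#' Template-matching regularity with self-comparisons included.
#'
#' @param x numeric window.
#' @param m template length.
#' @param r tolerance (absolute units).
#' @return ApEn; `NA` when undefined.
#' @export
approx_entropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  .apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Sample entropy
#'
#' Template-matching regularity without self-comparisons. Returns `NA`
#' (rather than infinity) when no template pair matches at the tolerance.
#'
#' @inheritParams approx_entropy
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  .sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Coarse-grain a series for multiscale entropy
#'
#' Non-overlapping means of `scale` consecutive samples; the output length
#' is `floor(length(x) / scale)`.
#'
#' @param x numeric series.
#' @param scale positive integer scale.
#' @return Coarse-grained series.
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  nb <- floor(length(x) / scale)
  if (nb < 1) return(numeric())
  colMeans(matrix(x[seq_len(nb * scale)], nrow = scale))
}

#' The full ECG feature vector for one window
#'
#' @param x filtered ECG window (>= 200 samples).
#' @param m,r_frac sample-entropy template length and tolerance as a
#'   fraction of the window SD (the same absolute tolerance is used at all
#'   coarse-graining scales).
#' @param mse_scales multiscale-entropy scales.
#' @param k_max Higuchi lag cap.
#' @param n_bins Shannon-entropy histogram bins.
#' @return Named numeric vector of 10 features.
#' @export
ecg_feature_vector <- function(x, m = 2L, r_frac = 0.2,
                               mse_scales = c(2L, 4L, 6L, 8L),
                               k_max = 17L, n_bins = 16L) {
  if (length(x) < 200) stop("ECG window must have at least 200 samples")
  hj <- hjorth(x)
  r_abs <- r_frac * sd(x)
  mse <- vapply(mse_scales, function(s) {
    cg <- coarse_grain(x, s)
    if (length(cg) < 50) return(NA_real_)
    .sampen_cpp(cg, as.integer(m), r_abs)
  }, numeric(1))
  c(hjorth_mobility = unname(hj["mobility"]),
    hjorth_complexity = unname(hj["complexity"]),
    fractal_dimension = higuchi_fd(x, k_max),
    shannon_entropy = shannon_entropy(x, n_bins),
    approx_entropy = approx_entropy(x, m, r_abs),
    sample_entropy = sample_entropy(x, m, r_abs),
    setNames(mse, paste0("mse_", mse_scales)))
}
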
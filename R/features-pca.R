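# Principal-component features: a basis is fitted per signal (PPG, VPG,
# APG) on pooled good-quality beats resampled to 100 samples and
# mean-normalized; each beat then contributes its projections onto the
# first three eigenvectors.

.resample_row <- function(x, len) {
  if (length(x) == len) return(x)
  spline(seq(0, 1, length.out = length(x)), x,
         xout = seq(0, 1, length.out = len))$y
}

#' Fit the PCA basis on pooled good-quality beats
#'
#' Pools beats with SQI above the threshold across the supplied
#' `ppgbp_beats` objects, resamples each to `len` samples, mean-normalizes
#' the pooled matrix (subtracting the mean beat) and extracts the leading
#' eigenvectors of the covariance matrix for each of the PPG, VPG and APG
#' signals. The sign convention makes each eigenvector's
#' largest-magnitude loading positive.
#'
#' @param beats_list list of `ppgbp_beats` (one per participant, or one).
#' @param sqi_threshold minimum beat quality for inclusion.
#' @param n_comp number of components retained.
#' @param len resampled beat length.
#' @return list of class `ppgbp_pca_basis` with elements `ppg`, `vpg`,
#'   `apg`, each holding `mean`, `vectors` (len x n_comp, orthonormal) and
#'   `explained` (variance fractions, descending).
#' @export
fit_pca_basis <- function(beats_list, sqi_threshold = 0.8, n_comp = 3L,
                          len = 100L) {
  if (inherits(beats_list, "ppgbp_beats")) beats_list <- list(beats_list)
  pool <- function(field) {
    do.call(rbind, lapply(beats_list, function(b) {
      good <- b$sqi > sqi_threshold
      m <- b[[field]][good, , drop = FALSE]
      if (!nrow(m)) return(NULL)
      t(apply(m, 1, .resample_row, len = len))
    }))
  }
  fit_one <- function(m) {
    if (is.null(m) || nrow(m) < 10) {
      stop("need at least 10 good-quality beats to fit a PCA basis")
    }
    mu <- colMeans(m)
    mc <- sweep(m, 2, mu)
    cv <- stats::cov(mc)
    if (max(abs(cv)) < 1e-12) {
      stop("beat ensemble has zero covariance; PCA basis is undefined")
    }
    eg <- eigen(cv, symmetric = TRUE)
    vec <- eg$vectors[, seq_len(n_comp), drop = FALSE]
    for (j in seq_len(ncol(vec))) {
      if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
    }
    ev <- pmax(eg$values, 0)
    list(mean = mu, vectors = vec,
         explained = ev[seq_len(n_comp)] / sum(ev))
  }
  structure(list(ppg = fit_one(pool("zeta")),
                 vpg = fit_one(pool("vpg")),
                 apg = fit_one(pool("apg"))),
            class = "ppgbp_pca_basis")
}

#' Principal-component projections for one beat
#'
#' Projects the mean-normalized, resampled beat (and its VPG/APG) onto the
#' fitted eigenvectors.
#'
#' @param zeta,vpg,apg the beat and its derivatives.
#' @param basis a `ppgbp_pca_basis`.
#' @return Named numeric vector `ppg_pca1..3`, `vpg_pca1..3`,
#'   `apg_pca1..3`.
#' @export
pca_features <- function(zeta, vpg, apg, basis) {
  proj <- function(x, b) {
    xr <- .resample_row(x, length(b$mean))
    as.numeric(crossprod(b$vectors, xr - b$mean))
  }
  out <- c(proj(zeta, basis$ppg), proj(vpg, basis$vpg),
           proj(apg, basis$apg))
  names(out) <- c(paste0("ppg_pca", 1:3), paste0("vpg_pca", 1:3),
                  paste0("apg_pca", 1:3))
  out
}
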
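# Four-Gaussian pulse decomposition. Each normalized beat zeta(t), t in
# [0, 1], is modelled as the sum of four Gaussian components g_i with
# amplitude A_i in [0, 1], centre mu_i and width sigma_i, the centres
# constrained to a monotone increasing sequence. The fit minimises the RMSE
# between beat and model by bounded Levenberg-Marquardt least squares; the
# monotone-centre constraint is enforced by reparameterising the centres as
# cumulative non-negative increments, which keeps the problem smooth.

# default initial conditions: evenly spread centres, equal widths, amplitudes
# tracing a typical pulse contour. The width entry of each component's
# parameter triple is a variance of 0.01, i.e. sigma = 0.1.
.default_theta <- c(A1 = 0.9, mu1 = 0.2, s1 = 0.1,
                    A2 = 2 / 3, mu2 = 0.4, s2 = 0.1,
                    A3 = 0.5, mu3 = 0.6, s3 = 0.1,
                    A4 = 1 / 3, mu4 = 0.8, s4 = 0.1)

# theta (A1,mu1,s1,...,A4,mu4,s4) <-> internal parameterisation
# (A1..A4, mu1, d2, d3, d4, s1..s4) with d_i = mu_i - mu_{i-1} >= 0.
.theta_to_par <- function(theta) {
  A <- theta[c(1, 4, 7, 10)]
  mu <- theta[c(2, 5, 8, 11)]
  s <- theta[c(3, 6, 9, 12)]
  c(A, mu[1], pmax(diff(mu), 0), s)
}
.par_to_theta <- function(par) {
  A <- par[1:4]
  mu <- cumsum(par[5:8])
  s <- par[9:12]
  out <- as.numeric(rbind(A, mu, s))
  names(out) <- names(.default_theta)
  out
}

#' Fit the 4-Gaussian pulse model to one normalized beat
#'
#' Minimises the RMSE between the beat and the 4-Gaussian reconstruction by
#' bounded Levenberg-Marquardt least squares, subject to all parameters
#' non-negative, amplitudes at most 1 and monotonically increasing centres.
#' The first beat of a sequence is seeded from the default initial
#' conditions; pass `seed_theta` (typically the previous beat's fit) to seed
#' subsequent beats.
#'
#' @param zeta normalized beat (>= 50 samples).
#' @param seed_theta optional length-12 named parameter vector
#'   (A1, mu1, s1, ..., A4, mu4, s4) used as the starting point.
#' @param max_iter,ftol optimizer iteration cap and relative
#'   cost-reduction tolerance.
#' @param sigma_floor lower bound on the widths (avoids singular
#'   components).
#' @return list of class `ppgbp_gaussfit`: `theta` (named length-12 vector),
#'   `loss` (fit RMSE), `converged`.
#' @export
fit_beat <- function(zeta, seed_theta = NULL, max_iter = 200L, ftol = 1e-8,
                     sigma_floor = 1e-4) {
  n <- length(zeta)
  if (n < 50) stop("beat must have at least 50 samples")
  u <- seq(0, 1, length.out = n)
  if (is.null(seed_theta)) seed_theta <- .default_theta
  par0 <- .theta_to_par(seed_theta)
  lower <- c(rep(0, 4), 0, rep(0, 3), rep(sigma_floor, 4))
  upper <- c(rep(1, 4), 1, rep(0.6, 3), rep(0.5, 4))
  par0 <- pmin(pmax(par0, lower), upper)
  resid_fn <- function(p) zeta - gauss_sum(u, .par_to_theta(p))
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol,
                                         ptol = 1e-10)
  )
  theta <- .par_to_theta(fit$par)
  loss <- sqrt(mean(resid_fn(fit$par)^2))
  converged <- fit$info %in% 1:4
  if (!converged) loss <- Inf
  structure(list(theta = theta, loss = loss, converged = converged),
            class = "ppgbp_gaussfit")
}

#' Fit a sequence of beats with sequential seeding
#'
#' The first beat is seeded from the default initial conditions; each
#' subsequent beat is seeded from the previous converged fit, encouraging
#' beat-to-beat parameter continuity.
#'
#' @param beats a `ppgbp_beats` object (or a matrix with one beat per row).
#' @param ... passed to [fit_beat()].
#' @param reseed_loss when a seeded fit exceeds this loss the beat is
#'   refitted from the default initial conditions (the better fit is kept)
#'   and the seed chain restarts, so one artefactual beat cannot poison the
#'   sequence.
#' @return list of `ppgbp_gaussfit`, one per beat.
#' @export
fit_beats <- function(beats, ..., reseed_loss = 0.03) {
  zeta <- if (is.matrix(beats)) beats else beats$zeta
  fits <- vector("list", nrow(zeta))
  seed <- NULL
  for (k in seq_len(nrow(zeta))) {
    f <- fit_beat(zeta[k, ], seed_theta = seed, ...)
    # a poor seeded fit (e.g. after an artefactual beat) must not poison the
    # chain: retry from the default seed and keep the better fit
    if (!is.null(seed) && (!f$converged || f$loss > reseed_loss)) {
      f2 <- fit_beat(zeta[k, ], seed_theta = NULL, ...)
      if (!is.finite(f$loss) || f2$loss < f$loss) f <- f2
    }
    fits[[k]] <- f
    seed <- if (f$converged && f$loss <= reseed_loss) f$theta else NULL
  }
  fits
}

#' Gate beat quality on the decomposition loss
#'
#' Sets the beat quality index to 0 when the fit RMSE exceeds the gate
#' (0.03 by default); otherwise the incoming SQI is unchanged.
#'
#' @param fit a `ppgbp_gaussfit`.
#' @param sqi incoming quality index.
#' @param gate loss threshold.
#' @return Updated SQI.
#' @export
gate_quality <- function(fit, sqi, gate = 0.03) {
  if (!is.finite(fit$loss) || fit$loss > gate) 0 else sqi
}

#' Evaluate the fitted Gaussian components
#'
#' Returns the four components, the systolic wave `g_s = g1 + g2`, the
#' diastolic wave `g_d = g3 + g4` and the full reconstruction on a time
#' grid.
#'
#' @param fit a `ppgbp_gaussfit`.
#' @param t_grid evaluation grid in normalized time.
#' @return list with `g1`..`g4`, `g_s`, `g_d`, `model`.
#' @export
components <- function(fit, t_grid = seq(0, 1, length.out = 100)) {
  th <- fit$theta
  g <- lapply(0:3, function(i) {
    th[3 * i + 1] * exp(-(t_grid - th[3 * i + 2])^2 / (2 * th[3 * i + 3]^2))
  })
  names(g) <- paste0("g", 1:4)
  g$g_s <- g$g1 + g$g2
  g$g_d <- g$g3 + g$g4
  g$model <- g$g_s + g$g_d
  g
}
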
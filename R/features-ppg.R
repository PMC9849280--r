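# The PPG-derived feature library: 19 pulse-morphology features, 4 VPG
# features, 8 APG features, 21 Gaussian-decomposition indices and 9
# principal-component projections (61 in total). Missing fiducials propagate
# missing feature values, never silent zeros.

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# width of the pulse at a given amplitude level, linear interpolation of the
# first up-crossing and last down-crossing
.width_at <- function(zeta, level) {
  n <- length(zeta)
  u <- seq(0, 1, length.out = n)
  above <- zeta >= level
  if (!any(above) || all(above)) return(NA_real_)
  i_up <- which(above)[1]
  i_dn <- which(above)[length(which(above))]
  t_up <- if (i_up == 1) u[1] else {
    u[i_up - 1] + (level - zeta[i_up - 1]) / (zeta[i_up] - zeta[i_up - 1]) *
      (u[i_up] - u[i_up - 1])
  }
  t_dn <- if (i_dn == n) u[n] else {
    u[i_dn] + (zeta[i_dn] - level) / (zeta[i_dn] - zeta[i_dn + 1]) *
      (u[i_dn + 1] - u[i_dn])
  }
  t_dn - t_up
}

# interpolated beat value at normalized time t
.zeta_at <- function(zeta, t) {
  u <- seq(0, 1, length.out = length(zeta))
  approx(u, zeta, xout = t, rule = 2)$y
}

#' PPG and VPG morphology features for one beat
#'
#' Evaluates the pulse-morphology block (notch amplitude, reflection index,
#' timing intervals, slope transit time, systolic/diastolic means and areas,
#' widths, pressure index, harmonic features, distribution moments) and the
#' four VPG features. Features depending on an invalid fiducial are returned
#' as `NA`.
#'
#' @param zeta,vpg normalized beat and its first derivative.
#' @param fid a `ppgbp_fiducials` for the beat.
#' @param height_cm participant height (enters the pressure index).
#' @param nha_harmonics number of beat-fundamental harmonics used by the
#'   normalised harmonic area.
#' @return Named numeric vector of 23 features.
#' @export
morphology_features <- function(zeta, vpg, fid, height_cm,
                                nha_harmonics = 10L) {
  n <- length(zeta)
  u <- seq(0, 1, length.out = n)
  v <- c(n_amp = NA_real_, ri = NA_real_, delta_t = NA_real_, ct = NA_real_,
         t_sys = NA_real_, t_dia = NA_real_, t_ratio = NA_real_,
         stt = NA_real_, svri = NA_real_, a1 = NA_real_, a2 = NA_real_,
         ipa = NA_real_, width25 = NA_real_, width50 = NA_real_,
         pi_idx = NA_real_, nha = NA_real_, ihar = NA_real_,
         skewness = NA_real_, kurtosis = NA_real_,
         sys_mu = NA_real_, sys_sigma = NA_real_,
         dia_mu = NA_real_, dia_sigma = NA_real_)
  s_ok <- fid$valid["s"]
  n_ok <- fid$valid["n"]
  d_ok <- fid$valid["d"]
  w_ok <- fid$valid["w"]
  if (s_ok) {
    v["ct"] <- fid$t_s
    if (fid$t_s > 0) v["stt"] <- (fid$amp_s - zeta[1]) / fid$t_s
  }
  if (n_ok) {
    v["n_amp"] <- fid$amp_n
    v["t_sys"] <- fid$t_n
    v["t_dia"] <- 1 - fid$t_n
    if (v["t_dia"] > 0) v["t_ratio"] <- v["t_sys"] / v["t_dia"]
    sys_i <- u <= fid$t_n
    v["svri"] <- mean(zeta[!sys_i]) / mean(zeta[sys_i])
    v["a1"] <- .trapz(u[sys_i], zeta[sys_i])
    v["a2"] <- .trapz(u[!sys_i], zeta[!sys_i])
    if (v["a1"] > 0) v["ipa"] <- v["a2"] / v["a1"]
    v["sys_mu"] <- mean(vpg[sys_i]); v["sys_sigma"] <- sd(vpg[sys_i])
    v["dia_mu"] <- mean(vpg[!sys_i]); v["dia_sigma"] <- sd(vpg[!sys_i])
  }
  if (d_ok) v["ri"] <- fid$amp_d
  if (s_ok && d_ok) v["delta_t"] <- fid$t_d - fid$t_s
  if (s_ok && n_ok && w_ok && (fid$t_n - fid$t_w) > 0) {
    v["pi_idx"] <- (fid$t_n - fid$t_s) / (fid$t_n - fid$t_w) * height_cm
  }
  v["width25"] <- .width_at(zeta, 0.25)
  v["width50"] <- .width_at(zeta, 0.50)
  # harmonic series of the beat fundamental (one cycle per beat): bin n + 1
  # of the DFT is the n-th harmonic
  F <- fft(zeta)
  nh <- min(nha_harmonics, floor(n / 2) - 1)
  pow <- Mod(F[2:(nh + 1)])^2
  tot <- sum(pow)
  if (tot > 0) {
    v["nha"] <- sum(pow[-1]) / tot
    if (is.finite(v["ipa"]) && v["ipa"] > 0) {
      v["ihar"] <- (1 - v["nha"]) / v["ipa"]
    }
  }
  m <- mean(zeta); s2 <- mean((zeta - m)^2)
  if (s2 > 0) {
    v["skewness"] <- mean((zeta - m)^3) / s2^1.5
    v["kurtosis"] <- mean((zeta - m)^4) / s2^2
  }
  v
}

#' APG-wave features for one beat
#'
#' Signed wave-amplitude ratios, the ageing index, the b-c and b-d slopes
#' (normalised by a) and the PPG augmentation index (pulse amplitude at the
#' d-wave time over the amplitude at the b-wave time). Missing waves yield
#' `NA` for the dependent features.
#'
#' @param fid a `ppgbp_fiducials`.
#' @param zeta the normalized beat (for the augmentation index).
#' @return Named numeric vector of 8 features.
#' @export
apg_features <- function(fid, zeta) {
  w <- fid$apg_waves
  v <- c(b_a = NA_real_, c_a = NA_real_, d_a = NA_real_, e_a = NA_real_,
         agi = NA_real_, slope_bc = NA_real_, slope_bd = NA_real_,
         ppg_ai = NA_real_)
  if (!w$valid["a"] || w$a == 0) return(v)
  if (w$valid["b"]) v["b_a"] <- w$b / w$a
  if (w$valid["c"]) v["c_a"] <- w$c / w$a
  if (w$valid["d"]) v["d_a"] <- w$d / w$a
  if (w$valid["e"]) v["e_a"] <- w$e / w$a
  if (all(w$valid[c("b", "c", "d", "e")])) {
    v["agi"] <- (w$b - w$c - w$d - w$e) / w$a
  }
  if (all(w$valid[c("b", "c")]) && w$t_c != w$t_b) {
    v["slope_bc"] <- ((w$c - w$b) / (w$t_c - w$t_b)) / w$a
  }
  if (all(w$valid[c("b", "d")]) && w$t_d != w$t_b) {
    v["slope_bd"] <- ((w$d - w$b) / (w$t_d - w$t_b)) / w$a
  }
  if (all(w$valid[c("b", "d")])) {
    zb <- .zeta_at(zeta, w$t_b)
    zd <- .zeta_at(zeta, w$t_d)
    if (zb != 0) v["ppg_ai"] <- zd / zb
  }
  v
}

#' Gaussian-decomposition features for one beat
#'
#' The 12 fitted parameters plus nine derived indices: augmentation and
#' reflection indices (two conventions), the reflected-wave transit time,
#' an approximation of left-ventricular ejection time (time at which the
#' systolic wave decays below 1% of its maximum after its peak), the
#' systolic/diastolic area ratio and the fourth-component amplitude and
#' width scaled by the first-component amplitude. Areas are computed by
#' quadrature on the unit interval.
#'
#' @param fit a `ppgbp_gaussfit`.
#' @param grid_n quadrature grid size.
#' @return Named numeric vector of 21 features (all `NA` when the fit did
#'   not converge).
#' @export
gaussian_features <- function(fit, grid_n = 200L) {
  nm <- c(paste0("a_g", 1:4), paste0("mu_g", 1:4), paste0("sigma_g", 1:4),
          "gauss_ai", "gauss_ri", "gauss_rtt", "gauss_ai_r", "gauss_ri_r",
          "gauss_lvet", "gauss_sys_dias", "gauss_a4_a1", "gauss_sigma4_a1")
  v <- setNames(rep(NA_real_, length(nm)), nm)
  if (!fit$converged) return(v)
  th <- fit$theta
  A <- th[c(1, 4, 7, 10)]; mu <- th[c(2, 5, 8, 11)]; sg <- th[c(3, 6, 9, 12)]
  v[paste0("a_g", 1:4)] <- A
  v[paste0("mu_g", 1:4)] <- mu
  v[paste0("sigma_g", 1:4)] <- sg
  tg <- seq(0, 1, length.out = grid_n)
  comp <- components(fit, tg)
  area <- function(y) .trapz(tg, y)
  v["gauss_ai"] <- max(comp$g_s) - A[3]
  v["gauss_ri"] <- area(comp$g_s) - area(comp$g3)
  v["gauss_rtt"] <- mu[3] - mu[1]
  if (A[1] > 0) {
    v["gauss_ai_r"] <- (A[1] - A[2]) / A[1]
    v["gauss_ri_r"] <- A[3] / A[1]
    v["gauss_a4_a1"] <- A[4] / A[1]
    v["gauss_sigma4_a1"] <- sg[4] / A[1]
  }
  ad <- area(comp$g_d)
  if (ad > 0) v["gauss_sys_dias"] <- area(comp$g_s) / ad
  # LVET approximation: decay of the systolic wave below 1% of its maximum
  i_pk <- which.max(comp$g_s)
  below <- which(comp$g_s < 0.01 * comp$g_s[i_pk])
  below <- below[below > i_pk]
  v["gauss_lvet"] <- if (length(below)) tg[below[1]] else 1
  v
}
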
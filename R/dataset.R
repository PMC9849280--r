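# Regression-dataset assembly: window and average per-beat features around
# the reference BP samples, condition the windowed streams (outlier removal,
# Kalman smoothing, nearest-neighbour imputation), apply hybrid calibration
# (relative change from each participant's rest-period baseline), augment
# from the smoothing splines, and remove collinear features by iterated
# variance inflation factors.

#' Average feature streams in windows around the reference BP samples
#'
#' Per-beat PPG features and PAT values are averaged over good-quality beats
#' (SQI above `sqi_min`) in a window of length `window_s` centred on each BP
#' time; a window is recorded as missing when more than half of its beats
#' are bad. ECG features are computed from the ECG samples in the same
#' window provided at least half the window is covered by good-quality
#' blocks.
#'
#' @param beat_df per-beat feature data.frame (columns `onset_time`, `sqi`
#'   and feature columns).
#' @param pat_df data.frame from [compute_pat()].
#' @param ecg,ecg_fs filtered ECG samples and their rate.
#' @param qrs a `ppgbp_qrs` (supplies the per-block ECG quality).
#' @param bp_times window centres, seconds.
#' @param window_s window length, seconds.
#' @param sqi_min quality threshold.
#' @param ecg_opts list of arguments forwarded to [ecg_feature_vector()].
#' @return data.frame: one row per BP time (`t`), PPG feature columns, a
#'   `pat` column and the 10 ECG feature columns; missing entries are `NA`.
#' @export
window_features <- function(beat_df, pat_df, ecg, ecg_fs, qrs, bp_times,
                            window_s = 40, sqi_min = 0.8,
                            ecg_opts = list()) {
  feat_cols <- setdiff(names(beat_df), c("onset_time", "sqi"))
  ecg_names <- c("hjorth_mobility", "hjorth_complexity", "fractal_dimension",
                 "shannon_entropy", "approx_entropy", "sample_entropy",
                 "mse_2", "mse_4", "mse_6", "mse_8")
  rows <- lapply(bp_times, function(tau) {
    lo <- tau - window_s / 2; hi <- tau + window_s / 2
    out <- setNames(as.list(rep(NA_real_, length(feat_cols))), feat_cols)
    inw <- beat_df$onset_time >= lo & beat_df$onset_time <= hi
    if (any(inw)) {
      good <- inw & beat_df$sqi > sqi_min
      if (sum(good) / sum(inw) >= 0.5 && any(good)) {
        out[feat_cols] <- lapply(beat_df[good, feat_cols, drop = FALSE],
                                 function(col) {
                                   m <- mean(col, na.rm = TRUE)
                                   if (is.nan(m)) NA_real_ else m
                                 })
      }
    }
    out$pat <- NA_real_
    pin <- pat_df$onset_time >= lo & pat_df$onset_time <= hi
    if (any(pin)) {
      pgood <- pin & pat_df$sqi_pat > sqi_min
      if (sum(pgood) / sum(pin) >= 0.5 && any(pgood)) {
        out$pat <- mean(pat_df$pat[pgood])
      }
    }
    out[ecg_names] <- NA_real_
    binw <- qrs$block_t >= lo - 5 & qrs$block_t <= hi + 5
    good_frac <- if (any(binw)) mean(qrs$sqi_ecg[binw] > sqi_min) else 0
    i0 <- max(1L, floor(lo * ecg_fs) + 1L)
    i1 <- min(length(ecg), ceiling(hi * ecg_fs))
    if (good_frac >= 0.5 && (i1 - i0) >= 200) {
      ev <- try(do.call(ecg_feature_vector, c(list(x = ecg[i0:i1]),
                                              ecg_opts)), silent = TRUE)
      if (!inherits(ev, "try-error")) out[ecg_names] <- as.list(ev)
    }
    c(list(t = tau), out)
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

# scalar random-walk Kalman filter + RTS smoother; variances estimated from
# the stream's first differences
.kalman_smooth <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) < 4) return(x)
  # measurement noise from second differences (robust to smooth trends:
  # var(diff2) = 6 * sigma^2 for white noise on a slowly varying signal)
  d2 <- diff(x[ok], differences = 2)
  r_var <- max(mad(d2)^2 / 6, 1e-12)
  q_var <- max(var(diff(x[ok])) - 2 * r_var, r_var / 10)
  n <- length(x)
  m <- numeric(n); P <- numeric(n)
  m_pred <- numeric(n); P_pred <- numeric(n)
  m[1] <- x[ok[1]]; P[1] <- r_var
  m_pred[1] <- m[1]; P_pred[1] <- P[1]
  for (k in 2:n) {
    m_pred[k] <- m[k - 1]
    P_pred[k] <- P[k - 1] + q_var
    if (!is.na(x[k])) {
      K <- P_pred[k] / (P_pred[k] + r_var)
      m[k] <- m_pred[k] + K * (x[k] - m_pred[k])
      P[k] <- (1 - K) * P_pred[k]
    } else {
      m[k] <- m_pred[k]; P[k] <- P_pred[k]
    }
  }
  ms <- m
  for (k in (n - 1):1) {
    G <- P[k] / P_pred[k + 1]
    ms[k] <- m[k] + G * (ms[k + 1] - m_pred[k + 1])
  }
  ms[is.na(x) & seq_len(n) < ok[1]] <- NA  # leave leading gap for imputation
  ms
}

#' Condition windowed feature streams
#'
#' Per feature and participant: values beyond `mad_k` robust deviations from
#' a rolling median are removed, a scalar random-walk Kalman smoother
#' reduces transient artefacts, and remaining gaps are filled by
#' nearest-neighbour imputation in time. A feature with no finite values for
#' a participant is left missing with a warning.
#'
#' @param rows data.frame from [window_features()] (must include `t`).
#' @param feature_cols columns to condition (default: all but `t`).
#' @param mad_k outlier threshold in MAD units.
#' @param mad_window rolling-median window, rows.
#' @param smooth apply the Kalman smoother (TRUE) or only outlier removal
#'   and imputation.
#' @return data.frame of the same shape.
#' @export
condition_feature_streams <- function(rows, feature_cols = NULL, mad_k = 5,
                                      mad_window = 10L, smooth = TRUE) {
  if (is.null(feature_cols)) feature_cols <- setdiff(names(rows), "t")
  for (cl in feature_cols) {
    x <- rows[[cl]]
    if (all(is.na(x))) {
      warning("feature '", cl, "' entirely missing; left as NA")
      next
    }
    med <- zoo::rollapply(zoo::zoo(x), width = mad_window,
                          FUN = function(v) median(v, na.rm = TRUE),
                          fill = NA, partial = TRUE, align = "center")
    med <- as.numeric(med)
    resid <- x - med
    s <- mad(resid, na.rm = TRUE)
    if (is.finite(s) && s > 0) {
      x[abs(resid) > mad_k * s] <- NA
    }
    if (smooth && sum(!is.na(x)) >= 3) x <- .kalman_smooth(x)
    # nearest-neighbour imputation on the time axis
    if (anyNA(x) && any(!is.na(x))) {
      ok <- which(!is.na(x))
      for (i in which(is.na(x))) {
        x[i] <- x[ok[which.min(abs(rows$t[ok] - rows$t[i]))]]
      }
    }
    rows[[cl]] <- x
  }
  rows
}

#' Hybrid calibration of one participant's rows
#'
#' Each dynamic feature becomes its relative change from the participant's
#' rest-period baseline, `x = (f - f_base) / f_base`, and each BP channel
#' becomes the change from the rest-period mean. If no rows fall in the rest
#' window the baseline is taken from a one-minute window centred on the
#' first row. Features with a zero baseline are dropped for the participant
#' with a warning.
#'
#' @param rows conditioned rows with columns `t`, feature columns and BP
#'   reference columns `sbp`, `map`, `dbp`.
#' @param rest_window c(from, to) seconds of the resting stage.
#' @param feature_cols the dynamic feature columns.
#' @return list: `rows` (calibrated; `dsbp`/`dmap`/`ddbp` targets),
#'   `baseline_features`, `baseline_bp` (named c(sbp, map, dbp)).
#' @export
calibrate <- function(rows, rest_window = c(0, 300), feature_cols) {
  in_rest <- rows$t >= rest_window[1] & rows$t <= rest_window[2]
  if (!any(in_rest)) {
    t0 <- rows$t[1]
    in_rest <- abs(rows$t - t0) <= 30
  }
  base_f <- vapply(feature_cols,
                   function(cl) mean(rows[[cl]][in_rest], na.rm = TRUE),
                   numeric(1))
  base_bp <- c(sbp = mean(rows$sbp[in_rest]), map = mean(rows$map[in_rest]),
               dbp = mean(rows$dbp[in_rest]))
  for (cl in feature_cols) {
    b <- base_f[[cl]]
    if (!is.finite(b) || b == 0) {
      warning("feature '", cl, "' has zero or undefined rest baseline; dropped")
      rows[[cl]] <- NA_real_
      next
    }
    rows[[cl]] <- (rows[[cl]] - b) / b
  }
  rows$dsbp <- rows$sbp - base_bp["sbp"]
  rows$dmap <- rows$map - base_bp["map"]
  rows$ddbp <- rows$dbp - base_bp["dbp"]
  list(rows = rows, baseline_features = base_f, baseline_bp = base_bp)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R_j^2)` where `R_j^2` is the unadjusted coefficient of
#' determination of regressing column j on the remaining columns (with
#' intercept).
#'
#' @param X numeric matrix or data.frame, no missing values.
#' @return Named vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  M <- ncol(X)
  if (M < 2) return(setNames(rep(1, M), colnames(X)))
  out <- vapply(seq_len(M), function(j) {
    yj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(others, yj)
    ssr <- sum(fit$residuals^2)
    sst <- sum((yj - mean(yj))^2)
    if (sst <= 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (r2 >= 1) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}

#' Condition number of a design matrix
#'
#' Ratio of the largest to smallest singular value after scaling columns to
#' unit standard deviation (a value above about 30 indicates strong
#' multicollinearity).
#'
#' @param X numeric matrix or data.frame.
#' @return Scalar condition number.
#' @export
condition_number <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  d <- svd(sweep(X, 2, s, "/"), nu = 0, nv = 0)$d
  d[1] / d[length(d)]
}

#' Iteratively remove collinear features by VIF
#'
#' On each iteration the feature with the largest VIF is removed until no
#' feature's VIF exceeds the threshold. Perfectly collinear features
#' (infinite VIF) are removed first. Exempt columns (e.g. demographics) are
#' never removed but do not enter the VIF computation.
#'
#' @param X numeric matrix or data.frame of candidate features.
#' @param threshold removal threshold (10 corresponds to R_j = 0.9...).
#' @param exempt column names excluded from removal.
#' @return list of class `ppgbp_collinearity`: `X_reduced`, `removed`
#'   (in removal order), `vif_history`, `kappa_before`, `kappa_after`,
#'   `vif_final`.
#' @export
remove_collinear <- function(X, threshold = 10, exempt = character()) {
  X <- as.data.frame(X)
  dyn <- setdiff(names(X), exempt)
  kappa_before <- condition_number(X[dyn])
  removed <- character()
  hist <- list()
  repeat {
    if (length(dyn) < 2) break
    v <- vif(X[dyn])
    hist[[length(hist) + 1L]] <- v
    if (max(v) <= threshold) break
    worst <- names(v)[which.max(v)]
    removed <- c(removed, worst)
    dyn <- setdiff(dyn, worst)
  }
  v_final <- if (length(dyn) >= 2) vif(X[dyn]) else setNames(rep(1, length(dyn)), dyn)
  structure(list(
    X_reduced = X[c(dyn, exempt)],
    removed = removed,
    vif_history = hist,
    vif_final = v_final,
    kappa_before = kappa_before,
    kappa_after = condition_number(X[dyn])
  ), class = "ppgbp_collinearity")
}
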
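# Windowing, stream conditioning, hybrid calibration and collinearity
# removal.

# minimal synthetic per-beat table: one feature, beats every second
fake_beat_df <- function(times, value, sqi = 1) {
  data.frame(onset_time = times, sqi = sqi, feat = value)
}
empty_pat <- data.frame(onset_time = numeric(), pat = numeric(),
                        sqi_pat = numeric())
fake_qrs <- function(span = 600) {
  nb <- max(1, floor(span / 10))
  structure(list(r_peak_times = numeric(), block_t = (seq_len(nb) - 0.5) * 10,
                 sqi_ecg = rep(0, nb)), class = "ppgbp_qrs")
}

test_that("windowing averages good beats and honours the half-bad rule", {
  tt <- seq(1, 200)
  bdf <- fake_beat_df(tt, value = 7)
  wf <- window_features(bdf, empty_pat, numeric(), 1, fake_qrs(200),
                        bp_times = 100, window_s = 40)
  expect_equal(wf$feat, 7)
  # 60% of the window flagged bad: feature missing
  sqi <- ifelse(tt %% 5 < 3, 0.1, 0.95)       # 60% bad everywhere
  wf2 <- window_features(fake_beat_df(tt, 7, sqi), empty_pat, numeric(), 1,
                         fake_qrs(200), 100, 40)
  expect_true(is.na(wf2$feat))
  # mixed values equal the arithmetic mean over included beats
  vals <- sin(tt / 3)
  sqi3 <- rep(c(0.95, 0.95, 0.95, 0.1), 50)
  wf3 <- window_features(fake_beat_df(tt, vals, sqi3), empty_pat, numeric(),
                         1, fake_qrs(200), 100, 40)
  inw <- tt >= 80 & tt <= 120 & sqi3 > 0.8
  expect_equal(wf3$feat, mean(vals[inw]), tolerance = 1e-12)
})

test_that("windowing is translation-equivariant", {
  tt <- seq(1, 200)
  vals <- cos(tt / 7)
  bdf <- fake_beat_df(tt, vals)
  wf <- window_features(bdf, empty_pat, numeric(), 1, fake_qrs(200), 100, 40)
  shift <- 55
  bdf2 <- fake_beat_df(tt + shift, vals)
  wf2 <- window_features(bdf2, empty_pat, numeric(), 1, fake_qrs(300),
                         100 + shift, 40)
  expect_equal(wf$feat, wf2$feat, tolerance = 1e-12)
})

test_that("stream conditioning removes spikes and is benign otherwise", {
  set.seed(1)
  n <- 60
  rows <- data.frame(t = seq_len(n) * 60, f = sin(seq_len(n) / 8))
  rows$f[30] <- rows$f[30] + 10 * mad(diff(rows$f))  # isolated spike
  out <- condition_feature_streams(rows, "f")
  expect_lt(abs(out$f[30] - sin(30 / 8)), 0.3)
  expect_lt(max(abs(out$f[-(28:32)] - rows$f[-(28:32)])), 0.2)
  # constant stream passes through unchanged (Kalman steady state)
  rowsc <- data.frame(t = seq_len(n) * 60, f = rep(2.5, n))
  expect_equal(condition_feature_streams(rowsc, "f")$f, rep(2.5, n),
               tolerance = 1e-9)
  # no missing values: imputation is the identity (outliers aside)
  rows2 <- data.frame(t = seq_len(n) * 60, f = sin(seq_len(n) / 8))
  out2 <- condition_feature_streams(rows2, "f", smooth = FALSE)
  expect_equal(out2$f, rows2$f, tolerance = 1e-12)
  # an entirely-missing feature warns and stays missing
  rows3 <- data.frame(t = 1:10, f = NA_real_)
  expect_warning(out3 <- condition_feature_streams(rows3, "f"),
                 "entirely missing")
  expect_true(all(is.na(out3$f)))
})

test_that("calibration zeroes rest means and applies the relative change", {
  rows <- data.frame(t = c(60, 120, 180, 240, 300, 360),
                     f = c(2, 2, 2, 2, 2, 2.4),
                     sbp = c(110, 110, 110, 110, 110, 125),
                     map = 90, dbp = 70)
  cal <- calibrate(rows, rest_window = c(0, 300), feature_cols = "f")
  expect_equal(cal$rows$f[1:5], rep(0, 5), tolerance = 1e-12)
  expect_equal(cal$rows$f[6], 0.2, tolerance = 1e-12)   # (2.4 - 2) / 2
  expect_equal(cal$rows$dsbp[1:5], rep(0, 5), tolerance = 1e-12)
  expect_equal(cal$rows$dsbp[6], 15, tolerance = 1e-12)
  # zero baseline: feature dropped with a warning
  rows$g <- c(0, 0, 0, 0, 0, 1)
  expect_warning(cal2 <- calibrate(rows, c(0, 300), c("f", "g")),
                 "zero or undefined")
  expect_true(all(is.na(cal2$rows$g)))
  # no rest rows: falls back to a window around the first reading
  rows3 <- rows[rows$t > 300, , drop = FALSE]
  cal3 <- calibrate(rows3, c(0, 300), "f")
  expect_equal(unname(cal3$baseline_bp["sbp"]), 125)
})

test_that("calibration is not idempotent in general", {
  rows <- data.frame(t = c(60, 120, 400), f = c(2, 4, 6),
                     sbp = c(110, 112, 126), map = 90, dbp = 70)
  c1 <- calibrate(rows, c(0, 300), "f")
  c2 <- suppressWarnings(calibrate(c1$rows[names(rows)], c(0, 300), "f"))
  expect_false(isTRUE(all.equal(c1$rows$f, c2$rows$f)))
})

test_that("VIF arithmetic: a 0.9 coefficient of determination gives exactly 10", {
  set.seed(2)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  u <- X[, 2] + 0.5 * X[, 3]
  u <- u - mean(u)
  e <- rnorm(n)
  e <- residuals(lm(e ~ X[, 2] + X[, 3]))    # orthogonal to the others
  e <- e * sqrt(sum(u^2) / (9 * sum(e^2)))   # SSR/SST = 0.1 exactly
  X[, 1] <- u + e
  v <- vif(X)
  expect_equal(unname(v[1]), 10, tolerance = 1e-9)
})

test_that("collinearity removal: identity design untouched, duplicates cut", {
  set.seed(3)
  n <- 100
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  colnames(Q) <- paste0("q", 1:4)
  rep0 <- remove_collinear(Q)
  expect_length(rep0$removed, 0)
  expect_equal(rep0$kappa_before, 1, tolerance = 1e-2)
  # duplicated column: exactly one of the pair goes on iteration one
  X <- as.data.frame(Q)
  X$q5 <- X$q1
  rep1 <- remove_collinear(X)
  expect_true(rep1$removed[1] %in% c("q1", "q5"))
  expect_equal(sum(c("q1", "q5") %in% names(rep1$X_reduced)), 1)
})

test_that("survivors of VIF removal all verify below threshold independently", {
  set.seed(4)
  n <- 150
  Z <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(Z,
             Z[, 1] + 0.1 * rnorm(n),
             Z[, 2] - Z[, 3] + 0.1 * rnorm(n),
             0.5 * Z[, 1] + 0.5 * Z[, 4] + 0.15 * rnorm(n))
  colnames(X) <- paste0("x", 1:7)
  rep2 <- remove_collinear(X, threshold = 10)
  Xr <- as.matrix(rep2$X_reduced)
  # independent regression oracle per surviving feature
  for (j in seq_len(ncol(Xr))) {
    r2 <- summary(lm(Xr[, j] ~ Xr[, -j]))$r.squared
    expect_lte(1 / (1 - r2), 10 + 1e-6)
  }
  expect_lt(rep2$kappa_after, rep2$kappa_before)
})

test_that("removal order follows the largest current VIF", {
  set.seed(5)
  n <- 120
  Z <- matrix(rnorm(n * 3), n, 3)
  X <- cbind(Z, Z[, 1] + 0.05 * rnorm(n), Z[, 2] + 0.5 * rnorm(n))
  colnames(X) <- paste0("x", 1:5)
  rep3 <- remove_collinear(X)
  v0 <- vif(X)
  expect_equal(rep3$removed[1], names(v0)[which.max(v0)])
})
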
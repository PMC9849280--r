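# The PPG feature library: morphology, APG ratios, Gaussian indices and
# principal-component projections.

test_that("timing features follow triangle-pulse geometry", {
  n <- 201
  u <- seq(0, 1, length.out = n)
  z <- ifelse(u <= 0.5, u / 0.5, (1 - u) / 0.5)
  fid <- structure(list(
    t_w = 0.25, t_s = 0.5, t_n = 0.75, t_d = 0.75,
    amp_s = 1, amp_n = 0.5, amp_d = 0.5,
    apg_waves = list(valid = c(a = FALSE, b = FALSE, c = FALSE, d = FALSE,
                               e = FALSE)),
    valid = c(w = TRUE, s = TRUE, n = TRUE, d = FALSE),
    notch_inferred = FALSE), class = "ppgbp_fiducials")
  vpg <- c(diff(z), 0) * (n - 1)
  v <- morphology_features(z, vpg, fid, height_cm = 170)
  expect_equal(unname(v["t_sys"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(v["t_dia"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(v["t_ratio"]), 3, tolerance = 1e-12)
  expect_equal(unname(v["t_sys"] + v["t_dia"]), 1, tolerance = 1e-9)
  expect_equal(unname(v["ct"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(v["stt"]), 2, tolerance = 1e-12)  # 1 amplitude / 0.5
  expect_true(is.na(v["ri"]))                           # D invalid
  # widths of the triangle at 25% and 50% amplitude
  expect_equal(unname(v["width25"]), 0.75, tolerance = 0.01)
  expect_equal(unname(v["width50"]), 0.5, tolerance = 0.01)
  # A1/A2 against the trapezoid oracle
  expect_equal(unname(v["a1"]),
               sum(diff(u[u <= 0.75]) *
                   (head(z[u <= 0.75], -1) + tail(z[u <= 0.75], -1)) / 2),
               tolerance = 1e-12)
  expect_equal(unname(v["ipa"]), unname(v["a2"] / v["a1"]), tolerance = 1e-12)
})

test_that("a single-lobe sinusoid has zero normalised harmonic area", {
  n <- 100
  u <- seq_len(n) / n
  z <- (1 - cos(2 * pi * u)) / 2   # exactly one cycle: all power in bin 2
  fid <- detect_fiducials(z, rep(0, n), rep(0, n))
  v <- morphology_features(z, rep(0, n), fid, height_cm = 170)
  expect_equal(unname(v["nha"]), 0, tolerance = 1e-9)
})

test_that("skewness and kurtosis match direct moment computation", {
  b <- theta_beat(0.4)
  d <- beat_with_derivs(b$zeta)
  fid <- detect_fiducials(b$zeta, d$vpg, d$apg)
  v <- morphology_features(b$zeta, d$vpg, fid, 170)
  z <- b$zeta; m <- mean(z); s2 <- mean((z - m)^2)
  expect_equal(unname(v["skewness"]), mean((z - m)^3) / s2^1.5,
               tolerance = 1e-12)
  expect_equal(unname(v["kurtosis"]), mean((z - m)^4) / s2^2,
               tolerance = 1e-12)
})

test_that("APG ratio features follow the printed arithmetic", {
  w <- list(t_a = 0.05, t_b = 0.15, t_c = 0.25, t_d = 0.35, t_e = 0.45,
            a = 2, b = -1, c = 0.5, d = -0.25, e = 0.1,
            valid = c(a = TRUE, b = TRUE, c = TRUE, d = TRUE, e = TRUE))
  fid <- structure(list(apg_waves = w), class = "ppgbp_fiducials")
  z <- textbook_beat()
  v <- apg_features(fid, z)
  expect_equal(unname(v["agi"]), (-1 - 0.5 + 0.25 - 0.1) / 2,
               tolerance = 1e-12)              # -0.675
  expect_equal(unname(v["b_a"]), -0.5, tolerance = 1e-12)
  expect_equal(unname(v["slope_bc"]), ((0.5 - (-1)) / 0.1) / 2,
               tolerance = 1e-12)
  # b = c makes the b-c slope zero
  w2 <- w; w2$c <- w2$b
  fid2 <- structure(list(apg_waves = w2), class = "ppgbp_fiducials")
  expect_equal(unname(apg_features(fid2, z)["slope_bc"]), 0,
               tolerance = 1e-12)
  # equal pulse amplitude at the b and d wave times gives unit index
  u <- seq(0, 1, length.out = 100)
  w3 <- w; w3$t_b <- 0.2; w3$t_d <- 0.2
  fid3 <- structure(list(apg_waves = w3), class = "ppgbp_fiducials")
  expect_equal(unname(apg_features(fid3, z)["ppg_ai"]), 1, tolerance = 1e-12)
  # missing later waves propagate NA, never zero
  w4 <- w; w4$valid["d"] <- FALSE
  fid4 <- structure(list(apg_waves = w4), class = "ppgbp_fiducials")
  v4 <- apg_features(fid4, z)
  expect_true(is.na(v4["agi"]) && is.na(v4["slope_bd"]) && is.na(v4["d_a"]))
})

test_that("Gaussian indices follow their definitions", {
  th <- setNames(c(0.5, 0.2, 0.05, 0.5, 0.35, 0.06, 0.3, 0.6, 0.07,
                   0.1, 0.8, 0.08),
                 c("A1", "mu1", "s1", "A2", "mu2", "s2", "A3", "mu3", "s3",
                   "A4", "mu4", "s4"))
  fit <- structure(list(theta = th, loss = 0.01, converged = TRUE),
                   class = "ppgbp_gaussfit")
  v <- gaussian_features(fit)
  expect_equal(unname(v["gauss_ai_r"]), 0, tolerance = 1e-12)   # A1 == A2
  expect_equal(unname(v["gauss_rtt"]), 0.4, tolerance = 1e-12)  # mu3 - mu1
  expect_equal(unname(v["gauss_ri_r"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(v["gauss_a4_a1"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(v["gauss_sigma4_a1"]), 0.16, tolerance = 1e-12)
  # area ratio against an independent fine-grid quadrature oracle
  tg <- seq(0, 1, length.out = 4001)
  gs <- 0.5 * exp(-(tg - 0.2)^2 / (2 * 0.05^2)) +
        0.5 * exp(-(tg - 0.35)^2 / (2 * 0.06^2))
  gd <- 0.3 * exp(-(tg - 0.6)^2 / (2 * 0.07^2)) +
        0.1 * exp(-(tg - 0.8)^2 / (2 * 0.08^2))
  tr <- function(y) sum(diff(tg) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(unname(v["gauss_sys_dias"]), tr(gs) / tr(gd), tolerance = 0.01)
  expect_equal(unname(v["gauss_ai"]), max(gs) - 0.3, tolerance = 1e-3)
  # non-converged fits yield all-missing features
  bad <- structure(list(theta = th, loss = Inf, converged = FALSE),
                   class = "ppgbp_gaussfit")
  expect_true(all(is.na(gaussian_features(bad))))
})

test_that("features are invariant to raw amplitude scaling", {
  cfg <- default_config()
  lat <- latent_hemodynamics(10, cfg$cohort)
  lat <- lat[lat$t < 60, ]
  fs <- 100
  ppg <- synthesize_ppg(lat, fs, seed = 3, noise_sd = 0)
  f <- filter_ppg(ppg$x, fs)
  b1 <- segment_beats(f, fs)
  b2 <- segment_beats(3.7 * f, fs)
  k <- 5
  fid1 <- detect_fiducials(b1$zeta[k, ], b1$vpg[k, ], b1$apg[k, ])
  fid2 <- detect_fiducials(b2$zeta[k, ], b2$vpg[k, ], b2$apg[k, ])
  v1 <- morphology_features(b1$zeta[k, ], b1$vpg[k, ], fid1, 170)
  v2 <- morphology_features(b2$zeta[k, ], b2$vpg[k, ], fid2, 170)
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("the assembled feature library has the documented cardinality", {
  fn <- feature_names()
  expect_length(fn$ppg, 61)
  expect_length(fn$ecg, 10)
  expect_length(fn$demo, 6)
  expect_length(unique(c(fn$ppg, fn$ecg, fn$demo)), 77)
})

test_that("PCA basis recovers a planted two-component structure", {
  set.seed(10)
  n <- 120; len <- 100
  u <- seq(0, 1, length.out = len)
  mean_beat <- textbook_beat(len)
  c1 <- sin(2 * pi * u); c2 <- cos(4 * pi * u)
  scores <- cbind(rnorm(n, 0, 1), rnorm(n, 0, 0.5))
  zeta <- matrix(rep(mean_beat, n), n, byrow = TRUE) +
    scores %*% rbind(c1, c2) / sqrt(len)
  beats <- structure(list(zeta = zeta, vpg = zeta, apg = zeta,
                          onset_time = seq_len(n), duration = rep(1, n),
                          sqi = rep(1, n)), class = "ppgbp_beats")
  basis <- fit_pca_basis(beats, sqi_threshold = 0.5, n_comp = 3)
  # the top-2 eigenvectors span the planted space: principal angles < 1 degree
  V <- basis$ppg$vectors[, 1:2]
  B <- qr.Q(qr(cbind(c1, c2)))
  angles <- acos(pmin(svd(crossprod(B, V))$d, 1)) * 180 / pi
  expect_lt(max(angles), 1)
  expect_true(all(diff(basis$ppg$explained) <= 0))
  expect_lte(sum(basis$ppg$explained), 1 + 1e-9)
  # degenerate ensemble of identical beats errors informatively
  same <- structure(list(zeta = matrix(rep(mean_beat, 20), 20, byrow = TRUE),
                         vpg = matrix(0, 20, len), apg = matrix(0, 20, len),
                         onset_time = 1:20, duration = rep(1, 20),
                         sqi = rep(1, 20)), class = "ppgbp_beats")
  expect_error(fit_pca_basis(same, sqi_threshold = 0.5), "covariance")
  expect_error(fit_pca_basis(structure(list(zeta = zeta[1:5, ],
                                            vpg = zeta[1:5, ],
                                            apg = zeta[1:5, ],
                                            onset_time = 1:5,
                                            duration = rep(1, 5),
                                            sqi = rep(1, 5)),
                                       class = "ppgbp_beats")),
               "at least 10")
})

test_that("PCA projections obey the orthonormal-basis identities", {
  set.seed(11)
  n <- 60; len <- 100
  zeta <- matrix(rnorm(n * len, sd = 0.1), n, len) +
    matrix(rep(textbook_beat(len), n), n, byrow = TRUE)
  beats <- structure(list(zeta = zeta, vpg = zeta, apg = zeta,
                          onset_time = seq_len(n), duration = rep(1, n),
                          sqi = rep(1, n)), class = "ppgbp_beats")
  basis <- fit_pca_basis(beats, sqi_threshold = 0.5)
  mu <- basis$ppg$mean
  # the mean beat projects to zero
  p0 <- pca_features(mu, mu, mu, basis)
  expect_lt(max(abs(p0[1:3])), 1e-9)
  # mean + 2 * eigenvector projects to (2, 0, 0)
  e1 <- basis$ppg$vectors[, 1]
  p1 <- pca_features(mu + 2 * e1, mu, mu, basis)
  expect_equal(unname(p1["ppg_pca1"]), 2, tolerance = 1e-9)
  expect_lt(max(abs(p1[c("ppg_pca2", "ppg_pca3")])), 1e-9)
  # arbitrary beat matches the brute-force dot product
  z <- zeta[7, ]
  p <- pca_features(z, z, z, basis)
  expect_equal(unname(p["ppg_pca2"]),
               sum((z - mu) * basis$ppg$vectors[, 2]), tolerance = 1e-9)
})
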
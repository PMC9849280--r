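# Shapley attributions (kernel and tree), the ranking coefficient and
# cross-channel rank agreement.

# brute-force Shapley oracle over all feature coalitions with the
# interventional value function (background-mean replacement)
shap_oracle <- function(predict_fn, x, X_bg) {
  M <- length(x)
  v <- function(S) {
    Xh <- X_bg
    for (j in S) Xh[, j] <- x[j]
    mean(predict_fn(Xh))
  }
  phi <- numeric(M)
  subsets <- function(set) {
    if (!length(set)) return(list(integer()))
    unlist(lapply(0:(2^length(set) - 1), function(mask) {
      list(set[bitwAnd(mask, 2^(seq_along(set) - 1)) > 0])
    }), recursive = FALSE)
  }
  for (j in seq_len(M)) {
    for (S in subsets(setdiff(seq_len(M), j))) {
      w <- factorial(length(S)) * factorial(M - length(S) - 1) / factorial(M)
      phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
    }
  }
  list(phi = phi, phi0 = v(integer()))
}

test_that("kernel SHAP on a linear model equals the closed form", {
  set.seed(1)
  X <- as.data.frame(matrix(rnorm(300 * 4), 300, 4))
  names(X) <- paste0("f", 1:4)
  y <- 2 * X$f1 - 3 * X$f3 + rnorm(300, 0, 0.1)
  m <- fit_lasso_ols(X, y, lambda = 0.05)
  bg <- X[1:60, ]; ex <- X[61:66, ]
  s <- shap_linear(m, bg, ex)
  beta <- setNames(rep(0, 4), names(X))
  beta[m$support] <- m$coef[-1][m$support]
  closed <- sweep(as.matrix(ex), 2, colMeans(bg)) %*% diag(beta)
  expect_lt(max(abs(s$phi - closed)), 1e-6)
  # a row equal to the background mean gets zero attribution
  s0 <- shap_linear(m, bg, rbind(colMeans(bg)))
  expect_lt(max(abs(s0$phi)), 1e-9)
})

test_that("kernel SHAP matches exhaustive enumeration for three features", {
  set.seed(2)
  X <- as.data.frame(matrix(rnorm(80 * 3), 80, 3))
  names(X) <- c("a", "b", "c")
  pf <- function(m) {
    m <- as.data.frame(m)
    m$a * m$b + sin(m$c)            # deliberately non-additive
  }
  bg <- X[1:30, ]; x <- as.numeric(X[40, ])
  s <- shap_kernel(pf, as.matrix(bg), matrix(x, 1))
  oracle <- shap_oracle(pf, x, bg)
  expect_lt(max(abs(s$phi - oracle$phi)), 1e-6)
  expect_equal(s$phi0[1], oracle$phi0, tolerance = 1e-9)
  expect_error(shap_kernel(pf, X[0, ], X[1, , drop = FALSE]), "empty")
})

test_that("sampled kernel SHAP recovers additive models above the exact cap", {
  set.seed(3)
  M <- 15
  X <- as.data.frame(matrix(rnorm(200 * M), 200, M))
  names(X) <- paste0("f", seq_len(M))
  beta <- rnorm(M)
  pf <- function(m) as.matrix(as.data.frame(m)) %*% beta
  bg <- X[1:40, ]; ex <- X[41:43, ]
  s <- shap_kernel(pf, as.matrix(bg), as.matrix(ex), max_exact = 12,
                   n_samples = 600, seed = 5)
  closed <- sweep(as.matrix(ex), 2, colMeans(bg)) %*% diag(beta)
  expect_lt(max(abs(s$phi - closed)), 1e-6)
})

test_that("tree SHAP: a stump attributes only to its split feature", {
  set.seed(4)
  X <- data.frame(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
  y <- 2 * (X$x1 > 0)
  m <- fit_rf(X, y, mtry = 3, n_trees = 40, seed = 6)
  s <- shap_tree(m, X[1:30, ], X[31:40, ])
  used <- unique(unlist(lapply(seq_len(m$rf$num.trees), function(t) {
    ti <- ranger::treeInfo(m$rf, t)
    stats::na.omit(ti$splitvarName)
  })))
  for (j in setdiff(names(X), used)) {
    expect_true(all(s$phi[, j] == 0))        # missingness
  }
})

test_that("tree SHAP equals brute-force enumeration on a small forest", {
  set.seed(5)
  X <- data.frame(u = rnorm(60), v = rnorm(60))
  y <- 1.5 * (X$u > 0) - 0.5 * (X$v > 0.2) + rnorm(60, 0, 0.05)
  m <- fit_rf(X, y, mtry = 2, n_trees = 15, seed = 3)
  bg <- X[1:20, ]; ex <- X[21:26, ]
  s <- shap_tree(m, bg, ex)
  pf <- function(d) predict(m, as.data.frame(d))
  for (i in seq_len(nrow(ex))) {
    oracle <- shap_oracle(pf, as.numeric(ex[i, ]), bg)
    expect_lt(max(abs(s$phi[i, ] - oracle$phi)), 1e-9)
  }
  # base value is the mean background prediction
  expect_equal(s$phi0[1], mean(predict(m, bg)), tolerance = 1e-9)
  # local accuracy on every explained row
  expect_lt(max(abs(s$phi0 + rowSums(s$phi) - predict(m, ex))), 1e-9)
  # schema mismatch is an error
  expect_error(shap_tree(m, bg, data.frame(u = 1)), "lack")
})

test_that("a larger marginal contribution never lowers the attribution", {
  # two-feature toy models differing only in feature 1's contribution
  set.seed(6)
  X <- data.frame(a = rnorm(200), b = rnorm(200))
  bg <- X[1:50, ]
  x <- c(a = 1, b = 1)
  for (gain in c(0.5, 1, 2)) {
    pf <- function(m) { m <- as.data.frame(m); gain * m$a + m$b }
    s <- shap_kernel(pf, as.matrix(bg), matrix(x, 1))
    expect_equal(s$phi[1, 1], gain * (1 - mean(bg$a)), tolerance = 1e-9)
  }
})

test_that("ranking coefficients normalise ranks with average-tie handling", {
  phiA <- matrix(c(3, 3, 1, 1), 2, 2)        # feature 1 always dominant
  colnames(phiA) <- c("big", "small")
  r <- ranking_coefficient(list(phiA, phiA))
  s <- r$summary
  expect_equal(s$median_coef[s$feature == "big"], 1)
  expect_equal(s$median_coef[s$feature == "small"], 0)
  # hand-set magnitudes follow the sort order
  phiB <- rbind(c(0.1, 0.7, 0.4))
  colnames(phiB) <- c("lo", "hi", "mid")
  rb <- ranking_coefficient(list(phiB))
  expect_equal(rb$per_fold$rank[rb$per_fold$feature == "hi"], 1)
  expect_equal(rb$per_fold$coefficient,
               (3 - rb$per_fold$rank) / 2, tolerance = 1e-12)
  # all-equal attributions tie at coefficient one half
  phiC <- rbind(c(2, 2, 2))
  colnames(phiC) <- c("x", "y", "z")
  rc <- ranking_coefficient(list(phiC))
  expect_true(all(rc$per_fold$coefficient == 0.5))
})

test_that("rank agreement reproduces Kendall pair counting", {
  mk <- function(coefs) {
    structure(list(summary = data.frame(feature = names(coefs),
                                        median_coef = unname(coefs),
                                        min_coef = 0, max_coef = 1)),
              class = "ppgbp_ranking")
  }
  a <- mk(c(f1 = 1, f2 = 0.8, f3 = 0.5, f4 = 0.1))
  expect_equal(rank_agreement(a, a)$tau, 1)
  rev_a <- mk(c(f1 = 0.1, f2 = 0.5, f3 = 0.8, f4 = 1))
  expect_equal(rank_agreement(a, rev_a)$tau, -1)
  b <- mk(c(f1 = 0.9, f2 = 0.2, f3 = 0.6, f4 = 0.3))
  # O(n^2) concordant/discordant pair oracle (no ties)
  av <- c(1, 0.8, 0.5, 0.1); bv <- c(0.9, 0.2, 0.6, 0.3)
  conc <- disc <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    s <- sign(av[i] - av[j]) * sign(bv[i] - bv[j])
    if (s > 0) conc <- conc + 1 else disc <- disc + 1
  }
  expect_equal(rank_agreement(a, b)$tau, (conc - disc) / choose(4, 2),
               tolerance = 1e-12)
  c_disjoint <- mk(c(g1 = 1, g2 = 0))
  expect_error(rank_agreement(a, c_disjoint), "share no features")
})
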
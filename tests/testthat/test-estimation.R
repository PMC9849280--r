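# LASSO+OLS and random-forest estimators, nested LOSOCV, the zero-change
# baseline and paired model comparisons.

test_that("zero penalty reduces LASSO+OLS to plain OLS", {
  set.seed(1)
  X <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
  names(X) <- paste0("f", 1:4)
  y <- 1 + 2 * X$f1 - X$f2 + rnorm(200, 0, 0.3)
  m <- fit_lasso_ols(X, y, lambda = 0)
  ols <- lm(y ~ ., data = cbind(y = y, X))
  expect_lt(max(abs(coef(m$fit) - coef(ols))), 1e-6)
})

test_that("a huge penalty empties the support and predicts the mean", {
  set.seed(2)
  X <- as.data.frame(matrix(rnorm(100 * 3), 100, 3))
  names(X) <- paste0("f", 1:3)
  y <- X$f1 + rnorm(100, 0, 0.1)
  m <- fit_lasso_ols(X, y, lambda = 1e6)
  expect_true(m$empty_support)
  expect_equal(predict(m, X), rep(mean(y), 100), tolerance = 1e-12)
})

test_that("LASSO recovers a planted single-feature support", {
  set.seed(3)
  n <- 500
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- 3 * X$x1 + rnorm(n)
  m <- fit_lasso_ols(X, y, lambda = 0.3)
  expect_identical(m$support, "x1")
  expect_gt(unname(m$coef["x1"]), 2.5)
  expect_lt(unname(m$coef["x1"]), 3.5)
})

test_that("forest predictions respect tree-mean bounds and constants", {
  set.seed(4)
  X <- data.frame(x = rnorm(150))
  yconst <- rep(2.5, 150)
  mc <- fit_rf(X, yconst, mtry = 1, n_trees = 30, seed = 1)
  expect_equal(predict(mc, X), yconst, tolerance = 1e-12)
  y <- X$x + rnorm(150, 0, 0.2)
  m <- fit_rf(X, y, mtry = 1, n_trees = 50, seed = 1)
  p <- predict(m, data.frame(x = c(-50, 0, 50)))
  expect_true(all(p >= min(y) & p <= max(y)))
  # determinism given the seed
  m2 <- fit_rf(X, y, mtry = 1, n_trees = 50, seed = 1)
  expect_identical(predict(m, X), predict(m2, X))
})

test_that("a forest learns a step function", {
  set.seed(5)
  n <- 1000
  X <- data.frame(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  y <- as.numeric(X$x1 > 0)
  tr <- sample(n, 700)
  m <- fit_rf(X[tr, ], y[tr], mtry = 2, n_trees = 100, seed = 2)
  rmse <- sqrt(mean((predict(m, X[-tr, ]) - y[-tr])^2))
  expect_lt(rmse, 0.2)
})

test_that("nested LOSOCV counts folds, keeps participants disjoint and scores honestly", {
  ds <- make_linear_dataset()
  cv <- nested_losocv(ds, "lasso_ols", channel = "sbp",
                      feature_set = "ppg+ecg", seed = 7)
  parts <- unique(ds$participant_id)
  expect_equal(length(cv$folds), length(parts))
  for (f in cv$folds) {
    expect_false(f$test_participant %in% f$train_participants)
    expect_setequal(c(f$test_participant, f$train_participants), parts)
    # metrics recompute exactly from stored predictions
    expect_equal(unname(f$metrics["rmse"]),
                 sqrt(mean((f$predictions - f$reference)^2)),
                 tolerance = 1e-12)
    expect_equal(unname(f$metrics["mae"]),
                 mean(abs(f$predictions - f$reference)), tolerance = 1e-12)
    expect_equal(unname(f$metrics["rho_p"]),
                 cor(f$predictions, f$reference), tolerance = 1e-12)
  }
  # evaluation rows are the unaugmented rows of the held-out participant
  n_eval <- sum(ds$participant_id == cv$folds[[1]]$test_participant &
                  !ds$augmented)
  expect_length(cv$folds[[1]]$predictions, n_eval)
  # a planted linear signal is recovered with high per-fold correlation
  expect_gte(median(cv$metrics$rho_p), 0.9)
})

test_that("a single-element hyperparameter grid is used in every fold", {
  ds <- make_linear_dataset(n_parts = 4, rows_per = 20)
  cv <- nested_losocv(ds, "lasso_ols", hyper_grid = 0.123, seed = 1)
  expect_true(all(cv$metrics$hyper == 0.123))
  expect_error(nested_losocv(make_linear_dataset(n_parts = 2), "lasso_ols"),
               "at least 3")
})

test_that("the zero-change baseline reports RMS reference changes", {
  ds <- make_linear_dataset(n_parts = 3, rows_per = 8)
  # plant known values for one participant (even unaugmented row count)
  sel <- ds$participant_id == "S01" & !ds$augmented
  stopifnot(sum(sel) %% 2 == 0)
  ds$y$dsbp[sel] <- rep(c(3, -4), length.out = sum(sel))
  b <- baseline_reference(ds, "sbp")
  row <- b[b$participant == "S01", ]
  expect_equal(row$rmse, sqrt(mean(c(3, -4)^2)), tolerance = 1e-9)
  expect_equal(row$mae, 3.5, tolerance = 1e-9)
  expect_true(is.na(row$rho_p))               # undefined, never zero
})

test_that("Wilcoxon comparison matches exhaustive sign-pattern enumeration", {
  a <- c(10.2, 8.1, 9.5, 12.3, 7.7, 11.0)
  b <- a - c(1.3, 0.8, 2.1, 0.4, 1.7, 0.9)   # all positive, distinct diffs
  res <- compare_models(list(A = a, B = b))
  d <- a - b
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  # brute force over all 2^6 sign assignments of the ranked differences
  n <- length(d)
  stats_all <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_exact <- mean(stats_all >= W) + mean(stats_all <= (sum(r) - W))
  expect_equal(res$p, min(1, p_exact), tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment follows the step-up arithmetic", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.04), tolerance = 1e-12)
  # adjusted p never drop below raw p in the comparison table
  set.seed(8)
  m <- list(A = rnorm(8, 10), B = rnorm(8, 11), C = rnorm(8, 12))
  tab <- compare_models(m)
  expect_true(all(tab$p_adj >= tab$p - 1e-12))
})

test_that("identical metric vectors compare at p = 1 with a warning", {
  x <- c(1, 2, 3, 4)
  expect_warning(res <- compare_models(list(A = x, B = x)), "zero")
  expect_equal(res$p, 1)
})
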
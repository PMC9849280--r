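# Regression models for dBP and their evaluation: LASSO-selected OLS and a
# random forest, tuned and evaluated in nested leave-one-subject-out
# cross-validation (the inner loop selects the hyperparameter minimising
# mean RMSE; the held-out participant is scored on unaugmented rows only),
# plus the zero-change baseline reference and paired Wilcoxon / BH model
# comparisons.

#' Fit a LASSO-selected OLS model
#'
#' LASSO (L1-penalised least squares at the given `lambda`) selects the
#' support; ordinary least squares refitted on the selected features
#' provides the final coefficients. Features are standardized internally.
#' An empty support yields an intercept-only model (predicting the training
#' mean), flagged `empty_support`.
#'
#' @param X data.frame or matrix of features.
#' @param y numeric response.
#' @param lambda L1 penalty weight (>= 0).
#' @return Object of class `ppgbp_lasso_ols` with `support`, `coef`,
#'   `lambda`, `empty_support`.
#' @export
fit_lasso_ols <- function(X, y, lambda) {
  X <- as.matrix(X)
  stopifnot(lambda >= 0)
  las <- glmnet::glmnet(X, y, alpha = 1, lambda = lambda,
                        standardize = TRUE, thresh = 1e-12)
  b <- as.numeric(coef(las))[-1]
  support <- colnames(X)[b != 0]
  if (!length(support)) {
    fit <- NULL
    cf <- c(`(Intercept)` = mean(y))
  } else {
    df <- data.frame(y = y, X[, support, drop = FALSE], check.names = FALSE)
    fit <- lm(y ~ ., data = df)
    cf <- coef(fit)
  }
  structure(list(support = support, coef = cf, fit = fit, lambda = lambda,
                 empty_support = !length(support),
                 feature_names = colnames(X)),
            class = "ppgbp_lasso_ols")
}

#' @export
predict.ppgbp_lasso_ols <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata, check.names = FALSE)
  if (object$empty_support) {
    return(rep(unname(object$coef[1]), nrow(newdata)))
  }
  as.numeric(predict(object$fit, newdata[object$support]))
}

# data-driven lambda grid: n_lambda log-spaced values from the smallest
# penalty zeroing all coefficients down to lambda_max * min_ratio
.lambda_grid <- function(X, y, n_lambda = 30L, min_ratio = 1e-4) {
  X <- as.matrix(X)
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / length(y)
  10^seq(log10(lmax), log10(lmax * min_ratio), length.out = n_lambda)
}

#' Fit a random-forest regressor
#'
#' Bootstrap-per-tree regression forest with squared-error splitting and
#' mean-over-trees prediction; deterministic given the seed.
#'
#' @param X data.frame of features.
#' @param y numeric response.
#' @param mtry features tried per split (1..ncol(X)).
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return Object of class `ppgbp_rf` wrapping the fitted forest.
#' @export
fit_rf <- function(X, y, mtry, n_trees = 300L, seed = 1L) {
  X <- as.data.frame(X, check.names = FALSE)
  stopifnot(mtry >= 1, mtry <= ncol(X))
  rf <- ranger::ranger(
    x = X, y = y, num.trees = n_trees, mtry = mtry,
    splitrule = "variance", seed = seed, num.threads = 1
  )
  structure(list(rf = rf, feature_names = names(X)), class = "ppgbp_rf")
}

#' @export
predict.ppgbp_rf <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata, check.names = FALSE)
  as.numeric(predict(object$rf, data = newdata[object$feature_names],
                     num.threads = 1)$predictions)
}

# metrics for one fold
.fold_metrics <- function(pred, ref) {
  rho <- if (length(ref) >= 3 && sd(ref) > 0 && sd(pred) > 0) {
    cor(pred, ref)
  } else NA_real_
  c(rho_p = rho, rmse = sqrt(mean((pred - ref)^2)),
    mae = mean(abs(pred - ref)))
}

#' Select the feature columns for a model feature set
#'
#' @param dataset a `ppgbp_dataset` (see [assemble_dataset()]).
#' @param feature_set one of "ppg", "ecg", "ppg+ecg", "pat".
#' @return Character vector: dynamic columns of the set (post collinearity
#'   removal) plus the demographic columns.
#' @export
feature_set_columns <- function(dataset, feature_set) {
  dyn <- dataset$feature_names
  sel <- switch(feature_set,
    "ppg" = setdiff(dyn, c(dataset$ecg_features, "pat")),
    "ecg" = intersect(dyn, dataset$ecg_features),
    "ppg+ecg" = setdiff(dyn, "pat"),
    "pat" = intersect(dyn, "pat"),
    stop("unknown feature set: ", feature_set)
  )
  c(sel, dataset$demo_names)
}

#' Nested leave-one-subject-out cross-validation
#'
#' The outer loop holds out each participant in turn; the inner loop (a
#' LOSOCV over the remaining participants) selects the hyperparameter
#' (lambda for LASSO+OLS, mtry for the forest) minimising mean inner RMSE.
#' Training and inner validation use augmented rows; all evaluation (inner
#' scoring and the held-out fold) uses unaugmented rows only.
#'
#' @param dataset a `ppgbp_dataset`.
#' @param model_kind "lasso_ols" or "rf".
#' @param channel "sbp", "map" or "dbp".
#' @param feature_set "ppg", "ecg", "ppg+ecg" or "pat".
#' @param hyper_grid optional hyperparameter grid; data-driven defaults.
#' @param n_trees forest size.
#' @param seed master seed, fanned out per fold.
#' @return list of class `ppgbp_cv`: per-fold results (test participant,
#'   predictions, reference, metrics, chosen hyperparameter, fitted model)
#'   and a `metrics` data.frame.
#' @export
nested_losocv <- function(dataset, model_kind = c("lasso_ols", "rf"),
                          channel = "sbp", feature_set = "ppg+ecg",
                          hyper_grid = NULL, n_trees = 300L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  parts <- unique(dataset$participant_id)
  if (length(parts) < 3) stop("need at least 3 participants")
  cols <- feature_set_columns(dataset, feature_set)
  ycol <- paste0("d", channel)
  X <- dataset$X[cols]
  y <- dataset$y[[ycol]]
  pid <- dataset$participant_id
  aug <- dataset$augmented
  fold_seeds <- {
    set.seed(seed %% .Machine$integer.max)
    sample.int(2^30, length(parts))
  }
  run_model <- function(idx_tr, hyper, fold_seed) {
    if (model_kind == "lasso_ols") {
      fit_lasso_ols(X[idx_tr, , drop = FALSE], y[idx_tr], lambda = hyper)
    } else {
      fit_rf(X[idx_tr, , drop = FALSE], y[idx_tr], mtry = hyper,
             n_trees = n_trees, seed = fold_seed)
    }
  }
  if (is.null(hyper_grid)) {
    hyper_grid <- if (model_kind == "lasso_ols") {
      .lambda_grid(X, y)
    } else {
      unique(pmax(1, pmin(ncol(X), ceiling(ncol(X) / c(10, 3, 2, 1)))))
    }
  }
  folds <- list()
  for (fi in seq_along(parts)) {
    test_p <- parts[fi]
    idx_test <- which(pid == test_p & !aug)
    if (!length(idx_test)) {
      warning("participant ", test_p, " has no evaluable rows; fold skipped")
      next
    }
    idx_train <- which(pid != test_p)
    inner_parts <- setdiff(parts, test_p)
    if (length(hyper_grid) > 1) {
      inner_rmse <- vapply(hyper_grid, function(h) {
        errs <- vapply(inner_parts, function(ip) {
          itr <- which(pid != test_p & pid != ip)
          ite <- which(pid == ip & !aug)
          if (!length(ite)) return(NA_real_)
          m <- run_model(itr, h, fold_seeds[fi])
          sqrt(mean((predict(m, X[ite, , drop = FALSE]) - y[ite])^2))
        }, numeric(1))
        mean(errs, na.rm = TRUE)
      }, numeric(1))
      best <- hyper_grid[which.min(inner_rmse)]
    } else {
      best <- hyper_grid[1]
    }
    model <- run_model(idx_train, best, fold_seeds[fi])
    pred <- predict(model, X[idx_test, , drop = FALSE])
    folds[[length(folds) + 1L]] <- list(
      test_participant = test_p,
      predictions = pred, reference = y[idx_test],
      t = dataset$t[idx_test],
      metrics = .fold_metrics(pred, y[idx_test]),
      hyper = best, model = model,
      train_participants = unique(pid[idx_train])
    )
  }
  metrics <- do.call(rbind, lapply(folds, function(f) {
    data.frame(participant = f$test_participant, t(f$metrics),
               hyper = f$hyper)
  }))
  structure(list(folds = folds, metrics = metrics, model_kind = model_kind,
                 channel = channel, feature_set = feature_set,
                 columns = cols),
            class = "ppgbp_cv")
}

#' Zero-change baseline reference
#'
#' Assumes dBP = 0 everywhere; per participant the RMSE is the root mean
#' square of the reference changes and the MAE their mean absolute value.
#' The correlation is undefined for a constant prediction and reported
#' missing.
#'
#' @param dataset a `ppgbp_dataset`.
#' @param channel BP channel.
#' @return data.frame of per-participant metrics (rho_p all `NA`).
#' @export
baseline_reference <- function(dataset, channel = "sbp") {
  ycol <- paste0("d", channel)
  keep <- !dataset$augmented
  y <- dataset$y[[ycol]][keep]
  pid <- dataset$participant_id[keep]
  do.call(rbind, lapply(unique(pid), function(p) {
    yp <- y[pid == p]
    data.frame(participant = p, rho_p = NA_real_,
               rmse = sqrt(mean(yp^2)), mae = mean(abs(yp)))
  }))
}

#' Paired model comparisons with multiplicity adjustment
#'
#' Two-tailed Wilcoxon signed-rank tests on per-participant metric pairs
#' (exact distribution for n <= 25 without ties, normal approximation
#' otherwise), with Benjamini-Hochberg adjustment across the family of
#' comparisons.
#'
#' @param metric_list named list of per-participant metric vectors, aligned
#'   by participant.
#' @return data.frame: model_a, model_b, statistic, p, p_adj.
#' @export
compare_models <- function(metric_list) {
  nm <- names(metric_list)
  stopifnot(length(nm) >= 2)
  pairs <- utils::combn(nm, 2)
  out <- apply(pairs, 2, function(pr) {
    a <- metric_list[[pr[1]]]; b <- metric_list[[pr[2]]]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    if (all(a == b)) {
      warning("all paired differences are zero; p = 1")
      return(data.frame(model_a = pr[1], model_b = pr[2],
                        statistic = NA_real_, p = 1))
    }
    wt <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = length(a) <= 25,
                  correct = FALSE)
    )
    data.frame(model_a = pr[1], model_b = pr[2],
               statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, out)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
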
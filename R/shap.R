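# Shapley-value feature attributions and the cross-fold ranking
# coefficient. Attributions use the interventional value function: the
# worth of a coalition S at a point x is the mean model output over the
# background set with the features in S taken from x and the rest from the
# background row. KernelSHAP enumerates all coalitions exactly for small
# feature counts and otherwise solves the Shapley-kernel-weighted
# regression on sampled coalitions; for tree ensembles an exact per-leaf
# algorithm (src/treeshap.cpp) is used.

# v(S) for a batch of coalition vectors (rows of Z) at point x:
# mean over background rows of f(hybrid). Returns one value per coalition.
.coalition_values <- function(predict_fn, x, X_bg, Z) {
  nb <- nrow(X_bg)
  M <- length(x)
  big <- X_bg[rep(seq_len(nb), times = nrow(Z)), , drop = FALSE]
  for (ci in seq_len(nrow(Z))) {
    on <- which(Z[ci, ] == 1)
    if (length(on)) {
      rows <- (ci - 1) * nb + seq_len(nb)
      for (j in on) big[rows, j] <- x[j]
    }
  }
  pred <- predict_fn(big)
  colMeans(matrix(pred, nrow = nb))
}

# exact Shapley values by full coalition enumeration (M <= ~12)
.shap_exact <- function(predict_fn, x, X_bg) {
  M <- length(x)
  n_co <- 2^M
  Z <- matrix(0L, n_co, M)
  for (j in seq_len(M)) {
    Z[, j] <- bitwAnd(seq_len(n_co) - 1L, bitwShiftL(1L, j - 1L)) > 0
  }
  v <- .coalition_values(predict_fn, x, X_bg, Z)
  sizes <- rowSums(Z)
  w_size <- factorial(seq_len(M) - 1) * factorial(M - seq_len(M)) /
    factorial(M)  # weight for |S| = s - 1 when adding the j-th player
  phi <- numeric(M)
  for (j in seq_len(M)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(seq_len(n_co) - 1L, bit) == 0)
    with_j <- without + bit
    s <- sizes[without]
    phi[j] <- sum(w_size[s + 1] * (v[with_j] - v[without]))
  }
  list(phi = phi, phi0 = v[1])
}

# sampled KernelSHAP: Shapley-kernel-weighted regression with the two
# boundary coalitions imposed as constraints
.shap_sampled <- function(predict_fn, x, X_bg, n_samples) {
  M <- length(x)
  sz_w <- (M - 1) / (seq_len(M - 1) * (M - seq_len(M - 1)))
  sizes <- sample(seq_len(M - 1), n_samples, replace = TRUE,
                  prob = sz_w / sum(sz_w))
  Z <- t(vapply(sizes, function(s) {
    z <- integer(M); z[sample.int(M, s)] <- 1L; z
  }, integer(M)))
  Z <- unique(Z)
  v <- .coalition_values(predict_fn, x, X_bg,
                         rbind(matrix(0L, 1, M), matrix(1L, 1, M), Z))
  v0 <- v[1]; v1 <- v[2]; v <- v[-(1:2)]
  s <- rowSums(Z)
  w <- (M - 1) / (choose(M, s) * s * (M - s))
  delta <- v1 - v0
  # impose sum(phi) = delta by eliminating the last coefficient
  A <- sweep(Z[, -M, drop = FALSE], 1, Z[, M])
  b <- v - v0 - Z[, M] * delta
  WA <- A * sqrt(w)
  Wb <- b * sqrt(w)
  phi_head <- tryCatch(qr.solve(WA, Wb), error = function(e) {
    as.numeric(stats::lm.fit(WA, Wb)$coefficients)
  })
  phi_head[is.na(phi_head)] <- 0
  phi <- c(phi_head, delta - sum(phi_head))
  list(phi = phi, phi0 = v0)
}

#' Kernel SHAP attributions for an arbitrary regression model
#'
#' @param predict_fn function mapping a feature matrix/data.frame to
#'   predictions.
#' @param X_bg background rows (the training-set reference distribution).
#' @param X_explain rows to explain.
#' @param max_exact enumerate all coalitions exactly when the feature count
#'   is at most this.
#' @param n_samples sampled coalitions otherwise.
#' @param seed RNG seed for coalition sampling.
#' @return list of class `ppgbp_shap`: `phi` (rows x features), `phi0`
#'   (expected model value over the background per row — identical across
#'   rows), `feature_names`.
#' @export
shap_kernel <- function(predict_fn, X_bg, X_explain, max_exact = 12L,
                        n_samples = 2048L, seed = 1L) {
  X_bg <- as.matrix(X_bg); X_explain <- as.matrix(X_explain)
  if (!nrow(X_bg)) stop("background set is empty")
  M <- ncol(X_explain)
  set.seed(seed %% .Machine$integer.max)
  res <- lapply(seq_len(nrow(X_explain)), function(i) {
    x <- X_explain[i, ]
    if (M <= max_exact) {
      .shap_exact(predict_fn, x, X_bg)
    } else {
      .shap_sampled(predict_fn, x, X_bg, n_samples)
    }
  })
  phi <- do.call(rbind, lapply(res, `[[`, "phi"))
  colnames(phi) <- colnames(X_explain)
  structure(list(phi = phi, phi0 = vapply(res, `[[`, numeric(1), "phi0"),
                 feature_names = colnames(X_explain)),
            class = "ppgbp_shap")
}

#' SHAP attributions for a LASSO+OLS (linear) model
#'
#' Kernel SHAP on the fitted linear model. With the interventional value
#' function this equals the closed form
#' `phi_j = beta_j * (x_j - mean(background_j))`.
#'
#' @param model a `ppgbp_lasso_ols`.
#' @param X_bg,X_explain background and explained rows (data.frames with
#'   the training columns).
#' @param ... passed to [shap_kernel()].
#' @export
shap_linear <- function(model, X_bg, X_explain, ...) {
  cols <- model$feature_names
  pf <- function(m) {
    predict(model, as.data.frame(m, check.names = FALSE))
  }
  shap_kernel(pf, as.matrix(X_bg[, cols, drop = FALSE]),
              as.matrix(X_explain[, cols, drop = FALSE]), ...)
}

# ranger forest -> list of flat node tables for the C++ kernel
.forest_tables <- function(model) {
  rf <- model$rf
  lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    terminal <- ti$terminal
    list(left = as.integer(ifelse(terminal, -1L, ti$leftChild)),
         right = as.integer(ifelse(terminal, -1L, ti$rightChild)),
         splitvar = as.integer(ifelse(terminal, -1L, ti$splitvarID)),
         splitval = as.numeric(ifelse(terminal, 0, ti$splitval)),
         pred = as.numeric(ifelse(terminal, ti$prediction, 0)))
  })
}

#' Exact interventional SHAP attributions for a random forest
#'
#' Per background row and tree, coalition worths are piecewise constant on
#' leaf "cubes", so each leaf's Shapley contribution has a closed form in
#' the counts of foreground- and background-constrained path features; the
#' algorithm enumerates leaves once per (row, background, tree). Satisfies
#' local accuracy exactly: `phi0 + sum(phi)` equals the forest prediction.
#'
#' @param model a `ppgbp_rf`.
#' @param X_bg,X_explain background and explained rows.
#' @return A `ppgbp_shap`.
#' @export
shap_tree <- function(model, X_bg, X_explain) {
  cols <- model$feature_names
  miss <- setdiff(cols, colnames(as.data.frame(X_explain)))
  if (length(miss)) {
    stop("explained rows lack training features: ", paste(miss, collapse = ", "))
  }
  Xe <- as.matrix(as.data.frame(X_explain)[, cols, drop = FALSE])
  Xb <- as.matrix(as.data.frame(X_bg)[, cols, drop = FALSE])
  res <- .tree_shap_cpp(.forest_tables(model), Xe, Xb)
  phi <- res$phi
  colnames(phi) <- cols
  structure(list(phi = phi, phi0 = as.numeric(res$phi0),
                 feature_names = cols),
            class = "ppgbp_shap")
}

#' Cross-fold SHAP ranking coefficient
#'
#' Within each fold, features are ranked by their mean absolute SHAP value
#' (rank 1 best, ties receive average ranks) and the rank is normalised to
#' a coefficient `(M - rank) / (M - 1)` in \[0, 1\] (1 = most important).
#' Medians and ranges are reported across folds.
#'
#' @param attributions list with one `ppgbp_shap` (or phi matrix) per fold.
#' @return list of class `ppgbp_ranking`: `per_fold` (long data.frame) and
#'   `summary` (per-feature median/min/max coefficient, ordered).
#' @export
ranking_coefficient <- function(attributions) {
  stopifnot(length(attributions) >= 1)
  per_fold <- do.call(rbind, lapply(seq_along(attributions), function(fi) {
    a <- attributions[[fi]]
    phi <- if (inherits(a, "ppgbp_shap")) a$phi else as.matrix(a)
    imp <- colMeans(abs(phi))
    M <- length(imp)
    rk <- rank(-imp, ties.method = "average")
    coefv <- if (M > 1) (M - rk) / (M - 1) else rep(1, M)
    data.frame(fold = fi, feature = names(imp), mean_abs_phi = unname(imp),
               rank = unname(rk), coefficient = unname(coefv))
  }))
  summ <- do.call(rbind, lapply(split(per_fold, per_fold$feature),
                                function(d) {
    data.frame(feature = d$feature[1],
               median_coef = median(d$coefficient),
               min_coef = min(d$coefficient), max_coef = max(d$coefficient))
  }))
  summ <- summ[order(-summ$median_coef), ]
  rownames(summ) <- NULL
  structure(list(per_fold = per_fold, summary = summ),
            class = "ppgbp_ranking")
}

#' Rank agreement between BP channels
#'
#' Kendall's tau-b between the median ranking coefficients of each pair of
#' reports, over their common features.
#'
#' @param ... two or more `ppgbp_ranking` objects (optionally named).
#' @return data.frame of pairwise tau values.
#' @export
rank_agreement <- function(...) {
  reports <- list(...)
  nm <- names(reports)
  if (is.null(nm) || any(nm == "")) nm <- paste0("report", seq_along(reports))
  stopifnot(length(reports) >= 2)
  getcoef <- function(r) {
    s <- r$summary
    setNames(s$median_coef, s$feature)
  }
  pairs <- utils::combn(seq_along(reports), 2)
  out <- apply(pairs, 2, function(pr) {
    a <- getcoef(reports[[pr[1]]]); b <- getcoef(reports[[pr[2]]])
    common <- intersect(names(a), names(b))
    if (!length(common)) stop("reports share no features")
    data.frame(report_a = nm[pr[1]], report_b = nm[pr[2]],
               tau = cor(a[common], b[common], method = "kendall"))
  })
  do.call(rbind, out)
}
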
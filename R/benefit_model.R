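# Benefit model: label winsorization, Boruta shadow-feature selection with
# path-attribution importances, randomized hyperparameter search over the
# boosted-tree grid with early stopping, and name-bound prediction.

#' Winsorize individualized log-HR labels
#'
#' Clips labels at their own 2.5th/97.5th percentiles (linear-interpolation
#' convention) before regression, recording the bounds. Idempotent.
#'
#' Because clipping moves probability mass onto the bounds, re-estimating
#' percentiles on already-clipped labels would shift them inward; passing the
#' recorded `bounds` back in freezes the transform and makes it idempotent.
#'
#' @param labels a `benefit_labels` data frame (or numeric vector).
#' @param bounds optional frozen `(lower, upper)` bounds; when `NULL` the
#'   2.5/97.5 percentiles of `labels` are used and recorded.
#' @return list with `labels` (same shape as input, clipped) and `bounds`.
#' @export
winsorize_labels <- function(labels, bounds = NULL) {
  v <- if (is.data.frame(labels)) labels$loghr else as.numeric(labels)
  ok <- !is.na(v)
  if (sum(ok) < 20) stopf("need >= 20 labels to winsorize")
  b <- if (is.null(bounds)) unname(quantile(v[ok], WINSOR_PROBS, type = 7))
       else as.numeric(bounds)
  v[ok] <- pmin(pmax(v[ok], b[1]), b[2])
  if (is.data.frame(labels)) labels$loghr <- v else labels <- v
  list(labels = labels, bounds = b)
}

#' Boruta selection with shadow features and path-attribution importances
#'
#' For `n_iter` (default 20) iterations: each feature is permuted into a
#' shadow copy, a boosted regressor is fitted on the concatenated
#' `[original | shadow]` matrix, mean absolute path attributions are
#' computed, and a feature scores a hit when its importance exceeds the
#' maximum shadow importance. Features whose hit counts are significantly
#' above the Binomial(n_iter, 0.5) null (two-sided binomial test at
#' `alpha`) are selected. Deterministic given `seed`.
#'
#' @param X numeric feature matrix (named columns, >= 2 features, >= 50 rows).
#' @param y numeric labels.
#' @param seed integer seed.
#' @param n_iter Boruta iterations (20).
#' @param alpha binomial-test significance threshold (0.05).
#' @param nrounds,eta,max_depth booster settings for the selection fits.
#' @return object of class `selection_report`: `selected`, `n_iterations`,
#'   `hit_counts`, `shadow_max_importance`, `p_values`.
#' @export
boruta_shap_select <- function(X, y, seed = 1L, n_iter = 20L, alpha = 0.05,
                               nrounds = 50L, eta = 0.1, max_depth = 5L) {
  stopifnot(is.matrix(X) || is.data.frame(X))
  X <- as.matrix(X)
  if (ncol(X) < 2) stopf("need >= 2 candidate features")
  if (nrow(X) < 50) stopf("need >= 50 rows for selection")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  p <- ncol(X)
  hits <- setNames(integer(p), colnames(X))
  shadow_max <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    shadow <- with_seed(stage_seed(seed, "shadow", it), {
      apply(X, 2, sample)
    })
    colnames(shadow) <- paste0(".shadow.", colnames(X))
    Xs <- cbind(X, shadow)
    fit <- pt_boost(Xs, y, nrounds = nrounds, eta = eta,
                    max_depth = max_depth, subsample = 1,
                    seed = stage_seed(seed, "boruta_fit", it))
    imp <- pt_boost_importance(fit, Xs)
    thr <- max(imp[colnames(shadow)])
    shadow_max[it] <- thr
    hits <- hits + as.integer(imp[colnames(X)] > thr)
  }
  pv <- vapply(hits, function(h)
    binom.test(h, n_iter, 0.5, alternative = "two.sided")$p.value, numeric(1))
  selected <- names(hits)[pv < alpha & hits > n_iter / 2]
  structure(list(selected = selected, n_iterations = as.integer(n_iter),
                 hit_counts = hits, shadow_max_importance = shadow_max,
                 p_values = pv),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d/%d features selected over %d iterations\n",
              length(x$selected), length(x$hit_counts), x$n_iterations))
  if (length(x$selected))
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# The stated hyperparameter grid. `trees` doubles as the maximum number of
# boosting rounds for that draw (early stopping may end sooner).
benefit_grid <- function() {
  list(eta = c(0.01, 0.05, 0.10, 0.15),
       max_depth = c(3L, 5L, 6L, 10L, 15L, 20L),
       subsample = seq(0.5, 1.0, by = 0.1),
       colsample_bytree = seq(0.4, 1.0, by = 0.1),
       colsample_bylevel = seq(0.4, 1.0, by = 0.1),
       trees = c(100L, 500L, 1000L))
}

sample_grid <- function(n_draws, seed) {
  grid <- benefit_grid()
  sizes <- vapply(grid, length, integer(1))
  total <- prod(sizes)
  picks <- with_seed(seed, sample(total, min(n_draws, total)))
  lapply(picks, function(k) {
    k <- k - 1
    out <- list()
    for (nm in names(grid)) {
      out[[nm]] <- grid[[nm]][(k %% sizes[[nm]]) + 1]
      k <- k %/% sizes[[nm]]
    }
    out
  })
}

#' Fit the boosted benefit regressor with randomized grid search
#'
#' Inner 80/20 train/validation split, `n_draws` (default 25) distinct
#' random draws from the stated hyperparameter grid (learning rate, tree
#' depth, row subsample, per-tree and per-level feature fractions, tree
#' count), each trained with early stopping (patience 20) on validation
#' RMSE; the best draw is refit on all rows at its best iteration count.
#'
#' @param X numeric feature matrix (named columns; typically the
#'   Boruta-selected subset).
#' @param y numeric labels (already winsorized).
#' @param seed integer seed.
#' @param n_draws grid draws (25).
#' @param selection optional [boruta_shap_select()] report to carry along.
#' @param label_bounds optional winsorization bounds to record.
#' @return object of class `benefit_model`.
#' @export
fit_benefit_model <- function(X, y, seed = 1L, n_draws = 25L,
                              selection = NULL, label_bounds = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (nrow(X) < 50) stopf("need >= 50 rows to fit the benefit model")
  n <- nrow(X)
  if (var(y) <= 0) {
    model <- list(constant = y[1])
    return(structure(list(selection = selection, booster = NULL,
                          constant = y[1], best_params = NULL,
                          train_rmse = 0, valid_rmse = 0,
                          label_bounds = label_bounds,
                          feature_names = colnames(X)),
                     class = "benefit_model"))
  }
  idx <- with_seed(stage_seed(seed, "inner_split"), sample.int(n))
  n_tr <- floor(0.8 * n)
  tr <- idx[seq_len(n_tr)]
  va <- idx[(n_tr + 1L):n]
  draws <- sample_grid(n_draws, stage_seed(seed, "grid"))
  best <- NULL
  best_rmse <- Inf
  for (k in seq_along(draws)) {
    par <- draws[[k]]
    fit <- pt_boost(X[tr, , drop = FALSE], y[tr],
                    nrounds = min(par$trees, 1000L), eta = par$eta,
                    max_depth = par$max_depth, subsample = par$subsample,
                    colsample_bytree = par$colsample_bytree,
                    colsample_bylevel = par$colsample_bylevel,
                    Xval = X[va, , drop = FALSE], yval = y[va],
                    early_stopping_rounds = 20L,
                    seed = stage_seed(seed, "grid_fit", k))
    if (fit$best_valid_rmse < best_rmse) {
      best_rmse <- fit$best_valid_rmse
      best <- list(params = par, best_iter = fit$best_iter)
    }
  }
  final <- pt_boost(X, y, nrounds = max(best$best_iter, 1L),
                    eta = best$params$eta, max_depth = best$params$max_depth,
                    subsample = best$params$subsample,
                    colsample_bytree = best$params$colsample_bytree,
                    colsample_bylevel = best$params$colsample_bylevel,
                    seed = stage_seed(seed, "final_fit"))
  structure(list(selection = selection, booster = final,
                 best_params = c(best$params, best_iter = best$best_iter),
                 train_rmse = final$train_rmse, valid_rmse = best_rmse,
                 label_bounds = label_bounds,
                 feature_names = colnames(X)),
            class = "benefit_model")
}

#' @export
print.benefit_model <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<benefit_model> constant predictor (%.4f)\n", x$constant))
    return(invisible(x))
  }
  cat(sprintf("<benefit_model> %d features, valid RMSE %.4f (eta %.2f, depth %d, %d rounds)\n",
              length(x$feature_names), x$valid_rmse, x$best_params$eta,
              x$best_params$max_depth, x$best_params$best_iter))
  invisible(x)
}

#' Predict individualized benefit (log HR) for new rows
#'
#' Columns are bound by name, so consistent column permutations of `X_new`
#' leave predictions unchanged; a missing selected feature is a schema error.
#'
#' @param model a [fit_benefit_model()] result.
#' @param X_new numeric matrix containing (at least) the model's features.
#' @return numeric vector of predicted log HRs (lower = more benefit).
#' @export
predict_benefit <- function(model, X_new) {
  stopifnot(inherits(model, "benefit_model"))
  X_new <- as.matrix(X_new)
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X_new)))
  X_new <- align_feature_matrix(X_new, model$feature_names)
  predict_pt_boost(model$booster, X_new, use_best_iter = FALSE)
}

#' @export
predict.benefit_model <- function(object, newdata, ...) {
  predict_benefit(object, newdata)
}
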
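# Thin R wrapper around the compiled gradient-boosted tree learner.

pt_boost <- function(X, y, nrounds = 100L, eta = 0.1, max_depth = 5L,
                     subsample = 1, colsample_bytree = 1,
                     colsample_bylevel = 1, lambda = 1,
                     min_child_weight = 1, Xval = NULL, yval = NULL,
                     early_stopping_rounds = 0L, seed = 1L) {
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) stopf("booster input contains missing values")
  if (!is.null(Xval)) storage.mode(Xval) <- "double"
  fit <- .cpp_boost_fit(X, as.numeric(y), as.integer(nrounds), eta,
                        as.integer(max_depth), subsample, colsample_bytree,
                        colsample_bylevel, lambda, min_child_weight,
                        Xval, if (is.null(yval)) NULL else as.numeric(yval),
                        as.integer(early_stopping_rounds), as.integer(seed))
  fit$feature_names <- colnames(X)
  class(fit) <- "pt_boost"
  fit
}

predict_pt_boost <- function(fit, X, use_best_iter = TRUE) {
  X <- align_feature_matrix(X, fit$feature_names)
  lim <- if (use_best_iter) fit$best_iter else 0L
  .cpp_boost_predict(fit$trees, fit$base_score, X, as.integer(lim))
}

# mean |path attribution| per feature: the importance used by the Boruta
# shadow-feature comparison (exact, deterministic, additive per tree path).
pt_boost_importance <- function(fit, X, use_best_iter = TRUE) {
  X <- align_feature_matrix(X, fit$feature_names)
  lim <- if (use_best_iter) fit$best_iter else 0L
  phi <- .cpp_path_attribution(fit$trees, X, as.integer(lim))
  setNames(colMeans(abs(phi)), fit$feature_names)
}

# per-row signed attributions (for explainability exports)
pt_boost_phi <- function(fit, X, use_best_iter = TRUE) {
  X <- align_feature_matrix(X, fit$feature_names)
  lim <- if (use_best_iter) fit$best_iter else 0L
  phi <- .cpp_path_attribution(fit$trees, X, as.integer(lim))
  colnames(phi) <- fit$feature_names
  phi
}

# name-based (not position-based) column binding for prediction inputs
align_feature_matrix <- function(X, feature_names) {
  storage.mode(X) <- "double"
  if (is.null(feature_names)) return(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(feature_names))
      stopf("unnamed feature matrix with wrong column count")
    return(X)
  }
  miss <- setdiff(feature_names, colnames(X))
  if (length(miss)) stopf("missing feature column(s): %s",
                          paste(miss, collapse = ", "))
  X[, feature_names, drop = FALSE]
}
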
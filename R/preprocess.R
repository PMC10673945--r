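# Leakage-free fit/transform preprocessing: missingness screen, collinearity
# screen among continuous covariates, 95% winsorization, zero-variance factor
# drop, iterative forest imputation (<= 5 rounds), one-hot encoding.
# All statistics are computed on the training rows only; `apply_preprocess`
# replays the frozen state on any conforming dataset.

WINSOR_PROBS <- c(0.025, 0.975)

#' Fit the preprocessing pipeline on a training dataset
#'
#' Ordered pipeline fitted on `train` only:
#' 1. drop covariates with missing fraction > `missing_cut` (default 10%);
#' 2. among continuous pairs with absolute Pearson correlation > `collinear_cut`
#'    (default 0.9), iteratively drop the member with the largest mean
#'    absolute correlation against the other continuous covariates
#'    (recomputed after each drop, pairs scanned in descending |r|);
#' 3. record 2.5th/97.5th percentile winsorization bounds for continuous
#'    covariates (linear-interpolation percentile convention, R type 7);
#' 4. drop zero-variance factor (binary/categorical) covariates;
#' 5. fit an iterative round-robin imputer with bagged random-forest base
#'    learners, at most `max_iter` (default 5) rounds, seeded;
#' 6. build the one-hot encoder map for kept categorical covariates
#'    (reference-free: one indicator column per level).
#'
#' @param train a [trial_dataset()] with >= 20 participants.
#' @param missing_cut,collinear_cut screening thresholds.
#' @param max_iter maximum imputer rounds.
#' @param ntree,max_depth forest size of the imputer base learner.
#' @param seed integer seed for the imputer.
#' @return object of class `preprocess_fit`.
#' @export
fit_preprocess <- function(train, missing_cut = 0.10, collinear_cut = 0.9,
                           max_iter = 5L, ntree = 20L, max_depth = 10L,
                           seed = 1L) {
  stopifnot(inherits(train, "trial_dataset"))
  if (n_participants(train) < 20) stopf("need >= 20 participants to fit preprocessing")
  schema <- train$schema
  cf <- covariate_frame(train)

  miss_frac <- vapply(cf, function(v) mean(is.na(v)), numeric(1))
  dropped_missing <- names(miss_frac)[miss_frac > missing_cut]
  kept <- setdiff(schema$name, dropped_missing)

  cont <- kept[schema$kind[match(kept, schema$name)] == "continuous"]
  dropped_collinear <- character()
  if (length(cont) >= 2) {
    cmat <- suppressWarnings(abs(cor(cf[cont], use = "pairwise.complete.obs")))
    cmat[is.na(cmat)] <- 0
    diag(cmat) <- 0
    repeat {
      if (max(cmat) <= collinear_cut) break
      ij <- which(cmat == max(cmat), arr.ind = TRUE)[1, ]
      mean_abs <- rowMeans(cmat)  # mean |r| vs all others (diag = 0)
      pair <- rownames(cmat)[ij]
      drop <- pair[which.max(mean_abs[pair])]
      dropped_collinear <- c(dropped_collinear, drop)
      keep_idx <- setdiff(rownames(cmat), drop)
      cmat <- cmat[keep_idx, keep_idx, drop = FALSE]
      if (nrow(cmat) < 2) break
    }
    kept <- setdiff(kept, dropped_collinear)
    cont <- setdiff(cont, dropped_collinear)
  }

  winsor_bounds <- lapply(cf[cont], function(v)
    unname(quantile(v, WINSOR_PROBS, na.rm = TRUE, type = 7)))
  names(winsor_bounds) <- cont

  kinds <- schema$kind[match(kept, schema$name)]
  dropped_zero_var <- character()
  for (i in seq_along(kept)) {
    if (kinds[i] == "continuous") next
    v <- cf[[kept[i]]]
    if (length(unique(v[!is.na(v)])) < 2)
      dropped_zero_var <- c(dropped_zero_var, kept[i])
  }
  kept <- setdiff(kept, dropped_zero_var)
  if (length(kept) == 0) stopf("all covariates dropped during preprocessing")
  kinds <- schema$kind[match(kept, schema$name)]

  work <- cf[kept]
  for (nm in intersect(cont, kept))
    work[[nm]] <- pmin(pmax(work[[nm]], winsor_bounds[[nm]][1]),
                       winsor_bounds[[nm]][2])

  imputer <- fit_forest_imputer(work, kinds, max_iter = max_iter,
                                ntree = ntree, max_depth = max_depth,
                                seed = seed)

  encoder_map <- list()
  for (i in seq_along(kept)) {
    if (kinds[i] == "categorical") {
      lv <- schema_levels(schema, kept[i])
      encoder_map[[kept[i]]] <- setNames(paste0(kept[i], "=", lv), lv)
    }
  }

  structure(list(schema = schema,
                 kept_features = kept, kinds = kinds,
                 winsor_bounds = winsor_bounds,
                 dropped_missing = dropped_missing,
                 dropped_collinear = dropped_collinear,
                 dropped_zero_var = dropped_zero_var,
                 encoder_map = encoder_map,
                 imputer = imputer),
            class = "preprocess_fit")
}

#' @export
print.preprocess_fit <- function(x, ...) {
  cat(sprintf("<preprocess_fit> kept %d covariates (dropped: %d missing, %d collinear, %d zero-variance)\n",
              length(x$kept_features), length(x$dropped_missing),
              length(x$dropped_collinear), length(x$dropped_zero_var)))
  invisible(x)
}

#' Apply a fitted preprocessing pipeline
#'
#' Deterministically replays the frozen preprocessing state on `ds`:
#' winsorizes with training bounds, imputes with the frozen forest imputer,
#' and (for `output = "matrix"`) one-hot encodes. Unseen categorical levels
#' map to all-zero indicator rows.
#'
#' @param fit a [fit_preprocess()] result.
#' @param ds a [trial_dataset()] whose covariates conform to the fit schema.
#' @param output `"matrix"` for the fully numeric one-hot feature matrix
#'   (the ML view) or `"frame"` for kept covariates on their original scales
#'   and levels, winsorized and imputed (the Gower view).
#' @return list with `ids` and either `X` (matrix) or `frame` (data.frame).
#' @export
apply_preprocess <- function(fit, ds, output = c("matrix", "frame")) {
  output <- match.arg(output)
  stopifnot(inherits(fit, "preprocess_fit"), inherits(ds, "trial_dataset"))
  missing_cols <- setdiff(fit$kept_features, names(ds$data))
  if (length(missing_cols))
    stopf("covariate(s) present at fit are absent: %s",
          paste(missing_cols, collapse = ", "))
  work <- ds$data[fit$kept_features]
  for (nm in names(fit$winsor_bounds))
    work[[nm]] <- pmin(pmax(work[[nm]], fit$winsor_bounds[[nm]][1]),
                       fit$winsor_bounds[[nm]][2])
  work <- apply_forest_imputer(fit$imputer, work)
  if (output == "frame")
    return(list(ids = ds$data$id, frame = work))

  cols <- list()
  for (i in seq_along(fit$kept_features)) {
    nm <- fit$kept_features[i]
    if (fit$kinds[i] == "categorical") {
      emap <- fit$encoder_map[[nm]]
      for (lv in names(emap))
        cols[[emap[[lv]]]] <- as.numeric(work[[nm]] == lv &
                                           !is.na(work[[nm]]))
    } else {
      cols[[nm]] <- as.numeric(work[[nm]])
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  list(ids = ds$data$id, X = X)
}

# ---------------------------------------------------------------------------
# Iterative forest imputer.
#
# Round-robin over covariates (ascending training missingness): regress each
# covariate on the one-hot design of all others, replacing its missing cells
# with forest predictions; repeat up to max_iter rounds or until the imputed
# values stabilize. Continuous/binary targets use regression forests (binary
# predictions rounded to {0,1}); categorical targets use one indicator
# regression per level with argmax decoding. The final round's forests plus
# the training means/modes form the frozen transform state.

impute_init_value <- function(v, kind) {
  obs <- v[!is.na(v)]
  if (kind == "continuous") return(mean(obs))
  if (kind == "binary") return(as.numeric(round(mean(obs))))
  tab <- table(obs)
  names(tab)[which.max(tab)]  # modal level
}

# one-hot design of all columns except `skip`
imputer_design <- function(work, kinds, skip) {
  cols <- list()
  for (i in seq_along(work)) {
    nm <- names(work)[i]
    if (nm == skip) next
    v <- work[[nm]]
    if (kinds[i] == "categorical") {
      for (lv in levels(v)) cols[[paste0(nm, "=", lv)]] <- as.numeric(v == lv)
    } else cols[[nm]] <- as.numeric(v)
  }
  if (!length(cols)) return(matrix(0.0, nrow(work), 1))
  do.call(cbind, cols)
}

fit_forest_imputer <- function(work, kinds, max_iter, ntree, max_depth,
                               seed) {
  nms <- names(work)
  na_mask <- lapply(work, is.na)
  init <- list()
  for (i in seq_along(nms)) {
    init[[nms[i]]] <- impute_init_value(work[[nms[i]]], kinds[i])
    v <- work[[nms[i]]]
    v[na_mask[[nms[i]]]] <- init[[nms[i]]]
    work[[nms[i]]] <- v
  }
  has_na <- vapply(na_mask, any, logical(1))
  order_nms <- nms[order(vapply(na_mask, mean, numeric(1)))]
  models <- list()
  if (any(has_na) && length(nms) >= 2) {
    prev <- NULL
    for (iter in seq_len(max_iter)) {
      for (nm in order_nms) {
        i <- match(nm, nms)
        if (!has_na[[nm]]) next
        X <- imputer_design(work, kinds, nm)
        obs <- !na_mask[[nm]]
        mods <- fit_imputer_target(X, work[[nm]], obs, kinds[i],
                                   ntree, max_depth,
                                   stage_seed(seed, nm, iter))
        models[[nm]] <- mods
        pred <- predict_imputer_target(mods, X[na_mask[[nm]], , drop = FALSE],
                                       kinds[i])
        v <- work[[nm]]
        v[na_mask[[nm]]] <- pred
        work[[nm]] <- v
      }
      cur <- unlist(lapply(nms, function(nm) {
        v <- work[[nm]][na_mask[[nm]]]
        if (is.factor(v)) as.numeric(v) else as.numeric(v)
      }))
      if (!is.null(prev) && length(cur) &&
          sum((cur - prev)^2) <= 1e-8 * max(1, sum(prev^2))) break
      prev <- cur
    }
  }
  list(names = nms, kinds = kinds, init = init, models = models,
       levels = lapply(work, function(v) if (is.factor(v)) levels(v)))
}

fit_imputer_target <- function(X, y, obs, kind, ntree, max_depth, seed) {
  Xo <- X[obs, , drop = FALSE]
  if (kind == "categorical") {
    lv <- levels(y)
    mods <- lapply(seq_along(lv), function(k)
      .cpp_forest_fit(Xo, as.numeric(y[obs] == lv[k]), ntree, max_depth,
                      5.0, 1 / 3, seed + k))
    list(kind = kind, levels = lv, forests = mods)
  } else {
    list(kind = kind,
         forest = .cpp_forest_fit(Xo, as.numeric(y[obs]), ntree, max_depth,
                                  5.0, 1 / 3, seed))
  }
}

predict_imputer_target <- function(mods, Xnew, kind) {
  if (nrow(Xnew) == 0)
    return(if (kind == "categorical") factor(character(), levels = mods$levels)
           else numeric())
  if (kind == "categorical") {
    scores <- vapply(mods$forests,
                     function(f) .cpp_forest_predict(f$trees, Xnew),
                     numeric(nrow(Xnew)))
    scores <- matrix(scores, nrow = nrow(Xnew))
    mods$levels[max.col(scores, ties.method = "first")]
  } else {
    p <- .cpp_forest_predict(mods$forest$trees, Xnew)
    if (kind == "binary") as.numeric(p >= 0.5) else p
  }
}

apply_forest_imputer <- function(imp, work) {
  nms <- imp$names
  na_mask <- lapply(work, is.na)
  for (i in seq_along(nms)) {
    v <- work[[nms[i]]]
    v[na_mask[[nms[i]]]] <- imp$init[[nms[i]]]
    work[[nms[i]]] <- v
  }
  if (!any(vapply(na_mask, any, logical(1)))) return(work)
  for (pass in 1:2) {
    for (nm in nms) {
      i <- match(nm, nms)
      mods <- imp$models[[nm]]
      if (is.null(mods) || !any(na_mask[[nm]])) next
      X <- imputer_design(work, imp$kinds, nm)
      pred <- predict_imputer_target(mods, X[na_mask[[nm]], , drop = FALSE],
                                     imp$kinds[i])
      v <- work[[nm]]
      v[na_mask[[nm]]] <- pred
      work[[nm]] <- v
    }
  }
  work
}
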
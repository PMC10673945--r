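# The per-interim learning pipeline as a single fitting function returning a
# classed object: split -> preprocess -> phenomap -> individualized weighted
# Cox labels -> Boruta selection -> boosted benefit regressor.

#' Learn a phenomapping benefit signature at an interim analysis
#'
#' Runs the full per-interim estimation pipeline on the participants of `ds`
#' (those accrued before `interim_cut`): 50:50 split, leakage-free
#' preprocessing fitted on the training half, Gower phenomap, individualized
#' log-HR labels from phenotype-proximity weighted Cox fits censored at the
#' cut, label winsorization, Boruta shadow-feature selection, and a
#' grid-searched gradient-boosted regressor on the selected features.
#'
#' @param ds a [trial_dataset()] of enrolled participants.
#' @param interim_cut interim analysis calendar day.
#' @param seed integer seed (fans out to per-stage seeds).
#' @param min_events minimum weighted events per individualized Cox fit.
#' @param n_draws hyperparameter-grid draws (default 25).
#' @param boruta_alpha Boruta binomial-test threshold.
#' @param n_boruta_iter Boruta iterations (default 20).
#' @return object of class `benefit_pipeline` with elements `split`, `prep`,
#'   `map`, `labels`, `label_bounds`, `selection`, `model`, `train`, `test`.
#'   `model` is `NULL` when Boruta rejects every feature (the caller's
#'   no-enrichment fallback).
#' @export
learn_benefit <- function(ds, interim_cut, seed = 1L, min_events = 5,
                          n_draws = 25L, boruta_alpha = 0.05,
                          n_boruta_iter = 20L) {
  ds <- subset_trial(ds, rows = which(ds$data$accrual_time < interim_cut))
  split <- split_half(ds, stage_seed(seed, "split"))
  train <- subset_trial(ds, split$train_ids)
  test <- subset_trial(ds, split$test_ids)

  prep <- fit_preprocess(train, seed = stage_seed(seed, "impute"))
  map <- gower_matrix(train, prep)
  labels <- individualized_loghr(train, map, interim_cut,
                                 min_events = min_events)
  ok <- !is.na(labels$loghr)
  if (sum(ok) < 50)
    stopf("only %d converged individualized labels (< 50)", sum(ok))
  wl <- winsorize_labels(labels[ok, , drop = FALSE])
  y <- wl$labels$loghr

  Xtr <- apply_preprocess(prep, subset_trial(train, wl$labels$id))$X
  selection <- boruta_shap_select(Xtr, y, seed = stage_seed(seed, "boruta"),
                                  n_iter = n_boruta_iter,
                                  alpha = boruta_alpha)
  model <- NULL
  if (length(selection$selected) > 0) {
    model <- fit_benefit_model(Xtr[, selection$selected, drop = FALSE], y,
                               seed = stage_seed(seed, "fit"),
                               n_draws = n_draws, selection = selection,
                               label_bounds = wl$bounds)
  }
  structure(list(split = split, prep = prep, map = map, labels = labels,
                 label_bounds = wl$bounds, selection = selection,
                 model = model, train = train, test = test,
                 interim_cut = interim_cut, seed = as.integer(seed)),
            class = "benefit_pipeline")
}

#' @export
print.benefit_pipeline <- function(x, ...) {
  cat(sprintf("<benefit_pipeline> interim cut day %.0f: %d train / %d test\n",
              x$interim_cut, n_participants(x$train), n_participants(x$test)))
  cat(sprintf("  labels: %d converged of %d; features selected: %d\n",
              sum(!is.na(x$labels$loghr)), nrow(x$labels),
              length(x$selection$selected)))
  if (is.null(x$model)) cat("  no benefit model (empty selection)\n")
  invisible(x)
}

#' @export
summary.benefit_pipeline <- function(object, ...) {
  lab <- object$labels$loghr
  out <- list(n_train = n_participants(object$train),
              n_test = n_participants(object$test),
              n_labels = sum(!is.na(lab)),
              label_mean = mean(lab, na.rm = TRUE),
              label_sd = sd(lab, na.rm = TRUE),
              selected = object$selection$selected,
              valid_rmse = if (!is.null(object$model)) object$model$valid_rmse)
  class(out) <- "summary.benefit_pipeline"
  out
}

#' @export
print.summary.benefit_pipeline <- function(x, ...) {
  cat(sprintf("train %d / test %d; labels %d (mean %.3f, sd %.3f)\n",
              x$n_train, x$n_test, x$n_labels, x$label_mean, x$label_sd))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Plot a fitted benefit pipeline
#'
#' Two base-graphics panels: the distribution of the individualized log-HR
#' labels (with the winsorization bounds), and the mean absolute path
#' attribution of the selected features in the fitted booster.
#'
#' @param x a `benefit_pipeline`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.benefit_pipeline <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4, 2.5, 1))
  on.exit(graphics::par(op))
  lab <- x$labels$loghr[!is.na(x$labels$loghr)]
  graphics::hist(lab, breaks = 30, col = "grey85", border = "white",
                 main = "Individualized log HR labels",
                 xlab = "log hazard ratio (intervention vs control)", ...)
  graphics::abline(v = x$label_bounds, lty = 2)
  graphics::abline(v = 0, col = "red3")
  if (!is.null(x$model) && is.null(x$model$constant)) {
    ap <- apply_preprocess(x$prep, x$train)
    imp <- pt_boost_importance(x$model$booster,
                               ap$X[, x$model$feature_names, drop = FALSE])
    imp <- sort(imp, decreasing = FALSE)
    graphics::barplot(imp, horiz = TRUE, las = 1, col = "steelblue",
                      main = "Selected-feature importance",
                      xlab = "mean |path attribution|")
  } else {
    graphics::plot.new()
    graphics::title("no benefit model (empty selection)")
  }
  invisible(x)
}

#' Predict individualized benefit for raw trial participants
#'
#' Applies the frozen preprocessing and the fitted benefit model of a
#' [learn_benefit()] pipeline to the baseline covariates of `newdata`.
#'
#' @param object a `benefit_pipeline`.
#' @param newdata a [trial_dataset()] (defaults to the pipeline's test half).
#' @param ... unused.
#' @return named numeric vector of predicted log HRs.
#' @export
predict.benefit_pipeline <- function(object, newdata = NULL, ...) {
  if (is.null(object$model)) stopf("pipeline has no benefit model (empty selection)")
  if (is.null(newdata)) newdata <- object$test
  ap <- apply_preprocess(object$prep, newdata)
  setNames(predict_benefit(object$model, ap$X), ap$ids)
}
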
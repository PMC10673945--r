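# Computational trial phenomap: pairwise Gower dissimilarity over mixed-type
# baseline data, and the phenotype-proximity weight transform used by the
# individualized weighted Cox fits.

#' Gower dissimilarity matrix (phenomap) of a participant set
#'
#' Computes the pairwise Gower distance over the preprocessed (winsorized,
#' imputed, original-level) covariates: continuous features contribute
#' `|x_i - x_j| / range`, binary and categorical features contribute 0 when
#' equal and 1 otherwise, and the distance is the unweighted mean of the
#' per-feature contributions. Ranges are the observed ranges in the supplied
#' analysis subset. Zero-range continuous features are excluded from the
#' mean with a warning.
#'
#' @param ds a [trial_dataset()] (>= 2 participants), or `NULL` when `frame`
#'   is supplied directly.
#' @param fit a [fit_preprocess()] result used to winsorize/impute the
#'   covariates before distance computation (ignored when `frame` given).
#' @param frame optional preprocessed covariate data frame (the
#'   `output = "frame"` view of [apply_preprocess()]); bypasses `fit`.
#' @param ids participant ids (required with `frame`).
#' @return object of class `phenomap`: `ids`, symmetric distance matrix `D`
#'   with entries in \[0, 1\], `feature_kinds`, and per-continuous `ranges`.
#' @export
gower_matrix <- function(ds = NULL, fit = NULL, frame = NULL, ids = NULL) {
  if (is.null(frame)) {
    stopifnot(inherits(ds, "trial_dataset"), inherits(fit, "preprocess_fit"))
    ap <- apply_preprocess(fit, ds, output = "frame")
    frame <- ap$frame
    ids <- ap$ids
  }
  n <- nrow(frame)
  if (n < 2) stopf("need >= 2 participants for a phenomap")
  if (is.null(ids) || length(ids) != n) stopf("ids must match frame rows")

  kinds <- vapply(frame, function(v)
    if (is.factor(v) || is.character(v)) "categorical" else "continuous",
    character(1))
  # binary numeric columns behave identically under either branch
  ranges <- numeric(0)
  acc <- matrix(0, n, n)
  used <- 0L
  for (j in seq_along(frame)) {
    v <- frame[[j]]
    if (kinds[j] == "categorical") {
      code <- as.integer(factor(v))
      contrib <- outer(code, code, `!=`) * 1.0
    } else {
      v <- as.numeric(v)
      rg <- max(v) - min(v)
      ranges[names(frame)[j]] <- rg
      if (rg <= 0) {
        warnf("zero-range continuous feature '%s' excluded from Gower mean",
              names(frame)[j])
        next
      }
      contrib <- abs(outer(v, v, `-`)) / rg
    }
    acc <- acc + contrib
    used <- used + 1L
  }
  if (used == 0L) stopf("no usable features for Gower distance")
  D <- acc / used
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  structure(list(ids = ids, D = D, feature_kinds = kinds, ranges = ranges,
                 n_features_used = used),
            class = "phenomap")
}

#' @export
print.phenomap <- function(x, ...) {
  cat(sprintf("<phenomap> %d participants, %d features (%d used), mean distance %.3f\n",
              length(x$ids), length(x$feature_kinds), x$n_features_used,
              mean(x$D[upper.tri(x$D)])))
  invisible(x)
}

#' Phenotype-proximity weights for an index participant
#'
#' The weight of participant j in the Cox fit centered on the index
#' participant is the cubic transform of similarity,
#' `w_j = max(0, (1 - d(index, j))^3)`, passed through a ReLU guard (the
#' cube of a value in \[0, 1\] is already non-negative; the guard only
#' protects against numeric noise). The self-weight is exactly 1.
#'
#' @param map a [gower_matrix()] result.
#' @param index_id participant id in `map$ids`.
#' @return named numeric weight vector over `map$ids`.
#' @export
similarity_weights <- function(map, index_id) {
  stopifnot(inherits(map, "phenomap"))
  i <- match(index_id, map$ids)
  if (is.na(i)) stopf("unknown participant id '%s'", index_id)
  w <- pmax(0, (1 - map$D[i, ])^3)
  w[i] <- 1
  setNames(w, map$ids)
}
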
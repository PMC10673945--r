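# Stability machinery: pairwise rank-concordance across repeated random
# splits of an interim population, and selected-feature frequencies.

#' Pairwise concordance ratio of repeated rankings
#'
#' For a pair ranked `counts_ge_ij` times one way and `counts_ge_ji` times
#' the other across iterations: 1 when the counts are equal, otherwise the
#' majority-to-minority ratio. A zero minority count makes the printed ratio
#' undefined; by default a +0.5 continuity correction is applied to both
#' counts (so (4, 0) evaluates to 4.5/0.5 = 9). Both counts zero (the pair
#' never co-occurred in a test set) is undefined and excluded from means.
#'
#' @param counts_ge_ij,counts_ge_ji non-negative counts.
#' @param continuity apply the +0.5 correction on a zero minority count.
#' @return the concordance value `C(i, j)` (NA when both counts are 0).
#' @export
pair_concordance <- function(counts_ge_ij, counts_ge_ji, continuity = TRUE) {
  a <- counts_ge_ij; b <- counts_ge_ji
  if (a == 0 && b == 0) return(NA_real_)
  if (a == b) return(1)
  if (min(a, b) == 0 && continuity) { a <- a + 0.5; b <- b + 0.5 }
  max(a, b) / min(a, b)
}

build_concordance_matrix <- function(counts_ge, continuity = TRUE) {
  n <- nrow(counts_ge)
  M <- matrix(NA_real_, n, n, dimnames = dimnames(counts_ge))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- pair_concordance(counts_ge[i, j],
                                             counts_ge[j, i], continuity)
    }
  }
  M
}

#' Average concordance odds with bootstrap CI
#'
#' Mean over the defined upper-triangle entries of the concordance matrix,
#' with a seeded percentile bootstrap over participants (default 1000
#' replicates) for the 95% interval.
#'
#' @param M symmetric concordance matrix (NA = undefined pair).
#' @param n_boot bootstrap replicates (0 disables the CI).
#' @param seed integer seed.
#' @return list with `mean`, `ci_low`, `ci_high`, `n_pairs`.
#' @export
average_concordance_odds <- function(M, n_boot = 1000L, seed = 1L) {
  ut <- M[upper.tri(M)]
  ut <- ut[!is.na(ut)]
  if (!length(ut)) stopf("no defined pairs")
  est <- mean(ut)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    n <- nrow(M)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, replace = TRUE)
        Mb <- M[idx, idx]
        # resampled self-pairs are undefined; NA entries already excluded
        diag(Mb) <- NA_real_
        v <- Mb[upper.tri(Mb)]
        dup <- outer(idx, idx, `==`)[upper.tri(Mb)]
        v <- v[!dup & !is.na(v)]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    })
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE, type = 7))
  }
  list(mean = est, ci_low = ci[1], ci_high = ci[2], n_pairs = length(ut))
}

#' Stability analysis of an interim benefit signature
#'
#' Repeats the per-interim pipeline (`n_iter` random 50:50 splits of the
#' population accrued before the cut), accumulating (a) pairwise predicted
#' rank counts over participants whenever both members of a pair land in
#' the test set (participant i counts above j when its predicted log HR is
#' lower, i.e. more benefit), and (b) the Boruta-selected feature
#' indicators. Per-iteration failures are logged and skipped.
#'
#' @param ds a [trial_dataset()].
#' @param interim_cut interim calendar day.
#' @param n_iter number of random splits (design default: 100).
#' @param seed integer seed (iteration i uses a seed derived from it).
#' @param continuity passed to [pair_concordance()].
#' @param ... passed to [learn_benefit()] (e.g. `n_draws`).
#' @return object of class `stability_result`: `ids`, `counts_ge`, `M`,
#'   `feature_freq`, `n_done`, `n_failed`.
#' @export
stability_run <- function(ds, interim_cut, n_iter = 100L, seed = 1L,
                          continuity = TRUE, ...) {
  ds <- subset_trial(ds, rows = which(ds$data$accrual_time < interim_cut))
  ids <- ds$data$id
  n <- length(ids)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  feat_counts <- integer(0)
  n_failed <- 0L
  for (it in seq_len(n_iter)) {
    res <- tryCatch({
      pl <- learn_benefit(ds, interim_cut,
                          seed = stage_seed(seed, "stability", it), ...)
      if (is.null(pl$model)) list(pred = NULL, sel = pl$selection$selected)
      else list(pred = predict(pl), sel = pl$selection$selected)
    }, error = function(e) e)
    if (inherits(res, "error")) { n_failed <- n_failed + 1L; next }
    for (nm in res$sel)
      feat_counts[nm] <- (if (nm %in% names(feat_counts)) feat_counts[nm] else 0L) + 1L
    if (!is.null(res$pred)) {
      idx <- match(names(res$pred), ids)
      above <- outer(res$pred, res$pred, `<`)  # lower log HR ranks above
      counts[idx, idx] <- counts[idx, idx] + above
    }
  }
  n_done <- n_iter - n_failed
  freq <- if (length(feat_counts)) sort(feat_counts / n_done, decreasing = TRUE)
          else numeric(0)
  structure(list(ids = ids, counts_ge = counts,
                 M = build_concordance_matrix(counts, continuity),
                 feature_freq = freq, n_done = n_done, n_failed = n_failed),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  avg <- tryCatch(average_concordance_odds(x$M, n_boot = 0)$mean,
                  error = function(e) NA_real_)
  cat(sprintf("<stability_result> %d iterations done (%d failed), mean concordance odds %.3f\n",
              x$n_done, x$n_failed, avg))
  if (length(x$feature_freq)) {
    top <- head(x$feature_freq, 5)
    cat("  top features:", paste(sprintf("%s (%.0f%%)", names(top), 100 * top),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}
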
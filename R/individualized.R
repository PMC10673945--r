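# Individualized treatment-effect estimation: phenotype-proximity weighted
# Cox regression with the treatment arm as the sole covariate, repeated with
# each training participant as the index, yielding per-participant
# individualized log hazard ratios (the ML regression labels).

#' Weighted Cox regression of arm on the primary outcome
#'
#' Maximizes the weight-incorporated Cox partial likelihood (Breslow tie
#' handling) with the treatment arm as the only covariate, and reports a
#' robust (sandwich) standard error, since the weights encode phenotypic
#' proximity rather than replication.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param arm arm labels (`"control"`/`"intervention"`), factor or character,
#'   or a 0/1 numeric vector (1 = intervention).
#' @param weights non-negative case weights; at least one weighted event and
#'   positive total weight in both arms required.
#' @return list of class `weighted_cox`: `loghr` (intervention vs control),
#'   `se` (robust), `converged`, `n_effective` (sum of weights).
#' @export
weighted_cox <- function(times, events, arm, weights = NULL) {
  n <- length(times)
  if (is.null(weights)) weights <- rep(1, n)
  if (all(weights == 0)) stopf("all-zero weights")
  trt <- if (is.numeric(arm)) as.numeric(arm) else
    as.numeric(as.character(arm) == "intervention")
  if (sum(weights[trt == 1]) <= 0 || sum(weights[trt == 0]) <= 0)
    stopf("both arms need positive total weight")
  keep <- weights > 0
  dat <- data.frame(times = times[keep], events = events[keep],
                    trt = trt[keep], w = weights[keep])
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(times, events) ~ trt, data = dat, weights = w,
      ties = "breslow", robust = TRUE)),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(coef(fit))) {
    return(structure(list(loghr = NA_real_, se = NA_real_, converged = FALSE,
                          n_effective = sum(weights)),
                     class = "weighted_cox"))
  }
  beta <- unname(coef(fit)[1])
  converged <- is.finite(beta) && abs(beta) < 15
  structure(list(loghr = beta, se = sqrt(diag(vcov(fit)))[1],
                 converged = converged, n_effective = sum(weights)),
            class = "weighted_cox")
}

#' @export
print.weighted_cox <- function(x, ...) {
  cat(sprintf("<weighted_cox> log HR %.4f (robust SE %.4f), HR %.3f, n_eff %.1f%s\n",
              x$loghr, x$se, exp(x$loghr), x$n_effective,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# Fast internal path: weighted Breslow partial-likelihood fit of a single
# binary covariate via survival's C routine, skipping formula/robust
# machinery. Returns the coefficient or NA on non-convergence.
wcox_beta <- function(times, events, trt, weights) {
  keep <- weights > 0
  if (!any(events[keep] == 1)) return(NA_real_)
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      x = matrix(trt[keep], ncol = 1), y = survival::Surv(times[keep], events[keep]),
      strata = NULL, offset = NULL, init = 0,
      control = survival::coxph.control(), weights = weights[keep],
      method = "breslow", rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  beta <- unname(fit$coefficients[1])
  if (!is.finite(beta) || abs(beta) >= 15) NA_real_ else beta
}

#' Individualized log hazard ratios over a phenomap
#'
#' For each index participant in `ds_train`, forms the phenotype-proximity
#' weight vector from the phenomap and fits the weighted arm-only Cox model
#' on follow-up censored at the interim calendar cut, recording the
#' individualized log HR. Fits with fewer than `min_events` weighted events
#' or with monotone likelihood (non-convergence) yield a missing label,
#' excluded downstream.
#'
#' @param ds_train training [trial_dataset()] (already restricted to
#'   participants accrued before the cut).
#' @param map a [gower_matrix()] covering all training participants.
#' @param interim_cut interim analysis calendar day.
#' @param min_events minimum weighted event count (default 5).
#' @param weight_floor weights below this are zeroed for speed (0 = off).
#' @return object of class `benefit_labels`: data frame with `id`, `loghr`.
#' @export
individualized_loghr <- function(ds_train, map, interim_cut, min_events = 5,
                                 weight_floor = 0) {
  stopifnot(inherits(map, "phenomap"))
  cens <- censor_at(ds_train, interim_cut)
  idx <- match(cens$data$id, map$ids)
  if (anyNA(idx)) stopf("phenomap does not cover all training participants")
  times <- cens$data$primary_time
  events <- cens$data$primary_event
  trt <- as.numeric(cens$data$arm == "intervention")
  W <- (1 - map$D[idx, idx, drop = FALSE])^3
  W[W < 0] <- 0
  diag(W) <- 1
  loghr <- rep(NA_real_, nrow(W))
  for (i in seq_len(nrow(W))) {
    w <- W[i, ]
    if (weight_floor > 0) w[w < weight_floor] <- 0
    if (sum(w * events) < min_events) next
    if (sum(w[trt == 1]) <= 0 || sum(w[trt == 0]) <= 0) next
    loghr[i] <- wcox_beta(times, events, trt, w)
  }
  structure(data.frame(id = cens$data$id, loghr = loghr,
                       stringsAsFactors = FALSE),
            class = c("benefit_labels", "data.frame"))
}
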
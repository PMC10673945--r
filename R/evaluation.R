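# Outcome analyses: arm-only Cox hazard ratio, hierarchical win ratio with a
# U-statistic confidence interval, arm-balance and composition checks,
# period-wise log-rank comparisons, and run summarization.

#' Primary-outcome Cox hazard ratio
#'
#' Unweighted arm-only Cox fit on follow-up censored at the calendar cut.
#'
#' @param ds a [trial_dataset()].
#' @param cut calendar day (`Inf` = full follow-up).
#' @return list with `hr`, `loghr`, `se`, `p` (Wald), `events`, `n`.
#' @export
primary_cox_hr <- function(ds, cut = Inf) {
  if (is.finite(cut)) ds <- censor_at(ds, cut)
  d <- ds$data
  if (sum(d$primary_event) == 0) stopf("no events at this cut")
  fit <- weighted_cox(d$primary_time, d$primary_event, d$arm)
  z <- fit$loghr / fit$se
  list(hr = exp(fit$loghr), loghr = fit$loghr, se = fit$se,
       p = 2 * pnorm(-abs(z)), events = sum(d$primary_event), n = nrow(d))
}

#' Hierarchical win ratio
#'
#' Unmatched pairwise comparison of every intervention-control pair over the
#' ordered safety-outcome hierarchy (tier 1 first, e.g. all-cause
#' mortality). Within a tier, the intervention member wins if the control
#' member had the event and the intervention member is known event-free
#' beyond that time (and vice versa for a loss); undecidable pairs fall
#' through to the next tier, and pairs undecided after all tiers are ties.
#' The 95% CI uses the two-sample U-statistic (projection) variance of the
#' win and loss proportions with the delta method on `log(WR)`.
#'
#' @param ds a [trial_dataset()] with >= 1 safety tier.
#' @param cut calendar censoring day (`Inf` = full follow-up).
#' @return object of class `win_ratio_result`: `wins`, `losses`, `ties`,
#'   `wr`, `ci_low`, `ci_high`, `se_log`, `undefined` flag.
#' @export
win_ratio <- function(ds, cut = Inf) {
  if (ds$n_safety < 1) stopf("dataset has no safety-outcome tiers")
  if (is.finite(cut)) ds <- censor_at(ds, cut)
  d <- ds$data
  I <- d$arm == "intervention"
  nI <- sum(I); nC <- sum(!I)
  if (nI == 0 || nC == 0) stopf("both arms must be non-empty")
  win <- matrix(FALSE, nI, nC)
  loss <- matrix(FALSE, nI, nC)
  open <- matrix(TRUE, nI, nC)
  for (k in seq_len(ds$n_safety)) {
    tI <- d[[sprintf("safety_%d_time", k)]][I]
    eI <- d[[sprintf("safety_%d_event", k)]][I] == 1L
    tC <- d[[sprintf("safety_%d_time", k)]][!I]
    eC <- d[[sprintf("safety_%d_event", k)]][!I] == 1L
    w_k <- outer(tI, tC, `>`) & matrix(eC, nI, nC, byrow = TRUE)
    l_k <- outer(tI, tC, `<`) & matrix(eI, nI, nC)
    win <- win | (open & w_k)
    loss <- loss | (open & l_k & !w_k)
    open <- open & !w_k & !l_k
  }
  W <- sum(win); L <- sum(loss); Ties <- nI * nC - W - L
  if (L == 0 || W == 0) {
    return(structure(list(wins = W, losses = L, ties = Ties,
                          wr = if (L > 0) W / L else if (W == 0) 1 else Inf,
                          ci_low = NA_real_, ci_high = NA_real_,
                          se_log = NA_real_, undefined = TRUE),
                     class = "win_ratio_result"))
  }
  tw <- W / (nI * nC); tl <- L / (nI * nC)
  wi <- rowMeans(win); wj <- colMeans(win)
  li <- rowMeans(loss); lj <- colMeans(loss)
  vw <- var(wi) / nI + var(wj) / nC
  vl <- var(li) / nI + var(lj) / nC
  cv <- cov(wi, li) / nI + cov(wj, lj) / nC
  se_log <- sqrt(max(vw / tw^2 + vl / tl^2 - 2 * cv / (tw * tl), 0))
  wr <- W / L
  structure(list(wins = W, losses = L, ties = Ties, wr = wr,
                 ci_low = wr * exp(-1.959964 * se_log),
                 ci_high = wr * exp(1.959964 * se_log),
                 se_log = se_log, undefined = FALSE),
            class = "win_ratio_result")
}

#' @export
print.win_ratio_result <- function(x, ...) {
  cat(sprintf("<win_ratio> %.3f (95%% CI %.3f-%.3f); W/L/T = %d/%d/%d%s\n",
              x$wr, x$ci_low, x$ci_high, x$wins, x$losses, x$ties,
              if (x$undefined) " [CI undefined]" else ""))
  invisible(x)
}

#' Arm balance and demographic composition of the final population
#'
#' Chi-square test of arm counts in the final (possibly enriched) population
#' against the original candidate pool, plus the share of each level of the
#' requested demographic strata in both populations.
#'
#' @param ds_final,ds_original [trial_dataset()] objects.
#' @param strata character vector of binary/categorical covariate names.
#' @return list with `arm_p` and a `shares` data frame.
#' @export
balance_and_composition <- function(ds_final, ds_original,
                                    strata = character()) {
  tab <- rbind(final = table(ds_final$data$arm)[ARM_LEVELS],
               original = table(ds_original$data$arm)[ARM_LEVELS])
  if (any(is.na(tab)) || any(colSums(tab) == 0)) stopf("empty stratum table")
  arm_p <- suppressWarnings(chisq.test(tab)$p.value)
  shares <- NULL
  for (nm in strata) {
    fv <- factor(ds_final$data[[nm]])
    ov <- factor(ds_original$data[[nm]], levels = levels(fv))
    for (lv in levels(fv)) {
      shares <- rbind(shares, data.frame(
        stratum = nm, level = lv,
        share_final = mean(fv == lv, na.rm = TRUE),
        share_original = mean(ov == lv, na.rm = TRUE),
        stringsAsFactors = FALSE))
    }
  }
  list(arm_p = arm_p, shares = shares)
}

#' Log-rank comparison of period enrollees across simulations
#'
#' Two-sample log-rank test of the primary outcome between the enrollees of
#' the same accrual period in two simulations (e.g. adaptive vs original).
#'
#' @param ds_adaptive,ds_original [trial_dataset()] objects.
#' @param period numeric `c(start, end]` calendar window of accrual.
#' @param cut calendar censoring day (`Inf` = full follow-up).
#' @return list with `p`, `chisq`, `n_adaptive`, `n_original`.
#' @export
period_logrank <- function(ds_adaptive, ds_original, period = c(0, Inf),
                           cut = Inf) {
  pick <- function(ds) {
    if (is.finite(cut)) ds <- censor_at(ds, cut)
    d <- ds$data
    d[d$accrual_time > period[1] & d$accrual_time <= period[2], , drop = FALSE]
  }
  da <- pick(ds_adaptive); do <- pick(ds_original)
  if (nrow(da) == 0 || nrow(do) == 0) stopf("empty period subset")
  if (sum(da$primary_event) + sum(do$primary_event) == 0)
    stopf("no events in either period subset")
  comb <- data.frame(time = c(da$primary_time, do$primary_time),
                     event = c(da$primary_event, do$primary_event),
                     grp = rep(c("adaptive", "original"),
                               c(nrow(da), nrow(do))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = comb)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(p = p, chisq = unname(sd$chisq), n_adaptive = nrow(da),
       n_original = nrow(do))
}

#' Summarize simulation runs against a reference value
#'
#' Per-metric mean, standard error of the mean, and a one-sample t test of
#' the run values against the original-trial reference. The design uses a
#' one-sided alpha of 0.025 for final sample-size counts and two-sided 0.05
#' otherwise.
#'
#' @param values numeric vector of per-run values (length >= 2).
#' @param reference reference scalar from the original trial.
#' @param alternative `"two.sided"` (default) or `"less"`/`"greater"`.
#' @return list with `mean`, `sem`, `t`, `df`, `p`, `zero_variance` flag.
#' @export
summarize_runs <- function(values, reference,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  r <- length(values)
  if (r < 2) stopf("need >= 2 runs")
  m <- mean(values); s <- sd(values)
  if (s == 0) {
    return(list(mean = m, sem = 0, t = if (m == reference) 0 else Inf,
                df = r - 1, p = if (m == reference) 1 else NA_real_,
                zero_variance = TRUE))
  }
  tt <- t.test(values, mu = reference, alternative = alternative)
  list(mean = m, sem = s / sqrt(r), t = unname(tt$statistic),
       df = r - 1, p = tt$p.value, zero_variance = FALSE)
}
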
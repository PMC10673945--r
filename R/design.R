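# Group-sequential scaffolding: design specification, event-count interim
# triggers, alpha-spending efficacy boundaries by recursive numerical
# integration, the interaction heterogeneity gate, Schoenfeld sample sizes,
# and enrichment-aware sample-size revision over the enrichment-level grid.

#' Group-sequential design specification
#'
#' @param n_planned originally planned total sample size.
#' @param control_rate,intervention_rate assumed primary-event proportions.
#' @param power target power (0.80).
#' @param alpha_one_sided one-sided type-I error (0.025).
#' @param interim_event_triggers event counts triggering the interim looks
#'   (strictly increasing; default 50/100/150).
#' @param spending alpha-spending family: `"obrien_fleming"` or `"pocock"`.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(n_planned,
                        control_rate = 0.118,
                        intervention_rate = 0.090,
                        power = 0.80,
                        alpha_one_sided = 0.025,
                        interim_event_triggers = c(50L, 100L, 150L),
                        spending = c("obrien_fleming", "pocock")) {
  spending <- match.arg(spending)
  if (alpha_one_sided <= 0 || alpha_one_sided >= 0.5)
    stopf("alpha_one_sided must be in (0, 0.5)")
  if (any(diff(interim_event_triggers) <= 0))
    stopf("interim event triggers must be strictly increasing")
  if (control_rate <= 0 || control_rate >= 1 ||
      intervention_rate <= 0 || intervention_rate >= 1)
    stopf("event rates must be in (0, 1)")
  structure(list(n_planned = as.integer(n_planned),
                 control_rate = control_rate,
                 intervention_rate = intervention_rate,
                 power = power, alpha_one_sided = alpha_one_sided,
                 interim_event_triggers = as.integer(interim_event_triggers),
                 n_looks = length(interim_event_triggers) + 1L,
                 spending = spending),
            class = "design_spec")
}

#' Calendar times of the interim analyses
#'
#' The k-th interim occurs on the calendar day (accrual time + follow-up
#' time) of the trigger-k-th primary outcome event in `ds`.
#'
#' @param ds the reference [trial_dataset()] (the original candidate pool).
#' @param triggers increasing event counts (default from the design).
#' @return numeric vector of calendar days, one per trigger.
#' @export
interim_calendar_times <- function(ds, triggers = c(50L, 100L, 150L)) {
  ev <- ds$data$primary_event == 1L
  cal <- sort(ds$data$accrual_time[ev] + ds$data$primary_time[ev])
  if (length(cal) < max(triggers))
    stopf("only %d events observed; cannot reach trigger %d",
          length(cal), max(triggers))
  cal[triggers]
}

# alpha-spending functions (one-sided alpha), t in (0, 1]
spending_value <- function(spending, alpha, t) {
  switch(spending,
         obrien_fleming = 2 - 2 * pnorm(qnorm(1 - alpha / 2) / sqrt(t)),
         pocock = alpha * log(1 + (exp(1) - 1) * t),
         stopf("unknown spending function '%s'", spending))
}

#' Alpha-spending efficacy boundaries
#'
#' Computes one-sided group-sequential efficacy boundaries for the given
#' information fractions under the Lan-DeMets alpha-spending approach, with
#' the O'Brien-Fleming-type spending function
#' `f(t) = 2 - 2*Phi(z_{1-alpha/2}/sqrt(t))` or the Pocock-type
#' `f(t) = alpha*ln(1 + (e-1)t)`. The joint law of the sequential z
#' statistics (correlation `sqrt(t_i/t_j)`) is handled by grid-based
#' recursive numerical integration of the score-process density.
#'
#' @param spec a [design_spec()].
#' @param information_fractions increasing fractions in (0, 1], one per look.
#' @param grid_step integration grid step (score scale).
#' @return data frame with `look`, `fraction`, `boundary_z`, `alpha_spent`
#'   (cumulative) and `alpha_increment`.
#' @export
spending_boundaries <- function(spec, information_fractions,
                                grid_step = 0.01) {
  t <- information_fractions
  if (any(t <= 0) || any(t > 1) || any(diff(t) <= 0))
    stopf("information fractions must be increasing and in (0, 1]")
  alpha <- spec$alpha_one_sided
  K <- length(t)
  cum <- spending_value(spec$spending, alpha, t)
  cum[K] <- if (t[K] == 1) alpha else cum[K]
  inc <- diff(c(0, cum))

  # score-scale grid: S_k = Z_k * sqrt(t_k), S_1 ~ N(0, t1),
  # S_k | S_{k-1} ~ N(S_{k-1}, t_k - t_{k-1}). The density is carried as
  # midpoint-cell masses so truncation at a boundary can split the
  # straddling cell fractionally (keeps the root search smooth in b).
  h <- grid_step
  s <- seq(-9, 9, by = h)
  ns <- length(s)
  cell_tail <- function(mass, cut) {
    # total mass above `cut` under the midpoint-cell representation
    upper <- s + h / 2
    frac <- pmin(pmax((upper - cut) / h, 0), 1)
    sum(mass * frac)
  }
  cell_truncate <- function(mass, cut) {
    # keep mass below `cut` (the continue region)
    upper <- s + h / 2
    frac <- pmin(pmax((upper - cut) / h, 0), 1)
    mass * (1 - frac)
  }
  bounds <- numeric(K)
  bounds[1] <- qnorm(1 - inc[1])  # look 1 in closed form
  mass <- dnorm(s, sd = sqrt(t[1])) * h
  if (K > 1) {
    for (k in 2:K) {
      g <- cell_truncate(mass, bounds[k - 1] * sqrt(t[k - 1]))
      sdk <- sqrt(t[k] - t[k - 1])
      kern <- dnorm(seq(-(ns - 1), ns - 1) * h, sd = sdk) * h
      full <- stats::convolve(g, rev(kern), type = "open")
      mass <- full[ns:(2 * ns - 1)]  # aligned back onto s
      bounds[k] <- uniroot(function(b) cell_tail(mass, b * sqrt(t[k])) - inc[k],
                           c(0.5, 9), tol = 1e-10)$root
    }
  }
  data.frame(look = seq_len(K), fraction = t, boundary_z = bounds,
             alpha_spent = cum, alpha_increment = inc)
}

#' Required sample size from the Schoenfeld events formula
#'
#' Events `D = 4 * (z_{1-alpha} + z_{1-power})^2 / log(hr)^2` for a 1:1
#' two-arm comparison, converted to a total sample size via the average
#' event probability across arms; the intervention-arm event probability is
#' derived from the control rate under proportional hazards,
#' `p_i = 1 - (1 - p_c)^hr`.
#'
#' @param spec a [design_spec()].
#' @param hr_assumed hazard ratio under the alternative, in (0, 1).
#' @param event_rate_control control-arm event proportion (defaults to the
#'   design's).
#' @return list with `d_required` (events) and `n_required` (total N,
#'   rounded up to an even count).
#' @export
required_sample <- function(spec, hr_assumed,
                            event_rate_control = spec$control_rate) {
  if (hr_assumed <= 0) stopf("hr_assumed must be positive")
  if (hr_assumed == 1) return(list(d_required = Inf, n_required = Inf))
  za <- qnorm(1 - spec$alpha_one_sided)
  zb <- qnorm(spec$power)
  d <- 4 * (za + zb)^2 / log(hr_assumed)^2
  p_c <- event_rate_control
  p_i <- 1 - (1 - p_c)^hr_assumed
  pbar <- (p_c + p_i) / 2
  n <- 2 * ceiling(ceiling(d) / pbar / 2)
  list(d_required = ceiling(d), n_required = n)
}

#' Heterogeneity gate: interaction test on predicted-benefit subgroups
#'
#' Dichotomizes the test population on predicted benefit and tests the
#' treatment-by-subgroup interaction in a Cox model on follow-up censored at
#' the interim cut. The default cutpoint is the prespecified median of the
#' predictions (calibrated at the stated threshold); `cutpoint = "scan"`
#' scans the prediction deciles between the 20th and 80th percentiles and
#' takes the cut minimizing the interaction p value (anti-conservative,
#' provided for sensitivity analyses). The gate passes when the interaction
#' p value is below `threshold` (default 0.2); the minor subgroup always
#' holds at least `min_share` of the population.
#'
#' @param test_ds test-half [trial_dataset()].
#' @param predictions named predicted log HRs covering every test participant.
#' @param interim_cut calendar day of the interim analysis.
#' @param threshold interaction p-value threshold (0.2).
#' @param min_share minimum minor-subgroup share (0.2).
#' @param cutpoint `"median"` (default) or `"scan"`.
#' @return list of class `heterogeneity_gate`: `interaction_p`,
#'   `gate_passed`, `cut_value`, `benefit_ids` (predicted-benefit subgroup,
#'   i.e. predictions below the cut), `hr_benefit`, `hr_other`.
#' @export
heterogeneity_gate <- function(test_ds, predictions, interim_cut,
                               threshold = 0.2, min_share = 0.2,
                               cutpoint = c("median", "scan")) {
  cutpoint <- match.arg(cutpoint)
  cens <- censor_at(test_ds, interim_cut)
  pred <- predictions[cens$data$id]
  if (anyNA(pred)) stopf("predictions must cover every test participant")
  fail <- list(interaction_p = NA_real_, gate_passed = FALSE,
               cut_value = NA_real_, benefit_ids = character(),
               hr_benefit = NA_real_, hr_other = NA_real_)
  class(fail) <- "heterogeneity_gate"
  if (length(unique(pred)) < 2) return(fail)  # constant: no valid dichotomy

  probe <- function(cut_value, strict = TRUE) {
    # 1 = predicted benefit (low predicted log HR); with heavily tied
    # predictions the <= variant can be the only valid dichotomy
    grp <- if (strict) as.integer(pred < cut_value)
           else as.integer(pred <= cut_value)
    share <- mean(grp)
    if (share < min_share || share > 1 - min_share) return(NULL)
    d <- data.frame(time = cens$data$primary_time,
                    event = cens$data$primary_event,
                    trt = as.numeric(cens$data$arm == "intervention"),
                    grp = grp)
    ev <- with(d, tapply(event, interaction(trt, grp), sum))
    if (anyNA(ev) || any(ev == 0)) return(NULL)  # empty arm-by-subgroup cell
    fit <- tryCatch(suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ trt * grp, data = d,
                      ties = "breslow")), error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit))) return(NULL)
    z <- coef(fit)["trt:grp"] / sqrt(diag(vcov(fit))["trt:grp"])
    hr_b <- exp(sum(coef(fit)[c("trt", "trt:grp")]))
    hr_o <- exp(coef(fit)[["trt"]])
    list(p = unname(2 * pnorm(-abs(z))), cut_value = cut_value,
         hr_benefit = hr_b, hr_other = hr_o, grp = grp)
  }

  if (cutpoint == "median") {
    # prespecified split: of the two tie-handling variants, keep the valid
    # one with group shares closest to 1:1 (chosen on shares, never on p)
    cands <- Filter(Negate(is.null),
                    list(probe(median(pred), strict = TRUE),
                         probe(median(pred), strict = FALSE)))
    if (!length(cands)) return(fail)
    shares <- vapply(cands, function(r) abs(mean(r$grp) - 0.5), numeric(1))
    best <- cands[[which.min(shares)]]
  } else {
    cuts <- unique(quantile(pred, seq(0.2, 0.8, by = 0.1), type = 7))
    results <- Filter(Negate(is.null), lapply(cuts, probe))
    if (!length(results)) return(fail)
    best <- results[[which.min(vapply(results, `[[`, numeric(1), "p"))]]
  }
  out <- list(interaction_p = best$p, gate_passed = best$p < threshold,
              cut_value = best$cut_value,
              benefit_ids = cens$data$id[best$grp == 1],
              hr_benefit = best$hr_benefit, hr_other = best$hr_other)
  class(out) <- "heterogeneity_gate"
  out
}

#' Enrichment-aware sample-size revision
#'
#' For each enrichment level `q` in the grid (enroll the top-q fraction of
#' future candidates by predicted benefit), projects the final-population
#' effect size as the event-weighted blend of (a) the observed log HR in the
#' already-enrolled cohort and (b) the test-set log HR among the top-q
#' predicted responders (standing in for future enrollees), recomputes the
#' Schoenfeld sample size at the design's power and alpha, keeps levels
#' whose required N does not exceed the planned N, and returns the level
#' minimizing the required N.
#'
#' @param spec a [design_spec()].
#' @param enrolled_ds already-enrolled cohort, censored at the interim cut
#'   internally.
#' @param test_ds test-half dataset used to estimate subgroup effects.
#' @param predictions named predicted log HRs for the test participants.
#' @param interim_cut calendar day of the interim analysis.
#' @param q_grid enrichment levels (default 0.50 to 0.95 by 0.05).
#' @return `NULL` when no level is adequately powered at or below the
#'   planned size; otherwise list with `q_chosen`, `n_revised`,
#'   `hr_projected`, and the per-level table `grid`.
#' @export
revise_under_enrichment <- function(spec, enrolled_ds, test_ds, predictions,
                                    interim_cut,
                                    q_grid = seq(0.50, 0.95, by = 0.05)) {
  enr <- censor_at(enrolled_ds, interim_cut)
  fit_enr <- weighted_cox(enr$data$primary_time, enr$data$primary_event,
                          enr$data$arm)
  if (!fit_enr$converged) return(NULL)
  d_enr <- sum(enr$data$primary_event)
  n_enr <- n_participants(enr)

  cens <- censor_at(test_ds, interim_cut)
  pred <- predictions[cens$data$id]
  if (anyNA(pred)) stopf("predictions must cover every test participant")

  rows <- lapply(q_grid, function(q) {
    cut_q <- quantile(pred, q, type = 7)
    sub <- cens$data[pred <= cut_q, , drop = FALSE]
    if (!all(table(factor(sub$arm, ARM_LEVELS)) > 0)) return(NULL)
    if (sum(sub$primary_event) < 2) return(NULL)
    fit_q <- tryCatch(weighted_cox(sub$primary_time, sub$primary_event,
                                   sub$arm), error = function(e) NULL)
    if (is.null(fit_q) || !fit_q$converged) return(NULL)
    # expected events among future enrollees at the subgroup's effect size
    n_future <- max(spec$n_planned - n_enr, 0)
    p_c <- spec$control_rate
    p_i <- 1 - (1 - p_c)^exp(fit_q$loghr)
    d_future <- n_future * (p_c + p_i) / 2
    loghr_proj <- (d_enr * fit_enr$loghr + d_future * fit_q$loghr) /
      max(d_enr + d_future, 1e-12)
    hr_proj <- exp(loghr_proj)
    if (hr_proj >= 1) return(NULL)
    req <- required_sample(spec, hr_proj)
    data.frame(q = q, hr_subgroup = exp(fit_q$loghr), hr_projected = hr_proj,
               n_required = req$n_required)
  })
  grid <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(grid) || nrow(grid) == 0) return(NULL)
  ok <- grid[grid$n_required <= spec$n_planned, , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  best <- ok[which.min(ok$n_required), ]
  list(q_chosen = best$q, n_revised = best$n_required,
       hr_projected = best$hr_projected, grid = grid)
}
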
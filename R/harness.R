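# End-to-end harness: one group-sequential adaptive trial run (period 1
# enrolls everyone; each interim learns a fresh benefit signature and, when
# the heterogeneity gate and the revised power calculation allow, enriches
# the next period's enrollment), and the repeated experiment with its
# covariate-shuffling negative control.

#' Run one adaptive predictively-enriched trial simulation
#'
#' The candidate pool `ds_candidates` plays the role of the original trial:
#' its participants arrive at their accrual times, interim analyses occur at
#' the calendar times of the design's event triggers within the pool, and
#' the final analysis at the calendar time of the pool's last primary event.
#' Period 1 enrolls every arrival. At each interim, the enrolled cohort is
#' split 50:50, a fresh benefit signature is learned on the training half
#' ([learn_benefit()]), and the test half drives the heterogeneity gate and
#' the enrichment-aware sample-size revision; when both allow enrichment,
#' the next period's arrivals are sampled at level `q` with squared-sigmoid
#' weights on predicted benefit. Treatment assignment is never modified.
#'
#' @param ds_candidates [trial_dataset()] covering the full accrual window.
#' @param spec a [design_spec()].
#' @param seed integer run seed (fans out to per-stage seeds).
#' @param enrich set `FALSE` to disable all learning/enrichment (the run
#'   then reproduces the all-comers analysis exactly).
#' @param cutpoint heterogeneity-gate cutpoint rule (see
#'   [heterogeneity_gate()]).
#' @param min_events,n_draws,n_boruta_iter passed to [learn_benefit()].
#' @param strata covariate names for the final composition table.
#' @param compute_win_ratio compute the hierarchical win ratio per look.
#' @param on_stage_error `"fallback"` (default): a failed learning stage at
#'   an interim is logged and that period continues without enrichment;
#'   `"abort"`: any stage failure aborts the run.
#' @return object of class `simulation_result`.
#' @export
run_adaptive_trial <- function(ds_candidates, spec, seed = 1L, enrich = TRUE,
                               cutpoint = c("median", "scan"),
                               min_events = 5, n_draws = 25L,
                               n_boruta_iter = 20L,
                               strata = character(),
                               compute_win_ratio = TRUE,
                               on_stage_error = c("fallback", "abort")) {
  cutpoint <- match.arg(cutpoint)
  on_stage_error <- match.arg(on_stage_error)
  stopifnot(inherits(spec, "design_spec"))
  cuts <- interim_calendar_times(ds_candidates, spec$interim_event_triggers)
  ev <- ds_candidates$data$primary_event == 1L
  t_final <- max(ds_candidates$data$accrual_time[ev] +
                   ds_candidates$data$primary_time[ev])
  d_total <- sum(ev)
  fractions <- c(spec$interim_event_triggers, d_total) / d_total
  boundaries <- spending_boundaries(spec, fractions)

  period_start <- c(0, cuts)
  period_end <- c(cuts, Inf)
  n_periods <- length(period_start)
  arrivals <- lapply(seq_len(n_periods), function(k) {
    ds_candidates$data$id[ds_candidates$data$accrual_time > period_start[k] &
                            ds_candidates$data$accrual_time <= period_end[k]]
  })

  enrolled <- arrivals[[1]]
  decisions <- list()
  enrichment_active <- logical(n_periods)

  for (k in seq_along(cuts)) {
    ds_enr <- subset_trial(ds_candidates, enrolled)
    interim_fit <- primary_cox_hr(ds_enr, cut = cuts[k])
    interim_z <- -interim_fit$loghr / interim_fit$se
    dec <- list(look_index = k, calendar_time = cuts[k],
                boundary_z = boundaries$boundary_z[k],
                interim_z = interim_z,
                events = interim_fit$events, n_enrolled = length(enrolled),
                interaction_p = NA_real_, gate_passed = FALSE,
                q_chosen = NA_real_, n_revised = NA_real_,
                enrich = FALSE, stage_error = NA_character_)
    if (enrich) {
      stage <- "learn_benefit"
      res <- tryCatch({
        pl <- learn_benefit(ds_enr, cuts[k],
                            seed = stage_seed(seed, "interim", k),
                            min_events = min_events, n_draws = n_draws,
                            n_boruta_iter = n_boruta_iter)
        if (is.null(pl$model)) list(pl = pl, gate = NULL, rev = NULL)
        else {
          stage <- "heterogeneity_gate"
          preds <- predict(pl)
          gate <- heterogeneity_gate(pl$test, preds, cuts[k],
                                     cutpoint = cutpoint)
          rev <- NULL
          if (gate$gate_passed) {
            stage <- "revise_under_enrichment"
            rev <- revise_under_enrichment(spec, ds_enr, pl$test, preds,
                                           cuts[k])
          }
          list(pl = pl, gate = gate, rev = rev)
        }
      }, error = function(e) {
        if (on_stage_error == "abort")
          stopf("stage '%s' failed at look %d: %s", stage, k,
                conditionMessage(e))
        structure(list(stage = stage, message = conditionMessage(e)),
                  class = "stage_error")
      })
      if (inherits(res, "stage_error")) {
        dec$stage_error <- sprintf("%s: %s", res$stage, res$message)
      } else {
        if (!is.null(res$gate)) {
          dec$interaction_p <- res$gate$interaction_p
          dec$gate_passed <- res$gate$gate_passed
        }
        if (!is.null(res$rev)) {
          dec$q_chosen <- res$rev$q_chosen
          dec$n_revised <- res$rev$n_revised
          dec$enrich <- TRUE
        }
      }
      if (dec$enrich) {
        cand_ids <- arrivals[[k + 1]]
        if (length(cand_ids) >= 2) {
          cand_ds <- subset_trial(ds_candidates, cand_ids)
          pred_cand <- predict(res$pl, newdata = cand_ds)
          x <- benefit_to_x(pred_cand)
          z <- responder_ratio(predict(res$pl))
          p <- enrollment_probability(x, z)
          new_ids <- sample_period_candidates(cand_ids, p, dec$q_chosen,
                                              stage_seed(seed, "sample", k))
          enrolled <- c(enrolled, new_ids)
          enrichment_active[k + 1] <- TRUE
        } else {
          enrolled <- c(enrolled, cand_ids)
        }
      } else {
        enrolled <- c(enrolled, arrivals[[k + 1]])
      }
    } else {
      enrolled <- c(enrolled, arrivals[[k + 1]])
    }
    decisions[[k]] <- dec
  }

  ds_final <- subset_trial(ds_candidates, enrolled)
  final_fit <- primary_cox_hr(ds_final)
  look_times <- c(cuts, t_final)
  event_counts <- vapply(look_times, function(ct)
    sum(censor_at(ds_final, ct)$data$primary_event), numeric(1))
  wr_by_look <- NULL
  if (compute_win_ratio && ds_final$n_safety >= 1) {
    wr_by_look <- lapply(look_times, function(ct)
      tryCatch(win_ratio(ds_final, cut = ct), error = function(e) NULL))
  }
  comp <- balance_and_composition(ds_final, ds_candidates, strata = strata)

  structure(list(run_seed = as.integer(seed), decisions = decisions,
                 interim_cuts = cuts, t_final = t_final,
                 boundaries = boundaries,
                 final_n = length(enrolled), final_ids = enrolled,
                 final_hr = final_fit$hr, final_p = final_fit$p,
                 event_counts = event_counts, win_ratio = wr_by_look,
                 arm_balance_p = comp$arm_p, demographics = comp$shares,
                 enrichment_active_periods = which(enrichment_active)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> seed %d: final N %d, HR %.3f, p %.4f\n",
              x$run_seed, x$final_n, x$final_hr, x$final_p))
  for (d in x$decisions) {
    cat(sprintf("  look %d (day %.0f, %d events): gate p %s -> %s\n",
                d$look_index, d$calendar_time, d$events,
                ifelse(is.na(d$interaction_p), "NA",
                       sprintf("%.3f", d$interaction_p)),
                if (d$enrich) sprintf("enrich q=%.2f (N revised %d)",
                                      d$q_chosen, d$n_revised)
                else "standard enrollment"))
  }
  invisible(x)
}

#' Run the repeated adaptive experiment with its negative control
#'
#' Executes `r` independent adaptive runs on the candidate pool (and, when
#' `negative_control` is `TRUE`, `r` runs on covariate-shuffled copies, the
#' shuffled-covariate negative control preserving the average treatment effect but
#' destroying covariate-linked heterogeneity), and summarizes final sample
#' sizes, hazard ratios and p values against the all-comers reference
#' analysis of the same pool.
#'
#' @param ds a [trial_dataset()] candidate pool.
#' @param spec a [design_spec()].
#' @param r number of repeats (design default: 10).
#' @param seed integer master seed.
#' @param negative_control run the shuffled-covariate control arm.
#' @param ... passed to [run_adaptive_trial()].
#' @return object of class `experiment_result`: `runs`, `negative_runs`,
#'   `reference` (all-comers), `summary`, `summary_negative`.
#' @export
run_experiment <- function(ds, spec, r = 10L, seed = 1L,
                           negative_control = TRUE, ...) {
  if (r < 1) stopf("r must be >= 1")
  ref_fit <- primary_cox_hr(ds)
  reference <- list(final_n = n_participants(ds), final_hr = ref_fit$hr,
                    final_p = ref_fit$p)
  runs <- lapply(seq_len(r), function(i)
    run_adaptive_trial(ds, spec, seed = stage_seed(seed, "run", i), ...))
  negative_runs <- NULL
  if (negative_control) {
    negative_runs <- lapply(seq_len(r), function(i) {
      shuf <- shuffle_covariates(ds, stage_seed(seed, "shuffle", i))
      run_adaptive_trial(shuf, spec, seed = stage_seed(seed, "negrun", i), ...)
    })
  }
  summarize_set <- function(rs) {
    if (is.null(rs) || length(rs) < 2) return(NULL)
    list(final_n = summarize_runs(vapply(rs, `[[`, numeric(1), "final_n"),
                                  reference$final_n, alternative = "less"),
         final_hr = summarize_runs(vapply(rs, `[[`, numeric(1), "final_hr"),
                                   reference$final_hr),
         final_p = summarize_runs(vapply(rs, `[[`, numeric(1), "final_p"),
                                  reference$final_p))
  }
  structure(list(runs = runs, negative_runs = negative_runs,
                 reference = reference,
                 summary = summarize_set(runs),
                 summary_negative = summarize_set(negative_runs)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  r <- length(x$runs)
  cat(sprintf("<experiment_result> %d adaptive runs vs all-comers N = %d (HR %.3f)\n",
              r, x$reference$final_n, x$reference$final_hr))
  if (!is.null(x$summary)) {
    s <- x$summary
    cat(sprintf("  adaptive: final N %.1f +/- %.1f (one-sided p = %.4f), HR %.3f +/- %.3f\n",
                s$final_n$mean, s$final_n$sem, s$final_n$p,
                s$final_hr$mean, s$final_hr$sem))
  }
  if (!is.null(x$summary_negative)) {
    s <- x$summary_negative
    cat(sprintf("  negative control: final N %.1f +/- %.1f (one-sided p = %.4f)\n",
                s$final_n$mean, s$final_n$sem, s$final_n$p))
  }
  invisible(x)
}
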
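# Synthetic two-arm RCT generator with known ground-truth average and
# heterogeneous treatment effects (the parameter-recovery oracle for every
# downstream stage), plus the covariate-shuffling negative control.

#' Configuration for the synthetic trial generator
#'
#' Defaults emulate an IRIS-like cardiovascular outcome trial: ~4000
#' participants accrued uniformly over 2899 days, a control-arm primary-event
#' proportion of 11.8% at a 5-year (1825-day) per-participant follow-up
#' horizon, and an average treatment hazard ratio of 0.76. Event times are
#' exponential (constant hazard), with the individual log hazard
#' `log(lambda0) + arm * (ate_loghr + sum(hte_coeffs * x))`, administrative
#' censoring at the horizon and an optional light random-censoring hazard.
#'
#' @param n_total number of participants.
#' @param accrual_days accrual window (uniform arrivals on `[0, accrual_days]`).
#' @param horizon_days per-participant administrative follow-up horizon.
#' @param n_continuous,n_binary,n_categorical covariate counts. Continuous
#'   covariates are standard normal, binary are Bernoulli with success
#'   probabilities drawn once from `[0.2, 0.5]`, categorical are uniform over
#'   3 levels.
#' @param control_rate control-arm event proportion at the horizon (0,1).
#' @param ate_loghr average treatment effect on the log-hazard scale
#'   (negative = intervention benefit).
#' @param hte_features character vector of covariate names carrying a
#'   treatment interaction (subset of the generated covariate names
#'   `x1..`, `b1..`, `c1..`).
#' @param hte_coeffs numeric interaction log-HR coefficients, one per
#'   `hte_features` entry (for categorical features the coefficient applies
#'   to an indicator of the first level).
#' @param censor_rate random-censoring hazard as a fraction of the baseline
#'   event hazard (0 disables random censoring).
#' @param missing_frac MCAR missingness fraction per covariate, in [0, 0.5].
#' @param corr optional equicorrelation of the latent Gaussian copula used
#'   for the continuous block (0 = independent).
#' @param n_safety number of hierarchical safety tiers to generate (tier 1 =
#'   all-cause mortality analog, rarer than the primary outcome).
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_total = 4000L,
                             accrual_days = 2899,
                             horizon_days = 1825,
                             n_continuous = 10L,
                             n_binary = 8L,
                             n_categorical = 2L,
                             control_rate = 0.118,
                             ate_loghr = log(0.76),
                             hte_features = character(),
                             hte_coeffs = numeric(),
                             censor_rate = 0.1,
                             missing_frac = 0.02,
                             corr = 0,
                             n_safety = 2L,
                             seed = 1L) {
  if (control_rate <= 0 || control_rate >= 1)
    stopf("control_rate must be strictly inside (0, 1)")
  if (missing_frac < 0 || missing_frac > 0.5)
    stopf("missing_frac must be in [0, 0.5]")
  if (length(hte_features) != length(hte_coeffs))
    stopf("hte_features and hte_coeffs lengths differ")
  cfg <- list(n_total = as.integer(n_total), accrual_days = accrual_days,
              horizon_days = horizon_days,
              n_continuous = as.integer(n_continuous),
              n_binary = as.integer(n_binary),
              n_categorical = as.integer(n_categorical),
              control_rate = control_rate, ate_loghr = ate_loghr,
              hte_features = as.character(hte_features),
              hte_coeffs = as.numeric(hte_coeffs),
              censor_rate = censor_rate, missing_frac = missing_frac,
              corr = corr, n_safety = as.integer(n_safety),
              seed = as.integer(seed))
  nms <- synthetic_covariate_names(cfg)
  bad <- setdiff(cfg$hte_features, nms)
  if (length(bad)) stopf("hte_features not among generated covariates: %s",
                         paste(bad, collapse = ", "))
  class(cfg) <- "synthetic_config"
  cfg
}

synthetic_covariate_names <- function(cfg) {
  c(if (cfg$n_continuous) paste0("x", seq_len(cfg$n_continuous)),
    if (cfg$n_binary) paste0("b", seq_len(cfg$n_binary)),
    if (cfg$n_categorical) paste0("c", seq_len(cfg$n_categorical)))
}

#' Schema of a synthetic trial
#' @param cfg a [synthetic_config()].
#' @return the [covariate_schema()] of datasets produced by [generate_trial()].
#' @export
synthetic_schema <- function(cfg) {
  nms <- synthetic_covariate_names(cfg)
  kinds <- c(rep("continuous", cfg$n_continuous), rep("binary", cfg$n_binary),
             rep("categorical", cfg$n_categorical))
  lv <- list()
  for (nm in nms[kinds == "categorical"]) lv[[nm]] <- c("A", "B", "C")
  covariate_schema(nms, kinds, lv)
}

# numeric value of a covariate as it enters the linear HTE term:
# continuous/binary as-is; categorical as indicator of its first level.
hte_design_value <- function(x) {
  if (is.factor(x)) as.numeric(x == levels(x)[1]) else as.numeric(x)
}

#' Generate a synthetic two-arm randomized trial
#'
#' 1:1 randomized arms; exponential primary-event times with individual
#' log hazard `baseline + arm * (ate_loghr + sum(hte_coeffs * x_hte))`;
#' administrative censoring at the horizon, optional random censoring;
#' uniform accrual; MCAR missingness injected after outcomes are generated.
#' The complete (pre-missingness) covariates and the true per-participant
#' log HR are attached as the `"truth"` attribute for recovery oracles.
#'
#' @param cfg a [synthetic_config()].
#' @return a [trial_dataset()] with a `"truth"` attribute.
#' @export
generate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_total
    schema <- synthetic_schema(cfg)
    lambda0 <- -log(1 - cfg$control_rate) / cfg$horizon_days

    covs <- list()
    if (cfg$n_continuous > 0) {
      if (cfg$corr > 0) {
        z <- matrix(rnorm(n * cfg$n_continuous), n)
        shared <- rnorm(n)
        z <- sqrt(1 - cfg$corr) * z + sqrt(cfg$corr) * shared
      } else z <- matrix(rnorm(n * cfg$n_continuous), n)
      for (j in seq_len(cfg$n_continuous)) covs[[paste0("x", j)]] <- z[, j]
    }
    if (cfg$n_binary > 0) {
      pb <- runif(cfg$n_binary, 0.2, 0.5)
      # planted interaction features are balanced: the canonical
      # single-binary-HTE world has carrier prevalence 1/2
      pb[paste0("b", seq_len(cfg$n_binary)) %in% cfg$hte_features] <- 0.5
      for (j in seq_len(cfg$n_binary))
        covs[[paste0("b", j)]] <- rbinom(n, 1, pb[j])
    }
    if (cfg$n_categorical > 0) {
      for (j in seq_len(cfg$n_categorical))
        covs[[paste0("c", j)]] <- factor(sample(c("A", "B", "C"), n, TRUE),
                                         levels = c("A", "B", "C"))
    }
    cf <- as.data.frame(covs, stringsAsFactors = FALSE)

    arm <- sample(rep(ARM_LEVELS, length.out = n))
    trt <- as.numeric(arm == "intervention")

    eta <- rep(cfg$ate_loghr, n)
    for (k in seq_along(cfg$hte_features))
      eta <- eta + cfg$hte_coeffs[k] * hte_design_value(cf[[cfg$hte_features[k]]])
    rate <- lambda0 * exp(trt * eta)

    gen_outcome <- function(rate_i) {
      t_event <- rexp(n, rate_i)
      t_cens <- if (cfg$censor_rate > 0)
        rexp(n, cfg$censor_rate * lambda0) else rep(Inf, n)
      time <- pmin(t_event, t_cens, cfg$horizon_days)
      list(time = pmax(time, 1e-8),
           event = as.integer(t_event <= pmin(t_cens, cfg$horizon_days)))
    }
    prim <- gen_outcome(rate)

    d <- data.frame(id = sprintf("P%05d", seq_len(n)), arm = arm,
                    accrual_time = runif(n, 0, cfg$accrual_days),
                    primary_time = prim$time, primary_event = prim$event,
                    stringsAsFactors = FALSE)
    # hierarchical safety tiers: tier 1 (mortality analog) rarer, same ATE
    # direction; lower tiers progressively more frequent, null effect.
    for (k in seq_len(cfg$n_safety)) {
      mult <- if (k == 1) 0.4 else 0.8 * k
      eff <- if (k == 1) exp(trt * cfg$ate_loghr) else 1
      sk <- gen_outcome(lambda0 * mult * eff)
      d[[sprintf("safety_%d_time", k)]] <- sk$time
      d[[sprintf("safety_%d_event", k)]] <- sk$event
    }

    truth_cov <- cf
    if (cfg$missing_frac > 0) {
      for (nm in names(cf)) {
        hide <- runif(n) < cfg$missing_frac
        cf[[nm]][hide] <- NA
      }
    }
    d <- cbind(d, cf)
    ds <- trial_dataset(d, schema)
    attr(ds, "truth") <- list(covariates = truth_cov, loghr = eta,
                              lambda0 = lambda0)
    ds
  })
}

#' Ground-truth individualized log hazard ratio
#'
#' Returns `ate_loghr + sum(hte_coeffs * x_hte)` per participant, using the
#' pre-missingness covariate values stored by [generate_trial()] when
#' available; errors if an HTE feature value is missing and no stored truth
#' exists.
#'
#' @param cfg the [synthetic_config()] that generated `ds`.
#' @param ds the generated [trial_dataset()].
#' @return named numeric vector of true log HRs (names = participant ids).
#' @export
true_individual_loghr <- function(cfg, ds) {
  truth <- attr(ds, "truth")
  cf <- if (!is.null(truth)) truth$covariates[match(ds$data$id, sprintf("P%05d", seq_len(cfg$n_total))), , drop = FALSE]
        else covariate_frame(ds)
  eta <- rep(cfg$ate_loghr, nrow(ds$data))
  for (k in seq_along(cfg$hte_features)) {
    v <- hte_design_value(cf[[cfg$hte_features[k]]])
    if (anyNA(v)) stopf("HTE feature '%s' has missing values and no stored truth",
                        cfg$hte_features[k])
    eta <- eta + cfg$hte_coeffs[k] * v
  }
  setNames(eta, ds$data$id)
}

#' Negative control: shuffle baseline covariates across participants
#'
#' Permutes whole covariate rows across participants while leaving arm,
#' accrual and all outcomes untouched. Marginal covariate distributions and
#' the average treatment effect are preserved; covariate-outcome links (and
#' hence any covariate-driven treatment-effect heterogeneity) are destroyed.
#'
#' @param ds a [trial_dataset()].
#' @param seed integer seed.
#' @return a `trial_dataset` with permuted covariate rows.
#' @export
shuffle_covariates <- function(ds, seed) {
  n <- n_participants(ds)
  if (n == 0) stopf("empty dataset")
  perm <- with_seed(seed, sample.int(n))
  out <- ds
  for (nm in ds$schema$name) out$data[[nm]] <- ds$data[[nm]][perm]
  attr(out, "truth") <- NULL
  out
}
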
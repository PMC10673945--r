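---
title: "Phenomapping-guided adaptive predictive enrichment: models, parameters, and design choices"
author: "phenotrial authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomapping-guided adaptive predictive enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large outcome-driven randomized clinical trials are expensive chiefly because
of the number of participants needed to demonstrate a treatment effect. If
the relative benefit of an intervention varies across patient phenotypes,
a trial that preferentially enrolls the patients most likely to benefit
(*predictive enrichment*, as opposed to *prognostic* enrichment on absolute
risk) can reach the same statistical conclusion with fewer participants.
`phenotrial` implements a complete, testable simulation of one such strategy:
at each planned interim analysis of a group-sequential design, the accrued
population is used to *learn* a phenotypic signature of individualized
benefit, and — if prespecified evidence and power conditions are met — the
probability of enrolling each subsequent candidate is conditioned on their
predicted benefit, while treatment assignment itself stays 1:1 randomized
throughout.

## The estimation pipeline at an interim analysis

`learn_benefit()` is the package's core fitting function. Given the enrolled
cohort and the interim calendar day it performs, on the training half of a
50:50 split:

1. **Preprocessing** (`fit_preprocess()`), fitted on training rows only to
   avoid leakage: covariates with more than 10% missingness are dropped;
   continuous pairs with |Pearson r| > 0.9 are resolved by dropping the
   member with the largest mean absolute correlation (recomputed after each
   drop); continuous covariates are winsorized at their 2.5th/97.5th
   percentiles; zero-variance factors are dropped; remaining missing values
   are filled by an iterative round-robin imputer with bagged
   random-forest base learners (at most 5 rounds, seeded); categorical
   covariates are one-hot encoded (reference-free — the downstream learner
   is tree-based, so no reference level is needed).
2. **Phenomap** (`gower_matrix()`): the pairwise Gower dissimilarity over
   the winsorized, imputed covariates on their original scales and levels
   (not the one-hot columns, which would inflate the weight of categorical
   features). Continuous features contribute |x_i − x_j| / range with the
   range taken in the analysis subset; categorical features contribute the
   mismatch indicator; the distance is the unweighted mean. A zero-range
   continuous feature carries no information at this interim and is
   excluded from the mean with a warning.
3. **Individualized effects** (`individualized_loghr()`): for each index
   participant, every participant is weighted by
   w = max(0, (1 − d)³) — a cubic decay of Gower similarity with a ReLU
   guard that is mathematically redundant for d ∈ [0, 1] and retained only
   against numeric noise — and a weighted Cox model with the treatment arm
   as the sole covariate (Breslow ties, case weights in the partial
   likelihood) is fitted on follow-up censored at the interim day. The
   fitted log hazard ratio is that participant's individualized benefit
   label. Fits with fewer than 5 weighted events, or with monotone
   likelihood (no events in one arm of the weighted neighborhood), yield a
   missing label that is dropped rather than clipped: fabricating a value
   would bias the regressor, and the later label winsorization already
   tames legitimate outliers.
4. **Benefit model** (`boruta_shap_select()`, `fit_benefit_model()`): labels
   are 95%-winsorized, then an all-relevant feature selection is run for 20
   iterations: each iteration permutes every feature into a "shadow" copy,
   fits the gradient-boosted regressor on the concatenated matrix, and
   counts a hit for each real feature whose mean absolute path attribution
   exceeds the best shadow feature's. Features with hit counts above the
   Binomial(20, ½) null at the two-sided 0.05 level are kept. The final
   regressor is tuned by 25 random draws (without replacement) from the
   grid {learning rate 0.01–0.15} × {depth 3–20} × {row subsample 0.5–1} ×
   {per-tree and per-level feature fractions 0.4–1} × {100/500/1000 trees},
   each trained with early stopping (patience 20) on an inner 80/20
   validation split by RMSE, then refit on all rows at the best iteration.

The fitted object predicts an individualized log hazard ratio from raw
baseline covariates of any conforming dataset (`predict()`), binding
feature columns by name.

### Why a hand-rolled booster and path attributions

The target environment provides no gradient-boosting or tree package, so
`src/boosting.cpp` implements the standard second-order squared-loss
formulation (leaf weight −G/(H+λ), gain from the left/right/parent scores,
shrinkage, row and column subsampling, early stopping) with exact greedy
splits over presorted features. Feature importance inside the selection loop
is the mean absolute *path attribution* (the change in node value along each
prediction path, credited to the split feature and summed over trees). Like
Shapley-based tree attributions it is exact, deterministic, and additive —
the per-row attributions plus the root drift reconstruct the prediction
exactly, which the test suite asserts — and it needs no background dataset.

## The adaptive design

- **Looks**: three interim analyses at the calendar days when the candidate
  pool reaches its 50th, 100th and 150th primary event (configurable), and
  a final analysis when the pool's last primary event has occurred.
- **Boundaries** (`spending_boundaries()`): one-sided efficacy boundaries
  from Lan–DeMets alpha spending (O'Brien–Fleming-type
  f(t) = 2 − 2Φ(z₁₋α/₂/√t), or Pocock-type f(t) = α·ln(1+(e−1)t)), with the
  joint law of the sequential z statistics integrated by a grid recursion
  of the score-process density (FFT convolution; midpoint-cell masses so
  that truncation at a boundary splits the straddling cell fractionally).
  Information fractions are event fractions, the standard choice for
  survival designs. Boundaries are computed and logged at every look;
  stop-on-efficacy is off by default because the simulated experiment
  always proceeds to the final analysis, and there is no futility stopping.
- **Heterogeneity gate** (`heterogeneity_gate()`): the test half is split
  at the *median* predicted benefit and a Cox model with arm, subgroup and
  their interaction (censored at the interim) supplies the Wald interaction
  p value; the gate opens below 0.2. The deliberately liberal threshold
  reflects that only half the interim information is available for testing.
  A scanning variant (deciles between the 20th and 80th percentiles,
  minimum p) is available via `cutpoint = "scan"`, but it is *not* the
  default: selecting the minimizing cut inflates the type-I rate of the
  gate roughly two-fold, whereas the prespecified median split is calibrated
  — under a no-heterogeneity null it opens in ≈20% of simulations, which
  the acceptance suite verifies. With heavily tied predictions the median
  can coincide with a mass point; the gate then considers both the `<` and
  `≤` dichotomies and keeps the valid one with shares closest to 1:1 (the
  choice never looks at the p value). The minor subgroup must hold at least
  20% of the population.
- **Sample-size revision** (`revise_under_enrichment()`): for each
  enrichment level q ∈ {0.50, …, 0.95}, the package projects the final
  effect size as the event-weighted blend of (a) the observed log HR in the
  already-enrolled cohort and (b) the test-set log HR among the top-q
  predicted responders, standing in for future enrollees; expected future
  events use the control rate and the subgroup hazard ratio under
  proportional hazards. The Schoenfeld formula
  D = 4(z₁₋α + z₁₋β)²/ln(HR)² converts the projected effect into a required
  sample via the average event probability across arms. Levels whose
  required N exceeds the planned N are discarded; the accepted level with
  the smallest required N wins, and if none is accepted the period proceeds
  with standard enrollment. The blend is this package's explicit reading of
  "revising the expected effect size under the assumption of predictive
  enrichment", which the source design leaves unformalized; subgroup
  uncertainty enters through point estimates only.
- **Enrichment** (`benefit_to_x()`, `enrollment_probability()`,
  `sample_period_candidates()`): predicted log HRs of the next period's
  candidates are sign-flipped and min–max scaled to x ∈ [0, 1] over the
  period's batch (all-equal predictions map to 0.5); the enrollment weight
  is the squared logistic p = σ(10·(x − (1 − z)))², where z is the
  responder-to-non-responder ratio (#predicted log HR < 0 over ≥ 0) in the
  interim test set — the population the model was validated on — capped at
  the responder count when no non-responders exist. The next period enrolls
  exactly ⌈q·n⌉ candidates by weighted sampling without replacement, which
  makes the sample-size arithmetic deterministic while respecting relative
  weights; enrollment probability is monotone in predicted benefit but never
  degenerate, so both high and low responders keep enrolling at different
  rates. Arms remain randomized independently of enrichment, so arm balance
  is preserved by construction (tested by chi-square calibration).

## The synthetic world

`generate_trial()` emulates an IRIS-like cardiovascular outcome trial and is
the package's parameter-recovery oracle. Defaults state the world once:

- n = 4000 participants, 1:1 randomized, uniform accrual over 2899 days
  (the IRIS recruitment window), administrative follow-up horizon 1825 days
  (5 years).
- Exponential event times — the simplest constant-hazard model satisfying
  the proportional-hazards assumption of the weighted Cox stage, with the
  control rate calibrated in closed form: λ₀ = −ln(1 − 0.118)/horizon so
  the control-arm event proportion at the horizon is 11.8%; the average
  treatment effect is HR 0.76. A SPRINT-like world is a parameter choice
  away (control rate 6.8%, HR ≈ 0.79).
- 10 standard-normal continuous covariates (optional Gaussian-copula
  equicorrelation), 8 Bernoulli(0.2–0.5) binary covariates, 2 three-level
  categoricals — enough to exercise every Gower branch. A binary covariate
  that carries a planted interaction is generated balanced (prevalence ½),
  the canonical single-binary-heterogeneity world.
- Treatment-arm log hazard = ate + Σ coeffs·x on the interaction features;
  the true per-participant log HR is stored for recovery tests.
- Random censoring at 10% of the baseline event hazard; 2% MCAR
  missingness per covariate (the imputer is tested for mechanics, not for
  missingness-mechanism robustness, so MCAR suffices).
- Two hierarchical safety tiers: a rarer mortality-like tier sharing the
  treatment effect, and a null-effect lower tier, enough to exercise the
  win-ratio hierarchy.

What the generator does *not* emulate: competing risks, informative
censoring, site/cluster structure, non-proportional hazards, or the real
trials' covariate correlation structure (unreported; exposed as the `corr`
knob instead of being fixed). A green test therefore establishes that the
machinery recovers planted structure under its stated assumptions — not
that it would reproduce the headline numbers of any particular real trial,
which rest on restricted-access data.

### Scaled test geometry

The end-to-end acceptance scenario runs at n = 1500 with interim triggers
{20, 40, 60}: the same *fractions* of total primary events as the full-size
design's {50, 100, 150} out of ≈400. Keeping the absolute triggers at a
scaled n would push the third interim past the end of accrual, leaving no
candidates to enrich — a geometry artifact of scaling, not a property of
the method.

## Evaluation and stability machinery

- `primary_cox_hr()` — unadjusted arm-only Cox fit at any calendar cut.
- `win_ratio()` — unmatched pairwise hierarchical comparison (mortality
  tier first; within a tier the intervention member wins if the control
  member had the event and the intervention member is known event-free past
  that time); the 95% CI uses the two-sample U-statistic (projection)
  variance of the win and loss proportions with the delta method on
  log(WR). The naive 1/W + 1/L variance is *invalid* here — pairwise counts
  are strongly correlated and it would shrink to zero with millions of
  pairs; the projection estimator's ≈95% coverage under a null world is
  verified by simulation in the test suite.
- `pair_concordance()` / `average_concordance_odds()` / `stability_run()` —
  across repeated random splits, how often a pair of participants keeps the
  same predicted-benefit order when both are in the test set. Equal counts
  give 1; otherwise the majority/minority ratio; a zero minority count is
  undefined as printed and receives a +0.5 continuity correction to both
  counts (so (4, 0) → 9), with the raw variant available via
  `continuity = FALSE`. Pairs that never co-occur are excluded from the
  mean (the alternative — dividing by all n(n−1)/2 pairs — would conflate
  co-occurrence frequency with rank stability). The bootstrap CI resamples
  participants (1000 replicates, seeded); resampling pairs would ignore the
  participant-level dependence.
- `summarize_runs()` — mean ± SEM and one-sample t tests of per-run
  quantities against the all-comers reference; final sample sizes use a
  one-sided α of 0.025, other quantities two-sided 0.05.
- `shuffle_covariates()` — the negative control: permuting whole covariate
  rows preserves every marginal distribution and the average treatment
  effect while destroying covariate-linked heterogeneity, so enrichment
  should (and in the tests does) stop firing systematically.

## Numerical choices and degenerate inputs

- Percentiles everywhere use the linear-interpolation convention (R type 7),
  so winsorization bounds are reproducible (1..100 → 3.475/97.525).
- Winsorization by re-estimated percentiles is not exactly idempotent
  (clipping moves mass onto the bounds, shifting the next percentile
  inward); the idempotent form applies the *recorded* bounds, which is what
  `apply_preprocess()` and `winsorize_labels(bounds=)` do.
- CSV round trips write doubles with 17 significant digits, so
  read(write(ds)) is bit-exact.
- Constant benefit labels yield a constant predictor; constant predictions
  make the gate fail (no valid dichotomy) and map to x = 0.5 in the
  enrichment transform.
- A learning-stage failure at an interim (e.g. too few weighted events at
  the first look of a small simulation) is logged in the decision record
  and treated as "no evidence of heterogeneity" for that period —
  scientifically that is what it is; an `on_stage_error = "abort"` mode
  preserves the strict alternative.
- Every source of randomness flows through per-stage seeds derived from one
  run seed, so whole experiments are bit-reproducible.

## Known limitations

- Phenomap labels are smooth functionals of the covariate geometry, so the
  all-relevant selector legitimately picks up features that shape
  neighborhoods as well as those driving the planted effect; selection
  frequency of the true driver approaches 1 only as events accumulate.
- The projected-effect blend in the sample-size revision uses point
  estimates of noisy interim subgroup hazard ratios; at small scales the
  revision can accept enrichment on noise (visible as occasional
  negative-control activations).
- The win-ratio CI is asymptotic; with very few decided pairs it is
  flagged undefined rather than bootstrapped (a bootstrap variant would be
  straightforward but is not the default).
- Only two-arm, 1:1, individually randomized designs with numeric-day
  timelines are supported.
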
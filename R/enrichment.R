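# Enrichment engine: map predicted benefit to enrollment probabilities via
# the squared-sigmoid transform, and perform weighted without-replacement
# sampling of each period's candidates at the chosen enrichment level.

#' Normalize predicted benefit to the [0, 1] enrollment input
#'
#' Predicted log HRs are sign-flipped (so larger = more benefit) and min-max
#' scaled to \[0, 1\] over the candidate batch. All-equal predictions map to
#' 0.5 everywhere.
#'
#' @param predicted_loghr numeric vector (>= 2 candidates).
#' @return numeric vector `x` in \[0, 1\].
#' @export
benefit_to_x <- function(predicted_loghr) {
  if (length(predicted_loghr) < 2) stopf("need >= 2 candidates")
  v <- -predicted_loghr
  rg <- max(v) - min(v)
  if (rg == 0) return(rep(0.5, length(v)))
  (v - min(v)) / rg
}

#' Squared-sigmoid enrollment probability
#'
#' `p = sigma(k * (x - (1 - z)))^2` with logistic `sigma` and scale `k = 10`:
#' candidates far above the responder-threshold anchor `1 - z` approach
#' certain enrollment weight, those far below approach zero, and the
#' squaring sharpens the suppression of low-benefit candidates.
#'
#' @param x normalized benefit in \[0, 1\] (from [benefit_to_x()]).
#' @param z responder-to-non-responder ratio, > 0.
#' @param k sigmoid scale (fixed 10 in the design).
#' @return enrollment weights in (0, 1).
#' @export
enrollment_probability <- function(x, z, k = 10) {
  if (any(z <= 0)) stopf("z must be positive")
  (1 / (1 + exp(-k * (x - (1 - z)))))^2
}

#' Responder-to-non-responder ratio
#'
#' `z = #\{predicted log HR < 0\} / #\{predicted log HR >= 0\}`, computed on
#' the population the model was validated on (the interim test set). When
#' no non-responders exist the ratio is capped at the responder count.
#'
#' @param predicted_loghr numeric vector (>= 1 prediction).
#' @return positive scalar `z`.
#' @export
responder_ratio <- function(predicted_loghr) {
  if (!length(predicted_loghr)) stopf("need >= 1 prediction")
  n_resp <- sum(predicted_loghr < 0)
  n_non <- sum(predicted_loghr >= 0)
  if (n_non == 0) return(max(n_resp, 1))
  max(n_resp / n_non, 1e-8)
}

#' Sample a period's candidates with enrichment weights
#'
#' Weighted sampling without replacement of `ceiling(q * n)` candidate ids
#' (at least 1), with inclusion probability increasing in the enrollment
#' weight `p`. Treatment assignment of enrollees is untouched: arms remain
#' randomized independently of enrichment.
#'
#' @param candidate_ids character vector of candidate ids.
#' @param p enrollment weights (positive, recycled checks apply).
#' @param q enrichment level in (0, 1].
#' @param seed integer seed.
#' @return character vector of enrolled ids.
#' @export
sample_period_candidates <- function(candidate_ids, p, q, seed) {
  n <- length(candidate_ids)
  if (n == 0) return(character())
  if (length(p) != n) stopf("p must have one weight per candidate")
  size <- max(1L, as.integer(ceiling(q * n)))
  size <- min(size, n)
  p <- pmax(p, 1e-12)
  with_seed(seed, sample(candidate_ids, size, replace = FALSE, prob = p))
}
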
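# Fixtures built in code: a tiny hand-writable trial and a small synthetic
# trial wrapper used across test files.

toy_schema <- function() {
  covariate_schema(c("age", "smoker", "region"),
                   c("continuous", "binary", "categorical"),
                   levels = list(region = c("north", "south")))
}

# deterministic 8-participant trial with both arms and a few events
toy_trial <- function() {
  d <- data.frame(
    id = paste0("p", 1:8),
    arm = rep(c("control", "intervention"), 4),
    accrual_time = c(0, 10, 20, 30, 40, 50, 60, 70),
    primary_time = c(100, 400, 250, 80, 300, 120, 500, 60),
    primary_event = c(1, 0, 1, 1, 0, 1, 0, 1),
    safety_1_time = c(150, 400, 300, 90, 300, 200, 500, 70),
    safety_1_event = c(1, 0, 0, 1, 0, 1, 0, 1),
    age = c(50, 60, 40, 55, 65, 45, 52, 58),
    smoker = c(1, 0, 1, 0, 0, 1, 1, 0),
    region = c("north", "south", "north", "south",
               "north", "south", "north", "south"),
    stringsAsFactors = FALSE)
  trial_dataset(d, toy_schema())
}

small_trial <- function(n = 400, seed = 1, hte = 0, censor = 0.1,
                        missing = 0, ...) {
  cfg <- synthetic_config(
    n_total = n, seed = seed,
    hte_features = if (hte != 0) "b1" else character(),
    hte_coeffs = if (hte != 0) hte else numeric(),
    censor_rate = censor, missing_frac = missing, ...)
  list(cfg = cfg, ds = generate_trial(cfg))
}

# brute-force maximizer of the weighted Breslow partial likelihood for a
# single binary covariate: the independent oracle for weighted_cox.
grid_wcox_oracle <- function(times, events, trt, w,
                             grid = seq(-5, 5, by = 1e-4)) {
  eb <- exp(grid)
  ev <- which(events == 1 & w > 0)
  ll <- numeric(length(grid))
  for (i in ev) {
    risk <- times >= times[i]
    A <- sum(w[risk & trt == 0])
    B <- sum(w[risk & trt == 1])
    ll <- ll + w[i] * (trt[i] * grid - log(A + B * eb))
  }
  grid[which.max(ll)]
}

with_seed_local <- function(seed, expr) phenotrial:::with_seed(seed, expr)
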
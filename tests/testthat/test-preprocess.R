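make_cont_trial <- function(df, extra = list()) {
  n <- nrow(df)
  base <- data.frame(id = paste0("q", seq_len(n)),
                     arm = rep(c("control", "intervention"), length.out = n),
                     accrual_time = seq_len(n),
                     primary_time = 100 + seq_len(n),
                     primary_event = rep(c(0L, 1L), length.out = n),
                     stringsAsFactors = FALSE)
  d <- cbind(base, df)
  sch <- covariate_schema(names(df), rep("continuous", ncol(df)))
  trial_dataset(d, sch)
}

test_that("covariates above the missingness cut are dropped", {
  set.seed(1)
  df <- data.frame(a = rnorm(100), b = rnorm(100))
  df$a[1:15] <- NA   # 15% > 10%
  df$b[1:5] <- NA    # 5%
  fit <- fit_preprocess(make_cont_trial(df))
  expect_identical(fit$dropped_missing, "a")
  expect_identical(fit$kept_features, "b")
})

test_that("the collinearity screen drops the member with larger mean |r|", {
  set.seed(42)
  n <- 300
  B <- rnorm(n)
  A <- 0.98 * B + 0.2 * rnorm(n)       # |r(A,B)| > 0.9
  C <- 0.6 * A + 0.8 * rnorm(n)        # C leans on A, not B directly
  df <- data.frame(A = A, B = B, C = C)
  cm <- abs(cor(df)); diag(cm) <- 0
  expect_gt(cm["A", "B"], 0.9)
  expect_gt(rowMeans(cm)[["A"]], rowMeans(cm)[["B"]])  # A has larger mean |r|
  fit <- fit_preprocess(make_cont_trial(df))
  expect_identical(fit$dropped_collinear, "A")
  expect_setequal(fit$kept_features, c("B", "C"))
})

test_that("winsor bounds follow the linear percentile convention", {
  df <- data.frame(v = as.numeric(1:100), w = rnorm(100))
  fit <- fit_preprocess(make_cont_trial(df))
  expect_equal(fit$winsor_bounds$v, c(3.475, 97.525), tolerance = 1e-12)
  ap <- apply_preprocess(fit, make_cont_trial(df))
  expect_equal(min(ap$X[, "v"]), 3.475)
  expect_equal(max(ap$X[, "v"]), 97.525)
  # idempotence: transforming already-winsorized values is a no-op
  df2 <- data.frame(v = pmin(pmax(df$v, 3.475), 97.525), w = df$w)
  ap2 <- apply_preprocess(fit, make_cont_trial(df2))
  expect_equal(ap$X, ap2$X)
})

test_that("zero-variance factors are dropped, all dropped errors", {
  n <- 60
  d <- data.frame(id = paste0("z", 1:n),
                  arm = rep(c("control", "intervention"), n / 2),
                  accrual_time = 1:n, primary_time = 50 + 1:n,
                  primary_event = rep(0:1, n / 2),
                  flag = rep(1, n), x = rnorm(n),
                  stringsAsFactors = FALSE)
  sch <- covariate_schema(c("flag", "x"), c("binary", "continuous"))
  fit <- fit_preprocess(trial_dataset(d, sch))
  expect_identical(fit$dropped_zero_var, "flag")
  d2 <- d[, setdiff(names(d), "x")]
  expect_error(fit_preprocess(trial_dataset(d2, covariate_schema("flag", "binary"))),
               "all covariates dropped")
})

test_that("transform output is complete and frozen state is leakage-free", {
  st <- small_trial(n = 300, seed = 8, missing = 0.08)
  split <- split_half(st$ds, 1)
  train <- phenotrial:::subset_trial(st$ds, split$train_ids)
  test <- phenotrial:::subset_trial(st$ds, split$test_ids)
  fit <- fit_preprocess(train, seed = 3)
  ap_tr <- apply_preprocess(fit, train)
  expect_false(anyNA(ap_tr$X))
  ap_te <- apply_preprocess(fit, test)
  expect_false(anyNA(ap_te$X))
  # applying twice is deterministic (imputer state frozen)
  expect_identical(ap_te$X, apply_preprocess(fit, test)$X)
  # held-out extremes clip to *train* winsor bounds
  for (nm in names(fit$winsor_bounds)) {
    expect_gte(min(ap_te$X[, nm]), fit$winsor_bounds[[nm]][1])
    expect_lte(max(ap_te$X[, nm]), fit$winsor_bounds[[nm]][2])
  }
})

test_that("complete-data input passes through the imputer unchanged", {
  st <- small_trial(n = 120, seed = 10, missing = 0)
  fit <- fit_preprocess(st$ds)
  ap <- apply_preprocess(fit, st$ds, output = "frame")
  raw <- st$ds$data[fit$kept_features]
  for (nm in names(fit$winsor_bounds))
    raw[[nm]] <- pmin(pmax(raw[[nm]], fit$winsor_bounds[[nm]][1]),
                      fit$winsor_bounds[[nm]][2])
  expect_equal(ap$frame, raw, ignore_attr = TRUE)
})

test_that("forest imputation beats mean imputation on correlated data", {
  cfg <- synthetic_config(n_total = 400, seed = 17, corr = 0.7,
                          n_binary = 2, n_categorical = 0, missing_frac = 0)
  ds <- generate_trial(cfg)
  truth <- ds$data$x1
  masked <- ds
  set.seed(31)
  hide <- sample(400, 60)
  masked$data$x1[hide] <- NA
  fit <- fit_preprocess(masked, seed = 7)
  ap <- apply_preprocess(fit, masked, output = "frame")
  rmse_forest <- sqrt(mean((ap$frame$x1[hide] - truth[hide])^2))
  rmse_mean <- sqrt(mean((mean(masked$data$x1, na.rm = TRUE) - truth[hide])^2))
  expect_lt(rmse_forest, rmse_mean)
})

test_that("categorical encoding is reference-free complete one-hot", {
  ds <- toy_trial()
  big <- do.call(rbind, replicate(5, ds$data, simplify = FALSE))
  big$id <- paste0("r", seq_len(nrow(big)))
  ds40 <- trial_dataset(big, toy_schema())
  fit <- fit_preprocess(ds40)
  emap <- fit$encoder_map$region
  expect_setequal(unname(emap), c("region=north", "region=south"))
  ap <- apply_preprocess(fit, ds40)
  cols <- ap$X[, emap, drop = FALSE]
  expect_true(all(rowSums(cols) == 1))   # one indicator per level, exhaustive
  # levels outside the schema become missing at typing and are imputed to a
  # seen level, so encoded rows always stay valid one-hot
  newd <- ds40
  newd$data$region[1:6] <- NA
  ap2 <- apply_preprocess(fit, newd)
  expect_true(all(rowSums(ap2$X[, emap, drop = FALSE]) == 1))
})
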
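test_that("trial dataset validation enforces the core invariants", {
  ds <- toy_trial()
  expect_s3_class(ds, "trial_dataset")
  expect_equal(nrow(ds$data), 8)
  expect_equal(ds$n_safety, 1L)

  d <- ds$data
  d$arm <- "control"
  expect_error(trial_dataset(d, toy_schema()), "both arms")
  d <- ds$data
  d$id[2] <- d$id[1]
  expect_error(trial_dataset(d, toy_schema()), "duplicate")
  d <- ds$data
  d$primary_time[1] <- -1
  expect_error(trial_dataset(d, toy_schema()), "primary_time")
  expect_error(trial_dataset(ds$data[, -2], toy_schema()), "reserved")
})

test_that("CSV round-trip reproduces a random dataset bit-exactly", {
  st <- small_trial(n = 200, seed = 11, missing = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(st$ds, path)
  back <- read_trial_table(path, st$ds$schema)
  expect_identical(back$data$id, st$ds$data$id)
  expect_identical(as.character(back$data$arm), as.character(st$ds$data$arm))
  for (col in c("accrual_time", "primary_time", "safety_1_time")) {
    expect_identical(back$data[[col]], st$ds$data[[col]])
  }
  for (nm in st$ds$schema$name) {
    a <- back$data[[nm]]; b <- st$ds$data[[nm]]
    expect_identical(is.na(a), is.na(b))
    if (is.factor(b)) expect_identical(as.character(a), as.character(b))
    else expect_identical(a, b)
  }
})

test_that("unparseable covariate cells become missing, outcome cells error", {
  ds <- toy_trial()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(ds, path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  raw$age[1] <- "not-a-number"
  raw$region[2] <- "mars"      # unknown level -> missing
  write.csv(raw, path, row.names = FALSE, na = "NA")
  back <- read_trial_table(path, toy_schema())
  expect_true(is.na(back$data$age[1]))
  expect_true(is.na(back$data$region[2]))

  raw$primary_time[1] <- "oops"
  write.csv(raw, path, row.names = FALSE, na = "NA")
  expect_error(read_trial_table(path, toy_schema()), "unparseable")
})

subset_trial_n <- function(ds, n) {
  out <- ds
  out$data <- ds$data[seq_len(n), , drop = FALSE]
  out
}

test_that("split_half is a deterministic 50:50 partition", {
  st <- small_trial(n = 11, seed = 2)
  s1 <- split_half(st$ds, 1)
  s2 <- split_half(st$ds, 1)
  expect_identical(s1, s2)
  expect_setequal(c(s1$train_ids, s1$test_ids), st$ds$data$id)
  expect_length(intersect(s1$train_ids, s1$test_ids), 0)
  expect_true(abs(length(s1$train_ids) - length(s1$test_ids)) <= 1)
  expect_error(split_half(subset_trial_n(st$ds, 3), 1))
})

test_that("over many seeds each participant trains about half the time", {
  st <- small_trial(n = 10, seed = 3)
  in_train <- sapply(1:100, function(s)
    st$ds$data$id %in% split_half(st$ds, s)$train_ids)
  frac <- rowMeans(in_train)
  # binomial(100, 0.5): 0.5 +/- ~3.1 SE
  expect_true(all(frac > 0.35 & frac < 0.65))
})

test_that("censoring at a calendar cut clips follow-up correctly", {
  ds <- toy_trial()
  cens <- censor_at(ds, 130)
  # arrivals at day 0..70 all kept (accrual < 130)
  expect_equal(nrow(cens$data), 8)
  # p1: accrual 0, time 100 <= 130 - 0 -> event stands
  expect_equal(cens$data$primary_event[1], 1L)
  # p3: accrual 20, event at 250 > 110 of available follow-up -> censored
  expect_equal(cens$data$primary_event[3], 0L)
  expect_equal(cens$data$primary_time[3], 110)
  # nobody censored later than their available follow-up
  expect_true(all(cens$data$primary_time <= 130 - cens$data$accrual_time))
  summ <- arm_event_summary(ds)
  expect_equal(summ$events, c(2L, 3L))      # control, intervention
  expect_equal(summ$percent, 100 * c(2 / 4, 3 / 4))
})
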
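# Core data model: covariate schema, trial dataset container, CSV round-trip
# I/O, validation, censoring at a calendar cut, and deterministic 50:50 splits.

ARM_LEVELS <- c("control", "intervention")
RESERVED_COLS <- c("id", "arm", "accrual_time", "primary_time", "primary_event")

#' Covariate schema
#'
#' Describes the baseline covariates of a trial dataset: each entry has a
#' unique name and a kind (`continuous`, `binary`, or `categorical`);
#' categorical entries carry an ordered set of level labels.
#'
#' @param name character vector of covariate names (unique).
#' @param kind character vector, one of `"continuous"`, `"binary"`,
#'   `"categorical"` per covariate.
#' @param levels named list mapping each categorical covariate name to its
#'   ordered character vector of levels (at least 2).
#' @return An object of class `covariate_schema` (a data frame with a
#'   `levels` attribute).
#' @export
covariate_schema <- function(name, kind, levels = list()) {
  name <- as.character(name)
  kind <- as.character(kind)
  if (length(name) != length(kind)) stopf("name and kind lengths differ")
  if (anyDuplicated(name)) stopf("covariate names must be unique")
  bad <- setdiff(kind, c("continuous", "binary", "categorical"))
  if (length(bad)) stopf("unknown covariate kind: %s", paste(bad, collapse = ", "))
  cats <- name[kind == "categorical"]
  miss <- setdiff(cats, names(levels))
  if (length(miss)) stopf("levels missing for categorical covariate(s): %s",
                          paste(miss, collapse = ", "))
  for (nm in cats) {
    lv <- as.character(levels[[nm]])
    if (length(lv) < 2 || anyDuplicated(lv))
      stopf("categorical covariate '%s' needs >= 2 distinct levels", nm)
    levels[[nm]] <- lv
  }
  out <- data.frame(name = name, kind = kind, stringsAsFactors = FALSE)
  attr(out, "levels") <- levels[cats]
  class(out) <- c("covariate_schema", "data.frame")
  out
}

schema_levels <- function(schema, name) attr(schema, "levels")[[name]]

#' Trial dataset container
#'
#' Bundles one row per participant (id, arm, accrual calendar time, primary
#' time-to-event outcome, optional hierarchical safety outcomes, baseline
#' covariates) with its covariate schema, and validates the invariants:
#' unique ids, both arms present, positive outcome times, non-negative
#' accrual times.
#'
#' @param data data frame with columns `id`, `arm`, `accrual_time`,
#'   `primary_time`, `primary_event`, optional `safety_<k>_time` /
#'   `safety_<k>_event` pairs (k = 1 is the highest-priority tier, e.g.
#'   all-cause mortality), and one column per schema covariate.
#' @param schema a [covariate_schema()].
#' @param validate logical; skip invariant checks if `FALSE` (internal use).
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(data, schema, validate = TRUE) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  miss <- setdiff(RESERVED_COLS, names(data))
  if (length(miss)) stopf("missing reserved column(s): %s", paste(miss, collapse = ", "))
  miss <- setdiff(schema$name, names(data))
  if (length(miss)) stopf("missing covariate column(s): %s", paste(miss, collapse = ", "))
  data$id <- as.character(data$id)
  data$arm <- factor(as.character(data$arm), levels = ARM_LEVELS)
  for (col in c("accrual_time", "primary_time")) data[[col]] <- as.numeric(data[[col]])
  data$primary_event <- as.integer(data$primary_event)
  n_safety <- 0L
  repeat {
    tc <- sprintf("safety_%d_time", n_safety + 1L)
    ec <- sprintf("safety_%d_event", n_safety + 1L)
    if (!all(c(tc, ec) %in% names(data))) break
    data[[tc]] <- as.numeric(data[[tc]])
    data[[ec]] <- as.integer(data[[ec]])
    n_safety <- n_safety + 1L
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    data[[nm]] <- switch(schema$kind[i],
      continuous = as.numeric(data[[nm]]),
      binary = {
        v <- suppressWarnings(as.numeric(data[[nm]]))
        v[!(v %in% c(0, 1))] <- NA_real_
        v
      },
      categorical = factor(as.character(data[[nm]]), levels = schema_levels(schema, nm))
    )
  }
  ds <- structure(list(data = data, schema = schema, n_safety = n_safety),
                  class = "trial_dataset")
  if (validate) validate_trial_dataset(ds)
  ds
}

validate_trial_dataset <- function(ds) {
  d <- ds$data
  if (anyDuplicated(d$id)) stopf("duplicate participant id(s)")
  if (anyNA(d$arm)) stopf("arm must be one of: %s", paste(ARM_LEVELS, collapse = ", "))
  if (nrow(d) > 0 && length(unique(d$arm)) < 2)
    stopf("both arms must be non-empty in an analyzed dataset")
  if (anyNA(d$accrual_time) || any(d$accrual_time < 0))
    stopf("accrual_time must be numeric and >= 0")
  if (anyNA(d$primary_time) || any(d$primary_time <= 0))
    stopf("primary_time must be numeric and > 0")
  if (anyNA(d$primary_event) || !all(d$primary_event %in% c(0L, 1L)))
    stopf("primary_event must be 0/1")
  invisible(ds)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d participants, %d covariates, %d safety tier(s)\n",
              nrow(x$data), nrow(x$schema), x$n_safety))
  tab <- table(x$data$arm)
  cat(sprintf("  arms: control %d / intervention %d; events: %d\n",
              tab[["control"]], tab[["intervention"]], sum(x$data$primary_event)))
  invisible(x)
}

n_participants <- function(ds) nrow(ds$data)

covariate_frame <- function(ds) ds$data[, ds$schema$name, drop = FALSE]

subset_trial <- function(ds, ids = NULL, rows = NULL, validate = FALSE) {
  if (is.null(rows)) rows <- match(ids, ds$data$id)
  if (anyNA(rows)) stopf("unknown participant id(s)")
  out <- ds
  out$data <- ds$data[rows, , drop = FALSE]
  rownames(out$data) <- NULL
  if (validate) validate_trial_dataset(out)
  out
}

#' Summarize primary-event counts by arm
#'
#' Per-arm sample sizes, primary-event counts, and event proportions
#' (optionally after censoring at a calendar cut).
#'
#' @param ds a [trial_dataset()].
#' @param cut calendar day at which follow-up is administratively censored
#'   (`Inf` = use full follow-up).
#' @return data frame with columns `arm`, `n`, `events`, `proportion`, and
#'   `percent` (= 100 * proportion).
#' @export
arm_event_summary <- function(ds, cut = Inf) {
  if (is.finite(cut)) ds <- censor_at(ds, cut)
  d <- ds$data
  n <- as.integer(table(d$arm)[ARM_LEVELS])
  ev <- as.integer(tapply(d$primary_event, d$arm, sum)[ARM_LEVELS])
  data.frame(arm = ARM_LEVELS, n = n, events = ev,
             proportion = ev / n, percent = 100 * ev / n,
             stringsAsFactors = FALSE)
}

#' Censor a trial dataset at a calendar time
#'
#' Keeps participants accrued strictly before `cut` and administratively
#' censors each one's primary and safety follow-up at `cut - accrual_time`
#' (the follow-up observable at that calendar day).
#'
#' @param ds a [trial_dataset()].
#' @param cut calendar day (days since first randomization).
#' @return a censored `trial_dataset`.
#' @export
censor_at <- function(ds, cut) {
  d <- ds$data
  keep <- d$accrual_time < cut
  d <- d[keep, , drop = FALSE]
  avail <- cut - d$accrual_time
  clip <- function(time, event) {
    ev <- as.integer(event == 1L & time <= avail)
    list(time = pmin(time, avail), event = ev)
  }
  pc <- clip(d$primary_time, d$primary_event)
  d$primary_time <- pc$time
  d$primary_event <- pc$event
  for (k in seq_len(ds$n_safety)) {
    tc <- sprintf("safety_%d_time", k); ec <- sprintf("safety_%d_event", k)
    sc <- clip(d[[tc]], d[[ec]])
    d[[tc]] <- sc$time
    d[[ec]] <- sc$event
  }
  out <- ds
  out$data <- d
  rownames(out$data) <- NULL
  out
}

#' Read a trial table from CSV
#'
#' Reads a comma-separated, UTF-8, `NA`-sentinel trial table written by
#' [write_trial_table()] (or prepared externally with the same layout).
#' Unparseable covariate cells become missing; unparseable outcome, arm or
#' accrual cells are errors.
#'
#' @param path file path.
#' @param schema a [covariate_schema()] describing the covariate columns.
#' @return a [trial_dataset()].
#' @export
read_trial_table <- function(path, schema) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = "NA", fileEncoding = "UTF-8")
  miss <- setdiff(RESERVED_COLS, names(raw))
  if (length(miss)) stopf("missing reserved column(s): %s", paste(miss, collapse = ", "))
  num_cols <- c("accrual_time", "primary_time")
  int_cols <- "primary_event"
  k <- 1L
  while (all(sprintf("safety_%d_%s", k, c("time", "event")) %in% names(raw))) {
    num_cols <- c(num_cols, sprintf("safety_%d_time", k))
    int_cols <- c(int_cols, sprintf("safety_%d_event", k))
    k <- k + 1L
  }
  for (col in c(num_cols, int_cols)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !is.na(raw[[col]])
    if (any(bad)) stopf("unparseable value(s) in outcome column '%s'", col)
    raw[[col]] <- v
  }
  if (!all(raw$arm %in% ARM_LEVELS))
    stopf("arm column must contain only: %s", paste(ARM_LEVELS, collapse = ", "))
  trial_dataset(raw, schema)
}

#' Write a trial table to CSV
#'
#' Comma-separated, UTF-8, `.` decimal, literal `NA` for missing values.
#' Numeric cells are written with 17 significant digits so that
#' `read_trial_table(write_trial_table(ds))` reproduces non-missing values
#' bit-exactly.
#'
#' @param ds a [trial_dataset()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(ds, path) {
  d <- ds$data
  for (col in names(d)) {
    if (is.double(d[[col]])) {
      v <- sprintf("%.17g", d[[col]])
      v[is.na(d[[col]])] <- NA_character_
      d[[col]] <- v
    } else if (is.factor(d[[col]])) {
      d[[col]] <- as.character(d[[col]])
    }
  }
  write.csv(d, path, row.names = FALSE, na = "NA", quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Deterministic 50:50 split of a trial dataset
#'
#' Randomly partitions participant ids into training and testing halves
#' (sizes differing by at most one), reproducibly for a fixed seed.
#'
#' @param ds a [trial_dataset()] with at least 4 participants.
#' @param seed integer seed.
#' @return list with `seed`, `train_ids`, `test_ids`.
#' @export
split_half <- function(ds, seed) {
  ids <- ds$data$id
  n <- length(ids)
  if (n < 4) stopf("need at least 4 participants to split (have %d)", n)
  perm <- with_seed(seed, sample.int(n))
  n_train <- n %/% 2L
  list(seed = as.integer(seed),
       train_ids = sort(ids[perm[seq_len(n_train)]]),
       test_ids = sort(ids[perm[(n_train + 1L):n]]))
}
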
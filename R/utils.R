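# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic fan-out of a run-level seed into per-stage seeds, kept well
# below .Machine$integer.max. `stage` is a short label, `k` an optional look
# or iteration counter.
stage_seed <- function(seed, stage, k = 0L) {
  codes <- utf8ToInt(stage)
  h <- (sum(codes * seq_along(codes)) %% 10007L)
  as.integer((abs(as.numeric(seed)) * 2654435.0 + h * 97.0 + k * 13.0) %%
               2147483647) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
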
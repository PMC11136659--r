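## Internal helpers: seed fan-out and small argument checks.

## Derive a child seed from a master seed and a counter, keeping the result a
## valid 32-bit integer. All stage-level randomness flows through this so one
## master seed reproduces every stage.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 + 999983 * (as.numeric(k) %% 2146)) %%
               2147483647)
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

stopifnot_scalar01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
}

## Mean of the off-diagonal entries of a square matrix restricted to a day
## subset (both train and test day in `days`), NA-safe. A single-day block
## has no off-diagonal pairs; its same-day entry is used instead so that
## degenerate blocks (e.g. permutation tests on two-day cohorts) remain
## well defined.
offDiagMean <- function(m, days, allDays) {
  idx <- match(days, allDays)
  sub <- m[idx, idx, drop = FALSE]
  if (length(idx) == 1) return(mean(sub, na.rm = TRUE))
  diag(sub) <- NA
  mean(sub, na.rm = TRUE)
}
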
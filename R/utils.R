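# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Column means/variances without apply() overhead; variance uses denominator n - 1.
col_vars <- function(x, means = colMeans(x)) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to compute a variance")
  (colSums(x^2) - n * means^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
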
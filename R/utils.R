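# internal helpers

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. All seeded generators in the package go through this so
# that user-level RNG state is never clobbered.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of a master seed into per-stage / per-repetition seeds,
# kept below 2^31 - 1. Documented hash: 32-bit multiply-and-add on the UTF-8
# codes of the label.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- as.double(master) %% 2147483647
  for (c in utf8ToInt(as.character(label))) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_proportion <- function(x, name, lo = 0, hi = 1,
                              lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) stop2(sprintf("`%s` must be in %s%g, %g%s, got %s",
                         name, if (lo_open) "(" else "[", lo, hi,
                         if (hi_open) ")" else "]",
                         format(x)))
  invisible(x)
}
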
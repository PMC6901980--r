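# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's
# RNG state afterwards so library calls never clobber user streams.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic sub-seed derived from a root seed and a string key
# (stage name, gene-set name, ...). Keyed derivation makes per-set
# results invariant to the order sets are scored in, and keeps every
# derived seed a valid 32-bit integer.
.subSeed <- function(root, key) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  h <- 0
  for (ch in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(as.numeric(root)) + h) %% 2147483647)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

.assertCount <- function(x, name, minimum = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < minimum || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, minimum),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
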
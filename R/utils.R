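# Internal helpers shared across modules.

# Deterministic child seed for a named random stream. All simulator
# randomness flows from one top-level seed through named streams so stages
# can be re-run independently. Kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(stream)) h <- (h * 69069 + k) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

std_error <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
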
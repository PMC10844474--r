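# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  seed = NULL runs `code` against the
# ambient RNG stream (and does not restore anything).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed, kept within the 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483629L) + 1L
}

# sample() misbehaves on length-1 numeric input; this never does.
sample_one <- function(x) x[sample.int(length(x), 1L)]

stop_stage <- function(stage, msg, call. = FALSE) {
  stop(sprintf("[%s] %s", stage, msg), call. = call.)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
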
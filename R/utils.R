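# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards. seed = NULL runs in the ambient
# stream (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0))
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
}
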
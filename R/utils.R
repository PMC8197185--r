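# Internal helpers: seeded RNG scoping and deterministic seed derivation.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from a master seed. Kept below 2^31 so the
# result is always a valid R integer seed.
derive_seed <- function(master_seed, index) {
  master_seed <- as.double(master_seed)
  index <- as.double(index)
  as.integer((master_seed * 48271 + index * 16807 + 12345) %% 2147483647)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
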
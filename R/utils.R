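# Internal helpers: deterministic substream seeding and RNG hygiene.

# Derive a reproducible child seed from a master seed and a stream label.
# A small polynomial string hash folded into [0, 2^31 - 2]; every source of
# randomness in the package draws its seed through this so that one master
# seed pins down the cohort, every subject, every session, every fold split
# and every ensemble member independently of evaluation order.
substream_seed <- function(seed, ..., index = NULL) {
  label <- paste(c(..., index), collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed %% m)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}
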
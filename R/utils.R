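# Small shared internals: seeded evaluation, deterministic per-stage seed
# fan-out, and half-away-from-zero rounding.

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic fan-out: hashing the stage name into the seed means adding a
#' stage never perturbs the random streams of the others. Result is always a
#' valid positive 32-bit integer seed.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (string).
#' @return A positive integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587 + 1)
}

# round half away from zero (printed-percentage convention)
round_half_away <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
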
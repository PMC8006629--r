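# internal helpers shared across modules

#' Round half away from zero
#'
#' Commercial ("round half up") rounding, used when rendering percentages the
#' way clinical papers print them (93.75% -> 94%), in contrast to the
#' round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(93.75, 0) # 94
#' round_half_up(0.125, 2) # 0.13
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic per-patient substream seed: two mixed Lehmer steps over the
# Mersenne prime 2^31 - 1. Products stay below 2^53 so double arithmetic is
# exact. Ensures patient i's draws do not depend on cohort size.
substream_seed <- function(seed, i) {
  m <- 2147483647
  h <- (abs(as.numeric(seed)) %% m)
  h <- (h * 48271 + 1) %% m
  h <- ((h + as.numeric(i)) * 69621 + 11) %% m
  as.integer(h)
}

# Evaluate expr under a local RNG state; restores (or removes) .Random.seed.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# stop() with call.=FALSE and sprintf formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
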
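# Internal helpers shared across modules.

#' Derive a stage-local seed from a global seed
#'
#' One global seed fans out deterministically to per-stage seeds so that each
#' pipeline stage is independently reproducible. The derivation is a small
#' multiplicative hash of the stage name folded into the global seed, kept
#' below 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label, e.g. `"simulate"` or `"subject-3"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(((seed %% m) * 48271 + h) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so library calls do not perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    fail_field(field, "must be a finite numeric scalar")
  }
  if (x < lo || x > hi) {
    fail_field(field, sprintf("must be in [%s, %s], got %s", lo, hi, x))
  }
  invisible(x)
}

# Population (divide-by-n) standard deviation; the rmse^2 = me^2 + std^2
# identity used in evaluation is exact under this convention.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
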
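#' Derive a named substream seed from a root seed
#'
#' All randomness in a run flows from one root seed. Independent pipeline
#' stages (cohort generation, screening noise, randomisation, exercise
#' responses, ...) draw from named substreams so that changing one stage's
#' consumption of random numbers does not perturb the others.
#'
#' @param root integer root seed.
#' @param name character substream label.
#' @return An integer in `[1, 2^31 - 2]` suitable for `set.seed()`.
#' @export
#' @examples
#' substream_seed(1, "cohort")
substream_seed <- function(root, name) {
  stopifnot(length(root) == 1, is.finite(root), length(name) == 1)
  h <- fnv1a(paste0(format(root, scientific = FALSE), "/", name))
  as.integer(h %% 2147483645 + 1)
}

# 32-bit FNV-1a over the UTF-8 bytes of a string; arithmetic kept below 2^53.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- (lo + hi * 65536) %% 4294967296
    h <- ((h %% 65536) * 16777619 +
            ((h %/% 65536) * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

# Evaluate `expr` under a temporary RNG state; restores .Random.seed on exit.
# `seed = NULL` means: use the current stream (no isolation).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Truncated-normal sampler hitting a target post-truncation mean
#'
#' Draws from a normal distribution truncated to `[lower, upper]`, with the
#' location parameter solved (by `uniroot`) so that the mean of the
#' *truncated* distribution equals `target_mean`. Without the compensation,
#' truncating e.g. age at 60 or weekly activity hours at 0 would bias sample
#' means away from their configured targets by several tenths of a unit.
#'
#' @param n number of draws.
#' @param target_mean desired mean of the truncated distribution.
#' @param sd scale parameter (pre-truncation SD); must be > 0.
#' @param lower,upper truncation bounds.
#' @return Numeric vector of length `n`.
#' @export
rtrunc_norm <- function(n, target_mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  mu <- solve_trunc_location(target_mean, sd, lower, upper)
  a <- stats::pnorm(lower, mu, sd)
  b <- stats::pnorm(upper, mu, sd)
  stats::qnorm(a + stats::runif(n) * (b - a), mu, sd)
}

trunc_norm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

solve_trunc_location <- function(target_mean, sd, lower, upper) {
  if (!is.finite(lower) && !is.finite(upper)) return(target_mean)
  f <- function(mu) trunc_norm_mean(mu, sd, lower, upper) - target_mean
  # truncated mean is increasing in mu; bracket around the target
  lo <- target_mean - 6 * sd
  hi <- target_mean + 6 * sd
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a hash of a configuration object, used to stamp output files.
config_hash <- function(config) {
  h <- fnv1a(paste(deparse(config), collapse = "\n"))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
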
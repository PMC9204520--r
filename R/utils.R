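# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' Mixes a base seed with per-iteration (and optional class) counters into a
#' 31-bit integer.  Multipliers are small enough that all intermediate products
#' stay below 2^53, so the arithmetic is exact in double precision.
#'
#' @param seed base integer seed (< 2^31).
#' @param iteration iteration counter (>= 0).
#' @param offset optional extra counter (e.g. a parameter-class index).
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()].
#' @keywords internal
mix_seed <- function(seed, iteration, offset = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 131071 +
    as.numeric(iteration) * 524287 +
    as.numeric(offset) * 8191
  as.integer(s %% 2147483629) + 1L
}

# 2D rotation of row-wise points by angle(s) a (radians).
rot2 <- function(px, py, a) {
  ca <- cos(a); sa <- sin(a)
  cbind(x = ca * px - sa * py, y = sa * px + ca * py)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Gravitational acceleration used throughout (m/s^2).
GRAVITY <- 9.81
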
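#' Derive a reproducible sub-seed from a master seed
#'
#' One master seed fans out to per-run, per-particle and per-stream sub-seeds
#' through a fixed integer hash, so changing the number of particles or the
#' map choice never perturbs unrelated random draws. The result is always in
#' `[1, 2^31 - 2]` and safe to pass to [set.seed()].
#'
#' @param seed Integer master seed.
#' @param index Integer index of the consumer (run, particle, stream, ...).
#' @return An integer sub-seed.
#' @export
split_seed <- function(seed, index) {
  s <- abs(as.double(seed)) %% 2147483647
  v <- (s * 48271 + abs(as.double(index)) * 1299721 + 12345) %% 2147483646
  as.integer(v) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Wrap angles to the interval (-pi, pi]
#' @param x Numeric vector of angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
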
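#' Chaotic map single steps
#'
#' One iteration of each of the five chaotic maps used as deterministic
#' random-number sources by the swarm optimizer. All step functions are
#' vectorized in `x`.
#'
#' The maps and their default parameters (the values used throughout the
#' package) are:
#' \describe{
#'   \item{logistic}{`x' = alpha * x * (1 - x)`, `alpha = 4`. Chaotic on
#'     `(0,1)` for starts outside `{0.25, 0.5, 0.75}`; covers the whole
#'     unit interval.}
#'   \item{Singer}{`x' = mu * (7.86 x - 23.31 x^2 + 28.75 x^3 -
#'     13.302875 x^4)`, `mu = 1.07`; values stay inside `(0,1)`.}
#'   \item{sinusoidal}{`x' = alpha * x^2 * sin(pi x)`, `alpha = 2.3`; for
#'     starts in `[0.45, 0.92]` the iterates remain above 0.4, so this map
#'     never produces small multipliers.}
#'   \item{tent}{`x' = x/0.7` for `x < 0.7`, else `(10/3)(1 - x)`.}
#'   \item{Zaslavskii}{two-state map: the auxiliary state is advanced first,
#'     `y' = cos(2 pi x) + exp(-r) y`, then `x' = (x + v + a y') mod 1`,
#'     with `v = 400`, `r = 3`, `a = 12`. `|y|` is bounded by
#'     `1/(1 - exp(-r))`.}
#' }
#'
#' @param x Current state in `(0,1)` (`[0,1)` for the Zaslavskii map).
#' @param y Zaslavskii auxiliary state.
#' @param alpha,mu,v,r,a Map control parameters.
#' @return The next state; `zaslavskii_step()` returns `list(x, y)`.
#' @seealso [chaotic_stream()] for the re-seeding stream interface.
#' @export
logistic_step <- function(x, alpha = 4) alpha * x * (1 - x)

#' @rdname logistic_step
#' @export
singer_step <- function(x, mu = 1.07) {
  mu * (7.86 * x - 23.31 * x^2 + 28.75 * x^3 - 13.302875 * x^4)
}

#' @rdname logistic_step
#' @export
sinusoidal_step <- function(x, alpha = 2.3) alpha * x^2 * sin(pi * x)

#' @rdname logistic_step
#' @export
tent_step <- function(x) ifelse(x < 0.7, x / 0.7, (10 / 3) * (1 - x))

#' @rdname logistic_step
#' @export
zaslavskii_step <- function(x, y, v = 400, r = 3, a = 12) {
  y1 <- cos(2 * pi * x) + exp(-r) * y
  x1 <- (x + v + a * y1) %% 1
  list(x = x1, y = y1)
}

chaos_map_names <- c("logistic", "singer", "sinusoidal", "tent", "zaslavskii")

chaos_map_id <- function(map) match(map, chaos_map_names)

#' Default chaotic-map parameters
#'
#' @param map Map name.
#' @return Named list of the map's control parameters (empty for the tent
#'   map, which has none in its optimization form).
#' @export
chaos_params <- function(map = chaos_map_names) {
  map <- match.arg(map)
  switch(map,
    logistic = list(alpha = 4),
    singer = list(mu = 1.07),
    sinusoidal = list(alpha = 2.3),
    tent = list(),
    zaslavskii = list(v = 400, r = 3, a = 12)
  )
}

chaos_params_vec <- function(map, params) {
  switch(map,
    logistic = as.double(params$alpha),
    singer = as.double(params$mu),
    sinusoidal = as.double(params$alpha),
    tent = 0,
    zaslavskii = as.double(c(params$v, params$r, params$a))
  )
}

lcg_init <- function(seed) (abs(as.double(seed)) %% 2147483646) + 1

#' Create a chaotic stream
#'
#' A stateful generator that advances one of the five chaotic maps and hands
#' out values strictly inside `(0,1)`, for use as a drop-in replacement for
#' uniform random draws. If `x0` is not given, the start state is drawn from
#' the map's admissible chaotic start set (logistic: `(0,1)` minus
#' `{0.25, 0.5, 0.75}`; sinusoidal: `[0.45, 0.92]`; Singer/tent: `(0,1)`;
#' Zaslavskii: `x0` in `[0,1)` with `y0 = 0`) using a small self-contained
#' generator seeded by `seed` -- the stream never touches R's global RNG.
#'
#' If a step lands outside `(0,1)` or within `1e-12` of a fixed point (where
#' the floating-point dynamics would collapse), the stream transparently
#' re-seeds itself from the admissible set and steps again.
#'
#' @param map Map name.
#' @param seed Integer seed for (re-)initialization draws.
#' @param x0,y0 Optional explicit start state.
#' @param params Map parameters, defaulting to [chaos_params()].
#' @return An object of class `chaotic_stream`.
#' @export
chaotic_stream <- function(map = chaos_map_names, seed = 1L, x0 = NULL,
                           y0 = 0, params = chaos_params(map)) {
  map <- match.arg(map)
  st <- new.env(parent = emptyenv())
  st$map <- map
  st$map_id <- chaos_map_id(map)
  st$params <- params
  st$pvec <- chaos_params_vec(map, params)
  st$lcg <- lcg_init(seed)
  if (is.null(x0)) {
    init <- cpp_admissible_start(st$map_id, st$lcg)
    st$x <- init$x
    st$lcg <- init$lcg_state
  } else {
    st$x <- x0
  }
  st$y <- y0
  class(st) <- "chaotic_stream"
  st
}

#' @export
print.chaotic_stream <- function(x, ...) {
  cat("<chaotic_stream>", x$map, " state x =", format(x$x), "\n")
  invisible(x)
}

#' Draw the next value(s) from a chaotic stream
#'
#' Advances the stream `n` steps and returns the visited states, each
#' strictly inside `(0,1)` (degenerate states are re-seeded transparently,
#' see [chaotic_stream()]). For the Zaslavskii map the returned value is the
#' wrapped coordinate `x`.
#'
#' @param stream A [chaotic_stream()].
#' @param n Number of values to draw.
#' @return Numeric vector of length `n` (a scalar for `n = 1`).
#' @export
next_unit <- function(stream, n = 1L) {
  stopifnot(inherits(stream, "chaotic_stream"))
  res <- cpp_chaos_sequence(stream$map_id, as.integer(n), stream$x, stream$y,
                            stream$pvec, stream$lcg)
  stream$x <- res$x
  stream$y <- res$y
  stream$lcg <- res$lcg_state
  res$values
}

#' Raw chaotic trajectory (no degeneracy handling)
#'
#' Iterates the bare dynamical system from a given start, returning every
#' visited state. Unlike [next_unit()], no re-seeding is applied, so this is
#' the tool for studying the dynamics themselves (invariant ranges,
#' bifurcation structure, the Zaslavskii auxiliary state).
#'
#' @param map Map name.
#' @param n Number of iterates.
#' @param x0,y0 Start state.
#' @param params Map parameters.
#' @return A list with numeric vector `x` (and `y` for the Zaslavskii map).
#' @export
chaos_trajectory <- function(map = chaos_map_names, n, x0, y0 = 0,
                             params = chaos_params(map)) {
  map <- match.arg(map)
  cpp_chaos_trajectory(chaos_map_id(map), as.integer(n), x0, y0,
                       chaos_params_vec(map, params))
}
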
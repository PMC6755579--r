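#' Swarm configuration
#'
#' Settings of the particle swarm global search. The defaults are the
#' docking settings used throughout the package: 8 particles, inertia 0.36,
#' cognitive and social coefficients 0.99, Singer-map chaos, two-stage local
#' search with a 0.1 short-stage ratio, and termination after 18 consecutive
#' generations without meaningful improvement of the swarm best. Screening
#' uses 16 particles.
#'
#' @param n_particles Number of particles `N`.
#' @param inertia Constant inertia weight `w` (used when `chaos = "none"`).
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param chaos Chaotic map driving the velocity randomness, or `"none"`
#'   for stock uniform draws with constant inertia.
#' @param ls_ratio Ratio `R` of the first-stage local-search step budget to
#'   the full budget.
#' @param convergence Stall limit `Cr`: consecutive generations without an
#'   improvement of more than `stall_tol` that terminate the search.
#' @param max_generations Hard generation cap.
#' @param seed Master seed; all randomness (swarm init, uniform draws,
#'   chaotic stream starts) derives from it via [split_seed()].
#' @param local_search `"two_stage"` (default), `"full"` (every particle
#'   gets a full-budget refinement, the one-stage baseline), or `"none"`.
#' @param full_steps Full local-search step budget; default `10 * D + 30`.
#' @param stall_tol Minimum improvement (kcal/mol) that resets the stall
#'   counter.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 8, inertia = 0.36, c1 = 0.99,
                         c2 = 0.99,
                         chaos = c("singer", "logistic", "sinusoidal",
                                   "tent", "zaslavskii", "none"),
                         ls_ratio = 0.1, convergence = 18,
                         max_generations = 300, seed = 1L,
                         local_search = c("two_stage", "full", "none"),
                         full_steps = NULL, stall_tol = 1e-4) {
  chaos <- match.arg(chaos)
  local_search <- match.arg(local_search)
  stopifnot(n_particles >= 1, ls_ratio > 0, ls_ratio <= 1, convergence >= 1,
            max_generations >= 1)
  out <- list(n_particles = as.integer(n_particles), inertia = inertia,
              c1 = c1, c2 = c2, chaos = chaos, ls_ratio = ls_ratio,
              convergence = as.integer(convergence),
              max_generations = as.integer(max_generations),
              seed = as.integer(seed), local_search = local_search,
              full_steps = full_steps, stall_tol = stall_tol)
  class(out) <- "swarm_config"
  out
}

#' Velocity updates
#'
#' `velocity_update_standard()` is the canonical rule
#' `V' = w V + c1 r1 (pbest - X) + c2 r2 (gbest - X)` with independent
#' uniform `r1, r2`. `velocity_update_chaotic()` replaces the inertia weight
#' and the randomness by two chaotic variables drawn once per particle per
#' generation: `V' = w_cm V + c1 r_cm (pbest - X) + c2 (1 - r_cm)
#' (gbest - X)`; the cognitive and social random weights are coupled and sum
#' to one. The same scalars multiply all components of the D-vector.
#'
#' @param V,X,pbest,gbest Numeric D-vectors.
#' @param w,c1,c2 PSO coefficients.
#' @param r1,r2 Uniform draws in `[0, 1]`.
#' @param w_cm,r_cm Chaotic draws in `(0, 1)`.
#' @return The new velocity D-vector.
#' @export
velocity_update_standard <- function(V, X, pbest, gbest, w, c1, c2, r1, r2) {
  w * V + c1 * r1 * (pbest - X) + c2 * r2 * (gbest - X)
}

#' @rdname velocity_update_standard
#' @export
velocity_update_chaotic <- function(V, X, pbest, gbest, w_cm, r_cm, c1, c2) {
  w_cm * V + c1 * r_cm * (pbest - X) + c2 * (1 - r_cm) * (gbest - X)
}

#' Position update with box clamping
#'
#' `X' = X + V`, then projected back into the search region: either through
#' the supplied `project` function (the docking engine clamps positions,
#' renormalizes the quaternion and wraps torsions) or by plain clamping to
#' `[lower, upper]`.
#'
#' @param X,V Numeric D-vectors.
#' @param lower,upper Box bounds.
#' @param project Optional projection function.
#' @return The new position.
#' @export
position_update <- function(X, V, lower, upper, project = NULL) {
  Xn <- X + V
  if (!is.null(project)) project(Xn) else clamp(Xn, lower, upper)
}

#' BFGS local search with backtracking line search
#'
#' Quasi-Newton descent on an objective supplying value and gradient,
#' stopping at `max_steps` accepted steps or when the gradient norm drops
#' below `gtol`. The returned point is the best point *evaluated* (including
#' line-search trials), so the result value never exceeds the start value.
#' A non-finite objective at the start aborts and returns the input.
#'
#' @param x Start vector.
#' @param objective Function `f(x, want_gradient = TRUE)` returning
#'   `list(value, gradient)`.
#' @param max_steps Maximum number of accepted quasi-Newton steps.
#' @param gtol Gradient-norm stopping tolerance.
#' @param project Optional projection applied to every trial point.
#' @return `list(par, value, n_steps, n_evals)`.
#' @export
bfgs_local_search <- function(x, objective, max_steps, gtol = 1e-6,
                              project = NULL) {
  ev <- objective(x)
  n_evals <- 1L
  if (!is.finite(ev$value))
    return(list(par = x, value = ev$value, n_steps = 0L, n_evals = n_evals))
  f <- ev$value
  g <- as.double(ev$gradient)
  D <- length(x)
  H <- diag(D)
  best_x <- x
  best_f <- f
  steps <- 0L

  while (steps < max_steps && sqrt(sum(g * g)) >= gtol) {
    p <- as.double(-H %*% g)
    if (!all(is.finite(p)) || sum(p * g) >= 0) {  # not a descent direction
      H <- diag(D)
      p <- -g
    }
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:30) {
      xn <- x + alpha * p
      if (!is.null(project)) xn <- project(xn)
      s <- xn - x
      if (sqrt(sum(s * s)) < 1e-14) break
      en <- objective(xn)
      n_evals <- n_evals + 1L
      if (is.finite(en$value) && en$value <= f + 1e-4 * sum(g * s)) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break
    gn <- as.double(en$gradient)
    yv <- gn - g
    sy <- sum(s * yv)
    if (is.finite(sy) && sy > 1e-12) {
      rho <- 1 / sy
      Hy <- H %*% yv
      # inverse BFGS update
      H <- H - rho * (s %*% t(Hy) + Hy %*% t(s)) +
        rho * (rho * sum(yv * Hy) + 1) * (s %*% t(s))
    }
    x <- xn
    f <- en$value
    g <- gn
    steps <- steps + 1L
    if (f < best_f) {
      best_f <- f
      best_x <- x
    }
  }
  list(par = best_x, value = best_f, n_steps = steps, n_evals = n_evals)
}

#' Two-stage local search
#'
#' A cheap first-stage probe of `max(1, round(ls_ratio * full_steps))` BFGS
#' steps decides whether a freshly moved particle is promising: only when
#' the probe beats the particle's stored personal best does the second stage
#' spend the remaining budget (`full_steps` minus the steps already used) on
#' a full refinement, so the two stages together never exceed the one-stage
#' step budget.
#'
#' @param x The particle position after the velocity/position update.
#' @param pbest_score The particle's current personal-best score.
#' @param objective Objective as in [bfgs_local_search()].
#' @param full_steps Full local-search step budget.
#' @param ls_ratio First-stage fraction of the budget.
#' @param project Optional projection.
#' @return `list(par, value, improved, n_evals, n_steps)`; when
#'   `improved` is `FALSE`, `par` is the input `x` and `value` its
#'   objective value, and the caller should leave pbest untouched.
#' @export
two_stage_local_search <- function(x, pbest_score, objective, full_steps,
                                   ls_ratio = 0.1, project = NULL) {
  s1_steps <- max(1L, as.integer(round(ls_ratio * full_steps)))
  s1 <- bfgs_local_search(x, objective, s1_steps, project = project)
  if (is.finite(s1$value) && s1$value < pbest_score) {
    remaining <- max(0L, as.integer(full_steps) - s1$n_steps)
    if (remaining > 0L) {
      s2 <- bfgs_local_search(s1$par, objective, remaining, project = project)
      return(list(par = s2$par, value = s2$value, improved = TRUE,
                  n_evals = s1$n_evals + s2$n_evals,
                  n_steps = s1$n_steps + s2$n_steps))
    }
    return(list(par = s1$par, value = s1$value, improved = TRUE,
                n_evals = s1$n_evals, n_steps = s1$n_steps))
  }
  list(par = x, value = NA_real_, improved = FALSE,
       n_evals = s1$n_evals, n_steps = s1$n_steps)
}

#' Particle swarm global search
#'
#' Chaos-embedded PSO over a box-bounded search space with the two-stage
#' BFGS local search and stall-based convergence detection. The swarm is
#' initialized uniformly in the box (or by `init`), velocities start at
#' zero, and each generation applies the velocity update (chaotic or
#' standard), the position update with projection, and the configured local
#' search. The search stops when the swarm best has not improved by more
#' than `stall_tol` for `convergence` consecutive generations, or at
#' `max_generations`.
#'
#' @param objective Function `f(x, want_gradient = TRUE)` returning
#'   `list(value, gradient)`.
#' @param lower,upper Box bounds (length-D vectors).
#' @param cfg A [swarm_config()].
#' @param project Optional projection replacing plain clamping.
#' @param init Optional function `init(n)` returning an `n x D` start
#'   matrix (drawn with R's RNG, which is seeded before the call).
#' @param vmax Optional per-dimension velocity clamp (defaults to half the
#'   box length).
#' @param delta Optional function `delta(X, target)` returning the
#'   attraction vector `target - X` in the search geometry; the docking
#'   engine uses it to take the short way around for periodic torsions and
#'   to resolve the quaternion sign ambiguity. Default: plain difference.
#' @return `list(par, value, generations, n_evals, trace)` where `trace` is
#'   a data.frame of per-generation swarm bests and stall counts.
#' @export
pso_search <- function(objective, lower, upper, cfg = swarm_config(),
                       project = NULL, init = NULL, vmax = NULL,
                       delta = NULL) {
  D <- length(lower)
  stopifnot(length(upper) == D, all(upper >= lower))
  N <- cfg$n_particles
  full_steps <- cfg$full_steps %||% (10L * D + 30L)
  if (is.null(vmax)) vmax <- (upper - lower) / 2
  set.seed(split_seed(cfg$seed, 1L))

  X <- if (is.null(init)) {
    matrix(runif(N * D, rep(lower, each = N), rep(upper, each = N)), N, D)
  } else {
    init(N)
  }
  V <- matrix(0, N, D)

  chaos_on <- cfg$chaos != "none"
  if (chaos_on) {
    w_streams <- lapply(seq_len(N), function(i)
      chaotic_stream(cfg$chaos, seed = split_seed(cfg$seed, 100L + 2L * i)))
    r_streams <- lapply(seq_len(N), function(i)
      chaotic_stream(cfg$chaos, seed = split_seed(cfg$seed, 101L + 2L * i)))
  }

  pbest_X <- X
  pbest_f <- numeric(N)
  n_evals <- 0L
  for (i in seq_len(N)) {
    ev <- objective(X[i, ], want_gradient = FALSE)
    n_evals <- n_evals + 1L
    pbest_f[i] <- if (is.finite(ev$value)) ev$value else Inf
  }
  gb <- which.min(pbest_f)
  gbest_f <- pbest_f[gb]
  gbest_X <- pbest_X[gb, ]

  stall <- 0L
  gbest_prev <- Inf
  trace <- vector("list", cfg$max_generations)
  t_final <- 0L

  for (t in seq_len(cfg$max_generations)) {
    for (i in seq_len(N)) {
      pb_eff <- if (is.null(delta)) pbest_X[i, ] else
        X[i, ] + delta(X[i, ], pbest_X[i, ])
      gb_eff <- if (is.null(delta)) gbest_X else
        X[i, ] + delta(X[i, ], gbest_X)
      if (chaos_on) {
        w_cm <- next_unit(w_streams[[i]])
        r_cm <- next_unit(r_streams[[i]])
        Vn <- velocity_update_chaotic(V[i, ], X[i, ], pb_eff, gb_eff,
                                      w_cm, r_cm, cfg$c1, cfg$c2)
      } else {
        Vn <- velocity_update_standard(V[i, ], X[i, ], pb_eff, gb_eff,
                                       cfg$inertia, cfg$c1, cfg$c2,
                                       runif(1), runif(1))
      }
      Vn <- clamp(Vn, -vmax, vmax)
      Xn <- position_update(X[i, ], Vn, lower, upper, project)
      V[i, ] <- Vn

      if (cfg$local_search == "two_stage") {
        res <- two_stage_local_search(Xn, pbest_f[i], objective, full_steps,
                                      cfg$ls_ratio, project)
        n_evals <- n_evals + res$n_evals
        if (res$improved) {
          X[i, ] <- res$par
          pbest_X[i, ] <- res$par
          pbest_f[i] <- res$value
        } else {
          X[i, ] <- Xn
        }
      } else if (cfg$local_search == "full") {
        res <- bfgs_local_search(Xn, objective, full_steps, project = project)
        n_evals <- n_evals + res$n_evals
        X[i, ] <- res$par
        if (is.finite(res$value) && res$value < pbest_f[i]) {
          pbest_X[i, ] <- res$par
          pbest_f[i] <- res$value
        }
      } else {
        ev <- objective(Xn, want_gradient = FALSE)
        n_evals <- n_evals + 1L
        X[i, ] <- Xn
        if (is.finite(ev$value) && ev$value < pbest_f[i]) {
          pbest_X[i, ] <- Xn
          pbest_f[i] <- ev$value
        }
      }
    }

    gb <- which.min(pbest_f)
    gbest_f <- pbest_f[gb]
    gbest_X <- pbest_X[gb, ]
    if (gbest_prev - gbest_f > cfg$stall_tol) stall <- 0L else
      stall <- stall + 1L
    gbest_prev <- gbest_f
    trace[[t]] <- c(generation = t, gbest = gbest_f, stall = stall)
    t_final <- t
    if (stall >= cfg$convergence) break
  }

  list(par = gbest_X, value = gbest_f, generations = t_final,
       n_evals = n_evals,
       trace = as.data.frame(do.call(rbind, trace[seq_len(t_final)])))
}
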
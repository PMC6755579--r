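test_that("velocity updates match hand-computed 1-D cases", {
  # standard rule: w V + c1 r1 (pbest - X) + c2 r2 (gbest - X)
  expect_equal(velocity_update_standard(1, 0, 1, 2, w = 0.36, c1 = 0.99,
                                        c2 = 0.99, r1 = 1, r2 = 1),
               0.36 + 0.99 + 1.98)
  expect_equal(velocity_update_standard(5, 1, 1, 1, 0.36, 0.99, 0.99, 1, 1),
               0.36 * 5)
  expect_equal(velocity_update_standard(2, 0.5, 1, 3, 0.5, 0.99, 0.99, 0, 0),
               0.5 * 2)
  # equilibrium: at pbest = gbest = X with V = 0 nothing moves
  expect_equal(velocity_update_standard(0, 1, 1, 1, 0.36, 0.99, 0.99,
                                        0.3, 0.8), 0)
  # chaotic rule: w_cm V + c1 r_cm (pbest - X) + c2 (1 - r_cm) (gbest - X)
  expect_equal(velocity_update_chaotic(1, 0, 1, 2, w_cm = 0.5, r_cm = 0.25,
                                       c1 = 0.99, c2 = 0.99),
               0.5 + 0.2475 + 1.485)
  expect_equal(velocity_update_chaotic(0, 1, 1, 1, 0.9, 0.1, 0.99, 0.99), 0)
  # the cognitive and social random weights are coupled: r and (1 - r)
  for (r_cm in c(0.1, 0.5, 0.9)) {
    v <- velocity_update_chaotic(0, 0, 1, 1, 0.5, r_cm, 1, 1)
    expect_equal(v, r_cm + (1 - r_cm))
  }
})

test_that("position update clamps to the box and wraps torsions", {
  expect_equal(position_update(0, 1, -5, 5), 1)
  expect_equal(position_update(4.8, 1, -5, 5), 5)
  expect_equal(position_update(-4.9, -3, -5, 5), -5)
  proj <- function(X) c(clamp(X[1], -1, 1), wrap_angle(X[2]))
  out <- position_update(c(0.5, pi - 0.1), c(1, 0.2), NULL, NULL, proj)
  expect_equal(out, c(1, -pi + 0.1))
})

test_that("BFGS solves quadratic bowls and Rosenbrock", {
  # already at the minimum: no steps taken
  quad <- function(x, want_gradient = TRUE)
    list(value = sum((x - c(1, 2))^2), gradient = 2 * (x - c(1, 2)))
  res <- bfgs_local_search(c(1, 2), quad, 100)
  expect_equal(res$n_steps, 0L)
  expect_equal(res$par, c(1, 2))
  # from the origin
  res <- bfgs_local_search(c(0, 0), quad, 100)
  expect_equal(res$par, c(1, 2), tolerance = 1e-6)
  expect_lt(res$value, 1e-10)
  # Rosenbrock from the classic start
  obj <- make_test_objective("rosenbrock", 2)
  res <- bfgs_local_search(c(-1.2, 1), obj$fn, 200)
  expect_lt(res$value, 1e-6)
  # independent oracle: stats::optim BFGS reaches the same minimum
  ref <- stats::optim(c(-1.2, 1), function(x) obj$fn(x)$value,
                      function(x) obj$fn(x)$gradient, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  expect_equal(res$value, ref$value, tolerance = 1e-5)
  # non-finite start aborts, returning the input
  bad <- function(x, want_gradient = TRUE) list(value = NaN, gradient = x)
  res <- bfgs_local_search(c(1, 1), bad, 50)
  expect_equal(res$par, c(1, 1))
  expect_equal(res$n_steps, 0L)
})

test_that("BFGS never returns a value above the start and respects budgets", {
  set.seed(14)
  obj <- make_test_objective("rastrigin", 3)
  for (rep in 1:10) {
    x0 <- runif(3, -5.12, 5.12)
    v0 <- obj$fn(x0)$value
    res <- bfgs_local_search(x0, obj$fn, 5)
    expect_lte(res$value, v0)
    expect_lte(res$n_steps, 5L)
  }
})

test_that("two-stage search gates the full refinement on pbest improvement", {
  counter <- local({
    n <- 0L
    list(fn = function(x, want_gradient = TRUE) {
      n <<- n + 1L
      list(value = sum(x^2), gradient = 2 * x)
    },
    count = function() n,
    reset = function() n <<- 0L)
  })
  # pbest far better than anything reachable: stage 2 must not run
  counter$reset()
  res <- two_stage_local_search(c(3, 3), pbest_score = -100, counter$fn,
                                full_steps = 50, ls_ratio = 0.1)
  expect_false(res$improved)
  n_gated <- counter$count()
  # pbest worse than the probe result: stage 2 runs and spends more calls
  counter$reset()
  res2 <- two_stage_local_search(c(3, 3), pbest_score = 100, counter$fn,
                                 full_steps = 50, ls_ratio = 0.1)
  expect_true(res2$improved)
  expect_lt(res2$value, 1e-8)
  expect_gt(counter$count(), n_gated)
  # stage-1 + stage-2 step budget never exceeds the one-stage budget
  expect_lte(res2$n_steps, 50L)
})

test_that("with ls_ratio = 1 the two-stage search equals one full search", {
  obj <- make_test_objective("rosenbrock", 2)
  r2 <- two_stage_local_search(c(-1.2, 1), pbest_score = Inf, obj$fn,
                               full_steps = 80, ls_ratio = 1)
  r1 <- bfgs_local_search(c(-1.2, 1), obj$fn, 80)
  expect_equal(r2$par, r1$par)
  expect_equal(r2$value, r1$value)
})

test_that("the swarm recovers a shifted sphere minimum across seeds", {
  obj <- make_test_objective("sphere", 3, lower = -4, upper = 4,
                             center = c(1.2, -0.7, 2.1))
  for (seed in 1:20) {
    res <- pso_search(obj$fn, obj$lower, obj$upper,
                      swarm_config(seed = seed, max_generations = 120))
    expect_lt(res$value, 1e-6)
    expect_lt(max(abs(res$par - obj$minimizer)), 1e-3)
  }
})

test_that("gbest is monotone and equals the best evaluated value", {
  log_env <- new.env()
  log_env$values <- numeric(0)
  obj <- make_test_objective("rastrigin", 2)
  logged <- function(x, want_gradient = TRUE) {
    out <- obj$fn(x)
    log_env$values <- c(log_env$values, out$value)
    out
  }
  for (seed in c(3, 17)) {
    log_env$values <- numeric(0)
    res <- pso_search(logged, obj$lower, obj$upper,
                      swarm_config(seed = seed, max_generations = 40))
    expect_equal(res$value, min(log_env$values))
    expect_true(all(diff(res$trace$gbest) <= 0))
  }
})

test_that("a constant objective with Cr = 1 stops at generation 2", {
  flat <- function(x, want_gradient = TRUE)
    list(value = 1, gradient = rep(0, length(x)))
  res <- pso_search(flat, c(-1, -1), c(1, 1),
                    swarm_config(convergence = 1, local_search = "none",
                                 max_generations = 100))
  expect_equal(res$generations, 2)
})

test_that("fixed seeds reproduce the search exactly, with and without chaos", {
  obj <- make_test_objective("rastrigin", 2)
  for (chaos in c("none", "singer")) {
    cfg <- swarm_config(seed = 5, chaos = chaos, max_generations = 30)
    r1 <- pso_search(obj$fn, obj$lower, obj$upper, cfg)
    r2 <- pso_search(obj$fn, obj$lower, obj$upper, cfg)
    expect_identical(r1$par, r2$par)
    expect_identical(r1$value, r2$value)
    expect_identical(r1$trace, r2$trace)
  }
})
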
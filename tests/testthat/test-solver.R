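test_that("block update reduces to a diagonal Newton step without penalty", {
  set.seed(5)
  grid <- array(rnorm(4), dim = c(2, 2, 1))
  w <- matrix(c(0, 1, 1, 0), 2)
  cfg0 <- penalty_config(0, 0)
  grad <- 0.8; curv <- -2; bt <- grid[1, 1, ]
  got <- block_update(grid, 1, 1, grad, curv, bt, w, cfg0)
  expect_equal(got, bt - grad / curv)  # beta_tilde - W^{-1} LL'
})

test_that("block update on an empty cell is the weighted neighbour average", {
  # interior period, zero information: W = 0, LL' = 0
  p <- 2; q <- 3
  grid <- array(rnorm(p * q), dim = c(p, q, 1))
  w <- matrix(c(0, 0.4, 0.4, 0), 2)
  cfg <- penalty_config(1.2, 0.9)
  got <- block_update(grid, 1, 2, grad = 0, curv = 0,
                      beta_tilde = 0, w = w, cfg = cfg)
  osum <- 0.4
  expected <- (1.2 * (grid[1, 1, ] + grid[1, 3, ]) +
                 0.9 * 0.4 * grid[2, 2, ]) / (2 * 1.2 + 0.9 * osum)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("block update matches the hand-worked scalar case", {
  # m=1, W=-0.25, LL'=0.5, beta_tilde=0, interior period, all
  # neighbours at 1, lambda1=lambda2=1, spatial weight sum 0.5
  p <- 2; q <- 3
  grid <- array(1, dim = c(p, q, 1))
  w <- matrix(c(0, 0.5, 0.5, 0), 2)
  cfg <- penalty_config(1, 1)
  got <- block_update(grid, 1, 2, grad = 0.5, curv = -0.25,
                      beta_tilde = 0, w = w, cfg = cfg)
  expect_equal(got, -3 / -2.75, tolerance = 1e-10)  # ~1.0909
})

test_that("block update refuses an unpenalized zero-information coordinate", {
  grid <- array(0, dim = c(2, 1, 1))
  w <- matrix(c(0, 1, 1, 0), 2)
  expect_error(block_update(grid, 1, 1, grad = 0, curv = 0, beta_tilde = 0,
                            w = w, cfg = penalty_config(0, 0)),
               "non-identifiable")
})

test_that("inner cycle solves the surrogate exactly on a 2-cell toy", {
  # p=1, q=2, m=1 with hand-set derivatives: stationarity is a 2x2 system
  grid0 <- array(0, dim = c(1, 2, 1))
  bt <- array(c(0.3, -0.2), dim = c(1, 2, 1))
  derivs <- list(grad = matrix(c(1.1, -0.7), 2, 1),
                 curv = matrix(c(-2, -3), 2, 1))
  w <- matrix(0, 1, 1)
  cfg <- penalty_config(0.8, 0)
  opts <- solver_options()
  res <- inner_cycle(grid0, bt, derivs, w, cfg, opts)
  # (curv - lambda1) b1 + lambda1 b2 = curv*bt1 - grad1 ; symmetric for b2
  A <- matrix(c(-2 - 0.8, 0.8, 0.8, -3 - 0.8), 2, 2, byrow = TRUE)
  b <- c(-2 * 0.3 - 1.1, -3 * -0.2 + 0.7)
  expect_equal(as.vector(res$grid), solve(A, b), tolerance = 1e-8)
})

test_that("inner cycle decouples into diagonal Newton steps at lambda 0", {
  set.seed(13)
  p <- 2; q <- 2; m <- 2
  bt <- array(rnorm(p * q * m), dim = c(p, q, m))
  derivs <- list(grad = matrix(rnorm(p * q * m), p * q, m),
                 curv = matrix(-runif(p * q * m, 0.5, 2), p * q, m))
  w <- matrix(c(0, 1, 1, 0), 2)
  res <- inner_cycle(bt, bt, derivs, w, penalty_config(0, 0),
                     solver_options())
  expected <- matrix(bt, p * q, m) - derivs$grad / derivs$curv
  expect_equal(matrix(res$grid, p * q, m), expected, tolerance = 1e-10)
  # and a grid already at the optimum is a fixed point in one sweep
  res2 <- inner_cycle(res$grid, bt, derivs, w, penalty_config(0, 0),
                      solver_options())
  expect_equal(res2$grid, res$grid, tolerance = 1e-12)
  expect_equal(res2$sweeps, 1L)
})

test_that("smoothed fit with lambda 0 equals separate estimation", {
  sim <- small_sim(p = 2, q = 2, m = 2, n = 150, seed = 41)
  w <- weights_from_distances(sim$distances)
  f0 <- fit_smoothed(sim$panel, w, penalty_config(0, 0))
  sep <- fit_separate(sim$panel)
  expect_true(f0$converged)
  expect_lt(max(abs(f0$beta - sep$beta)), 1e-3)
})

test_that("objective ascends and stationarity holds at convergence", {
  set.seed(47)
  for (rep in 1:50) {
    sim <- small_sim(p = 2, q = 2, m = 1, n = 25, seed = 1000 + rep)
    w <- weights_from_distances(sim$distances)
    lam <- exp(runif(1, -2, 2))
    cfg <- penalty_config(lam, lam)
    fit <- fit_smoothed(sim$panel, w, cfg)
    expect_true(all(diff(fit$objective_trace) >= -1e-8))
    if (fit$converged) {
      pg <- penalized_gradient(sim$panel, fit$beta, w, cfg)
      expect_lt(max(abs(pg)), 10 * 1e-3)
    }
  }
})

test_that("estimates are continuous in lambda near zero", {
  sim <- small_sim(p = 2, q = 2, m = 2, n = 150, seed = 53)
  w <- weights_from_distances(sim$distances)
  f0 <- fit_smoothed(sim$panel, w, penalty_config(0, 0))
  fe <- fit_smoothed(sim$panel, w, penalty_config(1e-8, 1e-8))
  expect_lt(max(abs(f0$beta - fe$beta)), 1e-4)
})

test_that("an empty cell converges to the weighted neighbour average", {
  sim <- small_sim(p = 2, q = 2, m = 2, n = 120, seed = 59)
  panel <- sim$panel
  panel$strata[[3]] <- stratum_data(numeric(0), integer(0), matrix(0, 0, 2))
  panel$n_total <- sum(vapply(panel$strata, function(s) s$n, 0L))
  w <- weights_from_distances(sim$distances)
  cfg <- penalty_config(0.7, 1.1)
  fit <- fit_smoothed(panel, w, cfg)
  b <- fit$beta
  # cell (1, 2) is empty; q = 2 so its only temporal neighbour is j = 1
  osum <- sum(w[1, -1])
  expected <- (0.7 * b[1, 1, ] + 1.1 * w[1, 2] * b[2, 2, ]) /
    (0.7 + 1.1 * osum)
  expect_equal(b[1, 2, ], expected, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("total penalty at the fit is nonincreasing in lambda", {
  sim <- small_sim(p = 3, q = 3, m = 2, n = 80, seed = 61)
  w <- weights_from_distances(sim$distances)
  pens <- vapply(c(0.1, 1, 10, 100), function(lam) {
    cfg <- penalty_config(lam, lam)
    fit <- fit_smoothed(sim$panel, w, cfg)
    penalty_value(fit$beta, w, penalty_config(1, 1))
  }, 0)
  expect_true(all(diff(pens) <= 1e-8))
})

test_that("solver reports non-convergence at a tiny iteration cap", {
  sim <- small_sim(p = 2, q = 2, m = 2, n = 100, seed = 67)
  w <- weights_from_distances(sim$distances)
  fit <- fit_smoothed(sim$panel, w, penalty_config(1, 1),
                      solver_options(max_outer = 1L))
  expect_false(fit$converged)
  expect_equal(fit$outer_iterations, 1L)
})

test_that("separate initialization reaches the same optimum", {
  sim <- small_sim(p = 2, q = 2, m = 2, n = 120, seed = 71)
  w <- weights_from_distances(sim$distances)
  cfg <- penalty_config(1, 1)
  f_zero <- fit_smoothed(sim$panel, w, cfg, solver_options(init = "zero"))
  f_sep <- fit_smoothed(sim$panel, w, cfg,
                        solver_options(init = "separate"))
  expect_lt(max(abs(f_zero$beta - f_sep$beta)), 5e-3)
})
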
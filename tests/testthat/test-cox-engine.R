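test_that("log partial likelihood matches hand-worked values", {
  s <- stratum_data(c(1, 2), c(1, 1), matrix(c(0, 0), 2, 1))
  # beta = 0: each event contributes -log(risk set size)
  expect_equal(stratum_loglik(s, 0), -log(2))

  s2 <- stratum_data(c(1, 2), c(1, 1), matrix(c(1, 0), 2, 1))
  # first event: log 2 - log(2 + 1); second: 0 - log 1
  expect_equal(stratum_loglik(s2, log(2)), log(2) - log(3))

  s0 <- stratum_data(numeric(0), integer(0), matrix(0, 0, 1))
  expect_equal(stratum_loglik(s0, 5), 0)
  # no events -> 0 at any beta
  s3 <- stratum_data(c(1, 2), c(0, 0), matrix(c(1, 2), 2, 1))
  expect_equal(stratum_loglik(s3, 3), 0)

  expect_error(stratum_loglik(s2, c(1, 2)), "length")
})

test_that("score and curvature match hand-worked values", {
  s <- stratum_data(c(1, 2), c(1, 1), matrix(c(1, 0), 2, 1))
  expect_equal(stratum_gradient(s, 0), 0.5)
  expect_equal(stratum_diag_curvature(s, 0), -0.25)

  # constant covariate column: zero score and zero curvature at any beta
  sc <- stratum_data(1:4, c(1, 1, 0, 1), matrix(2, 4, 1))
  expect_equal(stratum_gradient(sc, 1.3), 0)
  expect_equal(stratum_diag_curvature(sc, 1.3), 0)

  s3 <- stratum_data(c(1, 2), c(0, 0), matrix(c(1, 2), 2, 1))
  expect_equal(stratum_gradient(s3, 0), 0)
})

test_that("cumulative-sum engine equals the naive risk-set oracle", {
  set.seed(101)
  for (rep in 1:20) {
    s <- rand_stratum(sample(5:50, 1), sample(1:3, 1),
                      ties = rep %% 2 == 0)
    beta <- rnorm(ncol(s$covariates))
    ref <- naive_derivs(s, beta)
    expect_equal(stratum_loglik(s, beta), ref$loglik, tolerance = 1e-10)
    expect_equal(stratum_gradient(s, beta), ref$gradient, tolerance = 1e-10)
    expect_equal(stratum_diag_curvature(s, beta), ref$diag_curvature,
                 tolerance = 1e-10)
  }
})

test_that("derivatives agree with finite differences of the likelihood", {
  set.seed(202)
  for (rep in 1:5) {
    m <- sample(2:4, 1)
    s <- rand_stratum(40, m)
    beta <- rnorm(m) / 2
    g <- stratum_gradient(s, beta)
    fd <- vapply(seq_len(m), function(l) {
      e <- numeric(m); e[l] <- 1e-5
      (stratum_loglik(s, beta + e) - stratum_loglik(s, beta - e)) / 2e-5
    }, 0)
    expect_equal(g, fd, tolerance = 1e-6)
    cu <- stratum_diag_curvature(s, beta)
    fd2 <- vapply(seq_len(m), function(l) {
      e <- numeric(m); e[l] <- 1e-4
      (stratum_gradient(s, beta + e)[l] -
         stratum_gradient(s, beta - e)[l]) / 2e-4
    }, 0)
    expect_equal(cu, fd2, tolerance = 1e-5)
    expect_true(all(cu <= 0))
  }
})

test_that("log partial likelihood is concave along random lines", {
  set.seed(303)
  s <- rand_stratum(30, 2)
  for (rep in 1:10) {
    b0 <- rnorm(2); dir <- rnorm(2); h <- 0.05
    f <- vapply(-1:1, function(k) stratum_loglik(s, b0 + k * h * dir), 0)
    expect_lte(f[1] - 2 * f[2] + f[3], 1e-8)
  }
})

test_that("extreme linear predictors do not overflow", {
  s <- stratum_data(c(1, 2), c(1, 1), matrix(c(1, 0), 2, 1))
  ll <- stratum_loglik(s, 700)
  expect_true(is.finite(ll))
  expect_true(all(is.finite(stratum_gradient(s, 700))))
})

test_that("total log likelihood is additive over cells", {
  sim <- small_sim(p = 2, q = 2, m = 2, n = 10, seed = 9)
  grid <- array(0.2, dim = c(2, 2, 2))
  manual <- sum(vapply(1:2, function(j) sum(vapply(1:2, function(i)
    stratum_loglik(panel_stratum(sim$panel, i, j), grid[i, j, ]), 0)), 0))
  expect_equal(total_loglik(sim$panel, grid), manual)

  empty <- stratum_data(numeric(0), integer(0), matrix(0, 0, 1))
  pan0 <- panel_data(list(empty, empty), location_ids = 1:2,
                     period_ids = 1, covariate_names = "x")
  expect_equal(total_loglik(pan0, array(1, c(2, 1, 1))), 0)
})

test_that("per-stratum Newton MLE matches coxph and handles separation", {
  set.seed(404)
  s <- rand_stratum(60, 3)
  fit <- fit_stratum_mle(s)
  expect_true(fit$converged)
  library(survival)
  cf <- coxph(Surv(s$times, s$events) ~ s$covariates, ties = "breslow")
  expect_equal(fit$beta, unname(coef(cf)), tolerance = 1e-6)

  # monotone likelihood: score 1/(e^b + 1) > 0 for all b, MLE diverges
  mono <- stratum_data(c(1, 2), c(1, 1), matrix(c(1, 0), 2, 1))
  mfit <- fit_stratum_mle(mono)
  expect_false(mfit$converged)

  # exchangeable covariate between tied events -> MLE exactly 0 by symmetry
  symfit <- fit_stratum_mle(stratum_data(c(1, 1), c(1, 1),
                                         matrix(c(1, -1), 2, 1)))
  expect_equal(symfit$beta, 0, tolerance = 1e-8)

  expect_error(fit_stratum_mle(stratum_data(1, 0, matrix(1, 1, 1))),
               "no events")
  expect_error(fit_stratum_mle(stratum_data(c(1, 2), c(1, 1),
                                            matrix(1, 2, 1))),
               "degenerate")
})

test_that("MLE recovers simulation truth within 3 standard errors", {
  set.seed(18)
  beta_true <- c(0.5, -0.5)
  X <- cbind(rnorm(500), rbinom(500, 1, 0.5))
  tt <- -log(runif(500)) / exp(X %*% beta_true)
  s <- stratum_data(as.vector(tt), rep(1L, 500), X)
  fit <- fit_stratum_mle(s)
  library(survival)
  se <- sqrt(diag(vcov(coxph(Surv(s$times, s$events) ~ s$covariates,
                             ties = "breslow"))))
  expect_true(all(abs(fit$beta - beta_true) < 3 * se))
})

test_that("separate estimation flags unfittable cells and matches per-cell MLE", {
  sim <- small_sim(p = 2, q = 2, m = 2, n = 60, seed = 21)
  panel <- sim$panel
  # empty one cell
  panel$strata[[2]] <- stratum_data(numeric(0), integer(0), matrix(0, 0, 2))
  panel$n_total <- sum(vapply(panel$strata, function(s) s$n, 0L))
  sep <- fit_separate(panel)
  expect_equal(sep$flags[2, 1], "no_events")
  expect_true(all(is.na(sep$beta[2, 1, ])))
  for (j in 1:2) for (i in 1:2) {
    if (i == 2 && j == 1) next
    ref <- fit_stratum_mle(panel_stratum(panel, i, j))
    expect_equal(sep$beta[i, j, ], unname(ref$beta), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("pooled estimation concatenates risk sets", {
  sim <- small_sim(p = 2, q = 2, m = 2, n = 40, seed = 23)
  pool <- fit_pooled(sim$panel, "over_both")
  expect_equal(dim(pool), c(1L, 2L))
  ref <- fit_stratum_mle(stcox:::concat_strata(sim$panel$strata, 2))
  expect_equal(unname(pool[1, ]), ref$beta, tolerance = 1e-10)

  # p = 1 panel: pooling over locations is the per-period separate fit
  sim1 <- simulate_panel(sim_config(p = 1, q = 3, m = 2, n_per_cell = 80,
                                    n_continuous = 1, n_binary = 1,
                                    seed = 29))
  overloc <- fit_pooled(sim1$panel, "over_locations")
  sep <- fit_separate(sim1$panel)
  expect_equal(dim(overloc), c(3L, 2L))
  for (j in 1:3)
    expect_equal(unname(overloc[j, ]), unname(sep$beta[1, j, ]),
                 tolerance = 1e-8)

  # homogeneous truth: pooled estimate near the common coefficients
  simh <- simulate_panel(sim_config(p = 2, q = 2, m = 2, n_per_cell = 400,
                                    n_continuous = 1, n_binary = 1,
                                    effect_scale = 0, seed = 31))
  poolh <- fit_pooled(simh$panel, "over_both")
  expect_true(all(abs(poolh[1, ]) < 3 * sqrt(1 / simh$panel$n_total) * 3))
})
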
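# shared fixtures and independent oracles, all built in code

# random stratum with optional tied times (times rounded to a lattice)
rand_stratum <- function(n, m, event_p = 0.7, ties = FALSE) {
  tm <- rexp(n)
  if (ties) tm <- ceiling(tm * 4) / 4
  stratum_data(tm, rbinom(n, 1, event_p), matrix(rnorm(n * m), n, m))
}

# naive O(n^2) risk-set oracle for loglik / gradient / diagonal curvature;
# independent of the package's cumulative-sum engine
naive_derivs <- function(s, beta) {
  n <- s$n
  m <- ncol(s$covariates)
  ll <- 0
  gr <- numeric(m)
  cv <- numeric(m)
  for (k in seq_len(n)) {
    if (s$events[k] != 1) next
    R <- which(s$times >= s$times[k])
    w <- exp(as.vector(s$covariates[R, , drop = FALSE] %*% beta))
    ll <- ll + sum(s$covariates[k, ] * beta) - log(sum(w))
    for (l in seq_len(m)) {
      x <- s$covariates[R, l]
      mu <- sum(w * x) / sum(w)
      gr[l] <- gr[l] + s$covariates[k, l] - mu
      cv[l] <- cv[l] - (sum(w * x^2) / sum(w) - mu^2)
    }
  }
  list(loglik = ll, gradient = gr, diag_curvature = cv)
}

# small simulated panel for solver/tuning/inference tests
small_sim <- function(p = 3, q = 3, m = 2, n = 100, seed = 1,
                      surface = "smooth", censoring = 0.25) {
  simulate_panel(sim_config(p = p, q = q, m = m, n_per_cell = n,
                            n_continuous = ceiling(m / 2),
                            n_binary = floor(m / 2),
                            target_censoring = censoring,
                            surface = surface, seed = seed))
}

# two-location, one-period toy panel written to CSV for the readers
write_toy_panel_csv <- function(path) {
  df <- data.frame(
    location = c("A", "A", "A", "B", "B", "B"),
    period = 1,
    time = c(3, 1, 2, 2.5, 0.5, 1.5),
    event = c(1, 1, 0, 1, 0, 1),
    age = c(60, 55, 70, 62, 58, 66),
    male = c(1, 0, 1, 0, 0, 1))
  write.csv(df, path, row.names = FALSE)
  df
}

grid_of <- function(vals, p, q, m) {
  array(vals, dim = c(p, q, m))
}

# full penalized gradient at a grid (likelihood score minus penalty grad)
penalized_gradient <- function(panel, grid, w, cfg) {
  out <- array(0, dim = dim(grid))
  for (j in seq_len(panel$q)) for (i in seq_len(panel$p))
    out[i, j, ] <- stratum_gradient(panel_stratum(panel, i, j), grid[i, j, ]) -
      penalty_gradient_block(grid, i, j, w, cfg)
  out
}
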
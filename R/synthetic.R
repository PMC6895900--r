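#' Simulation configuration
#'
#' Describes a synthetic survival panel: grid shape, per-cell sample
#' sizes, covariate mix, exponential baseline hazard, target censoring
#' rate, and the shape of the true coefficient surface.  The defaults
#' describe a moderate registry-style panel: 4 locations on a lattice,
#' 5 consecutive periods, 8 covariates (half continuous, half binary),
#' 100 subjects per cell, ~30% censoring, and a coefficient surface
#' that drifts smoothly over time and space with unit effect scale.
#'
#' @param p,q,m locations, periods, covariates.
#' @param n_per_cell scalar, or p x q matrix of per-cell sample sizes.
#' @param n_continuous,n_binary how many covariates are standard normal
#'   vs Bernoulli(0.5); must sum to m.
#' @param baseline_rate constant baseline hazard (exponential event
#'   times per unit time; the estimator never sees it).
#' @param target_censoring desired censoring fraction in \[0.01, 0.99\],
#'   or exactly 0 for no censoring.
#' @param surface `"smooth"` (affine drift in period and in the first
#'   spatial coordinate) or `"abrupt"` (independent random signs cell
#'   to cell — deliberately non-smooth, to stress the smoothing
#'   assumption).
#' @param effect_scale maximum absolute true coefficient.
#' @param location_layout `"grid"` (near-square unit lattice) or
#'   `"unit_square_random"` (uniform points).
#' @param seed integer seed; every random element of the simulation is
#'   derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(p = 4L, q = 5L, m = 8L, n_per_cell = 100L,
                       n_continuous = 4L, n_binary = 4L,
                       baseline_rate = 1, target_censoring = 0.3,
                       surface = c("smooth", "abrupt"), effect_scale = 1,
                       location_layout = c("grid", "unit_square_random"),
                       seed = 1L) {
  surface <- match.arg(surface)
  location_layout <- match.arg(location_layout)
  stopifnot(p >= 1, q >= 1, p >= 2 || q >= 2, m >= 1,
            n_continuous + n_binary == m,
            baseline_rate > 0, effect_scale >= 0)
  if (target_censoring != 0 &&
      (target_censoring < 0.01 || target_censoring > 0.99))
    stop("target_censoring must be 0 (none) or within [0.01, 0.99]")
  if (is.matrix(n_per_cell)) {
    stopifnot(all(dim(n_per_cell) == c(p, q)), all(n_per_cell >= 1))
  } else {
    stopifnot(length(n_per_cell) == 1, n_per_cell >= 1)
    n_per_cell <- matrix(as.integer(n_per_cell), p, q)
  }
  structure(list(p = as.integer(p), q = as.integer(q), m = as.integer(m),
                 n_per_cell = n_per_cell,
                 n_continuous = as.integer(n_continuous),
                 n_binary = as.integer(n_binary),
                 baseline_rate = baseline_rate,
                 target_censoring = target_censoring,
                 surface = surface, effect_scale = effect_scale,
                 location_layout = location_layout,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate study locations and their distance matrix
#'
#' `"grid"` places the first p points of a near-square lattice spanning
#' the unit square; `"unit_square_random"` draws uniform points,
#' resampling any draw that coincides with an existing point (pairwise
#' distances must be strictly positive for inverse-distance weights).
#'
#' @param p number of locations.
#' @param layout `"grid"` or `"unit_square_random"`.
#' @param seed integer seed.
#' @return List with `coords` (p x 2 matrix) and `distances` (validated
#'   p x p Euclidean distance matrix).
#' @export
make_locations <- function(p, layout = c("grid", "unit_square_random"),
                           seed = 1L) {
  layout <- match.arg(layout)
  coords <- with_seed(seed, {
    if (layout == "grid") {
      s <- ceiling(sqrt(p))
      ax <- if (s == 1) 0.5 else seq(0, 1, length.out = s)
      g <- as.matrix(expand.grid(x = ax, y = ax))
      g[seq_len(p), , drop = FALSE]
    } else {
      pts <- matrix(stats::runif(2 * p), p, 2)
      repeat {
        dd <- as.matrix(stats::dist(pts))
        clash <- which(dd == 0 & row(dd) > col(dd), arr.ind = TRUE)
        if (nrow(clash) == 0) break
        pts[clash[, 1], ] <- stats::runif(2 * nrow(clash))
      }
      pts
    }
  })
  colnames(coords) <- c("x", "y")
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  list(coords = coords, distances = validate_distance_matrix(d))
}

#' True coefficient surface for a simulated panel
#'
#' Smooth mode: for covariate l, `beta[i, j, l] = a_l + b_l * (j - 1) /
#' (q - 1) + c_l * x_i`, with x_i the first spatial coordinate of
#' location i and (a, b, c) drawn uniformly; the whole array is then
#' rescaled so its largest absolute entry equals `effect_scale`.  The
#' surface is thus exactly affine in period and in the first
#' coordinate.  Abrupt mode draws an independent random sign of
#' magnitude `effect_scale` for every (cell, covariate) — the
#' antithesis of a smooth surface.
#'
#' @param p,q,m grid dimensions.
#' @param surface `"smooth"` or `"abrupt"`.
#' @param effect_scale maximum absolute coefficient.
#' @param coords p x 2 location coordinates (smooth mode only).
#' @param seed integer seed.
#' @return p x q x m array of true coefficients.
#' @export
make_coefficient_surface <- function(p, q, m, surface = "smooth",
                                     effect_scale = 1, coords = NULL,
                                     seed = 1L) {
  with_seed(seed, {
    beta <- array(0, dim = c(p, q, m))
    if (effect_scale == 0) return(beta)
    if (surface == "smooth") {
      if (is.null(coords)) stop("smooth surface needs location coordinates")
      a <- stats::runif(m, -1, 1)
      b <- stats::runif(m, -1, 1)
      cc <- stats::runif(m, -1, 1)
      tfrac <- if (q > 1) (seq_len(q) - 1) / (q - 1) else rep(0, q)
      s <- coords[, 1]
      for (l in seq_len(m))
        beta[, , l] <- outer(cc[l] * s, a[l] + b[l] * tfrac, `+`)
      mx <- max(abs(beta))
      if (mx > 0) beta <- beta * (effect_scale / mx)
    } else {
      beta[] <- effect_scale * sample(c(-1, 1), p * q * m, replace = TRUE)
    }
    beta
  })
}

# censoring upper bound c_max such that E[min(T/c_max, 1)] ~= target,
# found by bisection on a pilot draw of event times
calibrate_cmax <- function(pilot_T, target, tol = 0.01) {
  frac <- function(cmax) mean(pmin(pilot_T / cmax, 1))
  lo <- min(pilot_T) / 2
  hi <- max(pilot_T) * 2
  while (frac(hi) > target) hi <- hi * 2
  while (frac(lo) < target) lo <- lo / 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    f <- frac(mid)
    if (abs(f - target) <= tol / 2) return(mid)
    if (f > target) lo <- mid else hi <- mid
  }
  mid
}

#' Simulate a survival panel with known truth
#'
#' Covariates are `n_continuous` standard-normal and `n_binary`
#' Bernoulli(0.5) columns.  Event times follow an exponential-baseline
#' proportional hazards model: `T = -log(U) / (h0 * exp(x' beta_cell))`.
#' Censoring times are uniform on (0, c_max), with c_max calibrated by
#' bisection on a 10,000-subject pilot draw so that the expected
#' censoring fraction matches the target within 0.01.  The observed
#' time is min(T, C) and the event indicator is T <= C.  Everything is
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sim_panel`: list with `panel`
#'   (a `panel_data`), `truth` (p x q x m array), `distances`, `coords`,
#'   `realized_censoring`, `config`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  loc <- make_locations(cfg$p, cfg$location_layout, seed = cfg$seed)
  truth <- make_coefficient_surface(cfg$p, cfg$q, cfg$m, cfg$surface,
                                    cfg$effect_scale, loc$coords,
                                    seed = cfg$seed + 1L)
  draw_x <- function(n) {
    X <- matrix(0, n, cfg$m)
    if (cfg$n_continuous > 0)
      X[, seq_len(cfg$n_continuous)] <- stats::rnorm(n * cfg$n_continuous)
    if (cfg$n_binary > 0)
      X[, cfg$n_continuous + seq_len(cfg$n_binary)] <-
        stats::rbinom(n * cfg$n_binary, 1, 0.5)
    X
  }

  with_seed(cfg$seed + 2L, {
    cmax <- Inf
    if (cfg$target_censoring > 0) {
      n_pilot <- 10000L
      cells <- sample.int(cfg$p * cfg$q, n_pilot, replace = TRUE,
                          prob = as.vector(cfg$n_per_cell))
      Xp <- draw_x(n_pilot)
      bmat <- matrix(truth, cfg$p * cfg$q, cfg$m)  # row (j-1)*p+i
      # n_per_cell is p x q so as.vector order matches cell order
      eta <- rowSums(Xp * bmat[cells, , drop = FALSE])
      Tp <- -log(stats::runif(n_pilot)) / (cfg$baseline_rate * exp(eta))
      cmax <- calibrate_cmax(Tp, cfg$target_censoring)
    }

    strata <- vector("list", cfg$p * cfg$q)
    n_events <- 0L
    for (j in seq_len(cfg$q)) for (i in seq_len(cfg$p)) {
      n <- cfg$n_per_cell[i, j]
      X <- draw_x(n)
      eta <- as.vector(X %*% truth[i, j, ])
      Tt <- -log(stats::runif(n)) / (cfg$baseline_rate * exp(eta))
      Ct <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
      obs <- pmin(Tt, Ct)
      ev <- as.integer(Tt <= Ct)
      n_events <- n_events + sum(ev)
      strata[[(j - 1L) * cfg$p + i]] <- stratum_data(obs, ev, X)
    }
    panel <- panel_data(strata,
                        location_ids = seq_len(cfg$p),
                        period_ids = seq_len(cfg$q),
                        covariate_names = sprintf("x%d", seq_len(cfg$m)))
    dimnames(truth) <- list(as.character(panel$location_ids),
                            as.character(panel$period_ids),
                            panel$covariate_names)
    structure(list(panel = panel, truth = truth,
                   distances = loc$distances, coords = loc$coords,
                   realized_censoring = 1 - n_events / panel$n_total,
                   config = cfg),
              class = "sim_panel")
  })
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("simulated panel: %d x %d cells, %d covariates, %d subjects\n",
              x$config$p, x$config$q, x$config$m, x$panel$n_total))
  cat(sprintf("  %s surface (effect scale %g), realized censoring %.1f%%\n",
              x$config$surface, x$config$effect_scale,
              100 * x$realized_censoring))
  invisible(x)
}
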
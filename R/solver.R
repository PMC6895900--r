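#' Solver options for the smoothed fit
#'
#' @param outer_tol l2-norm change between consecutive outer iterates
#'   below which the outer loop stops (default 1e-3).
#' @param inner_tol l2-norm change over one Gauss-Seidel sweep below
#'   which the inner cycle stops (default 1e-4).
#' @param max_outer outer iteration cap.
#' @param max_inner inner sweep cap.
#' @param init `"zero"` starts every cell at 0; `"separate"` starts
#'   from the per-cell MLEs (unfittable cells start at 0).
#' @param step_halving if `TRUE` (default) an outer update that would
#'   decrease the penalized objective is contracted toward the
#'   expansion point (factor 1/2, at most 10 times) before acceptance;
#'   the diagonal curvature surrogate does not majorize the true
#'   curvature, so ascent is otherwise not guaranteed.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(outer_tol = 1e-3, inner_tol = 1e-4,
                           max_outer = 100L, max_inner = 50L,
                           init = c("zero", "separate"),
                           step_halving = TRUE) {
  init <- match.arg(init)
  stopifnot(outer_tol > 0, inner_tol > 0, max_outer >= 1, max_inner >= 1)
  structure(list(outer_tol = outer_tol, inner_tol = inner_tol,
                 max_outer = as.integer(max_outer),
                 max_inner = as.integer(max_inner),
                 init = init, step_halving = isTRUE(step_halving)),
            class = "solver_options")
}

#' Penalized objective
#'
#' Total log partial likelihood minus the two-part smoothing penalty —
#' the quantity the smoothed estimator maximizes.
#'
#' @param panel a `panel_data` object.
#' @param grid p x q x m coefficient array.
#' @param w spatial weight matrix.
#' @param cfg a [penalty_config()].
#' @return A scalar.
#' @export
penalized_objective <- function(panel, grid, w, cfg) {
  total_loglik(panel, grid) - penalty_value(grid, w, cfg)
}

#' Closed-form block update for one cell
#'
#' Solves the stationarity condition of the quadratic surrogate in the
#' coefficients of cell (i, j), all other cells held fixed:
#' `beta = (W - c I)^{-1} (W beta_tilde - grad - lambda1 * (temporal
#' neighbour sum) - lambda2 * sum_r omega_{i,r} beta_{r,j})`, where W
#' is the diagonal curvature frozen at the expansion point and c is
#' [shrink_diagonal()].  The system is diagonal, so the solve is exact.
#' For an information-free cell (empty stratum: W = 0, grad = 0) the
#' update is the penalty-weighted average of the cell's neighbours.
#'
#' @param grid p x q x m array of current coefficient values (supplies
#'   the neighbours).
#' @param i,j cell indices.
#' @param grad length-m score of the cell's stratum at the expansion
#'   point.
#' @param curv length-m diagonal curvature at the expansion point
#'   (entries <= 0).
#' @param beta_tilde length-m expansion point for this cell.
#' @param w spatial weight matrix.
#' @param cfg a [penalty_config()].
#' @return Numeric vector of length m.
#' @export
block_update <- function(grid, i, j, grad, curv, beta_tilde, w, cfg) {
  dm <- dim(grid)
  p <- dm[1]; q <- dm[2]
  g <- resolve_gaps(cfg, q)
  gl <- if (j > 1) g[j - 1] else 0
  gr <- if (j < q) g[j] else 0
  cc <- shrink_diagonal(i, j, w, cfg, q)
  rhs <- curv * beta_tilde - grad
  if (gl > 0) rhs <- rhs - cfg$lambda1 * gl * grid[i, j - 1, ]
  if (gr > 0) rhs <- rhs - cfg$lambda1 * gr * grid[i, j + 1, ]
  if (p >= 2 && cfg$lambda2 > 0) {
    others <- setdiff(seq_len(p), i)
    nb <- colSums(w[i, others] * matrix(grid[others, j, ], nrow = p - 1))
    rhs <- rhs - cfg$lambda2 * nb
  }
  denom <- curv - cc
  if (any(denom == 0))
    stop("singular block system: non-identifiable covariate with no penalty")
  rhs / denom
}

# gradients and diagonal curvatures for all cells at an expansion grid;
# returns (p*q) x m matrices in cell order (j - 1) * p + i
panel_derivs <- function(panel, grid) {
  pq <- panel$p * panel$q
  grad <- matrix(0, pq, panel$m)
  curv <- matrix(0, pq, panel$m)
  ll <- 0
  for (j in seq_len(panel$q)) for (i in seq_len(panel$p)) {
    idx <- (j - 1L) * panel$p + i
    d <- cox_derivs(panel_stratum(panel, i, j), grid[i, j, ])
    grad[idx, ] <- d$gradient
    curv[idx, ] <- d$diag_curvature
    ll <- ll + d$loglik
  }
  list(grad = grad, curv = curv, loglik = ll)
}

as_cell_matrix <- function(grid) {
  dm <- dim(grid)
  matrix(grid, nrow = dm[1] * dm[2], ncol = dm[3])
}

from_cell_matrix <- function(mat, template) {
  array(mat, dim = dim(template), dimnames = dimnames(template))
}

#' Inner Gauss-Seidel cycle on the quadratic surrogate
#'
#' Repeats full lexicographic sweeps of [block_update()] over all
#' (location, period) cells, each update seeing the latest values of
#' every other block, until the l2 norm of the grid change over one
#' sweep falls below `inner_tol` or `max_inner` sweeps are reached.
#' The scores and curvatures stay frozen at the outer expansion point
#' throughout, so the cycle maximizes the surrogate objective, not the
#' likelihood itself.
#'
#' When the sweeps hit `max_inner` without converging — which happens
#' in the heavily smoothed regime, where the sweeps move the
#' penalty's near-null (grid-constant) modes extremely slowly — the
#' surrogate is finished off exactly: because the diagonal curvature
#' and the penalty never couple different covariates, the surrogate
#' stationarity system splits into m independent (p*q) x (p*q) linear
#' systems, one per covariate, which are solved directly.  The result
#' is the same unique surrogate maximizer the sweeps tend to.
#'
#' @param grid starting p x q x m coefficient array.
#' @param beta_tilde expansion-point array (same shape).
#' @param derivs result of the internal per-cell derivative pass at
#'   `beta_tilde`: list with `grad`, `curv` matrices.
#' @param w spatial weight matrix.
#' @param cfg a [penalty_config()].
#' @param opts a [solver_options()].
#' @return List: `grid` (updated array), `sweeps`, `converged`.
#' @export
inner_cycle <- function(grid, beta_tilde, derivs, w, cfg, opts) {
  q <- dim(grid)[2]
  res <- cpp_inner_cycle(as_cell_matrix(grid), as_cell_matrix(beta_tilde),
                         derivs$grad, derivs$curv, w,
                         cfg$lambda1, cfg$lambda2, resolve_gaps(cfg, q),
                         opts$inner_tol, opts$max_inner)
  out <- res$beta
  p <- dim(grid)[1]
  sys <- surrogate_system(derivs, w, cfg, p, q)
  resid <- 0
  scale <- 1
  for (l in seq_len(ncol(out))) {
    A <- sys$coup
    diag(A) <- diag(A) + derivs$curv[, l]
    b <- derivs$curv[, l] * as_cell_matrix(beta_tilde)[, l] - derivs$grad[, l]
    resid <- max(resid, max(abs(A %*% out[, l] - b)))
    scale <- max(scale, max(abs(b)))
  }
  if (resid > 1e-8 * scale) {
    direct <- tryCatch(
      surrogate_exact_solve(as_cell_matrix(beta_tilde), derivs, w, cfg, p, q),
      error = function(e) NULL)
    if (!is.null(direct)) out <- direct
  }
  list(grid = from_cell_matrix(out, grid), sweeps = res$sweeps,
       converged = res$converged)
}

# penalty coupling matrix of the surrogate stationarity system: the
# shrink diagonals (negated) on the diagonal, plus the temporal and
# spatial neighbour weights off it; covariates never mix, so the same
# p*q x p*q matrix serves every coordinate
surrogate_system <- function(derivs, w, cfg, p, q) {
  pq <- p * q
  g <- resolve_gaps(cfg, q)
  coup <- matrix(0, pq, pq)
  for (i in seq_len(p)) for (j in seq_len(q)) {
    idx <- (j - 1L) * p + i
    coup[idx, idx] <- -shrink_diagonal(i, j, w, cfg, q)
    if (j > 1) coup[idx, idx - p] <- cfg$lambda1 * g[j - 1]
    if (j < q) coup[idx, idx + p] <- cfg$lambda1 * g[j]
    if (p >= 2 && cfg$lambda2 > 0)
      for (r in seq_len(p)) if (r != i)
        coup[idx, (j - 1L) * p + r] <- cfg$lambda2 * w[i, r]
  }
  list(coup = coup)
}

# exact maximizer of the quadratic surrogate: per covariate l, solve
#   [diag(curv_l) + coup] beta_l = curv_l * beta_tilde_l - grad_l
surrogate_exact_solve <- function(beta_tilde_mat, derivs, w, cfg, p, q) {
  sys <- surrogate_system(derivs, w, cfg, p, q)
  out <- matrix(0, p * q, ncol(beta_tilde_mat))
  for (l in seq_len(ncol(beta_tilde_mat))) {
    A <- sys$coup
    diag(A) <- diag(A) + derivs$curv[, l]
    rhs <- derivs$curv[, l] * beta_tilde_mat[, l] - derivs$grad[, l]
    out[, l] <- solve(A, rhs)
  }
  out
}

#' Spatial- and temporal-smoothed Cox estimation
#'
#' Maximizes the sum of per-cell Cox log partial likelihoods minus the
#' two-part smoothing penalty.  Outer loop: the likelihood is replaced
#' by its second-order Taylor surrogate at the current estimate, with
#' the Hessian replaced by its diagonal; the surrogate-plus-penalty is
#' maximized by the inner block-wise cycle; the expansion point moves
#' to the maximizer.  The outer loop stops when the l2 norm of the
#' difference between consecutive estimates drops below
#' `opts$outer_tol` (default 1e-3).
#'
#' @param panel a `panel_data` object.
#' @param w p x p spatial weight matrix ([weights_from_distances()]).
#' @param cfg a [penalty_config()] holding lambda1, lambda2.
#' @param opts a [solver_options()].
#' @return An object of class `stcox_fit`: list with `beta` (p x q x m
#'   array), `converged`, `outer_iterations`, `objective_trace`
#'   (penalized objective at initialization and after each accepted
#'   outer update), `delta_trace` (l2 change per outer iteration),
#'   `lambda1`, `lambda2`, `inner_sweeps`.
#' @export
fit_smoothed <- function(panel, w, cfg, opts = solver_options()) {
  stopifnot(inherits(panel, "panel_data"), inherits(cfg, "penalty_config"),
            inherits(opts, "solver_options"))
  if (nrow(w) != panel$p) stop("weight matrix does not match panel locations")

  beta_tilde <- empty_grid(panel)
  if (opts$init == "separate") {
    sep <- fit_separate(panel)
    ok <- !is.na(sep$beta)
    beta_tilde[ok] <- sep$beta[ok]
  }

  # guard against an unpenalized, information-free coordinate
  if (cfg$lambda1 == 0 && cfg$lambda2 == 0) {
    d0 <- panel_derivs(panel, beta_tilde)
    if (any(d0$curv == 0))
      stop("singular block system: non-identifiable covariate with no penalty")
  }

  obj <- penalized_objective(panel, beta_tilde, w, cfg)
  objective_trace <- obj
  delta_trace <- numeric(0)
  inner_sweeps <- integer(0)
  converged <- FALSE
  iter <- 0L

  while (iter < opts$max_outer) {
    iter <- iter + 1L
    derivs <- panel_derivs(panel, beta_tilde)
    inner <- inner_cycle(beta_tilde, beta_tilde, derivs, w, cfg, opts)
    cand <- inner$grid
    if (opts$step_halving) {
      cand_obj <- penalized_objective(panel, cand, w, cfg)
      halvings <- 0L
      while (cand_obj < obj && halvings < 10L) {
        cand <- beta_tilde + (cand - beta_tilde) / 2
        cand_obj <- penalized_objective(panel, cand, w, cfg)
        halvings <- halvings + 1L
      }
      obj <- cand_obj
    } else {
      obj <- penalized_objective(panel, cand, w, cfg)
    }
    delta <- sqrt(sum((cand - beta_tilde)^2))
    beta_tilde <- cand
    objective_trace <- c(objective_trace, obj)
    delta_trace <- c(delta_trace, delta)
    inner_sweeps <- c(inner_sweeps, inner$sweeps)
    if (delta < opts$outer_tol) {
      converged <- TRUE
      break
    }
  }

  structure(list(beta = beta_tilde, converged = converged,
                 outer_iterations = iter,
                 objective_trace = objective_trace,
                 delta_trace = delta_trace,
                 inner_sweeps = inner_sweeps,
                 lambda1 = cfg$lambda1, lambda2 = cfg$lambda2),
            class = "stcox_fit")
}

#' @export
print.stcox_fit <- function(x, ...) {
  dm <- dim(x$beta)
  cat(sprintf("smoothed Cox fit: %d x %d cells, %d covariates\n",
              dm[1], dm[2], dm[3]))
  cat(sprintf("  lambda1 = %g, lambda2 = %g\n", x$lambda1, x$lambda2))
  cat(sprintf("  %s in %d outer iteration(s); objective %.4f\n",
              if (x$converged) "converged" else "NOT converged",
              x$outer_iterations, tail(x$objective_trace, 1)))
  invisible(x)
}

#' @importFrom utils tail modifyList
NULL
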
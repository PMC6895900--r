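#' Inverse-distance spatial weights
#'
#' The spatial penalty weights each pair of locations by the reciprocal
#' of their distance, so nearby models are pulled together more
#' strongly than distant ones.
#'
#' @param d validated p x p distance matrix (symmetric, zero diagonal,
#'   strictly positive off-diagonal).
#' @return p x p weight matrix with zero diagonal and entries 1/d
#'   off-diagonal.
#' @export
weights_from_distances <- function(d) {
  d <- validate_distance_matrix(d)
  w <- 1 / d
  diag(w) <- 0
  w
}

#' Penalty configuration
#'
#' Bundles the two tuning parameters: `lambda1` scales the fused
#' temporal penalty on adjacent periods, `lambda2` the inverse-distance
#' spatial penalty on location pairs.  `gap_weights` optionally
#' down-weights temporal adjacencies that straddle a recording gap
#' (weight 1 reproduces the plain fused penalty; see
#' [gap_weights_from_periods()]).
#'
#' @param lambda1 nonnegative temporal smoothing weight.
#' @param lambda2 nonnegative spatial smoothing weight.
#' @param gap_weights optional positive vector of length q - 1, one
#'   weight per consecutive-period adjacency; default all 1.
#' @return An object of class `penalty_config`.
#' @export
penalty_config <- function(lambda1, lambda2, gap_weights = NULL) {
  stopifnot(is.numeric(lambda1), length(lambda1) == 1, lambda1 >= 0,
            is.numeric(lambda2), length(lambda2) == 1, lambda2 >= 0)
  if (!is.null(gap_weights)) {
    stopifnot(is.numeric(gap_weights), all(gap_weights > 0))
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 gap_weights = gap_weights), class = "penalty_config")
}

#' Gap weights from period labels
#'
#' For panels with missing time intervals (periods 1, 2, 3, 5, 6 say),
#' consecutive recorded periods that are farther apart in calendar time
#' can be penalized less: the adjacency weight is 1 / gap length, so a
#' unit gap keeps weight 1 and a double-length gap gets weight 1/2.
#'
#' @param period_ids strictly increasing numeric period labels.
#' @return Numeric vector of length q - 1.
#' @export
gap_weights_from_periods <- function(period_ids) {
  period_ids <- as.numeric(period_ids)
  stopifnot(length(period_ids) >= 2, !is.unsorted(period_ids, strictly = TRUE))
  1 / diff(period_ids)
}

# resolve gap weights for a panel with q periods (default all ones)
resolve_gaps <- function(cfg, q) {
  if (q < 2) return(numeric(0))
  g <- cfg$gap_weights
  if (is.null(g)) g <- rep(1, q - 1)
  if (length(g) != q - 1)
    stop(sprintf("gap_weights has length %d but q - 1 = %d", length(g), q - 1))
  g
}

#' Two-part smoothing penalty value
#'
#' `0.5 * lambda1 * sum_i sum_{j>=2} g_{j-1} ||beta_{i,j} - beta_{i,j-1}||^2 +
#'  0.5 * lambda2 * sum_j sum_{r>i} omega_{i,r} ||beta_{i,j} - beta_{r,j}||^2`
#'
#' Each spatial pair is counted once (r > i).  The value is always
#' nonnegative and zero iff all penalized neighbour pairs coincide.
#'
#' @param grid p x q x m coefficient array.
#' @param w p x p spatial weight matrix ([weights_from_distances()]).
#' @param cfg a [penalty_config()].
#' @return A scalar.
#' @export
penalty_value <- function(grid, w, cfg) {
  dm <- dim(grid)
  p <- dm[1]; q <- dm[2]
  if (nrow(w) != p) stop("weight matrix does not match grid locations")
  g <- resolve_gaps(cfg, q)
  temporal <- 0
  if (q >= 2 && cfg$lambda1 > 0) {
    for (j in 2:q) {
      d <- grid[, j, , drop = FALSE] - grid[, j - 1, , drop = FALSE]
      temporal <- temporal + g[j - 1] * sum(d^2)
    }
  }
  spatial <- 0
  if (p >= 2 && cfg$lambda2 > 0) {
    for (i in seq_len(p - 1)) for (r in (i + 1):p) {
      d <- grid[i, , , drop = FALSE] - grid[r, , , drop = FALSE]
      spatial <- spatial + w[i, r] * sum(d^2)
    }
  }
  0.5 * cfg$lambda1 * temporal + 0.5 * cfg$lambda2 * spatial
}

#' Gradient of the penalty with respect to one cell's coefficients
#'
#' Differentiating the once-counted pairwise sums gives, for cell
#' (i, j): `lambda1 * (g_l + g_r) * beta_{i,j} - lambda1 * (g_l *
#' beta_{i,j-1} + g_r * beta_{i,j+1}) + lambda2 * (sum_r omega_{i,r}) *
#' beta_{i,j} - lambda2 * sum_r omega_{i,r} beta_{r,j}`, with the left/
#' right gap weights g dropped at the first/last period.
#'
#' @param grid p x q x m coefficient array.
#' @param i location index.
#' @param j period index.
#' @param w spatial weight matrix.
#' @param cfg a [penalty_config()].
#' @return Numeric vector of length m.
#' @export
penalty_gradient_block <- function(grid, i, j, w, cfg) {
  dm <- dim(grid)
  p <- dm[1]; q <- dm[2]; m <- dm[3]
  stopifnot(i >= 1, i <= p, j >= 1, j <= q)
  g <- resolve_gaps(cfg, q)
  gl <- if (j > 1) g[j - 1] else 0
  gr <- if (j < q) g[j] else 0
  out <- cfg$lambda1 * (gl + gr) * grid[i, j, ]
  if (gl > 0) out <- out - cfg$lambda1 * gl * grid[i, j - 1, ]
  if (gr > 0) out <- out - cfg$lambda1 * gr * grid[i, j + 1, ]
  if (p >= 2 && cfg$lambda2 > 0) {
    others <- setdiff(seq_len(p), i)
    osum <- sum(w[i, others])
    nb <- colSums(w[i, others] * matrix(grid[others, j, ], nrow = p - 1))
    out <- out + cfg$lambda2 * (osum * grid[i, j, ] - nb)
  }
  out
}

#' Shrinkage diagonal for one cell's block update
#'
#' The scalar added to (minus) the diagonal curvature in the block-wise
#' closed-form solve: `lambda1 * (g_l + g_r) + lambda2 * sum_{r != i}
#' omega_{i,r}`.  With unit gap weights this is `2*lambda1 + lambda2 *
#' sum omega` at interior periods and `lambda1 + lambda2 * sum omega`
#' at the first and last period; with q = 1 the temporal part is 0.
#'
#' @param i location index.
#' @param j period index.
#' @param w spatial weight matrix.
#' @param cfg a [penalty_config()].
#' @param q number of periods.
#' @return A nonnegative scalar.
#' @export
shrink_diagonal <- function(i, j, w, cfg, q) {
  g <- resolve_gaps(cfg, q)
  gl <- if (j > 1) g[j - 1] else 0
  gr <- if (j < q) g[j] else 0
  p <- nrow(w)
  osum <- if (p >= 2) sum(w[i, setdiff(seq_len(p), i)]) else 0
  cfg$lambda1 * (gl + gr) + cfg$lambda2 * osum
}
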
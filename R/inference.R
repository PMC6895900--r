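#' Stratified resampling of a panel
#'
#' Draws, independently within every (location, period) cell, `n_cell`
#' subjects with replacement, so each bootstrap replicate preserves the
#' original per-cell sample sizes exactly.  Resampled cells are
#' re-sorted into canonical time order.  Deterministic given the seed.
#'
#' @param panel a `panel_data` object.
#' @param seed integer seed.
#' @return A new `panel_data` of identical shape and cell sizes.
#' @export
resample_panel <- function(panel, seed) {
  with_seed(seed, {
    strata <- lapply(panel$strata, function(s) {
      if (s$n == 0) return(s)
      idx <- sample.int(s$n, s$n, replace = TRUE)
      stratum_data(s$times[idx], s$events[idx],
                   s$covariates[idx, , drop = FALSE])
    })
    panel_data(strata, panel$location_ids, panel$period_ids,
               panel$covariate_names)
  })
}

#' Stratified bootstrap standard errors and confidence intervals
#'
#' Refits the estimator on `B` stratified resamples of the panel, with
#' the smoothing parameters held fixed at their original values (they
#' are not re-selected per replicate).  The standard error of each
#' coefficient is the sample standard deviation (divisor B - 1) of its
#' replicate estimates; confidence intervals are normal-approximation,
#' `estimate +/- z * se`, centred at the point estimate.  Replicates
#' whose fit does not converge are dropped and counted; more than 20%
#' failures aborts with advice.
#'
#' @param panel a `panel_data` object.
#' @param w spatial weight matrix.
#' @param cfg a [penalty_config()] (ignored when
#'   `estimator = "separate"`).
#' @param B number of bootstrap replicates (>= 2; default 200).
#' @param level confidence level in (0, 1), default 0.95.
#' @param seed integer seed; replicate b uses seed + b.
#' @param opts a [solver_options()].
#' @param estimator `"smoothed"` (default) bootstraps [fit_smoothed()];
#'   `"separate"` bootstraps the per-cell MLEs (cells a replicate
#'   cannot fit are dropped coordinate-wise).
#' @param point optional point-estimate array to centre the intervals;
#'   computed from the original panel when missing.
#' @return An object of class `stcox_boot`: list with `se`, `ci_low`,
#'   `ci_high` (p x q x m arrays), `point`, `B`, `level`, `n_failed`.
#' @export
bootstrap_se <- function(panel, w, cfg, B = 200L, level = 0.95,
                         seed = 1L, opts = solver_options(),
                         estimator = c("smoothed", "separate"),
                         point = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(B >= 2, level > 0, level < 1)
  fit_one <- function(pn) {
    if (estimator == "smoothed") {
      fit <- fit_smoothed(pn, w, cfg, opts)
      if (!fit$converged) return(NULL)
      fit$beta
    } else {
      fit_separate(pn)$beta
    }
  }
  if (is.null(point)) {
    point <- fit_one(panel)
    if (is.null(point))
      stop("fit on the original panel did not converge; cannot bootstrap")
  } else {
    point <- coef_array(point)
  }
  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    bp <- resample_panel(panel, seed + b)
    est <- tryCatch(fit_one(bp), error = function(e) NULL)
    if (is.null(est)) {
      n_failed <- n_failed + 1L
      if (n_failed > 0.2 * B)
        stop("more than 20% of bootstrap replicates failed to converge; ",
             "consider larger cells or larger smoothing parameters")
      next
    }
    reps[[b]] <- est
  }
  reps <- reps[!vapply(reps, is.null, TRUE)]
  stack <- array(unlist(reps), dim = c(dim(point), length(reps)))
  se <- apply(stack, 1:3, stats::sd, na.rm = TRUE)
  dimnames(se) <- dimnames(point)
  z <- stats::qnorm((1 + level) / 2)
  structure(list(se = se, ci_low = point - z * se,
                 ci_high = point + z * se, point = point,
                 B = as.integer(B), level = level,
                 n_failed = n_failed),
            class = "stcox_boot")
}

#' @export
print.stcox_boot <- function(x, ...) {
  cat(sprintf("stratified bootstrap: B = %d (%d failed), level = %g\n",
              x$B, x$n_failed, x$level))
  cat(sprintf("  median se = %.4g\n", stats::median(x$se, na.rm = TRUE)))
  invisible(x)
}

#' @importFrom stats median
NULL
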
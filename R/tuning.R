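#' Cell-stratified V-fold assignment
#'
#' Subjects are assigned to folds independently within every nonempty
#' cell, as evenly as possible (cell sizes not divisible by V spread
#' their remainder over uniformly chosen folds), so that every training
#' set preserves the panel design.  Deterministic given the seed.
#'
#' @param panel a `panel_data` object.
#' @param V number of folds, at least 2.
#' @param seed integer seed.
#' @return List of length p*q (cell order `(j-1)*p + i`) of integer
#'   vectors giving each subject's fold in `1:V`, aligned with the
#'   stratum's canonical row order.
#' @export
make_folds <- function(panel, V, seed) {
  stopifnot(V >= 2)
  with_seed(seed, {
    lapply(panel$strata, function(s) {
      n <- s$n
      if (n == 0) return(integer(0))
      base <- n %/% V
      rem <- n %% V
      sizes <- rep(base, V)
      if (rem > 0) {
        lucky <- sample.int(V, rem)
        sizes[lucky] <- sizes[lucky] + 1L
      }
      sample(rep.int(seq_len(V), sizes))
    })
  })
}

# panel restricted to subjects with keep_fun(fold label) TRUE
subset_panel <- function(panel, folds, keep_fun) {
  strata <- vector("list", length(panel$strata))
  for (k in seq_along(panel$strata)) {
    s <- panel$strata[[k]]
    keep <- which(keep_fun(folds[[k]]))
    strata[[k]] <- stratum_data(s$times[keep], s$events[keep],
                                s$covariates[keep, , drop = FALSE])
  }
  panel_data(strata, panel$location_ids, panel$period_ids,
             panel$covariate_names)
}

#' Cross-validated partial likelihood score
#'
#' For each fold v, the model is fitted on the panel with fold v
#' removed, and the fold's contribution is the full-data log partial
#' likelihood minus the training-data log partial likelihood, both
#' evaluated at the training estimate (the Verweij-van Houwelingen
#' difference form).  The difference isolates the held-out subjects'
#' contribution without dismantling risk sets cell by cell.  Higher is
#' better.  A failed training fit scores the pair as `-Inf` with a
#' warning.
#'
#' @param panel a `panel_data` object.
#' @param folds fold assignment from [make_folds()].
#' @param w spatial weight matrix.
#' @param cfg a [penalty_config()].
#' @param opts a [solver_options()].
#' @return A scalar score.
#' @export
cv_score <- function(panel, folds, w, cfg, opts = solver_options()) {
  V <- max(1L, max(unlist(lapply(folds, function(f)
    if (length(f)) max(f) else 1L))))
  score <- 0
  for (v in seq_len(V)) {
    train <- subset_panel(panel, folds, function(f) f != v)
    fit <- tryCatch(fit_smoothed(train, w, cfg, opts),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("training fit failed for fold %d (lambda1=%g, lambda2=%g): %s",
                      v, cfg$lambda1, cfg$lambda2, conditionMessage(fit)))
      return(-Inf)
    }
    score <- score + (total_loglik(panel, fit$beta) -
                        total_loglik(train, fit$beta))
  }
  score
}

#' Default tuning grid
#'
#' All pairs from `{0.01, 0.1, 1, 10, 100}` for each of lambda1,
#' lambda2.
#'
#' @return Data frame with columns `lambda1`, `lambda2`.
#' @export
default_lambda_grid <- function() {
  vals <- c(0.01, 0.1, 1, 10, 100)
  expand.grid(lambda1 = vals, lambda2 = vals)
}

#' Cross-validated selection of the smoothing parameters
#'
#' Evaluates [cv_score()] on a common fold assignment for every
#' (lambda1, lambda2) pair and returns the maximizer; exact score ties
#' go to the smaller lambda1 + lambda2 (then smaller lambda1), so the
#' least-smoothed of equally good fits wins.
#'
#' @param panel a `panel_data` object.
#' @param w spatial weight matrix.
#' @param lambda_grid data frame with columns `lambda1`, `lambda2`
#'   (default [default_lambda_grid()]).
#' @param V number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param opts a [solver_options()].
#' @param gap_weights optional gap weights passed into every
#'   [penalty_config()].
#' @return An object of class `stcox_cv`: list with `best_lambda1`,
#'   `best_lambda2`, `score_table` (lambda1, lambda2, score), `V`,
#'   `seed`.
#' @export
select_lambdas <- function(panel, w, lambda_grid = default_lambda_grid(),
                           V = 5L, seed = 1L, opts = solver_options(),
                           gap_weights = NULL) {
  lambda_grid <- as.data.frame(lambda_grid)
  stopifnot(all(c("lambda1", "lambda2") %in% names(lambda_grid)),
            nrow(lambda_grid) >= 1)
  folds <- make_folds(panel, V, seed)
  scores <- numeric(nrow(lambda_grid))
  for (k in seq_len(nrow(lambda_grid))) {
    cfg <- penalty_config(lambda_grid$lambda1[k], lambda_grid$lambda2[k],
                          gap_weights)
    scores[k] <- cv_score(panel, folds, w, cfg, opts)
  }
  tab <- data.frame(lambda1 = lambda_grid$lambda1,
                    lambda2 = lambda_grid$lambda2, score = scores)
  best_score <- max(scores)
  cand <- which(scores == best_score)
  cand <- cand[order(tab$lambda1[cand] + tab$lambda2[cand],
                     tab$lambda1[cand])]
  best <- cand[1]
  structure(list(best_lambda1 = tab$lambda1[best],
                 best_lambda2 = tab$lambda2[best],
                 score_table = tab, V = as.integer(V),
                 seed = as.integer(seed)),
            class = "stcox_cv")
}

#' @export
print.stcox_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d (lambda1, lambda2) pairs\n",
              x$V, nrow(x$score_table)))
  cat(sprintf("  selected lambda1 = %g, lambda2 = %g (score %.4f)\n",
              x$best_lambda1, x$best_lambda2, max(x$score_table$score)))
  invisible(x)
}
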
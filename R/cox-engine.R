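#' Per-stratum Cox partial log-likelihood
#'
#' Breslow form: tied event times share a risk set, and the risk set at
#' an event time t is every subject with observed time >= t.  The
#' computation is a single reverse cumulative-sum pass over the sorted
#' times, with max-shifted exponentials so linear predictors up to
#' magnitude ~700 do not overflow.  An empty stratum, or one with no
#' events, contributes 0.
#'
#' @param stratum a [stratum_data()] object.
#' @param beta numeric coefficient vector of length m.
#' @return The log partial likelihood, a scalar.
#' @export
stratum_loglik <- function(stratum, beta) {
  cox_derivs(stratum, beta)$loglik
}

#' Per-stratum score vector
#'
#' First derivative of [stratum_loglik()] with respect to the
#' coefficients: for each event, the subject's covariates minus the
#' risk-set average weighted by exp(x'beta).
#'
#' @inheritParams stratum_loglik
#' @return Numeric vector of length m.
#' @export
stratum_gradient <- function(stratum, beta) {
  cox_derivs(stratum, beta)$gradient
}

#' Per-stratum diagonal curvature
#'
#' The diagonal of the second-derivative matrix of [stratum_loglik()]:
#' minus, for each event, the exp(x'beta)-weighted variance of each
#' covariate over the risk set.  Every entry is <= 0; the diagonal
#' matrix built from it replaces the full Hessian in the smoothing
#' solver.
#'
#' @inheritParams stratum_loglik
#' @return Numeric vector of length m, elementwise nonpositive.
#' @export
stratum_diag_curvature <- function(stratum, beta) {
  cox_derivs(stratum, beta)$diag_curvature
}

# loglik/gradient/diag curvature (and optionally full Hessian) in one pass
cox_derivs <- function(stratum, beta, hessian = FALSE) {
  m <- ncol(stratum$covariates)
  beta <- as.numeric(beta)
  if (length(beta) != m)
    stop(sprintf("beta has length %d but stratum has %d covariates",
                 length(beta), m))
  if (any(!is.finite(beta))) stop("beta must be finite")
  cpp_cox_derivs(stratum$times, stratum$events, stratum$covariates,
                 beta, hessian)
}

#' Total log partial likelihood of a panel
#'
#' Sum of the per-cell log partial likelihoods, each cell evaluated at
#' its own coefficient vector.
#'
#' @param panel a `panel_data` object.
#' @param grid p x q x m coefficient array.
#' @return A scalar.
#' @export
total_loglik <- function(panel, grid) {
  stopifnot(all(dim(grid) == c(panel$p, panel$q, panel$m)))
  ll <- 0
  for (j in seq_len(panel$q)) for (i in seq_len(panel$p))
    ll <- ll + stratum_loglik(panel_stratum(panel, i, j), grid[i, j, ])
  ll
}

#' Unpenalized Cox maximum likelihood for one stratum
#'
#' Full-Hessian Newton-Raphson with step halving.  Convergence is
#' declared when the score max-norm falls below `tol`.  Monotone
#' likelihood (separation), where the MLE diverges, returns the capped
#' iterate flagged `converged = FALSE` rather than failing — small
#' registry cells routinely exhibit it.
#'
#' @param stratum a `stratum_data` with at least one event.
#' @param tol score max-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return List with `beta`, `converged`, `iterations`, `loglik`.
#' @export
fit_stratum_mle <- function(stratum, tol = 1e-6, max_iter = 50L) {
  m <- ncol(stratum$covariates)
  if (stratum$n == 0 || sum(stratum$events) == 0)
    stop("no events in stratum")
  beta <- numeric(m)
  d <- cox_derivs(stratum, beta, hessian = TRUE)
  curv0 <- diag(d$hessian)
  if (any(abs(curv0) < 1e-12)) {
    bad <- which(abs(curv0) < 1e-12)[1]
    stop(sprintf("singular Hessian: covariate %d is degenerate (constant across risk sets)",
                 bad))
  }
  # separation drives a coefficient to +-Inf: the score still vanishes at a
  # large finite iterate, but the observed information collapses there
  flag_ok <- function(dd) all(abs(diag(dd$hessian)) > 1e-4 * abs(curv0))
  for (iter in seq_len(max_iter)) {
    if (max(abs(d$gradient)) < tol)
      return(list(beta = beta, converged = flag_ok(d),
                  iterations = iter - 1L, loglik = d$loglik))
    H <- d$hessian
    if (any(abs(diag(H)) < 1e-12)) {
      bad <- which(abs(diag(H)) < 1e-12)[1]
      stop(sprintf("singular Hessian: covariate %d is degenerate (constant across risk sets)",
                   bad))
    }
    step <- tryCatch(solve(H, d$gradient),
                     error = function(e)
                       stop("singular Hessian: covariates are collinear within the stratum"))
    step <- -step  # Newton ascent: beta - H^{-1} g, H negative definite
    new_beta <- beta + step
    new_d <- cox_derivs(stratum, new_beta, hessian = TRUE)
    halvings <- 0L
    while (new_d$loglik < d$loglik && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_d <- cox_derivs(stratum, new_beta, hessian = TRUE)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    d <- new_d
  }
  list(beta = beta, converged = max(abs(d$gradient)) < tol && flag_ok(d),
       iterations = max_iter, loglik = d$loglik)
}

#' Separate (unpenalized) estimation of every cell
#'
#' Fits the per-stratum Cox MLE independently in each (location,
#' period) cell — the heterogeneity-preserving comparator.  Cells with
#' no events, or with a degenerate covariate, are marked `NA` and
#' flagged instead of raising.
#'
#' @param panel a `panel_data` object.
#' @param tol,max_iter passed to [fit_stratum_mle()].
#' @return An object of class `stcox_separate`: list with `beta`
#'   (p x q x m array, `NA` where unfittable), `flags` (p x q character
#'   matrix: "ok", "no_events", "degenerate", "not_converged").
#' @export
fit_separate <- function(panel, tol = 1e-6, max_iter = 50L) {
  beta <- empty_grid(panel)
  beta[] <- NA_real_
  flags <- matrix("ok", panel$p, panel$q,
                  dimnames = dimnames(beta)[1:2])
  for (j in seq_len(panel$q)) for (i in seq_len(panel$p)) {
    s <- panel_stratum(panel, i, j)
    if (s$n == 0 || sum(s$events) == 0) {
      flags[i, j] <- "no_events"
      next
    }
    fit <- tryCatch(fit_stratum_mle(s, tol = tol, max_iter = max_iter),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      flags[i, j] <- "degenerate"
      next
    }
    beta[i, j, ] <- fit$beta
    if (!fit$converged) flags[i, j] <- "not_converged"
  }
  structure(list(beta = beta, flags = flags), class = "stcox_separate")
}

#' @export
print.stcox_separate <- function(x, ...) {
  cat(sprintf("separate Cox estimates: %d x %d cells, %d covariates; %d cell(s) flagged\n",
              dim(x$beta)[1], dim(x$beta)[2], dim(x$beta)[3],
              sum(x$flags != "ok")))
  invisible(x)
}

# concatenate strata into one (shared risk set); m columns preserved
concat_strata <- function(strata, m) {
  keep <- Filter(function(s) s$n > 0, strata)
  if (!length(keep))
    return(stratum_data(numeric(0), integer(0), matrix(0, 0, m)))
  stratum_data(unlist(lapply(keep, `[[`, "times")),
               unlist(lapply(keep, `[[`, "events")),
               do.call(rbind, lapply(keep, `[[`, "covariates")))
}

#' Pooled estimation across locations and/or periods
#'
#' Pools cells by concatenating their rows into a single stratum with a
#' common risk set and fitting one Cox MLE per remaining index:
#' `over_locations` pools the p locations within each period (q coefficient
#' vectors), `over_times` pools the q periods within each location
#' (p vectors), `over_both` pools everything (1 vector).  Pooling masks
#' heterogeneity by construction; it is provided as a comparator.
#'
#' @param panel a `panel_data` object.
#' @param mode one of `"over_locations"`, `"over_times"`, `"over_both"`.
#' @param tol,max_iter passed to [fit_stratum_mle()].
#' @return Matrix of coefficients, one row per unpooled index (period
#'   labels for `over_locations`, location labels for `over_times`, a
#'   single row for `over_both`), with a `converged` attribute.
#' @export
fit_pooled <- function(panel, mode = c("over_both", "over_locations",
                                       "over_times"),
                       tol = 1e-6, max_iter = 50L) {
  mode <- match.arg(mode)
  groups <- switch(mode,
    over_locations = lapply(seq_len(panel$q), function(j)
      lapply(seq_len(panel$p), function(i) panel_stratum(panel, i, j))),
    over_times = lapply(seq_len(panel$p), function(i)
      lapply(seq_len(panel$q), function(j) panel_stratum(panel, i, j))),
    over_both = list(panel$strata))
  labels <- switch(mode,
    over_locations = as.character(panel$period_ids),
    over_times = as.character(panel$location_ids),
    over_both = "all")
  out <- matrix(NA_real_, length(groups), panel$m,
                dimnames = list(labels, panel$covariate_names))
  conv <- logical(length(groups))
  for (g in seq_along(groups)) {
    s <- concat_strata(groups[[g]], panel$m)
    if (sum(s$events) == 0) stop("no events in pooled sample '", labels[g], "'")
    fit <- fit_stratum_mle(s, tol = tol, max_iter = max_iter)
    out[g, ] <- fit$beta
    conv[g] <- fit$converged
  }
  attr(out, "converged") <- conv
  out
}
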
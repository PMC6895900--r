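#' Construct a single (location, period) stratum
#'
#' A stratum holds the survival records of one cell of the panel:
#' observed times in months, event indicators, and the covariate matrix.
#' Rows are stored in canonical order — ascending time, events before
#' censorings at tied times, input order last — so that the risk set at
#' any event time is a suffix of the tied-time groups.
#'
#' @param times numeric vector of positive observed times (months).
#' @param events integer/numeric vector of event indicators, 1 = event,
#'   0 = right-censored.
#' @param covariates numeric matrix with one row per subject; a stratum
#'   may be empty (`n = 0`) but the matrix must still carry the panel's
#'   column count.
#' @return An object of class `stratum_data` with elements `times`,
#'   `events`, `covariates`, `n`.
#' @export
stratum_data <- function(times, events, covariates) {
  times <- as.numeric(times)
  events <- as.integer(events)
  if (is.null(dim(covariates))) covariates <- matrix(as.numeric(covariates),
                                                     nrow = length(times))
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  n <- length(times)
  if (length(events) != n || nrow(covariates) != n)
    stop("times, events and covariate rows must have equal length")
  if (n > 0) {
    if (any(!is.finite(times)) || any(times <= 0))
      stop("observed times must be finite and strictly positive")
    if (!all(events %in% c(0L, 1L)))
      stop("event indicators must be 0 or 1")
    if (any(!is.finite(covariates)))
      stop("covariate entries must be finite")
    ord <- order(times, -events, seq_len(n))
    times <- times[ord]
    events <- events[ord]
    covariates <- covariates[ord, , drop = FALSE]
  }
  structure(list(times = times, events = events, covariates = covariates,
                 n = n), class = "stratum_data")
}

#' @export
print.stratum_data <- function(x, ...) {
  cat(sprintf("stratum_data: %d subjects, %d events, %d covariates\n",
              x$n, sum(x$events), ncol(x$covariates)))
  invisible(x)
}

#' Assemble a panel of survival strata
#'
#' A panel is the full p x q grid of strata: p locations by q ordered,
#' consecutive time intervals.  Cells with no observations are kept as
#' empty strata so that the smoothing penalty graph stays a complete
#' grid.  At least one of p, q must exceed 1 (otherwise there is
#' nothing to smooth over).
#'
#' @param strata list of `stratum_data`, cell (i, j) at position
#'   `(j - 1) * p + i` (location index moving fastest).
#' @param location_ids length-p vector of location labels.
#' @param period_ids length-q vector of period labels, strictly ordered;
#'   adjacency for the temporal penalty is consecutive positions.
#' @param covariate_names length-m character vector.
#' @return An object of class `panel_data`.
#' @export
panel_data <- function(strata, location_ids, period_ids, covariate_names) {
  p <- length(location_ids)
  q <- length(period_ids)
  m <- length(covariate_names)
  if (p < 1 || q < 1) stop("need at least one location and one period")
  if (p < 2 && q < 2)
    stop("panel must have p >= 2 locations or q >= 2 periods")
  if (length(strata) != p * q)
    stop(sprintf("expected %d strata, got %d", p * q, length(strata)))
  if (anyDuplicated(location_ids)) stop("duplicated location ids")
  if (is.unsorted(period_ids, strictly = TRUE))
    stop("period ids must be strictly increasing")
  for (s in strata) {
    if (!inherits(s, "stratum_data")) stop("strata must be stratum_data")
    if (ncol(s$covariates) != m)
      stop("all strata must share the panel's covariate count")
  }
  structure(list(p = p, q = q, m = m, strata = strata,
                 location_ids = location_ids, period_ids = period_ids,
                 covariate_names = covariate_names,
                 n_total = sum(vapply(strata, function(s) s$n, 0L))),
            class = "panel_data")
}

#' Extract one stratum from a panel
#'
#' @param panel a `panel_data` object.
#' @param i location index in `1:p`.
#' @param j period index in `1:q`.
#' @return The `stratum_data` of cell (i, j).
#' @export
panel_stratum <- function(panel, i, j) {
  stopifnot(i >= 1, i <= panel$p, j >= 1, j <= panel$q)
  panel$strata[[(j - 1L) * panel$p + i]]
}

#' @export
print.panel_data <- function(x, ...) {
  ncell <- vapply(x$strata, function(s) s$n, 0L)
  cat(sprintf(paste0("panel_data: %d locations x %d periods, %d covariates, ",
                     "%d subjects (%d empty cells)\n"),
              x$p, x$q, x$m, x$n_total, sum(ncell == 0L)))
  invisible(x)
}

default_schema <- function() {
  list(location = "location", period = "period", time = "time",
       event = "event", covariates = NULL)
}

#' Read a long-format survival panel from CSV
#'
#' One row per subject with columns for location id, period id, observed
#' time, event indicator, and any number of numeric covariates.  Rows
#' are grouped into (location, period) cells; locations and periods are
#' ordered ascending; (location, period) pairs absent from the file
#' become empty cells.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named list mapping roles to column names; defaults to
#'   columns `location`, `period`, `time`, `event`, with every remaining
#'   column treated as a covariate.  Set `schema$covariates` to select a
#'   subset explicitly.
#' @return A [panel_data()] object.
#' @export
read_panel_csv <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- utils::modifyList(default_schema(), schema)
  df <- utils::read.csv(path, check.names = FALSE)
  for (role in c("location", "period", "time", "event")) {
    col <- schema[[role]]
    if (!col %in% names(df))
      stop(sprintf("schema error: required column '%s' (%s) not found",
                   col, role))
  }
  covs <- schema$covariates
  if (is.null(covs))
    covs <- setdiff(names(df), unlist(schema[c("location", "period",
                                               "time", "event")]))
  missing_cov <- setdiff(covs, names(df))
  if (length(missing_cov))
    stop("schema error: covariate column(s) not found: ",
         paste(missing_cov, collapse = ", "))
  for (col in c(schema$time, schema$event, covs)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) |
                     !grepl("^\\s*-?[0-9.eE+-]+\\s*$", as.character(v)))
      stop(sprintf("parse error: column '%s' is not numeric (first bad row %d)",
                   col, if (length(bad)) bad[1] else 1L))
    }
  }
  time <- df[[schema$time]]
  event <- df[[schema$event]]
  if (!all(event %in% c(0, 1)))
    stop("validation error: event values outside {0, 1} at row ",
         which(!event %in% c(0, 1))[1])
  if (any(!is.finite(time) | time <= 0))
    stop("validation error: nonpositive or non-finite time at row ",
         which(!is.finite(time) | time <= 0)[1])

  loc <- df[[schema$location]]
  per <- df[[schema$period]]
  location_ids <- sort(unique(loc))
  period_ids <- sort(unique(per))
  p <- length(location_ids)
  q <- length(period_ids)
  X <- as.matrix(df[, covs, drop = FALSE])
  storage.mode(X) <- "double"

  strata <- vector("list", p * q)
  li <- match(loc, location_ids)
  pj <- match(per, period_ids)
  cell <- (pj - 1L) * p + li
  for (j in seq_len(q)) for (i in seq_len(p)) {
    idx <- which(cell == (j - 1L) * p + i)
    strata[[(j - 1L) * p + i]] <- stratum_data(
      time[idx], event[idx], X[idx, , drop = FALSE])
  }
  panel_data(strata, location_ids, period_ids, covs)
}

#' Validate a matrix of inter-location distances
#'
#' @param d numeric p x p matrix: symmetric, zero diagonal, strictly
#'   positive finite off-diagonal entries (inverse-distance weights are
#'   undefined at distance zero).
#' @param tol asymmetry tolerance.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_distance_matrix <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(!is.finite(d))) stop("distance matrix entries must be finite")
  if (max(abs(d - t(d))) > tol)
    stop("distance matrix is asymmetric beyond tolerance ", tol)
  if (any(abs(diag(d)) > tol)) stop("distance matrix diagonal must be zero")
  off <- d[row(d) != col(d)]
  if (length(off) && any(off <= 0))
    stop("off-diagonal distances must be strictly positive")
  d
}

#' Read a p x p distance matrix from CSV
#'
#' Expects a square numeric table with a header row and an index column
#' of location ids; rows/columns are reordered to match the panel's
#' location order.
#'
#' @param path path to the CSV file.
#' @param location_ids location labels in panel order.
#' @return The validated distance matrix with `location_ids` dimnames.
#' @export
read_distance_matrix <- function(path, location_ids) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  d <- as.matrix(df)
  ids <- as.character(location_ids)
  extra <- setdiff(rownames(d), ids)
  missing <- setdiff(ids, rownames(d))
  if (length(missing) || length(extra) ||
      !setequal(colnames(d), rownames(d)))
    stop("distance matrix labels do not match panel locations; ",
         "missing: [", paste(missing, collapse = ", "),
         "], unexpected: [", paste(extra, collapse = ", "), "]")
  d <- d[ids, ids]
  storage.mode(d) <- "double"
  validate_distance_matrix(d)
  d
}

#' Write a survival panel to long-format CSV
#'
#' Inverse of [read_panel_csv()]: one row per subject with columns
#' `location`, `period`, `time`, `event`, then the covariates.
#'
#' @param panel a `panel_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  rows <- vector("list", panel$p * panel$q)
  for (j in seq_len(panel$q)) for (i in seq_len(panel$p)) {
    s <- panel_stratum(panel, i, j)
    if (s$n == 0) next
    X <- s$covariates
    colnames(X) <- panel$covariate_names
    rows[[(j - 1L) * panel$p + i]] <- data.frame(
      location = rep(panel$location_ids[i], s$n),
      period = rep(panel$period_ids[j], s$n),
      time = s$times, event = s$events, X, check.names = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix to CSV
#'
#' @param d p x p distance matrix.
#' @param location_ids labels for rows/columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, location_ids, path) {
  d <- as.matrix(d)
  dimnames(d) <- list(as.character(location_ids), as.character(location_ids))
  utils::write.csv(d, path, row.names = TRUE)
  invisible(path)
}

# coerce a fit result or bare array into a p x q x m coefficient array
coef_array <- function(x) {
  if (inherits(x, "stcox_fit")) return(x$beta)
  if (is.list(x) && !is.null(x$beta)) return(x$beta)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  stop("expected a fit result or a p x q x m coefficient array")
}

#' Write coefficient estimates (and optional bootstrap inference) to CSV
#'
#' Produces a long-format table with one row per (location, period,
#' covariate): columns `location`, `period`, `covariate`, `estimate`,
#' `se`, `ci_low`, `ci_high`.  The inference columns are `NA` unless a
#' bootstrap result is supplied.  Estimates must be finite (cells the
#' separate estimator could not fit are written as `NA` with no error);
#' nothing is written if validation fails.
#'
#' @param x a fit result ([fit_smoothed()], [fit_separate()]) or a
#'   p x q x m array with dimnames `(location, period, covariate)`.
#' @param path output path.
#' @param boot optional [bootstrap_se()] result providing `se`,
#'   `ci_low`, `ci_high` arrays of the same shape.
#' @return The written data frame, invisibly.
#' @export
write_estimates <- function(x, path, boot = NULL) {
  beta <- coef_array(x)
  dn <- dimnames(beta)
  if (is.null(dn)) stop("coefficient array must carry dimnames")
  allow_na <- isTRUE(inherits(x, "stcox_separate")) ||
    (is.list(x) && !is.null(x$flags))
  bad <- is.infinite(beta) | is.nan(beta) | (!allow_na & is.na(beta))
  if (any(bad))
    stop("non-finite estimate at (",
         paste(dn[[1]][which(bad, arr.ind = TRUE)[1, 1]],
               dn[[2]][which(bad, arr.ind = TRUE)[1, 2]],
               dn[[3]][which(bad, arr.ind = TRUE)[1, 3]], sep = ", "),
         "); nothing written")
  grid <- expand.grid(covariate = dn[[3]], period = dn[[2]],
                      location = dn[[1]], stringsAsFactors = FALSE)
  # order rows: location slowest, then period, then covariate
  df <- data.frame(location = grid$location, period = grid$period,
                   covariate = grid$covariate,
                   estimate = as.vector(aperm(beta, c(3, 2, 1))),
                   se = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  if (!is.null(boot)) {
    df$se <- as.vector(aperm(boot$se, c(3, 2, 1)))
    df$ci_low <- as.vector(aperm(boot$ci_low, c(3, 2, 1)))
    df$ci_high <- as.vector(aperm(boot$ci_high, c(3, 2, 1)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

# dimnamed p x q x m array of zeros matching a panel
empty_grid <- function(panel) {
  array(0, dim = c(panel$p, panel$q, panel$m),
        dimnames = list(as.character(panel$location_ids),
                        as.character(panel$period_ids),
                        panel$covariate_names))
}
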
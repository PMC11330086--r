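# Dimensionality reduction: low-variance and high-correlation filters with
# manual thresholds or a supervised grid search, plus per-column moment
# statistics for manual feature selection. Variance is population variance
# (divide by n) and removal uses <= threshold, so threshold 0 removes
# constant columns.

pop_var <- function(x) {
  n <- length(x)
  sum((x - mean(x))^2) / n
}

new_filter_result <- function(kept, removed, method, threshold,
                              search_trace = NULL, cv_mode = NULL) {
  structure(list(kept_columns = kept, removed_columns = removed,
                 method = method, threshold = threshold,
                 search_trace = search_trace, cv_mode = cv_mode),
            class = "chemgroup_filter")
}

#' @export
print.chemgroup_filter <- function(x, ...) {
  cat("<chemgroup_filter> ", x$method, " threshold ", x$threshold, ": ",
      length(x$kept_columns), " kept / ", length(x$removed_columns),
      " removed\n", sep = "")
  invisible(x)
}

#' Low-variance filter
#'
#' Removes every column whose population variance is at or below
#' `threshold`.
#'
#' @param fm Feature matrix.
#' @param threshold Non-negative variance threshold.
#' @return A `chemgroup_filter` with kept/removed column names.
#' @export
variance_filter <- function(fm, threshold) {
  stopifnot(threshold >= 0)
  x <- fm_values(fm)
  v <- apply(x, 2L, pop_var)
  keep <- v > threshold
  if (!any(keep))
    stop("variance filter removed all columns at threshold ", threshold)
  new_filter_result(colnames(x)[keep], colnames(x)[!keep],
                    "variance", threshold)
}

#' High-correlation filter
#'
#' Greedy pass in column order: for each ordered pair `(i < j)` with
#' `|Pearson r| > threshold` and both columns still kept, the later column
#' `j` is removed. Deterministic given the column order; constant columns
#' (undefined correlation) are never removed by this filter.
#'
#' @param fm Feature matrix with at least two columns.
#' @param threshold Absolute-correlation threshold in \[0, 1\].
#' @return A `chemgroup_filter`.
#' @export
correlation_filter <- function(fm, threshold) {
  x <- fm_values(fm)
  stopifnot(ncol(x) >= 2L)
  if (threshold < 0 || threshold > 1)
    stop("correlation threshold must be in [0, 1]")
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  p <- ncol(x)
  keep <- rep(TRUE, p)
  for (i in seq_len(p - 1L)) {
    if (!keep[i]) next
    for (j in seq.int(i + 1L, p)) {
      if (keep[j] && abs(r[i, j]) > threshold) keep[j] <- FALSE
    }
  }
  if (!any(keep))
    stop("correlation filter removed all columns at threshold ", threshold)
  new_filter_result(colnames(x)[keep], colnames(x)[!keep],
                    "correlation", threshold)
}

#' Apply a filter result to a matrix
#'
#' Filters are projections: applying the same result twice changes
#' nothing.
#'
#' @param fm Feature matrix.
#' @param filter A `chemgroup_filter`.
#' @return Feature matrix restricted to the kept columns.
#' @export
apply_filter <- function(fm, filter) {
  x <- fm_values(fm)
  keep <- intersect(colnames(x), filter$kept_columns)
  fm_replace(fm, x[, keep, drop = FALSE])
}

#' Supervised threshold search for the variance/correlation filters
#'
#' For every threshold on the grid the filter is applied, a learner is
#' fitted on the training portion(s), and the held-out accuracy
#' (classification) or R-squared (regression) is scored, either on a
#' single stratified 80/20 holdout or by 5-fold cross-validation. The
#' threshold with the best mean score is applied to the full matrix.
#' Thresholds that leave zero columns are skipped with a note in the
#' trace.
#'
#' The default grid (0 to 0.1 in steps of 0.01) is the published one for
#' both filters. Note that for the correlation filter such low thresholds
#' remove almost all correlated columns; supply a high-correlation grid
#' (e.g. `seq(0.8, 0.99, 0.01)`) if that is not intended.
#'
#' @param fm Feature matrix.
#' @param labels Labels for the supervised scoring.
#' @param learner A [learner_spec()].
#' @param filter_kind `"variance"` or `"correlation"`.
#' @param grid Numeric vector of thresholds.
#' @param cv_mode `"holdout_80_20"` or `"cv5"`.
#' @param seed Split seed (recorded in the trace).
#' @return A `chemgroup_filter` for the winning threshold, with the full
#'   `search_trace` of `(threshold, score)` pairs.
#' @export
auto_threshold_search <- function(fm, labels, learner,
                                  filter_kind = c("variance", "correlation"),
                                  grid = seq(0, 0.1, by = 0.01),
                                  cv_mode = c("holdout_80_20", "cv5"),
                                  seed = 1L) {
  filter_kind <- match.arg(filter_kind)
  cv_mode <- match.arg(cv_mode)
  stopifnot(length(grid) >= 1L)
  if (length(unique(labels)) < 2L) stop("labels are constant")
  x <- fm_values(fm)
  metric <- default_metric(learner)
  trace <- data.frame(threshold = grid, score = NA_real_,
                      n_kept = NA_integer_,
                      note = "", stringsAsFactors = FALSE)
  for (i in seq_along(grid)) {
    flt <- tryCatch(
      switch(filter_kind,
             variance = variance_filter(x, grid[i]),
             correlation = correlation_filter(x, grid[i])),
      error = function(e) NULL)
    if (is.null(flt)) {
      trace$note[i] <- "skipped: zero columns kept"
      next
    }
    xs <- x[, flt$kept_columns, drop = FALSE]
    trace$n_kept[i] <- ncol(xs)
    trace$score[i] <- if (cv_mode == "cv5") {
      cv_score(learner, xs, labels, metric, k_folds = 5L, seed = seed)
    } else {
      holdout_score(learner, xs, labels, metric, seed = seed)
    }
  }
  if (all(is.na(trace$score)))
    stop("no grid threshold left any columns")
  best <- which.max(trace$score)  # ties: first (lowest) threshold
  flt <- switch(filter_kind,
                variance = variance_filter(x, grid[best]),
                correlation = correlation_filter(x, grid[best]))
  flt$search_trace <- trace
  flt$cv_mode <- cv_mode
  flt
}

#' Per-column moment statistics
#'
#' Mean, population variance, skewness (g1) and excess kurtosis (g2) per
#' column, displayed to guide manual feature selection. Moments of
#' constant columns are reported as 0 by convention.
#'
#' @param fm Feature matrix.
#' @return data.frame with one row per column.
#' @export
column_stats <- function(fm) {
  x <- fm_values(fm)
  n <- nrow(x)
  stats_one <- function(col) {
    m <- mean(col)
    d <- col - m
    m2 <- mean(d^2)
    if (m2 == 0) return(c(m, 0, 0, 0))
    g1 <- mean(d^3) / m2^1.5
    g2 <- mean(d^4) / m2^2 - 3
    c(m, m2, g1, g2)
  }
  out <- t(apply(x, 2L, stats_one))
  data.frame(column = colnames(x), mean = out[, 1L], variance = out[, 2L],
             skewness = out[, 3L], kurtosis = out[, 4L],
             row.names = NULL, stringsAsFactors = FALSE)
}
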
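#' Evaluation metrics
#'
#' Pearson correlation, root-mean-square error and mean absolute error
#' between two series, as used to score reconstructed excitations (shape via
#' `r`, magnitude via RMSE) and joint-moment accuracy (MAE).
#'
#' @param x,y Equal-length numeric series.
#' @return Scalar metric value.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("series lengths differ")
  if (length(x) < 2) stopf("need >= 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: a series has zero variance")
  stats::cor(x, y)
}

#' @rdname pearson_r
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stopf("series lengths differ")
  sqrt(mean((x - y)^2))
}

#' @rdname pearson_r
#' @export
mae <- function(x, y) {
  if (length(x) != length(y)) stopf("series lengths differ")
  mean(abs(x - y))
}

#' Qualitative correlation bands
#'
#' Classifies a Pearson correlation into the conventional interpretation
#' bands: weak (`r < 0.35`), moderate (`0.35 <= r <= 0.67`), strong
#' (`0.67 < r < 0.9`), very strong (`r >= 0.9`).
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Factor with levels `weak < moderate < strong < very strong`.
#' @export
classify_correlation <- function(r) {
  if (any(!is.finite(r)) || any(r < -1 - 1e-12) || any(r > 1 + 1e-12))
    stopf("r must lie in [-1, 1]")
  bands <- ifelse(r >= 0.9, "very strong",
           ifelse(r > 0.67, "strong",
           ifelse(r >= 0.35, "moderate", "weak")))
  factor(bands, levels = c("weak", "moderate", "strong", "very strong"),
         ordered = TRUE)
}

#' Histogram of the best synergy number per trial
#'
#' For each trial in a sweep results table, finds the synergy count `p` that
#' maximizes `r` (or minimizes RMSE) and accumulates counts over trials;
#' ties go to the smallest `p`.
#'
#' @param results Sweep results `data.frame` with columns `trial`, `p` and
#'   the criterion column (`r` or `rmse`); typically one
#'   algorithm/scheme slice of [run_sweep()] output.
#' @param criterion `"max_r"` or `"min_rmse"`.
#' @return Named integer vector of counts indexed by `p`; counts sum to the
#'   number of scored trials.
#' @export
best_p_histogram <- function(results, criterion = c("max_r", "min_rmse")) {
  criterion <- match.arg(criterion)
  col <- if (criterion == "max_r") "r" else "rmse"
  results <- results[!results$failed & is.finite(results[[col]]), , drop = FALSE]
  if (nrow(results) == 0) stopf("no scored trials in the results table")
  ps <- sort(unique(results$p))
  counts <- stats::setNames(integer(length(ps)), ps)
  for (tr in unique(results$trial)) {
    sub <- results[results$trial == tr, , drop = FALSE]
    sub <- sub[order(sub$p), , drop = FALSE] # smallest p wins ties
    v <- sub[[col]]
    best <- if (criterion == "max_r") sub$p[which.max(v)] else sub$p[which.min(v)]
    counts[as.character(best)] <- counts[as.character(best)] + 1L
  }
  counts
}

#' Aggregate sweep results per methodological combination
#'
#' Means and standard deviations of `r`, `rmse`, `vaf` and `mae` per
#' (algorithm, scheme, p) cell.
#'
#' @param results A [run_sweep()] results table.
#' @return `data.frame` with one row per combination.
#' @export
aggregate_results <- function(results) {
  ok <- results[!results$failed, , drop = FALSE]
  if (nrow(ok) == 0) stopf("no successful rows to aggregate")
  keys <- unique(ok[, c("algorithm", "scheme", "p")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- ok[ok$algorithm == keys$algorithm[i] & ok$scheme == keys$scheme[i] &
                ok$p == keys$p[i], , drop = FALSE]
    data.frame(keys[i, ], n = nrow(sub),
               r_mean = mean(sub$r), r_sd = stats::sd(sub$r),
               rmse_mean = mean(sub$rmse), rmse_sd = stats::sd(sub$rmse),
               vaf_mean = mean(sub$vaf), mae_mean = mean(sub$mae),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Correlation between mean curves
#'
#' Averages each list of cycle-grid series into a mean curve and reports the
#' Pearson correlation between the two mean curves (the "average curve"
#' comparison, as opposed to per-trial correlations).
#'
#' @param xs,ys Lists of equal-length numeric series.
#' @return Scalar correlation.
#' @export
mean_curve_r <- function(xs, ys) {
  pearson_r(rowMeans(do.call(cbind, xs)), rowMeans(do.call(cbind, ys)))
}
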
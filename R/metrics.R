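# Evaluation metrics: AUROC via the rank (Mann-Whitney) identity, bootstrap
# confidence intervals over test-set resamples, and the one-sided
# Mann-Whitney U test used for significance statements.

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive case receives a higher
#' score than a randomly chosen negative case, with ties counted one half —
#' the normalized Mann-Whitney U statistic, computed from midranks.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (0/1).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Bootstrap confidence interval for a test-set metric
#'
#' Resamples the test units with replacement `n_boot` times, recomputes the
#' metric each time, and returns the mean of the bootstrap values with the
#' percentile interval. Resamples on which the metric is undefined (e.g. a
#' single-class AUROC resample) are redrawn.
#'
#' @param values_fn function(idx) computing the metric on a resample given
#'   integer indices into the test units.
#' @param n_units number of test units.
#' @param n_boot number of resamples (default 30).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return List with `point` (bootstrap mean), `lo`, `hi` and the vector of
#'   bootstrap `values`.
#' @export
bootstrap_ci <- function(values_fn, n_units, n_boot = 30L, level = 0.95,
                         seed = 0L) {
  stopifnot(n_boot >= 2)
  with_seed(seed, {
    vals <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n_units, n_units, replace = TRUE)
        v <- tryCatch(values_fn(idx), error = function(e) NA_real_)
        if (!is.na(v)) break
      }
      vals[b] <- v
    }
    qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    list(point = mean(vals), lo = qs[1], hi = qs[2], values = vals)
  })
}

#' One-sided Mann-Whitney U test
#'
#' Tests the alternative that sample `b` is stochastically greater than
#' sample `a`. Exact enumeration (via the exact U distribution) when the
#' smaller sample has at most 8 values and there are no ties; the normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param a,b numeric vectors.
#' @return p-value.
#' @export
mann_whitney_one_sided <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && min(length(a), length(b)) <= 8
  suppressWarnings(
    stats::wilcox.test(b, a, alternative = "greater", exact = use_exact,
                       correct = TRUE)$p.value
  )
}
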
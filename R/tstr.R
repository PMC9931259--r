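# Train-on-Synthetic-Test-on-Real protocol: two classifiers with identical
# architecture and training procedure, one fitted on real training data (E)
# and one on the synthetic cohort (E-hat), both scored on the same held-out
# real test set. The gap e - e_hat measures how faithful the generator is in
# the respects that matter for the downstream task.

#' Train-on-synthetic-test-on-real evaluation
#'
#' Trains the real arm on `real_split$train` and the synthetic arm on
#' `gen_cohort` with identical classifier settings, repeating each arm over
#' `seeds` and keeping the initialization with the best validation AUROC
#' (real validation data for the real arm; a held-out slice of the synthetic
#' cohort for the synthetic arm). Both selected classifiers are scored on the
#' same real test set; uncertainty comes from bootstrap resampling of the
#' test patients, and a one-sided Mann-Whitney U test compares the two
#' bootstrap distributions.
#'
#' @param gen_cohort synthetic training [cohort()].
#' @param real_split a [split_cohort()] result.
#' @param task_index which label to evaluate.
#' @param grud_args list of arguments passed on to [grud()] (shared by both
#'   arms).
#' @param seeds integer vector of initialization seeds (default `0:4`).
#' @param n_boot bootstrap resamples (default 30).
#' @param boot_seed seed for the bootstrap.
#' @param synth_val_fraction fraction of the synthetic cohort held out to
#'   select the synthetic arm's initialization.
#' @return List of class `tstr_report`: `e`, `e_hat`, `gap`, `ci_e`,
#'   `ci_e_hat`, `p_values`, per-arm seed tables.
#' @export
tstr <- function(gen_cohort, real_split, task_index = 1L,
                 grud_args = list(), seeds = 0:4, n_boot = 30L,
                 boot_seed = 0L, synth_val_fraction = 0.15) {
  fit_arm <- function(train_co, val_co) {
    best <- NULL
    tab <- data.frame(seed = seeds, val_auroc = NA_real_)
    for (i in seq_along(seeds)) {
      cl <- do.call(grud, c(list(train = train_co, task_index = task_index,
                                 seed = seeds[i]), grud_args))
      va <- auroc(predict(cl, val_co), cohort_labels(val_co, task_index))
      tab$val_auroc[i] <- va
      if (is.null(best) || va > best$val_auroc) {
        best <- list(classifier = cl, val_auroc = va, seed = seeds[i])
      }
    }
    best$table <- tab
    best
  }

  real_arm <- fit_arm(real_split$train, real_split$val)

  synth_split <- split_cohort(gen_cohort,
                              c(1 - synth_val_fraction, synth_val_fraction, 0),
                              task_index = task_index, seed = boot_seed)
  synth_arm <- fit_arm(synth_split$train, synth_split$val)

  test_co <- real_split$test
  y_test <- cohort_labels(test_co, task_index)
  scores_e <- predict(real_arm$classifier, test_co)
  scores_eh <- predict(synth_arm$classifier, test_co)
  e <- auroc(scores_e, y_test)
  e_hat <- auroc(scores_eh, y_test)

  boot_fn <- function(scores) {
    function(idx) auroc(scores[idx], y_test[idx])
  }
  ci_e <- bootstrap_ci(boot_fn(scores_e), length(y_test), n_boot = n_boot,
                       seed = boot_seed)
  ci_eh <- bootstrap_ci(boot_fn(scores_eh), length(y_test), n_boot = n_boot,
                        seed = boot_seed + 1L)

  p_values <- list(
    real_gt_synthetic = mann_whitney_one_sided(ci_eh$values, ci_e$values),
    synthetic_gt_chance = mann_whitney_one_sided(
      rep(0.5, length(ci_eh$values)), ci_eh$values)
  )

  structure(list(e = e, e_hat = e_hat, gap = e - e_hat,
                 ci_e = ci_e[c("point", "lo", "hi")],
                 ci_e_hat = ci_eh[c("point", "lo", "hi")],
                 boot_e = ci_e$values, boot_e_hat = ci_eh$values,
                 p_values = p_values,
                 real_seeds = real_arm$table, synth_seeds = synth_arm$table,
                 real_classifier = real_arm$classifier,
                 synth_classifier = synth_arm$classifier,
                 task_index = task_index),
            class = "tstr_report")
}

#' @export
print.tstr_report <- function(x, ...) {
  cat(sprintf("TSTR report (task %d)\n", x$task_index))
  cat(sprintf("  real-trained  e     = %.3f  [%.3f, %.3f]\n",
              x$e, x$ci_e$lo, x$ci_e$hi))
  cat(sprintf("  synth-trained e-hat = %.3f  [%.3f, %.3f]\n",
              x$e_hat, x$ci_e_hat$lo, x$ci_e_hat$hi))
  cat(sprintf("  gap e - e-hat = %.3f;  p(real > synth) = %.4f\n",
              x$gap, x$p_values$real_gt_synthetic))
  invisible(x)
}

#' Per-subgroup performance report
#'
#' AUROC with a bootstrap confidence interval for each category of a static
#' variable on the test cohort. Categories lacking a positive (or negative)
#' test case are omitted with a warning. The fairness gap is the difference
#' between the best and worst per-category AUROC.
#'
#' @param classifier a [grud()] fit.
#' @param test test [cohort()].
#' @param static_var_index which static variable to stratify on.
#' @param task_index label to evaluate.
#' @param n_boot bootstrap resamples per category.
#' @param seed integer seed.
#' @return List with `per_group` (data.frame: category, n, auroc, lo, hi) and
#'   `fairness_gap`.
#' @export
per_group_report <- function(classifier, test, static_var_index = 1L,
                             task_index = 1L, n_boot = 30L, seed = 0L) {
  vocab <- test$static_vocab[[static_var_index]]
  s <- cohort_statics(test)[, static_var_index]
  y <- cohort_labels(test, task_index)
  scores <- predict(classifier, test)
  rows <- list()
  for (k in seq_along(vocab)) {
    sel <- which(s == k)
    if (length(sel) == 0) next
    if (length(unique(y[sel])) < 2) {
      warning("category '", vocab[k],
              "' lacks both classes in the test set; omitted")
      next
    }
    ci <- bootstrap_ci(function(idx) auroc(scores[sel][idx], y[sel][idx]),
                       length(sel), n_boot = n_boot, seed = seed + k)
    rows[[length(rows) + 1L]] <- data.frame(
      category = vocab[k], n = length(sel),
      auroc = auroc(scores[sel], y[sel]), lo = ci$lo, hi = ci$hi)
  }
  per_group <- do.call(rbind, rows)
  gap <- if (is.null(per_group) || nrow(per_group) < 2) 0 else {
    max(per_group$auroc) - min(per_group$auroc)
  }
  list(per_group = per_group, fairness_gap = gap)
}
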
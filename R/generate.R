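# Ancestral sampling from the fitted generative model, conditional cohort
# synthesis with exact (s, y) composition control, and augmentation of real
# cohorts to equalize subgroup counts.

# Plain-matrix forward sampling of one or more patients sharing a
# conditioning row layout. s: n x M codes, y: n x L_cond bits.
hg_sample_batch <- function(model, s, y) {
  arch <- model$arch
  P <- model$params
  ops <- ops_plain
  konst <- identity
  n <- nrow(y)
  D <- model$D; Tn <- model$Tn
  cond <- encode_conditioning(s, y, model$vocab_sizes,
                              arch$condition_on_static,
                              arch$condition_on_label)
  v <- matrix(stats::rnorm(n * arch$dim_v), n, arch$dim_v)
  probs <- hg_mask_probs(ops, konst, P, v, cond)
  m_flat <- matrix(as.integer(stats::runif(n * Tn * D) < probs), n, Tn * D)
  # column j = (t-1) * D + d
  masks <- lapply(seq_len(n), function(i) {
    t(matrix(m_flat[i, ], D, Tn))
  })
  z <- matrix(stats::rnorm(n * arch$dim_z), n, arch$dim_z)   # z_0 ~ N(0, I)
  h <- matrix(0, n, arch$dim_h)
  x_prev <- matrix(0, n, D)
  xs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    h <- gru_step(ops, P$h_rnn, cbind(x_prev, v), h)
    pz <- gauss_head(ops, P$p_z, cbind(z, h), arch$sd_floor)
    z <- pz$mean + pz$sd * matrix(stats::rnorm(n * arch$dim_z), n, arch$dim_z)
    dx <- gauss_head(ops, P$dec_x, cbind(z, h, v, cond), arch$sd_floor)
    x_t <- dx$mean + dx$sd * matrix(stats::rnorm(n * D), n, D)
    m_t <- t(vapply(masks, function(mm) mm[t, ], numeric(D)))
    if (D == 1L) m_t <- matrix(unlist(lapply(masks, function(mm) mm[t, ])), n, 1)
    x_t <- x_t * m_t          # missing cells are zero, as in the real data
    xs[[t]] <- x_t
    x_prev <- x_t             # the recurrence consumes the mask-zeroed value
  }
  records <- vector("list", n)
  for (i in seq_len(n)) {
    x <- t(vapply(xs, function(xx) xx[i, ], numeric(D)))
    if (D == 1L) x <- matrix(unlist(lapply(xs, function(xx) xx[i, ])), Tn, 1)
    records[[i]] <- list(x = x, m = masks[[i]], s = s[i, ], y_cond = y[i, ])
  }
  records
}

#' Sample one synthetic patient
#'
#' Ancestral sampling: the static latent and the initial sequential latent
#' are drawn from standard normal priors, the missingness mask sheet is drawn
#' from its Bernoulli decoder in one shot, and the feature sequence is rolled
#' out through the transition prior, feature decoder and deterministic
#' recurrence. The sampled features are zeroed at generated-missing cells so
#' the record is a drop-in substitute for a preprocessed real record.
#'
#' @param model a [healthgen()] fit.
#' @param s integer vector of static codes (length M).
#' @param y binary vector matching the model's conditioning labels.
#' @param seed integer seed; deterministic given the seed.
#' @param patient_id id for the record.
#' @return A [patient_record()]. Its `y` slot carries the conditioning bits
#'   in the model's label columns and 0 elsewhere.
#' @export
sample_patient <- function(model, s, y, seed = 0L, patient_id = "synth-1") {
  rec <- with_seed(seed, {
    hg_sample_batch(model, matrix(as.integer(s), 1), matrix(as.integer(y), 1))
  })[[1]]
  y_full <- integer(length(model$label_names))
  y_full[model$label_cols] <- rec$y_cond
  patient_record(rec$x, rec$m, rec$s, y_full, patient_id)
}

#' Composition specification helpers
#'
#' `composition_mirror()` builds the composition table that reproduces a
#' template cohort's empirical joint (s, y) contingency; `composition_spec()`
#' validates a hand-built one. The table has one column per static variable
#' (category names, or `NA` to draw that variable from the template's
#' empirical marginal), a `y` column (0/1 for the conditioning task) and an
#' `n` column of requested counts.
#'
#' @param template a [cohort()].
#' @param task_index label whose value defines the `y` column.
#' @return A data.frame composition table.
#' @export
composition_mirror <- function(template, task_index = 1L) {
  M <- length(template$static_vocab)
  s <- cohort_statics(template)
  y <- cohort_labels(template, task_index)
  df <- as.data.frame(matrix(NA_character_, length(y), M))
  names(df) <- names(template$static_vocab)
  for (j in seq_len(M)) {
    df[[j]] <- template$static_vocab[[j]][s[, j]]
  }
  df$y <- y
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))), by = df, FUN = sum)
  agg
}

#' @rdname composition_mirror
#' @param spec a data.frame with static-variable columns, `y` and `n`.
#' @export
composition_spec <- function(spec) {
  stopifnot(is.data.frame(spec), all(c("y", "n") %in% names(spec)),
            all(spec$n >= 0), sum(spec$n) >= 1)
  spec
}

#' Conditionally generate a synthetic cohort
#'
#' Generates exactly the requested number of patients per (s, y) cell of the
#' composition table. Static variables left `NA` in a row (and all static
#' variables when the model is unconditional in s) are filled by sampling the
#' template's empirical marginals — they are bookkeeping for the record
#' container, not part of the conditioning.
#'
#' @param model a [healthgen()] fit.
#' @param spec composition table (see [composition_mirror()]).
#' @param template a [cohort()] supplying vocabularies, grid and
#'   standardizer.
#' @param seed integer seed.
#' @return A [cohort()] with `provenance = "synthetic"`.
#' @export
generate_cohort <- function(model, spec, template, seed = 0L) {
  spec <- composition_spec(spec)
  vocab <- template$static_vocab
  M <- length(vocab)
  svars <- names(vocab)
  emp_s <- cohort_statics(template)
  with_seed(seed, {
    rows <- list()
    for (r in seq_len(nrow(spec))) {
      n_r <- spec$n[r]
      if (n_r == 0) next
      s_mat <- matrix(0L, n_r, M)
      for (j in seq_len(M)) {
        cat_name <- if (svars[j] %in% names(spec)) spec[[svars[j]]][r] else NA
        if (is.na(cat_name)) {
          s_mat[, j] <- sample(emp_s[, j], n_r, replace = TRUE)
        } else {
          code <- match(cat_name, vocab[[j]])
          if (is.na(code)) {
            stop("unknown category '", cat_name, "' for static variable ",
                 svars[j])
          }
          s_mat[, j] <- code
        }
      }
      y_mat <- matrix(as.integer(spec$y[r]), n_r, length(model$label_cols))
      rows[[length(rows) + 1L]] <- list(s = s_mat, y = y_mat)
    }
    s_all <- do.call(rbind, lapply(rows, `[[`, "s"))
    y_all <- do.call(rbind, lapply(rows, `[[`, "y"))
    recs <- hg_sample_batch(model, s_all, y_all)
    records <- vector("list", length(recs))
    for (i in seq_along(recs)) {
      y_full <- integer(length(template$label_names))
      y_full[model$label_cols] <- recs[[i]]$y_cond
      records[[i]] <- patient_record(recs[[i]]$x, recs[[i]]$m, recs[[i]]$s,
                                     y_full, sprintf("synth-%05d", i))
    }
    cohort(records, template$feature_names, vocab, template$label_names,
           template$standardizer, template$grid, provenance = "synthetic")
  })
}

#' Simulate synthetic patients from a fitted model
#'
#' `simulate()` interface to [generate_cohort()]: mirrors the template
#' cohort's empirical (s, y) composition.
#'
#' @param object a [healthgen()] fit.
#' @param nsim number of cohorts to generate.
#' @param seed integer seed.
#' @param template a [cohort()] to mirror.
#' @param ... unused.
#' @return A cohort, or a list of cohorts when `nsim > 1`.
#' @export
simulate.healthgen <- function(object, nsim = 1, seed = 0L, template, ...) {
  spec <- composition_mirror(template, object$task_index)
  out <- lapply(seq_len(nsim), function(k) {
    generate_cohort(object, spec, template, seed = seed + k - 1L)
  })
  if (nsim == 1) out[[1]] else out
}

#' Augment a real cohort to balance a static variable
#'
#' For each category of the chosen static variable, synthesizes patients of
#' that category until every category count equals the majority category's
#' count. The within-category positive rate of the task label is copied from
#' the real data (rounded). Real records pass through bit-identical;
#' categories with zero real patients are skipped with a warning.
#'
#' @param real the real training [cohort()].
#' @param model a [healthgen()] fit.
#' @param static_var_index which static variable to balance.
#' @param task_index task label whose balance is preserved.
#' @param seed integer seed.
#' @return A [cohort()] with `provenance = "augmented"`.
#' @export
augment_cohort <- function(real, model, static_var_index = 1L,
                           task_index = 1L, seed = 0L) {
  vocab <- real$static_vocab[[static_var_index]]
  s <- cohort_statics(real)[, static_var_index]
  y <- cohort_labels(real, task_index)
  counts <- tabulate(s, nbins = length(vocab))
  target <- max(counts)
  spec_rows <- list()
  for (k in seq_along(vocab)) {
    need <- target - counts[k]
    if (counts[k] == 0) {
      if (need > 0) {
        warning("category '", vocab[k], "' has no real patients; skipped")
      }
      next
    }
    if (need == 0) next
    pos_rate <- mean(y[s == k])
    n_pos <- round(need * pos_rate)
    row_base <- stats::setNames(
      as.data.frame(matrix(NA_character_, 1, length(real$static_vocab))),
      names(real$static_vocab))
    row_base[[static_var_index]] <- vocab[k]
    if (n_pos > 0) {
      spec_rows[[length(spec_rows) + 1L]] <- cbind(row_base, y = 1L, n = n_pos)
    }
    if (need - n_pos > 0) {
      spec_rows[[length(spec_rows) + 1L]] <-
        cbind(row_base, y = 0L, n = need - n_pos)
    }
  }
  if (length(spec_rows) == 0) return(real)
  spec <- do.call(rbind, spec_rows)
  synth <- generate_cohort(model, spec, real, seed = seed)
  out <- real
  out$records <- c(real$records, synth$records)
  out$provenance <- "augmented"
  validate_cohort(out)
  out
}
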
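# Memorization audit: encode patients (real or synthetic) to a deterministic
# flattened latent vector — the posterior means of the static latent v and
# the sequential latents z_1:T — and look for suspiciously close training
# neighbours under cosine distance.

#' Deterministic flattened latent encoding of one patient
#'
#' Uses posterior means throughout (no sampling): the static latent mean from
#' the bidirectional summarizer, then the sequential posterior rolled forward
#' with each step conditioned on the previous step's mean. The record's own
#' (s, y) enter the conditioning. The result has length
#' `dim_v + T * dim_z` (832 at the default architecture and grid).
#'
#' @param record a [patient_record()].
#' @param model a [healthgen()] fit.
#' @return Numeric vector of length `dim_v + T * dim_z`.
#' @export
encode_flat <- function(record, model) {
  arch <- model$arch
  P <- model$params
  ops <- ops_plain
  konst <- identity
  Tn <- nrow(record$x); D <- ncol(record$x)
  xs <- lapply(seq_len(Tn), function(t) {
    matrix(record$x[t, ] * record$m[t, ], 1, D)
  })
  ms <- lapply(seq_len(Tn), function(t) matrix(record$m[t, ], 1, D))
  cond <- encode_conditioning(matrix(record$s, 1),
                              matrix(record$y[model$label_cols], 1),
                              model$vocab_sizes,
                              arch$condition_on_static,
                              arch$condition_on_label)
  vq <- hg_enc_v(ops, konst, P, arch, xs, ms, cond)
  v_mean <- vq$mean
  hs <- hg_h_chain(ops, konst, P, arch, xs, v_mean)
  gs <- hg_g_chain(ops, konst, P, arch, xs, hs, v_mean)
  z_prev <- matrix(0, 1, arch$dim_z)
  z_means <- matrix(0, Tn, arch$dim_z)
  for (t in seq_len(Tn)) {
    q_t <- gauss_head(ops, P$q_z, cbind(z_prev, gs[[t]]), arch$sd_floor)
    z_means[t, ] <- q_t$mean
    z_prev <- q_t$mean
  }
  c(as.numeric(v_mean), as.numeric(t(z_means)))
}

#' Cosine nearest neighbours
#'
#' Cosine distance `1 - a.b / (|a||b|)`, ascending; ties broken by pool
#' index (stable).
#'
#' @param query numeric vector.
#' @param pool numeric matrix, one candidate per row.
#' @param k number of neighbours (truncated to the pool size with a warning).
#' @return data.frame with `index` and `distance`, k rows.
#' @export
nearest_neighbours <- function(query, pool, k = 3L) {
  if (!is.matrix(pool)) pool <- matrix(pool, nrow = 1)
  if (nrow(pool) == 0) stop("empty pool")
  qn <- sqrt(sum(query^2))
  pn <- sqrt(rowSums(pool^2))
  if (qn == 0 || any(pn == 0)) stop("cosine distance undefined for zero-norm vectors")
  d <- 1 - as.numeric(pool %*% query) / (pn * qn)
  # identical vectors have cosine distance exactly 0; snap away the rounding
  d[abs(d) < 1e-12] <- 0
  d <- pmax(d, 0)
  if (k > nrow(pool)) {
    warning("k = ", k, " exceeds pool size ", nrow(pool), "; truncated")
    k <- nrow(pool)
  }
  ord <- order(d, seq_along(d))[seq_len(k)]
  data.frame(index = ord, distance = d[ord])
}

#' Latent nearest-neighbour memorization audit
#'
#' Encodes `n_queries` randomly chosen synthetic patients and all training
#' patients to flattened latents, finds each query's k cosine-nearest
#' training neighbours, and reports the distance table plus a memorization
#' flag (any query essentially at distance zero from a training record).
#' Optionally writes the table as CSV and side-by-side trajectory plots.
#'
#' @param synth synthetic [cohort()].
#' @param train training [cohort()].
#' @param model a [healthgen()] fit.
#' @param n_queries number of synthetic query patients.
#' @param k neighbours per query (default 3).
#' @param seed integer seed for the query draw.
#' @param out optional output directory for `distances.csv` and plots.
#' @param plot_features feature indices to draw (default up to 3).
#' @return List with `table` (query_id, rank, train_id, distance),
#'   `min_distance` and `possible_memorization`.
#' @export
audit_report <- function(synth, train, model, n_queries = 5L, k = 3L,
                         seed = 0L, out = NULL,
                         plot_features = seq_len(min(3L, model$D))) {
  stopifnot(length(train) > 0, length(synth) > 0)
  q_idx <- with_seed(seed, sample.int(length(synth), min(n_queries, length(synth))))
  pool <- t(vapply(train$records, encode_flat, model = model,
                   numeric(model$arch$dim_v + model$Tn * model$arch$dim_z)))
  train_ids <- cohort_ids(train)
  synth_ids <- cohort_ids(synth)
  rows <- list()
  for (qi in q_idx) {
    qv <- encode_flat(synth$records[[qi]], model)
    nn <- nearest_neighbours(qv, pool, k = k)
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = synth_ids[qi], rank = seq_len(nrow(nn)),
      train_id = train_ids[nn$index], train_index = nn$index,
      distance = nn$distance)
  }
  tab <- do.call(rbind, rows)
  min_d <- min(tab$distance)
  report <- list(table = tab, min_distance = min_d,
                 possible_memorization = min_d < 1e-8)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out, "distances.csv"), row.names = FALSE)
    for (qi in q_idx) {
      qid <- synth_ids[qi]
      nn1 <- tab[tab$query_id == qid, ]
      grDevices::png(file.path(out, paste0("audit_", qid, ".png")),
                     width = 900, height = 300 * length(plot_features))
      graphics::par(mfrow = c(length(plot_features), 1 + nrow(nn1)),
                    mar = c(2, 2, 2, 1))
      for (fd in plot_features) {
        plot_traj <- function(rec, title) {
          obs <- which(rec$m[, fd] == 1)
          graphics::plot(seq_len(nrow(rec$x)), rec$x[, fd], type = "l",
                         col = "grey70", main = title, xlab = "", ylab = "")
          graphics::points(obs, rec$x[obs, fd], pch = 16, cex = 0.7)
        }
        plot_traj(synth$records[[qi]],
                  sprintf("synthetic %s (f%d)", qid, fd))
        for (r in seq_len(nrow(nn1))) {
          plot_traj(train$records[[nn1$train_index[r]]],
                    sprintf("NN%d d=%.3f", r, nn1$distance[r]))
        }
      }
      grDevices::dev.off()
    }
  }
  report
}
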
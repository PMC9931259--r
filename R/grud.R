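# GRU-D time-series classifier: a gated recurrent cell with two trainable
# exponential-decay mechanisms for informative missingness. A missing input
# decays from its last observed value toward the feature's empirical training
# mean as the time since the last measurement grows; the hidden state decays
# toward zero for the same reason. Inputs are (x, m, delta) per time step.

#' GRU-D input decay
#'
#' `gamma = exp(-max(0, w * delta + b))` per feature; the imputed input is
#' `m * x + (1 - m) * (gamma * last_obs + (1 - gamma) * empirical_mean)`.
#' Observed cells pass through untouched.
#'
#' @param x,m,delta,last_obs numeric n x D matrices.
#' @param w,b numeric length-D decay parameters.
#' @param empirical_means numeric length-D decay targets.
#' @return Imputed n x D matrix.
#' @export
grud_input_decay <- function(x, m, delta, last_obs, w, b, empirical_means) {
  gamma <- exp(-pmax(sweep(delta, 2L, w, "*") + rep(b, each = nrow(delta)), 0))
  fallback <- gamma * last_obs +
    (1 - gamma) * matrix(empirical_means, nrow(x), ncol(x), byrow = TRUE)
  m * x + (1 - m) * fallback
}

#' GRU-D hidden-state decay
#'
#' `h <- exp(-max(0, delta %*% W + b)) * h_prev`, elementwise; the decay
#' factor always lies in (0, 1].
#'
#' @param h_prev n x H hidden state.
#' @param delta n x D time-since-observation matrix.
#' @param W D x H weight matrix, `b` length-H bias.
#' @export
grud_hidden_decay <- function(h_prev, delta, W, b) {
  h_prev * exp(-pmax(sweep(delta %*% W, 2L, b, "+"), 0))
}

init_grud_params <- function(D, H) {
  list(
    # small positive decay rates: starts off the ReLU kink so the decay
    # parameters receive gradient from step one
    w_in = matrix(stats::runif(D, 0.05, 0.15), 1L, D),
    b_in = matrix(stats::runif(D, 0.01, 0.05), 1L, D),
    W_hd = glorot(D, H), b_hd = zeros_row(H),
    cell = init_gru(2L * D, H),
    W_out = glorot(H, 1L), b_out = zeros_row(1L)
  )
}

# Forward pass shared by training (autodiff ops) and prediction (plain ops).
# batch must carry xs, ms (T-lists of n x D), deltas (T-list), last (T-list
# of last-observation matrices) and the empirical means row.
grud_logits <- function(ops, konst, P, batch, H) {
  n <- nrow(batch$xs[[1]])
  Tn <- length(batch$xs)
  h <- konst(matrix(0, n, H))
  mean_row <- batch$mean_mat                       # n x D constant
  for (t in seq_len(Tn)) {
    x_c <- konst(batch$xs[[t]]); m_c <- konst(batch$ms[[t]])
    d_c <- konst(batch$deltas[[t]]); l_c <- konst(batch$last[[t]])
    gamma <- ops$exp(ad_neg_or(ops, ops$relu(
      ops$add(ops$mulrow(d_c, P$w_in), P$b_in))))
    fallback <- ops$add(ops$mul(gamma, l_c),
                        ops$mul(ops$oneminus(gamma), konst(mean_row)))
    x_hat <- ops$add(ops$mul(m_c, x_c),
                     ops$mul(ops$oneminus(m_c), fallback))
    hdec <- ops$exp(ad_neg_or(ops, ops$relu(
      ops$add(ops$mm(d_c, P$W_hd), P$b_hd))))
    h <- ops$mul(h, hdec)
    h <- gru_step(ops, P$cell, ops$cbind(x_hat, m_c), h)
  }
  ops$add(ops$mm(h, P$W_out), P$b_out)
}

# negate a node or a plain matrix
ad_neg_or <- function(ops, a) if (is.environment(a)) ad_neg(a) else -a

grud_stack <- function(co, idx, task_index, empirical_means) {
  records <- co$records
  n <- length(idx)
  r1 <- records[[idx[1]]]
  Tn <- nrow(r1$x); D <- ncol(r1$x)
  arr_x <- array(0, c(n, Tn, D)); arr_m <- array(0, c(n, Tn, D))
  arr_d <- array(0, c(n, Tn, D)); arr_l <- array(0, c(n, Tn, D))
  y <- numeric(n)
  for (i in seq_len(n)) {
    r <- records[[idx[i]]]
    arr_x[i, , ] <- r$x * r$m
    arr_m[i, , ] <- r$m
    arr_d[i, , ] <- compute_deltas(r$m, co$grid)
    last <- empirical_means           # before any observation: the mean
    for (t in seq_len(Tn)) {
      arr_l[i, t, ] <- last
      last <- ifelse(r$m[t, ] == 1, r$x[t, ], last)
    }
    y[i] <- r$y[task_index]
  }
  list(
    xs = lapply(seq_len(Tn), function(t) matrix(arr_x[, t, ], n, D)),
    ms = lapply(seq_len(Tn), function(t) matrix(arr_m[, t, ], n, D)),
    deltas = lapply(seq_len(Tn), function(t) matrix(arr_d[, t, ], n, D)),
    last = lapply(seq_len(Tn), function(t) matrix(arr_l[, t, ], n, D)),
    mean_mat = matrix(empirical_means, n, D, byrow = TRUE),
    y = y
  )
}

#' Fit the GRU-D downstream classifier
#'
#' Trains the classifier on a cohort for one binary task with cross-entropy
#' loss (Adam). The empirical decay targets are the per-feature means of the
#' observed training cells (0 — the standardized prior mean — for features
#' never observed).
#'
#' @param train training [cohort()].
#' @param task_index which label to predict.
#' @param hidden_dim recurrent state size (default 32).
#' @param epochs,batch_size,learning_rate optimization settings.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @return Object of class `grud`.
#' @export
grud <- function(train, task_index = 1L, hidden_dim = 32L, epochs = 15L,
                 batch_size = 64L, learning_rate = 1e-2, seed = 0L) {
  y_all <- cohort_labels(train, task_index)
  if (length(unique(y_all)) < 2) {
    stop("training cohort has a single class for task ", task_index)
  }
  D <- length(train$feature_names)
  # empirical mean of observed cells per feature, on the training cohort
  sums <- numeric(D); cnts <- numeric(D)
  for (r in train$records) {
    sums <- sums + colSums(r$x * r$m)
    cnts <- cnts + colSums(r$m)
  }
  empirical_means <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)

  fit <- with_seed(seed, {
    params <- init_grud_params(D, hidden_dim)
    opt <- adam_init(params)
    N <- length(train$records)
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      tot <- 0; nb <- 0
      for (start in seq(1, N, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, N)]
        batch <- grud_stack(train, idx, task_index, empirical_means)
        ad_begin()
        P <- par_wrap(params)
        logits <- grud_logits(ops_ad, ad_const, P, batch, hidden_dim)
        # stable binary cross-entropy: softplus(l) - y * l, mean over batch
        yc <- ad_const(matrix(batch$y, ncol = 1))
        loss <- ad_scale(ad_sum(ad_sub(ad_softplus(logits),
                                       ad_mul(yc, logits))),
                         1 / length(idx))
        ad_backward(loss)
        upd <- adam_step(params, par_grads(P), opt, lr = learning_rate)
        params <- upd$params; opt <- upd$state
        tot <- tot + as.numeric(loss$value); nb <- nb + 1
      }
      losses[ep] <- tot / nb
    }
    list(params = params, losses = losses)
  })
  structure(list(params = fit$params, hidden_dim = as.integer(hidden_dim),
                 task_index = as.integer(task_index),
                 empirical_means = empirical_means,
                 loss_history = fit$losses, D = D, seed = as.integer(seed)),
            class = "grud")
}

#' @export
print.grud <- function(x, ...) {
  cat(sprintf("GRU-D classifier: task %d, hidden %d, %d features; final loss %.4f\n",
              x$task_index, x$hidden_dim, x$D,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Risk scores from a fitted GRU-D classifier
#'
#' @param object a [grud()] fit.
#' @param cohort_new a [cohort()] to score.
#' @param ... unused.
#' @return Numeric vector of sigmoid risk scores in (0, 1).
#' @export
predict.grud <- function(object, cohort_new, ...) {
  idx <- seq_along(cohort_new$records)
  batch <- grud_stack(cohort_new, idx, object$task_index,
                      object$empirical_means)
  logits <- grud_logits(ops_plain, identity, object$params, batch,
                        object$hidden_dim)
  as.numeric(1 / (1 + exp(-logits)))
}
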
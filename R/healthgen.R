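# The conditional dynamical VAE. A static latent v captures time-invariant
# patient state; a latent sequence z_1:T drives the feature dynamics through
# a deterministic forward recurrence h; the missingness masks are decoded
# from v (and the conditioning) in one shot as independent Bernoullis, so the
# mask channel and the feature channel are generated independently given v.
# Inference runs a bidirectional summarizer for v, the shared forward
# recurrence for h, an anti-causal recurrence g, and an autoregressive
# Gaussian posterior for z. Trained by maximizing the ELBO with the feature
# reconstruction term masked to observed cells only.

PROB_EPS <- 1e-6

#' Architecture configuration
#'
#' @param dim_v dimension of the static latent (default 32).
#' @param dim_z dimension of the per-step latent (default 32).
#' @param dim_h size of the forward deterministic recurrent state (default 64).
#' @param dim_g size of the backward recurrent state (default 64).
#' @param decoder_hidden hidden width of the feedforward heads (default 128).
#' @param condition_on_static if `FALSE` the static codes are omitted from
#'   every conditioning vector (unconditional-in-s generation).
#' @param condition_on_label if `FALSE` the labels are omitted.
#' @param sd_floor lower bound on every decoded/inferred standard deviation.
#' @return List of class `healthgen_arch`.
#' @export
healthgen_arch <- function(dim_v = 32, dim_z = 32, dim_h = 64, dim_g = 64,
                           decoder_hidden = 128, condition_on_static = TRUE,
                           condition_on_label = TRUE, sd_floor = 1e-3) {
  stopifnot(dim_v >= 1, dim_z >= 1, dim_h >= 1, dim_g >= 1,
            decoder_hidden >= 1, sd_floor > 0)
  structure(list(dim_v = as.integer(dim_v), dim_z = as.integer(dim_z),
                 dim_h = as.integer(dim_h), dim_g = as.integer(dim_g),
                 decoder_hidden = as.integer(decoder_hidden),
                 condition_on_static = condition_on_static,
                 condition_on_label = condition_on_label,
                 sd_floor = sd_floor),
            class = "healthgen_arch")
}

#' Build the conditioning vector
#'
#' One-hot encodes each static variable and concatenates the label bits;
#' blocks are dropped according to the architecture flags. This is the vector
#' appended to every conditioned network head.
#'
#' @param s integer matrix n x M of 1-based category codes (or a vector for a
#'   single patient).
#' @param y binary matrix n x L (or a vector).
#' @param vocab_sizes integer vector of per-variable vocabulary sizes.
#' @param condition_on_static,condition_on_label include the corresponding
#'   block?
#' @return Numeric n x C matrix (C may be zero).
#' @export
encode_conditioning <- function(s, y, vocab_sizes,
                                condition_on_static = TRUE,
                                condition_on_label = TRUE) {
  if (!is.matrix(s)) s <- matrix(s, nrow = 1)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  n <- nrow(y)
  blocks <- list()
  if (condition_on_static && length(vocab_sizes) > 0) {
    for (j in seq_along(vocab_sizes)) {
      K <- vocab_sizes[j]
      code <- s[, j]
      if (any(is.na(code)) || any(code < 1L) || any(code > K)) {
        stop("unknown category code for static variable ", j)
      }
      oh <- matrix(0, n, K)
      oh[cbind(seq_len(n), code)] <- 1
      blocks[[length(blocks) + 1L]] <- oh
    }
  }
  if (condition_on_label) blocks[[length(blocks) + 1L]] <- y
  if (length(blocks) == 0) return(matrix(0, n, 0))
  do.call(cbind, blocks)
}

cond_width <- function(arch, vocab_sizes, L) {
  (if (arch$condition_on_static) sum(vocab_sizes) else 0L) +
    (if (arch$condition_on_label) L else 0L)
}

## ---- parameters -----------------------------------------------------------

init_healthgen_params <- function(arch, D, Tn, C) {
  dh <- arch$decoder_hidden
  list(
    enc_f = init_gru(2L * D, arch$dim_h),
    enc_b = init_gru(2L * D, arch$dim_h),
    enc_v = init_gauss_head(2L * arch$dim_h + C, dh, arch$dim_v),
    h_rnn = init_gru(D + arch$dim_v, arch$dim_h),
    g_rnn = init_gru(D + arch$dim_h + arch$dim_v, arch$dim_g),
    q_z = init_gauss_head(arch$dim_z + arch$dim_g, dh, arch$dim_z),
    p_z = init_gauss_head(arch$dim_z + arch$dim_h, dh, arch$dim_z),
    dec_x = init_gauss_head(arch$dim_z + arch$dim_h + arch$dim_v + C, dh, D),
    dec_m = init_mlp(arch$dim_v + C, dh, Tn * D)
  )
}

## ---- shared forward chains (autodiff or plain, via ops + konst) -----------

# Bidirectional summarizer for the static-latent posterior. xs/ms are plain
# T-lists of n x D matrices; cond is a plain n x C matrix. Returns the
# Gaussian posterior parameters of v.
hg_enc_v <- function(ops, konst, P, arch, xs, ms, cond) {
  Tn <- length(xs)
  n <- nrow(xs[[1]])
  hf <- konst(matrix(0, n, arch$dim_h))
  for (t in seq_len(Tn)) {
    hf <- gru_step(ops, P$enc_f, konst(cbind(xs[[t]], ms[[t]])), hf)
  }
  hb <- konst(matrix(0, n, arch$dim_h))
  for (t in rev(seq_len(Tn))) {
    hb <- gru_step(ops, P$enc_b, konst(cbind(xs[[t]], ms[[t]])), hb)
  }
  gauss_head(ops, P$enc_v, ops$cbind(hf, hb, konst(cond)), arch$sd_floor)
}

# Forward deterministic recurrence: h_t depends on x_{1:t-1} and v only
# (h_1 is computed from the zero input). Returns a T-list.
hg_h_chain <- function(ops, konst, P, arch, xs, v) {
  Tn <- length(xs)
  n <- nrow(xs[[1]])
  D <- ncol(xs[[1]])
  h <- konst(matrix(0, n, arch$dim_h))
  hs <- vector("list", Tn)
  x_prev <- konst(matrix(0, n, D))
  for (t in seq_len(Tn)) {
    h <- gru_step(ops, P$h_rnn, ops$cbind(x_prev, v), h)
    hs[[t]] <- h
    x_prev <- konst(xs[[t]])
  }
  hs
}

# Anti-causal recurrence: g_t depends on x_{t:T}, h_{t:T} and v, with the
# terminal state g_{T+1} = 0. Returns a T-list.
hg_g_chain <- function(ops, konst, P, arch, xs, hs, v) {
  Tn <- length(xs)
  n <- nrow(xs[[1]])
  g <- konst(matrix(0, n, arch$dim_g))
  gs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    g <- gru_step(ops, P$g_rnn, ops$cbind(konst(xs[[t]]), hs[[t]], v), g)
    gs[[t]] <- g
  }
  gs
}

# Mask decoder: Bernoulli probabilities for the whole T x D sheet in one
# feedforward step from [v, cond]; probabilities clamped into
# [PROB_EPS, 1 - PROB_EPS] smoothly.
hg_mask_probs <- function(ops, konst, P, v, cond) {
  logits <- mlp2(ops, P$dec_m, ops$cbind(v, konst(cond)))
  ops$addc(ops$scale(ops$sigmoid(logits), 1 - 2 * PROB_EPS), PROB_EPS)
}

## ---- batch assembly -------------------------------------------------------

# Stacks records into per-timestep matrices. x is multiplied by m before any
# network consumes it, which makes the objective exactly independent of x at
# masked cells.
stack_batch <- function(records, idx, label_cols) {
  n <- length(idx)
  r1 <- records[[idx[1]]]
  Tn <- nrow(r1$x); D <- ncol(r1$x)
  arr_x <- array(0, c(n, Tn, D))
  arr_m <- array(0, c(n, Tn, D))
  s <- matrix(0L, n, length(r1$s))
  y <- matrix(0L, n, length(label_cols))
  for (i in seq_len(n)) {
    r <- records[[idx[i]]]
    arr_x[i, , ] <- r$x * r$m
    arr_m[i, , ] <- r$m
    if (length(r$s)) s[i, ] <- r$s
    y[i, ] <- r$y[label_cols]
  }
  xs <- lapply(seq_len(Tn), function(t) matrix(arr_x[, t, ], n, D))
  ms <- lapply(seq_len(Tn), function(t) matrix(arr_m[, t, ], n, D))
  # column j = (t-1) * D + d: feature index fastest
  m_flat <- matrix(aperm(arr_m, c(1, 3, 2)), n, Tn * D)
  list(n = n, Tn = Tn, D = D, xs = xs, ms = ms, m_flat = m_flat, s = s, y = y)
}

## ---- ELBO graph -----------------------------------------------------------

# Diagonal-Gaussian log-likelihood of x under (mu, sd), masked and summed.
ll_gauss_masked <- function(ops, x_const, m_const, mu, sd) {
  r <- ad_div(ops$sub(x_const, mu), sd)
  dens <- ops$addc(ad_neg(ops$add(ad_log(sd), ops$scale(ad_sq(r), 0.5))),
                   -0.5 * log(2 * pi))
  ad_sum(ops$mul(m_const, dens))
}

# KL( N(mu_q, sd_q) || N(mu_p, sd_p) ), summed over all entries.
kl_gauss <- function(ops, mu_q, sd_q, mu_p, sd_p) {
  t1 <- ops$sub(ad_log(sd_p), ad_log(sd_q))
  num <- ops$add(ad_sq(sd_q), ad_sq(ops$sub(mu_q, mu_p)))
  t2 <- ad_div(num, ops$scale(ad_sq(sd_p), 2))
  ad_sum(ops$addc(ops$add(t1, t2), -0.5))
}

# Builds the full ELBO graph for one batch on the active tape. `noise` holds
# the reparameterization draws (one set per Monte-Carlo sample). Returns the
# per-patient-mean term nodes.
elbo_graph <- function(P, arch, batch, cond, noise) {
  ops <- ops_ad
  konst <- ad_const
  n <- batch$n; Tn <- batch$Tn; D <- batch$D
  n_mc <- length(noise)

  vq <- hg_enc_v(ops, konst, P, arch, batch$xs, batch$ms, cond)
  kl_v <- kl_gauss(ops, vq$mean, vq$sd,
                   konst(matrix(0, n, arch$dim_v)),
                   konst(matrix(1, n, arch$dim_v)))
  m_flat_c <- konst(batch$m_flat)
  one_minus_m <- konst(1 - batch$m_flat)

  recon_x <- NULL; recon_m <- NULL; kl_z <- NULL
  for (s_mc in seq_len(n_mc)) {
    nz <- noise[[s_mc]]
    v <- ops$add(vq$mean, ops$mul(vq$sd, konst(nz$eps_v)))

    probs <- hg_mask_probs(ops, konst, P, v, cond)
    ll_m <- ad_sum(ops$add(ops$mul(m_flat_c, ad_log(probs)),
                           ops$mul(one_minus_m,
                                   ad_log(ops$oneminus(probs)))))

    hs <- hg_h_chain(ops, konst, P, arch, batch$xs, v)
    gs <- hg_g_chain(ops, konst, P, arch, batch$xs, hs, v)

    z_prev <- konst(matrix(0, n, arch$dim_z))
    ll_x <- NULL; kl_z_draw <- NULL
    for (t in seq_len(Tn)) {
      q_t <- gauss_head(ops, P$q_z, ops$cbind(z_prev, gs[[t]]), arch$sd_floor)
      p_t <- gauss_head(ops, P$p_z, ops$cbind(z_prev, hs[[t]]), arch$sd_floor)
      kl_t <- kl_gauss(ops, q_t$mean, q_t$sd, p_t$mean, p_t$sd)
      kl_z_draw <- if (is.null(kl_z_draw)) kl_t else ops$add(kl_z_draw, kl_t)
      z_t <- ops$add(q_t$mean, ops$mul(q_t$sd, konst(nz$eps_z[[t]])))
      dec <- gauss_head(ops, P$dec_x,
                        ops$cbind(z_t, hs[[t]], v, konst(cond)),
                        arch$sd_floor)
      ll_t <- ll_gauss_masked(ops, konst(batch$xs[[t]]), konst(batch$ms[[t]]),
                              dec$mean, dec$sd)
      ll_x <- if (is.null(ll_x)) ll_t else ops$add(ll_x, ll_t)
      z_prev <- z_t
    }
    recon_x <- if (is.null(recon_x)) ll_x else ops$add(recon_x, ll_x)
    recon_m <- if (is.null(recon_m)) ll_m else ops$add(recon_m, ll_m)
    kl_z <- if (is.null(kl_z)) kl_z_draw else ops$add(kl_z, kl_z_draw)
  }
  sc <- 1 / (n_mc * n)
  recon_x <- ops$scale(recon_x, sc)
  recon_m <- ops$scale(recon_m, sc)
  kl_z <- ops$scale(kl_z, sc)
  kl_v <- ops$scale(kl_v, 1 / n)
  total <- ops$sub(ops$add(recon_x, recon_m), ops$add(kl_v, kl_z))
  list(recon_x = recon_x, recon_m = recon_m, kl_v = kl_v, kl_z = kl_z,
       total = total)
}

draw_noise <- function(n, Tn, arch, n_mc) {
  lapply(seq_len(n_mc), function(s) {
    list(eps_v = matrix(stats::rnorm(n * arch$dim_v), n, arch$dim_v),
         eps_z = lapply(seq_len(Tn), function(t) {
           matrix(stats::rnorm(n * arch$dim_z), n, arch$dim_z)
         }))
  })
}

breakdown_from_nodes <- function(nodes) {
  b <- list(recon_x = as.numeric(nodes$recon_x$value),
            recon_m = as.numeric(nodes$recon_m$value),
            kl_v = as.numeric(nodes$kl_v$value),
            kl_z = as.numeric(nodes$kl_z$value))
  b$total <- b$recon_x + b$recon_m - b$kl_v - b$kl_z
  for (nm in names(b)) {
    if (!is.finite(b[[nm]])) {
      stop("non-finite ELBO term: ", nm)
    }
  }
  class(b) <- "elbo_breakdown"
  b
}

#' @export
print.elbo_breakdown <- function(x, ...) {
  cat(sprintf("ELBO %.4f  (recon_x %.4f, recon_m %.4f, kl_v %.4f, kl_z %.4f)\n",
              x$total, x$recon_x, x$recon_m, x$kl_v, x$kl_z))
  invisible(x)
}

#' Evidence lower bound of a fitted (or freshly initialized) model
#'
#' Computes the per-patient mean of the four objective terms on a cohort:
#' the mask reconstruction log-likelihood over the full mask sheet, the
#' feature reconstruction log-likelihood restricted to observed cells, and
#' the KL penalties for the static and sequential latents. Expectations are
#' estimated with `n_mc` reparameterized draws.
#'
#' @param model a [healthgen()] fit (or a list with `params`, `arch`,
#'   `label_cols`, `vocab_sizes`).
#' @param co a [cohort()].
#' @param n_mc number of Monte-Carlo draws (default 1).
#' @param seed seed for the draws.
#' @return List of class `elbo_breakdown` with `recon_x`, `recon_m`, `kl_v`,
#'   `kl_z`, `total`.
#' @export
elbo <- function(model, co, n_mc = 1L, seed = 0L) {
  records <- co$records
  batch <- stack_batch(records, seq_along(records), model$label_cols)
  cond <- encode_conditioning(batch$s, batch$y, model$vocab_sizes,
                              model$arch$condition_on_static,
                              model$arch$condition_on_label)
  noise <- with_seed(seed, draw_noise(batch$n, batch$Tn, model$arch, n_mc))
  ad_begin()
  P <- par_wrap(model$params)
  nodes <- elbo_graph(P, model$arch, batch, cond, noise)
  breakdown_from_nodes(nodes)
}

## ---- fitting --------------------------------------------------------------

#' Fit the conditional generative model
#'
#' Trains the dynamical VAE on a preprocessed cohort by stochastic gradient
#' ascent on the ELBO (Adam, global gradient-norm clipping). Conditioning is
#' on the task label by default (`condition_labels = "task"`); set
#' `condition_labels = "all"` to condition on the full label vector.
#'
#' @param train training [cohort()].
#' @param val optional validation cohort; its ELBO is tracked per epoch.
#' @param arch a [healthgen_arch()].
#' @param task_index label used for conditioning when
#'   `condition_labels = "task"`.
#' @param condition_labels `"task"` or `"all"`.
#' @param epochs,batch_size,learning_rate,n_mc,clip optimization settings.
#' @param seed integer seed controlling initialization, shuffling and the
#'   reparameterization draws; the fit is deterministic given the seed.
#' @param verbose print per-epoch progress?
#' @return An object of class `healthgen` with elements `params`, `arch`,
#'   `history` (per-epoch data.frame of objective terms), the cohort
#'   vocabularies/standardizer/grid, and the conditioning layout.
#' @export
healthgen <- function(train, val = NULL, arch = healthgen_arch(),
                      task_index = 1L, condition_labels = c("task", "all"),
                      epochs = 30L, batch_size = 64L, learning_rate = 1e-3,
                      n_mc = 1L, clip = 10, seed = 0L, verbose = FALSE) {
  condition_labels <- match.arg(condition_labels)
  stopifnot(length(train) >= 1, epochs >= 1, n_mc >= 1)
  label_cols <- if (condition_labels == "task") as.integer(task_index)
                else seq_along(train$label_names)
  vocab_sizes <- vapply(train$static_vocab, length, integer(1))
  D <- length(train$feature_names)
  Tn <- grid_obs_length(train$grid)
  C <- cond_width(arch, vocab_sizes, length(label_cols))

  history <- list()
  fit <- with_seed(seed, {
    params <- init_healthgen_params(arch, D, Tn, C)
    opt <- adam_init(params)
    N <- length(train$records)
    val_batch <- NULL
    if (!is.null(val) && length(val) > 0) {
      val_batch <- stack_batch(val$records, seq_along(val$records), label_cols)
      val_cond <- encode_conditioning(val_batch$s, val_batch$y, vocab_sizes,
                                      arch$condition_on_static,
                                      arch$condition_on_label)
    }
    diverged <- FALSE
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      nb <- 0; acc <- c(recon_x = 0, recon_m = 0, kl_v = 0, kl_z = 0, total = 0)
      for (start in seq(1, N, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, N)]
        batch <- stack_batch(train$records, idx, label_cols)
        cond <- encode_conditioning(batch$s, batch$y, vocab_sizes,
                                    arch$condition_on_static,
                                    arch$condition_on_label)
        noise <- draw_noise(batch$n, batch$Tn, arch, n_mc)
        ad_begin()
        P <- par_wrap(params)
        nodes <- elbo_graph(P, arch, batch, cond, noise)
        tot <- as.numeric(nodes$total$value)
        if (!is.finite(tot)) {
          warning("training diverged (non-finite ELBO); returning last finite state")
          diverged <- TRUE
          break
        }
        ad_backward(ad_neg(nodes$total))
        grads <- par_grads(P)
        upd <- adam_step(params, grads, opt, lr = learning_rate, clip = clip)
        params <- upd$params; opt <- upd$state
        nb <- nb + 1
        acc <- acc + c(as.numeric(nodes$recon_x$value),
                       as.numeric(nodes$recon_m$value),
                       as.numeric(nodes$kl_v$value),
                       as.numeric(nodes$kl_z$value), tot)
      }
      if (diverged) break
      acc <- acc / nb
      row <- data.frame(epoch = ep, split = "train", recon_x = acc[1],
                        recon_m = acc[2], kl_v = acc[3], kl_z = acc[4],
                        elbo = acc[5])
      if (!is.null(val_batch)) {
        vnoise <- draw_noise(val_batch$n, val_batch$Tn, arch, n_mc)
        ad_begin()
        vnodes <- elbo_graph(par_wrap(params), arch, val_batch, val_cond, vnoise)
        row <- rbind(row, data.frame(
          epoch = ep, split = "val",
          recon_x = as.numeric(vnodes$recon_x$value),
          recon_m = as.numeric(vnodes$recon_m$value),
          kl_v = as.numeric(vnodes$kl_v$value),
          kl_z = as.numeric(vnodes$kl_z$value),
          elbo = as.numeric(vnodes$total$value)))
      }
      history[[ep]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  elbo %.3f", ep, acc[5]))
      }
    }
    list(params = params, history = do.call(rbind, history))
  })

  obj <- structure(
    list(params = fit$params, arch = arch, history = fit$history,
         task_index = as.integer(task_index), label_cols = label_cols,
         vocab_sizes = vocab_sizes, D = D, Tn = Tn, C = C,
         feature_names = train$feature_names,
         static_vocab = train$static_vocab,
         label_names = train$label_names,
         standardizer = train$standardizer,
         grid = train$grid, seed = as.integer(seed),
         call = match.call()),
    class = "healthgen")
  obj
}

#' @export
print.healthgen <- function(x, ...) {
  cat("Conditional dynamical VAE for clinical time series\n")
  cat(sprintf("  features D = %d, sequence length T = %d\n", x$D, x$Tn))
  cat(sprintf("  latents: dim_v = %d, dim_z = %d (flattened %d)\n",
              x$arch$dim_v, x$arch$dim_z, x$arch$dim_v + x$Tn * x$arch$dim_z))
  cat(sprintf("  conditioning width C = %d (%s statics, %d label%s)\n",
              x$C, if (x$arch$condition_on_static) "with" else "without",
              length(x$label_cols), if (length(x$label_cols) > 1) "s" else ""))
  if (!is.null(x$history)) {
    tr <- x$history[x$history$split == "train", ]
    cat(sprintf("  trained %d epochs: ELBO %.3f -> %.3f\n",
                max(tr$epoch), tr$elbo[1], tr$elbo[nrow(tr)]))
  }
  invisible(x)
}

#' @export
summary.healthgen <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    tr <- object$history[object$history$split == "train", ]
    last <- tr[nrow(tr), ]
    cat(sprintf("  final terms: recon_x %.3f, recon_m %.3f, kl_v %.3f, kl_z %.3f\n",
                last$recon_x, last$recon_m, last$kl_v, last$kl_z))
  }
  cat(sprintf("  parameters: %d\n", par_count(object$params)))
  invisible(object)
}

#' @export
coef.healthgen <- function(object, ...) object$params

#' @export
plot.healthgen <- function(x, ...) {
  tr <- x$history[x$history$split == "train", ]
  graphics::plot(tr$epoch, tr$elbo, type = "l", xlab = "epoch",
                 ylab = "ELBO (per patient)", main = "Training objective", ...)
  va <- x$history[x$history$split == "val", ]
  if (nrow(va)) {
    graphics::lines(va$epoch, va$elbo, lty = 2)
    graphics::legend("bottomright", c("train", "val"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
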
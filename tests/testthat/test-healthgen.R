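# Structural and numerical checks of the generative model: conditioning
# layout, closed-form terms against independent oracles, the masked
# reconstruction contract, and the causality structure of the recurrences.

small_model <- function(co, arch = toy_arch(), seed = 0) {
  # an untrained model object (random initialization) around a cohort
  healthgen(co, arch = arch, epochs = 1, batch_size = length(co),
            learning_rate = 0, seed = seed)
}

test_that("conditioning vector one-hot layout matches the vocabulary", {
  # two static variables with vocab sizes (2, 3): second category of the
  # first, first of the second, label 1
  v <- encode_conditioning(s = c(2L, 1L), y = 1L, vocab_sizes = c(2L, 3L))
  expect_equal(as.numeric(v), c(0, 1, 1, 0, 0, 1))
  v2 <- encode_conditioning(c(1L, 1L), 0L, c(2L, 3L))
  expect_equal(as.numeric(v2), c(1, 0, 1, 0, 0, 0))
  # dropping the static block leaves only the label bits
  v3 <- encode_conditioning(c(2L, 1L), 1L, c(2L, 3L),
                            condition_on_static = FALSE)
  expect_equal(as.numeric(v3), 1)
  expect_error(encode_conditioning(c(3L, 1L), 1L, c(2L, 3L)), "category")
})

test_that("closed-form Gaussian KL identities hold", {
  ops <- healthgen:::ops_plain
  kl_plain <- function(mq, sq, mp, sp) {
    sum(log(sp / sq) + (sq^2 + (mq - mp)^2) / (2 * sp^2) - 0.5)
  }
  # KL(N(1,1) || N(0,1)) = 0.5 per dimension
  expect_equal(kl_plain(rep(1, 4), rep(1, 4), rep(0, 4), rep(1, 4)), 2)
  # KL is zero iff the distributions coincide
  expect_equal(kl_plain(0.3, 0.7, 0.3, 0.7), 0)
  # the autodiff node computes the same value
  healthgen:::ad_begin()
  k <- healthgen:::kl_gauss(healthgen:::ops_ad,
                            healthgen:::ad_const(matrix(1, 1, 4)),
                            healthgen:::ad_const(matrix(1, 1, 4)),
                            healthgen:::ad_const(matrix(0, 1, 4)),
                            healthgen:::ad_const(matrix(1, 1, 4)))
  expect_equal(as.numeric(k$value), 2)
})

test_that("closed-form KL matches a Monte-Carlo estimate within 3 SE", {
  # independent oracle: estimate E_q[log q - log p] by direct sampling
  healthgen:::with_seed(17, {
    for (rep in 1:6) {
      d <- 4
      mq <- rnorm(d); sq <- runif(d, 0.5, 2)
      mp <- rnorm(d); sp <- runif(d, 0.5, 2)
      closed <- sum(log(sp / sq) + (sq^2 + (mq - mp)^2) / (2 * sp^2) - 0.5)
      n_mc <- 256
      z <- matrix(rnorm(n_mc * d), n_mc, d)
      zq <- sweep(sweep(z, 2, sq, "*"), 2, mq, "+")
      lq <- rowSums(sapply(seq_len(d), function(j) {
        stats::dnorm(zq[, j], mq[j], sq[j], log = TRUE)
      }))
      lp <- rowSums(sapply(seq_len(d), function(j) {
        stats::dnorm(zq[, j], mp[j], sp[j], log = TRUE)
      }))
      mc <- mean(lq - lp)
      se <- stats::sd(lq - lp) / sqrt(n_mc)
      expect_lt(abs(mc - closed), 3 * se + 1e-9)
    }
  })
})

test_that("Bernoulli mask likelihood matches the closed form", {
  healthgen:::ad_begin()
  m <- matrix(c(1, 0, 0, 1), 1, 4)
  probs <- healthgen:::ad_const(matrix(0.5, 1, 4))
  ll <- healthgen:::ad_sum(healthgen:::ad_add(
    healthgen:::ad_mul(healthgen:::ad_const(m), healthgen:::ad_log(probs)),
    healthgen:::ad_mul(healthgen:::ad_const(1 - m),
                       healthgen:::ad_log(healthgen:::ad_oneminus(probs)))))
  expect_equal(as.numeric(ll$value), 4 * log(0.5))
})

test_that("Gaussian log-density at the mode matches the closed form", {
  healthgen:::ad_begin()
  sd_v <- 0.7
  D <- 3
  x <- matrix(rnorm(D), 1, D)
  node <- healthgen:::ll_gauss_masked(
    healthgen:::ops_ad,
    healthgen:::ad_const(x), healthgen:::ad_const(matrix(1, 1, D)),
    healthgen:::ad_const(x), healthgen:::ad_const(matrix(sd_v, 1, D)))
  expect_equal(as.numeric(node$value), -0.5 * D * log(2 * pi * sd_v^2))
})

test_that("the ELBO is exactly invariant to x at masked cells", {
  co <- toy_cohort(n = 6, D = 3)
  m <- small_model(co)
  b1 <- elbo(m, co, n_mc = 1, seed = 4)
  # poison every masked cell with large garbage, bypassing validation
  co2 <- co
  for (i in seq_along(co2$records)) {
    r <- co2$records[[i]]
    r$x[r$m == 0] <- 1e6 * i
    co2$records[[i]] <- structure(r, class = "patient_record")
  }
  b2 <- elbo(m, co2, n_mc = 1, seed = 4)
  expect_identical(b1$recon_x, b2$recon_x)
  expect_identical(b1$recon_m, b2$recon_m)
  expect_identical(b1$kl_v, b2$kl_v)
  expect_identical(b1$kl_z, b2$kl_z)
  expect_identical(b1$total, b2$total)
})

test_that("an all-missing cohort contributes zero feature reconstruction", {
  co <- toy_cohort(n = 4, D = 2)
  for (i in seq_along(co$records)) {
    co$records[[i]]$m[] <- 0L
    co$records[[i]]$x[] <- 0
  }
  m <- small_model(co)
  b <- elbo(m, co, n_mc = 1, seed = 0)
  expect_identical(b$recon_x, 0)
  expect_equal(b$total, b$recon_m - b$kl_v - b$kl_z)
})

test_that("ELBO terms satisfy the total identity and determinism", {
  co <- toy_cohort(n = 5, D = 2)
  m <- small_model(co)
  b <- elbo(m, co, n_mc = 2, seed = 9)
  expect_identical(b$total, b$recon_x + b$recon_m - b$kl_v - b$kl_z)
  expect_gte(b$kl_v, 0)
  expect_gte(b$kl_z, 0)
  b2 <- elbo(m, co, n_mc = 2, seed = 9)
  expect_identical(b$total, b2$total)
  b3 <- elbo(m, co, n_mc = 2, seed = 10)
  expect_false(identical(b$total, b3$total))
})

test_that("gradient of the mask reconstruction w.r.t. the feature decoder is zero", {
  co <- toy_cohort(n = 4, D = 2)
  mod <- small_model(co)
  batch <- healthgen:::stack_batch(co$records, 1:4, mod$label_cols)
  cond <- encode_conditioning(batch$s, batch$y, mod$vocab_sizes)
  noise <- healthgen:::with_seed(1, healthgen:::draw_noise(4, batch$Tn, mod$arch, 1))
  healthgen:::ad_begin()
  P <- healthgen:::par_wrap(mod$params)
  nodes <- healthgen:::elbo_graph(P, mod$arch, batch, cond, noise)
  healthgen:::ad_backward(nodes$recon_m)
  gx <- healthgen:::par_grads(P$dec_x)
  expect_true(all(vapply(gx, function(g) all(g == 0), logical(1))))
  # while the mask decoder itself does receive gradient
  gm <- healthgen:::par_grads(P$dec_m)
  expect_gt(max(abs(unlist(gm))), 0)
})

test_that("the forward recurrence is causal and the backward one anti-causal", {
  co <- toy_cohort(n = 2, D = 3)
  mod <- small_model(co)
  ops <- healthgen:::ops_plain
  Tn <- mod$Tn
  xs <- lapply(seq_len(Tn), function(t) matrix(rnorm(2 * 3), 2, 3))
  v <- matrix(rnorm(2 * mod$arch$dim_v), 2)
  hs <- healthgen:::hg_h_chain(ops, identity, mod$params, mod$arch, xs, v)
  # zero out the future: h_1..h_k must not move (h_t sees x_{1:t-1} only)
  k <- 10
  xs2 <- xs
  for (t in k:Tn) xs2[[t]] <- matrix(0, 2, 3)
  hs2 <- healthgen:::hg_h_chain(ops, identity, mod$params, mod$arch, xs2, v)
  for (t in 1:k) expect_identical(hs[[t]], hs2[[t]])
  expect_false(identical(hs[[k + 1]], hs2[[k + 1]]))
  expect_true(all(healthgen:::hg_h_chain(ops, identity, mod$params, mod$arch,
                                         xs, v)[[1]] == hs[[1]]))

  gs <- healthgen:::hg_g_chain(ops, identity, mod$params, mod$arch, xs, hs, v)
  # perturbing x_1 must leave g_2..g_T unchanged (given the same h)
  xs3 <- xs
  xs3[[1]] <- xs[[1]] + 5
  gs3 <- healthgen:::hg_g_chain(ops, identity, mod$params, mod$arch, xs3, hs, v)
  for (t in 2:Tn) expect_identical(gs[[t]], gs3[[t]])
  expect_false(identical(gs[[1]], gs3[[1]]))
})

test_that("encoder outputs are batch-equivariant and AD/plain paths agree", {
  co <- toy_cohort(n = 3, D = 2)
  mod <- small_model(co)
  batch <- healthgen:::stack_batch(co$records, 1:3, mod$label_cols)
  cond <- encode_conditioning(batch$s, batch$y, mod$vocab_sizes)
  vq <- healthgen:::hg_enc_v(healthgen:::ops_plain, identity, mod$params,
                             mod$arch, batch$xs, batch$ms, cond)
  perm <- c(3, 1, 2)
  batch_p <- healthgen:::stack_batch(co$records, perm, mod$label_cols)
  cond_p <- encode_conditioning(batch_p$s, batch_p$y, mod$vocab_sizes)
  vq_p <- healthgen:::hg_enc_v(healthgen:::ops_plain, identity, mod$params,
                               mod$arch, batch_p$xs, batch_p$ms, cond_p)
  expect_equal(vq_p$mean, vq$mean[perm, ], ignore_attr = TRUE)
  expect_equal(vq_p$sd, vq$sd[perm, ], ignore_attr = TRUE)

  # the autodiff graph computes the same encoder function
  healthgen:::ad_begin()
  vq_ad <- healthgen:::hg_enc_v(healthgen:::ops_ad, healthgen:::ad_const,
                                healthgen:::par_wrap(mod$params), mod$arch,
                                batch$xs, batch$ms, cond)
  expect_equal(vq_ad$mean$value, vq$mean, tolerance = 1e-12)
  expect_equal(vq_ad$sd$value, vq$sd, tolerance = 1e-12)
})

test_that("with condition_on_static = FALSE the objective ignores s", {
  co <- toy_cohort(n = 5, D = 2)
  arch <- healthgen_arch(dim_v = 4, dim_z = 4, dim_h = 8, dim_g = 8,
                         decoder_hidden = 16, condition_on_static = FALSE)
  mod <- small_model(co, arch = arch)
  b1 <- elbo(mod, co, n_mc = 1, seed = 2)
  co2 <- co
  for (i in seq_along(co2$records)) co2$records[[i]]$s <- c(1L, 1L)
  b2 <- elbo(mod, co2, n_mc = 1, seed = 2)
  expect_identical(b1$total, b2$total)
})

test_that("decoded standard deviations respect the floor under extreme inputs", {
  co <- toy_cohort(n = 2, D = 2)
  mod <- small_model(co)
  p <- healthgen:::gauss_head(
    healthgen:::ops_plain, mod$params$p_z,
    matrix(c(1e3, -1e3), 2, mod$arch$dim_z + mod$arch$dim_h), mod$arch$sd_floor)
  expect_true(all(is.finite(p$mean)))
  expect_true(all(p$sd >= mod$arch$sd_floor))
})

test_that("training is deterministic, frozen at lr 0, and reports history", {
  co <- toy_cohort(n = 24, D = 2)
  arch <- healthgen_arch(dim_v = 3, dim_z = 3, dim_h = 6, dim_g = 6,
                         decoder_hidden = 8)
  m1 <- healthgen(co, arch = arch, epochs = 2, batch_size = 12,
                  learning_rate = 1e-3, seed = 5)
  m2 <- healthgen(co, arch = arch, epochs = 2, batch_size = 12,
                  learning_rate = 1e-3, seed = 5)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  m0 <- healthgen(co, arch = arch, epochs = 3, batch_size = 24,
                  learning_rate = 0, seed = 5)
  tr <- m0$history[m0$history$split == "train", ]
  # full-batch training at lr 0: parameters never move, but the Monte-Carlo
  # draws differ per epoch, so compare under the frozen parameters directly
  expect_identical(m0$params, healthgen:::with_seed(5, {
    healthgen:::init_healthgen_params(arch, 2L, 25L, m0$C)
  }))
  expect_equal(nrow(tr), 3)
})

test_that("non-finite parameters surface as a named numeric error", {
  co <- toy_cohort(n = 2, D = 2)
  mod <- small_model(co)
  mod$params$enc_v$Wmu[1, 1] <- Inf
  expect_error(elbo(mod, co, n_mc = 1, seed = 0), "non-finite ELBO term")
})
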
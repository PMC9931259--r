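# Neural building blocks shared by the generative model and the downstream
# classifier. Each block is written once against a small "ops" interface and
# evaluated either on autodiff nodes (training) or on plain matrices
# (generation, encoding, prediction), which guarantees the two paths compute
# the same function.

ops_ad <- list(
  mm = ad_mm, add = ad_add, sub = ad_sub, mul = ad_mul, mulrow = ad_mulrow,
  sigmoid = ad_sigmoid, tanh = ad_tanh, softplus = ad_softplus,
  relu = ad_relu, exp = ad_exp, oneminus = ad_oneminus,
  cbind = ad_cbind, addc = ad_addc, scale = ad_scale
)

ops_plain <- list(
  mm = function(a, b) a %*% b,
  add = function(a, b) {
    if (nrow(b) == 1L && nrow(a) > 1L) sweep(a, 2L, as.numeric(b), "+") else a + b
  },
  sub = function(a, b) a - b,
  mul = function(a, b) a * b,
  mulrow = function(a, r) sweep(a, 2L, as.numeric(r), "*"),
  sigmoid = function(a) 1 / (1 + exp(-a)),
  tanh = tanh,
  softplus = softplus_mat,
  relu = function(a) pmax(a, 0),
  exp = exp,
  oneminus = function(a) 1 - a,
  cbind = cbind,
  addc = function(a, k) a + k,
  scale = function(a, k) a * k
)

## ---- initializers ---------------------------------------------------------

glorot <- function(din, dout) {
  s <- sqrt(6 / (din + dout))
  matrix(stats::runif(din * dout, -s, s), din, dout)
}

zeros_row <- function(k) matrix(0, 1L, k)

# Gated recurrent cell parameters: reset/update gates and candidate state.
init_gru <- function(din, dh) {
  list(
    Wr = glorot(din, dh), Ur = glorot(dh, dh), br = zeros_row(dh),
    Wu = glorot(din, dh), Uu = glorot(dh, dh), bu = zeros_row(dh),
    Wc = glorot(din, dh), Uc = glorot(dh, dh), bc = zeros_row(dh)
  )
}

# Two-layer feedforward map (tanh hidden layer, linear output).
init_mlp <- function(din, dhid, dout) {
  list(W1 = glorot(din, dhid), b1 = zeros_row(dhid),
       W2 = glorot(dhid, dout), b2 = zeros_row(dout))
}

# Gaussian head: shared tanh hidden layer, linear mean head and a softplus
# standard-deviation head. The sd bias starts at 0.5 so initial sds are near 1.
init_gauss_head <- function(din, dhid, dout) {
  list(W1 = glorot(din, dhid), b1 = zeros_row(dhid),
       Wmu = glorot(dhid, dout), bmu = zeros_row(dout),
       Wsd = glorot(dhid, dout), bsd = matrix(0.5, 1L, dout))
}

## ---- forward blocks -------------------------------------------------------

gru_step <- function(ops, p, x, h) {
  r <- ops$sigmoid(ops$add(ops$add(ops$mm(x, p$Wr), ops$mm(h, p$Ur)), p$br))
  u <- ops$sigmoid(ops$add(ops$add(ops$mm(x, p$Wu), ops$mm(h, p$Uu)), p$bu))
  cand <- ops$tanh(ops$add(ops$add(ops$mm(x, p$Wc),
                                   ops$mm(ops$mul(r, h), p$Uc)), p$bc))
  ops$add(ops$mul(u, h), ops$mul(ops$oneminus(u), cand))
}

mlp2 <- function(ops, p, x) {
  hid <- ops$tanh(ops$add(ops$mm(x, p$W1), p$b1))
  ops$add(ops$mm(hid, p$W2), p$b2)
}

# Returns list(mean, sd); sd = softplus(linear) + sd_floor (elementwise).
gauss_head <- function(ops, p, x, sd_floor) {
  hid <- ops$tanh(ops$add(ops$mm(x, p$W1), p$b1))
  mu <- ops$add(ops$mm(hid, p$Wmu), p$bmu)
  sd <- ops$addc(ops$softplus(ops$add(ops$mm(hid, p$Wsd), p$bsd)), sd_floor)
  list(mean = mu, sd = sd)
}

## ---- seed hygiene ---------------------------------------------------------

# Run `expr` under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
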
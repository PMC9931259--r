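# Minimal tape-based reverse-mode automatic differentiation on matrix-valued
# nodes. All values are numeric matrices; the batch dimension is rows.
# A node is an environment holding $value, $grad and a $backfn closure that
# pushes the incoming gradient to its parents. Nodes with a backfn are
# registered on the active tape in creation order, so a single reverse sweep
# over the tape is a valid topological backward pass.
#
# This engine is deliberately small: only the operations the models in this
# package need are implemented, and every operation's gradient is checked
# against central finite differences in the test suite.

.ad <- new.env(parent = emptyenv())

# The tape is a cons-cell linked list with the newest node at the head, so
# prepending is O(1) and walking from the head visits nodes in reverse
# creation order — exactly the order the backward sweep needs.
ad_begin <- function() {
  .ad$head <- NULL
  invisible(NULL)
}

ad_register <- function(nd) {
  .ad$head <- list(nd, .ad$head)
  nd
}

ad_new <- function(value, backfn = NULL, track = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  nd$track <- track
  if (!is.null(backfn)) ad_register(nd)
  nd
}

# Data enters the graph as constants: no gradient is ever accumulated.
ad_const <- function(value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ad_new(value, track = FALSE)
}

# Trainable leaves: gradients accumulate in $grad during the backward sweep.
ad_leaf <- function(value) ad_new(value)

ad_accum <- function(nd, g) {
  if (!nd$track) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Backward sweep from a scalar (1x1) root node.
ad_backward <- function(root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- matrix(1, 1L, 1L)
  h <- .ad$head
  while (!is.null(h)) {
    nd <- h[[1L]]
    if (!is.null(nd$grad)) nd$backfn(nd$grad)
    h <- h[[2L]]
  }
  invisible(NULL)
}

ad_grad <- function(nd) {
  if (is.null(nd$grad)) array(0, dim(nd$value)) else nd$grad
}

## ---- operations -----------------------------------------------------------

ad_mm <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_new(av %*% bv, function(g) {
    ad_accum(a, g %*% t(bv))
    ad_accum(b, crossprod(av, g))
  })
}

# a + b; b may be a 1 x k row (bias) broadcast over the rows of a.
ad_add <- function(a, b) {
  av <- a$value; bv <- b$value
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    ad_new(sweep(av, 2L, as.numeric(bv), "+"), function(g) {
      ad_accum(a, g)
      ad_accum(b, matrix(colSums(g), 1L))
    })
  } else {
    ad_new(av + bv, function(g) {
      ad_accum(a, g)
      ad_accum(b, g)
    })
  }
}

ad_sub <- function(a, b) {
  ad_new(a$value - b$value, function(g) {
    ad_accum(a, g)
    ad_accum(b, -g)
  })
}

# Elementwise product, equal shapes.
ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_new(av * bv, function(g) {
    ad_accum(a, g * bv)
    ad_accum(b, g * av)
  })
}

# a * r where r is a 1 x k row broadcast over rows of a.
ad_mulrow <- function(a, r) {
  av <- a$value; rv <- as.numeric(r$value)
  ad_new(sweep(av, 2L, rv, "*"), function(g) {
    ad_accum(a, sweep(g, 2L, rv, "*"))
    ad_accum(r, matrix(colSums(g * av), 1L))
  })
}

ad_div <- function(a, b) {
  av <- a$value; bv <- b$value
  v <- av / bv
  ad_new(v, function(g) {
    ad_accum(a, g / bv)
    ad_accum(b, -g * v / bv)
  })
}

ad_neg <- function(a) ad_new(-a$value, function(g) ad_accum(a, -g))

ad_scale <- function(a, k) ad_new(a$value * k, function(g) ad_accum(a, g * k))

ad_addc <- function(a, k) ad_new(a$value + k, function(g) ad_accum(a, g))

ad_oneminus <- function(a) ad_new(1 - a$value, function(g) ad_accum(a, -g))

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  ad_new(v, function(g) ad_accum(a, g * v * (1 - v)))
}

ad_tanh <- function(a) {
  v <- tanh(a$value)
  ad_new(v, function(g) ad_accum(a, g * (1 - v * v)))
}

# Numerically stable log(1 + exp(x)).
softplus_mat <- function(x) {
  out <- x
  low <- x <= 30
  out[low] <- log1p(exp(x[low]))
  out
}

ad_softplus <- function(a) {
  av <- a$value
  ad_new(softplus_mat(av), function(g) ad_accum(a, g / (1 + exp(-av))))
}

ad_relu <- function(a) {
  av <- a$value
  ad_new(pmax(av, 0), function(g) ad_accum(a, g * (av > 0)))
}

ad_exp <- function(a) {
  v <- exp(a$value)
  ad_new(v, function(g) ad_accum(a, g * v))
}

ad_log <- function(a) {
  av <- a$value
  ad_new(log(av), function(g) ad_accum(a, g / av))
}

ad_sq <- function(a) {
  av <- a$value
  ad_new(av * av, function(g) ad_accum(a, 2 * g * av))
}

ad_sum <- function(a) {
  av <- a$value
  ad_new(matrix(sum(av), 1L, 1L), function(g) {
    ad_accum(a, array(as.numeric(g), dim(av)))
  })
}

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, function(a) a$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_new(do.call(cbind, vals), function(g) {
    for (i in seq_along(args)) {
      ad_accum(args[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

## ---- parameter containers -------------------------------------------------

# Parameters live in nested named lists of matrices. These helpers apply a
# function over every matrix while preserving the nesting.

par_map <- function(p, f) {
  if (is.matrix(p)) return(f(p))
  lapply(p, par_map, f = f)
}

par_map2 <- function(p, q, f) {
  if (is.matrix(p)) return(f(p, q))
  mapply(par_map2, p, q, MoreArgs = list(f = f), SIMPLIFY = FALSE)
}

# Wrap each matrix as a trainable leaf node.
par_wrap <- function(p) par_map(p, ad_leaf)

# Collect gradients from wrapped leaves back into plain matrices.
par_grads <- function(wrapped) {
  if (is.environment(wrapped)) return(ad_grad(wrapped))
  lapply(wrapped, par_grads)
}

par_values <- function(wrapped) {
  if (is.environment(wrapped)) return(wrapped$value)
  lapply(wrapped, par_values)
}

par_sumsq <- function(p) {
  if (is.matrix(p)) return(sum(p * p))
  sum(vapply(p, par_sumsq, numeric(1)))
}

par_count <- function(p) {
  if (is.matrix(p)) return(length(p))
  sum(vapply(p, par_count, numeric(1)))
}

## ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  list(
    m = par_map(params, function(x) array(0, dim(x))),
    v = par_map(params, function(x) array(0, dim(x))),
    t = 0L
  )
}

# One Adam update with global gradient-norm clipping. Returns list(params,
# state). `clip` is the maximum allowed L2 norm of the full gradient.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 10) {
  gnorm <- sqrt(par_sumsq(grads))
  if (is.finite(gnorm) && gnorm > clip) {
    grads <- par_map(grads, function(g) g * (clip / gnorm))
  }
  state$t <- state$t + 1L
  state$m <- par_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- par_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- par_map2(state$m, state$v, function(m, v) {
    (m / corr1) / (sqrt(v / corr2) + eps)
  })
  params <- par_map2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}
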
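# Neural-network primitives on (C, T, N) tensors (channels x time x batch)
# and (N, F) feature matrices. Each forward returns list(out, cache); each
# backward takes (dout, cache) and returns list(dx, grads). Convolution is
# realized as k shifted BLAS matrix products, which is how a 1D convolution
# with stride 1 and 'same' zero padding decomposes.

conv1d_fwd <- function(x, W, b) {
  list(out = conv1d_forward(x, W, b), cache = list(x = x))
}

conv1d_bwd <- function(dy, cache, W) {
  res <- conv1d_backward(dy, cache$x, W)
  list(dx = res$dx, grads = list(W = res$dW, b = drop(res$db)))
}

# Batch norm over channels: statistics across (time, batch).
bn1d_fwd <- function(x, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  res <- bn1d_forward_cpp(x, gamma, beta, run$mean, run$var, training,
                          momentum, eps)
  list(out = res$out, run = list(mean = drop(res$mean), var = drop(res$var)),
       cache = list(xhat = res$xhat, inv_std = drop(res$inv_std),
                    gamma = gamma, training = training))
}

bn1d_bwd <- function(dy, cache) {
  res <- bn1d_backward_cpp(dy, cache$xhat, cache$inv_std, cache$gamma,
                           cache$training)
  list(dx = res$dx,
       grads = list(gamma = drop(res$dgamma), beta = drop(res$dbeta)))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_bwd <- function(dy, mask) dy * mask

# Dense layer on (N x F) matrices; W is F x G.
linear_fwd <- function(x, W, b) {
  list(out = x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE),
       cache = x)
}

linear_bwd <- function(dy, x, W) {
  list(dx = dy %*% t(W),
       grads = list(W = t(x) %*% dy, b = colSums(dy)))
}

# Feature-wise batch norm on (N x F) matrices (statistics over the batch).
bnvec_fwd <- function(x, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  N <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v * N / max(1, N - 1)
  } else {
    mu <- run$mean
    v <- run$var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2L, mu), 2L, inv_std, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = y, run = run,
       cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma,
                    training = training))
}

bnvec_bwd <- function(dy, cache) {
  N <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$gamma, `*`)
  if (cache$training) {
    dx <- sweep(
      N * dxhat - matrix(colSums(dxhat), N, ncol(dy), byrow = TRUE) -
        xhat * matrix(colSums(dxhat * xhat), N, ncol(dy), byrow = TRUE),
      2L, cache$inv_std / N, `*`)
  } else {
    dx <- sweep(dxhat, 2L, cache$inv_std, `*`)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- matrix(stats::rbinom(length(x), 1L, 1 - p), nrow(x)) / (1 - p)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- parameter-tree utilities (nested lists with numeric leaves) ----

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    out
  } else {
    f(a, b)
  }
}

tree_sumsq <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_sumsq, numeric(1L))) else sum(tree^2)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

# One Adam step with L2 regularization folded into the gradient
# (d/dw of l2 * ||w||^2 = 2 * l2 * w).
adam_step <- function(params, grads, opt, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.99, eps = 1e-8, l2 = 0) {
  opt$t <- opt$t + 1L
  t <- opt$t
  step_leaf <- function(p, g, m, v) {
    if (l2 > 0) g <- g + 2 * l2 * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(walk, p, g, m, v)
      list(p = lapply(res, `[[`, "p"),
           m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      step_leaf(p, g, m, v)
    }
  }
  res <- walk(params, grads, opt$m, opt$v)
  opt$m <- res$m
  opt$v <- res$v
  list(params = res$p, opt = opt)
}
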
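#' Encoder architecture configuration
#'
#' A 3-block 1D residual encoder: each block is conv -> batch norm -> ReLU
#' -> conv -> batch norm plus an identity (or 1x1-conv projection) shortcut,
#' followed by a ReLU. Global adaptive average pooling collapses the time
#' axis so windows of any length map to a fixed-size embedding, and a final
#' linear layer produces the `embed_dim`-dimensional embedding.
#'
#' @param channels integer vector of per-block channel widths
#'   (default `c(32, 64, 128)`; length fixes the block count at 3).
#' @param kernel convolution kernel width (odd, default 7).
#' @param embed_dim embedding size `D` (default 128).
#' @param proj_dim projection-head output size (default 64).
#' @param residual use residual shortcuts (default `TRUE`); `FALSE` gives
#'   three plain conv-BN-ReLU layers.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(channels = c(32L, 64L, 128L), kernel = 7L,
                           embed_dim = 128L, proj_dim = 64L, residual = TRUE) {
  if (length(channels) != 3L) stop_invalid("the encoder uses exactly 3 blocks")
  if (kernel %% 2L != 1L) stop_invalid("kernel width must be odd")
  if (embed_dim < proj_dim || proj_dim < 2L) {
    stop_invalid("need embed_dim >= proj_dim >= 2")
  }
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 embed_dim = as.integer(embed_dim),
                 proj_dim = as.integer(proj_dim), residual = residual),
            class = "encoder_config")
}

#' Classification-head configuration
#'
#' Two hidden layers of 256 and 128 units with ReLU activations, dropout
#' 0.2 after each, and a softmax output layer.
#'
#' @param n_classes number of classes (>= 2).
#' @param hidden hidden layer sizes (default `c(256, 128)`).
#' @param dropout dropout probability in `[0, 1)` (default 0.2).
#' @return A list of class `head_config`.
#' @export
head_config <- function(n_classes, hidden = c(256L, 128L), dropout = 0.2) {
  if (n_classes < 2L) stop_invalid("n_classes must be >= 2")
  if (dropout < 0 || dropout >= 1) stop_invalid("dropout must be in [0, 1)")
  structure(list(n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden), dropout = dropout),
            class = "head_config")
}

he_init <- function(n_out, n_in, k = 1L) {
  array(stats::rnorm(n_out * n_in * k, sd = sqrt(2 / (n_in * k))),
        dim = c(n_out, n_in, k))
}

init_conv <- function(c_out, c_in, k) {
  list(W = he_init(c_out, c_in, k), b = numeric(c_out))
}

init_bn <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

init_linear <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

bn_state <- function(c) list(mean = rep(0, c), var = rep(1, c))

#' Initialize an encoder + projection-head + classification-head model
#'
#' Weights use He initialization from a seeded stream; batch-norm scale and
#' shift start at 1 and 0. The classification head is created only when
#' `head_cfg` is supplied (it can be attached later by [finetune()]).
#'
#' @param n_channels input channel count `S`.
#' @param enc_cfg an [encoder_config()].
#' @param head_cfg a [head_config()] or `NULL`.
#' @param seed integer seed for weight initialization.
#' @return A list of class `tffc_model` with elements `enc_cfg`, `head_cfg`,
#'   `n_channels`, `params` (trainable tree) and `state` (batch-norm running
#'   statistics).
#' @export
init_model <- function(n_channels, enc_cfg = encoder_config(),
                       head_cfg = NULL, seed = 1L) {
  with_seed(mix_seed(seed, 4099L), {
    ch <- enc_cfg$channels
    k <- enc_cfg$kernel
    ins <- c(n_channels, ch[-3L])
    blocks <- vector("list", 3L)
    state_blocks <- vector("list", 3L)
    for (b in 1:3) {
      blk <- list(conv1 = init_conv(ch[b], ins[b], k), bn1 = init_bn(ch[b]),
                  conv2 = init_conv(ch[b], ch[b], k), bn2 = init_bn(ch[b]))
      st <- list(bn1 = bn_state(ch[b]), bn2 = bn_state(ch[b]))
      if (enc_cfg$residual && ins[b] != ch[b]) {
        blk$short <- init_conv(ch[b], ins[b], 1L)
        blk$bn_s <- init_bn(ch[b])
        st$bn_s <- bn_state(ch[b])
      }
      blocks[[b]] <- blk
      state_blocks[[b]] <- st
    }
    D <- enc_cfg$embed_dim
    params <- list(
      encoder = list(blocks = blocks, fc = init_linear(ch[3L], D)),
      projector = list(fc1 = init_linear(D, D), bn = init_bn(D),
                       fc2 = init_linear(D, enc_cfg$proj_dim))
    )
    state <- list(encoder = list(blocks = state_blocks),
                  projector = list(bn = bn_state(D)))
    model <- structure(list(enc_cfg = enc_cfg, head_cfg = head_cfg,
                            n_channels = as.integer(n_channels),
                            params = params, state = state),
                       class = "tffc_model")
    if (!is.null(head_cfg)) model <- attach_head(model, head_cfg)
    model
  })
}

attach_head <- function(model, head_cfg) {
  D <- model$enc_cfg$embed_dim
  h <- head_cfg$hidden
  model$head_cfg <- head_cfg
  model$params$head <- list(
    fc1 = init_linear(D, h[1L]),
    fc2 = init_linear(h[1L], h[2L]),
    fc3 = init_linear(h[2L], head_cfg$n_classes)
  )
  model
}

#' @export
print.tffc_model <- function(x, ...) {
  cat(sprintf("<tffc_model> %d input channel(s), blocks %s, D = %d, proj = %d%s\n",
              x$n_channels, paste(x$enc_cfg$channels, collapse = "/"),
              x$enc_cfg$embed_dim, x$enc_cfg$proj_dim,
              if (is.null(x$params$head)) "" else
                sprintf(", head %s -> %d classes",
                        paste(x$head_cfg$hidden, collapse = "/"),
                        x$head_cfg$n_classes)))
  invisible(x)
}

block_fwd <- function(x, blk, st, training, residual = TRUE, momentum = 0.1) {
  c1 <- conv1d_fwd(x, blk$conv1$W, blk$conv1$b)
  b1 <- bn1d_fwd(c1$out, blk$bn1$gamma, blk$bn1$beta, st$bn1, training, momentum)
  r1 <- relu_fwd(b1$out)
  c2 <- conv1d_fwd(r1$out, blk$conv2$W, blk$conv2$b)
  b2 <- bn1d_fwd(c2$out, blk$bn2$gamma, blk$bn2$beta, st$bn2, training, momentum)
  if (!is.null(blk$short)) {
    cs <- conv1d_fwd(x, blk$short$W, blk$short$b)
    bs <- bn1d_fwd(cs$out, blk$bn_s$gamma, blk$bn_s$beta, st$bn_s, training, momentum)
    shortcut <- bs$out
    st$bn_s <- bs$run
  } else if (residual && identical(dim(x)[1L], dim(b2$out)[1L])) {
    cs <- bs <- NULL
    shortcut <- x
  } else {
    cs <- bs <- NULL
    shortcut <- 0   # plain (non-residual) stack
  }
  pre <- b2$out + shortcut
  r2 <- relu_fwd(pre)
  st$bn1 <- b1$run
  st$bn2 <- b2$run
  list(out = r2$out, st = st,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    cs = if (is.null(cs)) NULL else cs$cache,
                    bs = if (is.null(bs)) NULL else bs$cache,
                    identity_short = is.null(cs) && !identical(shortcut, 0)))
}

block_bwd <- function(dy, cache, blk) {
  dpre <- relu_bwd(dy, cache$r2)
  g <- list()
  db2 <- bn1d_bwd(dpre, cache$b2)
  g$bn2 <- db2$grads
  dc2 <- conv1d_bwd(db2$dx, cache$c2, blk$conv2$W)
  g$conv2 <- dc2$grads
  dr1 <- relu_bwd(dc2$dx, cache$r1)
  db1 <- bn1d_bwd(dr1, cache$b1)
  g$bn1 <- db1$grads
  dc1 <- conv1d_bwd(db1$dx, cache$c1, blk$conv1$W)
  g$conv1 <- dc1$grads
  dx <- dc1$dx
  if (!is.null(cache$cs)) {
    dbs <- bn1d_bwd(dpre, cache$bs)
    g$bn_s <- dbs$grads
    dcs <- conv1d_bwd(dbs$dx, cache$cs, blk$short$W)
    g$short <- dcs$grads
    dx <- dx + dcs$dx
  } else if (cache$identity_short) {
    dx <- dx + dpre
  }
  # reorder grads to match the parameter tree layout
  out <- list(conv1 = g$conv1, bn1 = g$bn1, conv2 = g$conv2, bn2 = g$bn2)
  if (!is.null(g$short)) {
    out$short <- g$short
    out$bn_s <- g$bn_s
  }
  list(dx = dx, grads = out)
}

encoder_fwd <- function(model, xctn, training = FALSE, momentum = 0.1) {
  st <- model$state$encoder
  caches <- vector("list", 3L)
  h <- xctn
  for (b in 1:3) {
    res <- block_fwd(h, model$params$encoder$blocks[[b]],
                     st$blocks[[b]], training, model$enc_cfg$residual,
                     momentum)
    h <- res$out
    st$blocks[[b]] <- res$st
    caches[[b]] <- res$cache
  }
  d <- dim(h)                       # C x T x N
  pooled <- t(colMeans(aperm(h, c(2L, 1L, 3L))))  # N x C global average pool
  fc <- linear_fwd(pooled, model$params$encoder$fc$W, model$params$encoder$fc$b)
  list(emb = fc$out, state = st,
       cache = list(blocks = caches, fc = fc$cache, hdim = d))
}

encoder_bwd <- function(model, demb, cache) {
  fcb <- linear_bwd(demb, cache$fc, model$params$encoder$fc$W)
  d <- cache$hdim
  # un-pool: each time position receives d_pooled / T
  dpool <- t(fcb$dx) / d[2L]                       # C x N
  dh <- array(rep(dpool, each = d[2L]) , dim = c(d[2L], d[1L], d[3L]))
  dh <- aperm(dh, c(2L, 1L, 3L))
  grads_blocks <- vector("list", 3L)
  for (b in 3:1) {
    res <- block_bwd(dh, cache$blocks[[b]], model$params$encoder$blocks[[b]])
    dh <- res$dx
    grads_blocks[[b]] <- res$grads
  }
  list(dx = dh, grads = list(blocks = grads_blocks, fc = fcb$grads))
}

projector_fwd <- function(model, emb, training = FALSE, momentum = 0.1) {
  p <- model$params$projector
  f1 <- linear_fwd(emb, p$fc1$W, p$fc1$b)
  bn <- bnvec_fwd(f1$out, p$bn$gamma, p$bn$beta, model$state$projector$bn,
                  training, momentum)
  r <- relu_fwd(bn$out)
  f2 <- linear_fwd(r$out, p$fc2$W, p$fc2$b)
  list(proj = f2$out, state = list(bn = bn$run),
       cache = list(f1 = f1$cache, bn = bn$cache, r = r$cache, f2 = f2$cache))
}

projector_bwd <- function(model, dproj, cache) {
  p <- model$params$projector
  f2b <- linear_bwd(dproj, cache$f2, p$fc2$W)
  drelu <- relu_bwd(f2b$dx, cache$r)
  bnb <- bnvec_bwd(drelu, cache$bn)
  f1b <- linear_bwd(bnb$dx, cache$f1, p$fc1$W)
  list(dx = f1b$dx,
       grads = list(fc1 = f1b$grads, bn = bnb$grads, fc2 = f2b$grads))
}

head_fwd <- function(model, emb, training = FALSE) {
  h <- model$params$head
  p_drop <- model$head_cfg$dropout
  f1 <- linear_fwd(emb, h$fc1$W, h$fc1$b)
  r1 <- relu_fwd(f1$out)
  d1 <- dropout_fwd(r1$out, p_drop, training)
  f2 <- linear_fwd(d1$out, h$fc2$W, h$fc2$b)
  r2 <- relu_fwd(f2$out)
  d2 <- dropout_fwd(r2$out, p_drop, training)
  f3 <- linear_fwd(d2$out, h$fc3$W, h$fc3$b)
  logits <- f3$out
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits,
       cache = list(f1 = f1$cache, r1 = r1$cache, d1 = d1$cache,
                    f2 = f2$cache, r2 = r2$cache, d2 = d2$cache,
                    f3 = f3$cache))
}

head_bwd <- function(model, dlogits, cache) {
  h <- model$params$head
  f3b <- linear_bwd(dlogits, cache$f3, h$fc3$W)
  dd2 <- dropout_bwd(f3b$dx, cache$d2)
  dr2 <- relu_bwd(dd2, cache$r2)
  f2b <- linear_bwd(dr2, cache$f2, h$fc2$W)
  dd1 <- dropout_bwd(f2b$dx, cache$d1)
  dr1 <- relu_bwd(dd1, cache$r1)
  f1b <- linear_bwd(dr1, cache$f1, h$fc1$W)
  list(dx = f1b$dx,
       grads = list(fc1 = f1b$grads, fc2 = f2b$grads, fc3 = f3b$grads))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

batch_to_ctn <- function(batch) aperm(batch$X, c(2L, 3L, 1L))

#' Re-estimate batch-norm running statistics ("precise BN")
#'
#' Running means and variances accumulated with momentum during minibatch
#' training lag behind the final weights; after training they are replaced
#' by the exact layer statistics of one full forward pass over (a capped
#' subsample of) the training data. Called automatically at the end of
#' [pretrain()] and [finetune()], so evaluation-mode encoding matches the
#' statistics the trained weights actually produce.
#'
#' @param model a [init_model()] model.
#' @param batch the [window_batch()] whose distribution evaluation should
#'   reflect (typically the training split).
#' @param cap maximum windows used for the calibration pass (default 512;
#'   larger batches are subsampled deterministically).
#' @return The model with updated batch-norm state.
#' @export
calibrate_bn <- function(model, batch, cap = 512L) {
  n <- n_windows(batch)
  if (n > cap) {
    keep <- with_seed(mix_seed(9173L, n, cap), sort(sample.int(n, cap)))
    batch <- subset_windows(batch, keep)
  }
  res <- encoder_fwd(model, batch_to_ctn(batch), training = TRUE, momentum = 1)
  model$state$encoder <- res$state
  pr <- projector_fwd(model, res$emb, training = TRUE, momentum = 1)
  model$state$projector <- pr$state
  model
}

#' Encode windows into embeddings
#'
#' Runs the residual encoder forward in evaluation mode (batch-norm running
#' statistics, no dropout). Accepts windows of any length `T >= 1`; the
#' adaptive average pooling collapses the time axis.
#'
#' @param batch a [window_batch()] whose channel count matches the model.
#' @param model a [init_model()] model.
#' @return A numeric `N x D` embedding matrix.
#' @export
encode <- function(batch, model) {
  if (dim(batch$X)[2L] != model$n_channels) {
    stop_invalid("batch has %d channel(s) but model expects %d",
                 dim(batch$X)[2L], model$n_channels)
  }
  encoder_fwd(model, batch_to_ctn(batch), training = FALSE)$emb
}

#' Project embeddings through the contrastive projection head
#'
#' Two fully connected layers with batch normalization and ReLU between
#' them. Used only to compute the contrastive loss; the projections are not
#' length-normalized here (the cosine similarity inside the loss does that).
#'
#' @param emb `N x D` embedding matrix.
#' @param model a [init_model()] model.
#' @return A numeric `N x proj_dim` matrix.
#' @export
project <- function(emb, model) {
  if (ncol(emb) != model$enc_cfg$embed_dim) {
    stop_invalid("embedding width %d does not match D = %d",
                 ncol(emb), model$enc_cfg$embed_dim)
  }
  projector_fwd(model, emb, training = FALSE)$proj
}

#' Classify embeddings into class probabilities
#'
#' The fine-tuning head: 256-unit and 128-unit ReLU layers with dropout 0.2
#' (inactive in this evaluation-mode call) and a softmax output. Rows sum
#' to 1.
#'
#' @param emb `N x D` embedding matrix.
#' @param model a [init_model()] model with an attached classification head.
#' @return A numeric `N x n_classes` probability matrix.
#' @export
classify <- function(emb, model) {
  if (is.null(model$params$head)) stop_invalid("model has no classification head")
  if (ncol(emb) != model$enc_cfg$embed_dim) {
    stop_invalid("embedding width %d does not match D = %d",
                 ncol(emb), model$enc_cfg$embed_dim)
  }
  head_fwd(model, emb, training = FALSE)$probs
}
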
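#' Pre-training configuration
#'
#' Optimization settings for the self-supervised pretext stage: Adam with
#' learning rate `1e-4` and decay rates `(0.9, 0.99)`, L2 regularization
#' added to the loss, and the NT-Xent temperature.
#'
#' @param temperature NT-Xent temperature `tau > 0` (default 0.2).
#' @param batch_size contrastive batch size `N` (default 128; incomplete
#'   final batches are dropped so the `2N` negative pool is fixed).
#' @param epochs training epochs (default 100).
#' @param learning_rate Adam step size (default `1e-4`).
#' @param adam_betas Adam decay rates (default `c(0.9, 0.99)`).
#' @param l2_coefficient L2 regularization weight on all parameters
#'   (default `1e-5`).
#' @param mode augmented-view construction: `"tf-fc"` (kernel-PCA fusion of
#'   time- and frequency-augmented views), `"time-only"`, or `"freq-only"`.
#' @param seed integer seed governing shuffling and augmentation draws.
#' @return A list of class `pretrain_config`.
#' @export
pretrain_config <- function(temperature = 0.2, batch_size = 128L,
                            epochs = 100L, learning_rate = 1e-4,
                            adam_betas = c(0.9, 0.99), l2_coefficient = 1e-5,
                            mode = c("tf-fc", "time-only", "freq-only"),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (temperature <= 0) stop_invalid("temperature must be > 0")
  if (batch_size < 2L) stop_invalid("batch_size must be >= 2")
  if (epochs < 1L) stop_invalid("epochs must be >= 1")
  structure(list(temperature = temperature, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 adam_betas = adam_betas, l2_coefficient = l2_coefficient,
                 mode = mode, seed = as.integer(seed)),
            class = "pretrain_config")
}

row_normalize <- function(z) {
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) stop_invalid("zero-norm projection vector: cosine similarity undefined")
  z / nrm
}

#' NT-Xent loss of a single ordered pair
#'
#' The normalized temperature-scaled cross-entropy loss of anchor `i` with
#' positive `j` against the pooled `2N` projections:
#' `L_ij = -log( exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) )`
#' with `sim` the cosine similarity.
#'
#' @param i,j indices of the anchor and its positive inside `all_z`.
#' @param all_z numeric `2N x P` matrix of pooled projections.
#' @param temperature temperature `tau > 0`.
#' @return The scalar loss value.
#' @export
nt_xent_pair <- function(i, j, all_z, temperature = 0.2) {
  if (temperature <= 0) stop_invalid("temperature must be > 0")
  u <- row_normalize(all_z)
  sims <- drop(u %*% u[i, ]) / temperature
  denom <- sum(exp(sims[-i]))
  -log(exp(sims[j]) / denom)
}

#' Batch NT-Xent loss over two aligned views
#'
#' Rows `i` of `view_a` and `view_b` are the two views of instance `i`. The
#' loss is the mean over instances of the symmetrized pair losses
#' `(L_{i,i'} + L_{i',i}) / 2`, each computed against the pooled `2N`
#' projections. Optionally returns the analytic gradient with respect to
#' both views.
#'
#' @param view_a,view_b numeric `N x P` projection matrices.
#' @param temperature temperature `tau > 0`.
#' @param grad also return gradients (default `FALSE`).
#' @param norm_eps lower clamp on projection norms before the cosine;
#'   0 (default) treats a zero-norm vector as an error, a small positive
#'   value lets training proceed through transiently dead projections (the
#'   training loop uses `1e-12`).
#' @return The scalar loss, or (with `grad = TRUE`) a list
#'   `list(loss, grad_a, grad_b)`.
#' @export
nt_xent_batch <- function(view_a, view_b, temperature = 0.2, grad = FALSE,
                          norm_eps = 0) {
  if (!identical(dim(view_a), dim(view_b))) {
    stop_invalid("views must have identical dimensions")
  }
  if (temperature <= 0) stop_invalid("temperature must be > 0")
  N <- nrow(view_a)
  z <- rbind(view_a, view_b)
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) {
    if (norm_eps <= 0) {
      stop_invalid("zero-norm projection vector: cosine similarity undefined")
    }
    nrm <- pmax(nrm, norm_eps)
  }
  u <- z / nrm
  M <- 2L * N
  logits <- (u %*% t(u)) / temperature
  diag(logits) <- -Inf                      # k != i exclusion
  mx <- apply(logits, 1L, max)
  p <- exp(logits - mx)
  p <- p / rowSums(p)                       # row-wise softmax over negatives+positive
  pos <- c((N + 1L):M, 1L:N)                # index of i' for each i
  pos_logprob <- log(p[cbind(seq_len(M), pos)])
  loss <- -mean(pos_logprob)                # == (1/N) sum_i (L_ii' + L_i'i)/2
  if (!grad) return(loss)
  dlogits <- p
  dlogits[cbind(seq_len(M), pos)] <- dlogits[cbind(seq_len(M), pos)] - 1
  dlogits <- dlogits / M
  dlogits[!is.finite(dlogits)] <- 0
  dS <- dlogits / temperature
  du <- (dS + t(dS)) %*% u
  # back through row normalization u = z / |z|
  dz <- (du - u * rowSums(du * u)) / nrm
  list(loss = loss,
       grad_a = dz[seq_len(N), , drop = FALSE],
       grad_b = dz[(N + 1L):M, , drop = FALSE])
}

# Build the mode-dependent augmented view of a batch of windows.
augmented_view <- function(batch, mode, time_cfg, freq_cfg, fusion, stream,
                           indices = NULL) {
  switch(mode,
    "time-only" = apply_time_bank(batch, time_cfg, stream = stream,
                                  indices = indices),
    "freq-only" = apply_freq_bank(batch, freq_cfg, stream = stream,
                                  indices = indices),
    "tf-fc" = {
      t_aug <- apply_time_bank(batch, time_cfg, stream = stream,
                               indices = indices)
      f_aug <- apply_freq_bank(batch, freq_cfg, stream = stream,
                               indices = indices)
      fuse_views(fusion, t_aug, f_aug)
    },
    stop_invalid("unknown mode '%s'", mode)
  )
}

#' Fit the fusion model on augmented pretrain windows
#'
#' Draws one seeded pass of both augmentation banks over (a capped subsample
#' of) the pretrain split and fits the two kernel-PCA branches on the
#' flattened augmented views. Fitted once per pre-training run and reused
#' for every batch, so representations do not depend on batch composition.
#'
#' @param pretrain_batch the pretrain [window_batch()].
#' @param fusion an unfitted [fusion_model()].
#' @param time_cfg a [time_aug_config()].
#' @param freq_cfg a [freq_aug_config()].
#' @return The fitted [fusion_model()].
#' @export
fit_fusion_on_pretrain <- function(pretrain_batch, fusion = fusion_model(),
                                   time_cfg = time_aug_config(),
                                   freq_cfg = freq_aug_config()) {
  n <- n_windows(pretrain_batch)
  if (n > fusion$fit_cap) {
    keep <- with_seed(mix_seed(fusion$fit_seed, 5003L),
                      sort(sample.int(n, fusion$fit_cap)))
    pretrain_batch <- subset_windows(pretrain_batch, keep)
  }
  t_aug <- apply_time_bank(pretrain_batch, time_cfg, stream = -1L)
  f_aug <- apply_freq_bank(pretrain_batch, freq_cfg, stream = -1L)
  fit_fusion(fusion, flatten_windows(t_aug), flatten_windows(f_aug))
}

#' Self-supervised contrastive pre-training
#'
#' Pairs each original window with its mode-dependent augmented view
#' (kernel-PCA fusion of the time- and frequency-bank outputs in `"tf-fc"`
#' mode), encodes and projects both views, and minimizes the batch NT-Xent
#' loss plus L2 regularization with Adam. Augmentations are re-drawn every
#' epoch from per-`(epoch, window)` RNG substreams; runs are fully seeded.
#'
#' @param data the pretrain [window_batch()] (needs at least `batch_size`
#'   windows).
#' @param model a [init_model()] model (encoder + projector).
#' @param cfg a [pretrain_config()].
#' @param fusion a fitted [fusion_model()] (required in `"tf-fc"` mode).
#' @param time_cfg a [time_aug_config()].
#' @param freq_cfg a [freq_aug_config()].
#' @param verbose print the per-epoch loss (default `FALSE`).
#' @return The trained model with an added `pretrain_history` element (mean
#'   NT-Xent loss per epoch).
#' @export
pretrain <- function(data, model, cfg = pretrain_config(),
                     fusion = NULL, time_cfg = time_aug_config(),
                     freq_cfg = freq_aug_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "pretrain_config"))
  N_all <- n_windows(data)
  if (N_all < cfg$batch_size) {
    stop_invalid("pretrain split (%d windows) smaller than batch_size (%d)",
                 N_all, cfg$batch_size)
  }
  if (cfg$mode == "tf-fc" && (is.null(fusion) || !isTRUE(fusion$fitted))) {
    stop_invalid("tf-fc mode requires a fitted fusion model")
  }
  opt_params <- list(encoder = model$params$encoder,
                     projector = model$params$projector)
  opt <- adam_init(opt_params)
  history <- numeric(cfg$epochs)
  n_batches <- N_all %/% cfg$batch_size
  for (epoch in seq_len(cfg$epochs)) {
    perm <- with_seed(mix_seed(cfg$seed, 6007L, epoch), sample.int(N_all))
    epoch_loss <- numeric(n_batches)
    for (bi in seq_len(n_batches)) {
      idx <- perm[((bi - 1L) * cfg$batch_size + 1L):(bi * cfg$batch_size)]
      orig <- subset_windows(data, idx)
      # bank substreams are keyed by epoch and absolute window index, so a
      # window's augmentation does not depend on which batch it landed in
      aug <- augmented_view(orig, cfg$mode, time_cfg, freq_cfg, fusion,
                            stream = epoch, indices = idx)
      enc_a <- encoder_fwd(model, batch_to_ctn(orig), training = TRUE)
      model$state$encoder <- enc_a$state
      enc_b <- encoder_fwd(model, batch_to_ctn(aug), training = TRUE)
      model$state$encoder <- enc_b$state
      pr_a <- projector_fwd(model, enc_a$emb, training = TRUE)
      model$state$projector <- pr_a$state
      pr_b <- projector_fwd(model, enc_b$emb, training = TRUE)
      model$state$projector <- pr_b$state
      lz <- nt_xent_batch(pr_a$proj, pr_b$proj, cfg$temperature, grad = TRUE,
                          norm_eps = 1e-12)
      gb_a <- projector_bwd(model, lz$grad_a, pr_a$cache)
      gb_b <- projector_bwd(model, lz$grad_b, pr_b$cache)
      ge_a <- encoder_bwd(model, gb_a$dx, enc_a$cache)
      ge_b <- encoder_bwd(model, gb_b$dx, enc_b$cache)
      grads <- list(
        encoder = tree_map2(`+`, ge_a$grads, ge_b$grads),
        projector = tree_map2(`+`, gb_a$grads, gb_b$grads)
      )
      opt_params <- list(encoder = model$params$encoder,
                         projector = model$params$projector)
      upd <- adam_step(opt_params, grads, opt, lr = cfg$learning_rate,
                       beta1 = cfg$adam_betas[1L], beta2 = cfg$adam_betas[2L],
                       l2 = cfg$l2_coefficient)
      opt <- upd$opt
      model$params$encoder <- upd$params$encoder
      model$params$projector <- upd$params$projector
      epoch_loss[bi] <- lz$loss +
        cfg$l2_coefficient * tree_sumsq(opt_params)
    }
    history[epoch] <- mean(epoch_loss)
    if (verbose) {
      message(sprintf("epoch %3d/%d  loss %.5f", epoch, cfg$epochs, history[epoch]))
    }
  }
  model <- calibrate_bn(model, data)
  model$pretrain_history <- history
  model$pretrain_mode <- cfg$mode
  model
}
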
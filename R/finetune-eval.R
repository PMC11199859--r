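#' Build a classification metrics report
#'
#' Confusion matrix (rows = truth, columns = prediction), overall accuracy,
#' and macro-averaged precision, recall and F1 (each class weighted equally;
#' a class with no predicted positives contributes precision 0, and a class
#' with degenerate precision + recall contributes F1 0). The averaging
#' scheme is recorded in the report.
#'
#' @param truth integer vector of true class ids in `0..C-1`.
#' @param pred integer vector of predicted class ids.
#' @param n_classes number of classes `C` (default: inferred from `truth`).
#' @return An object of class `metrics_report` with elements `accuracy`,
#'   `precision`, `recall`, `f1`, `per_class` (data frame), `confusion`
#'   (`C x C` count matrix) and `averaging`.
#' @export
metrics_report <- function(truth, pred, n_classes = NULL) {
  if (!length(truth)) stop_invalid("empty evaluation set")
  if (length(truth) != length(pred)) stop_invalid("truth/pred length mismatch")
  if (is.null(n_classes)) n_classes <- max(truth) + 1L
  lv <- 0:(n_classes - 1L)
  confusion <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("truth", "pred")
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  precision_c <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall_c <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1_c <- ifelse(precision_c + recall_c > 0,
                 2 * precision_c * recall_c / (precision_c + recall_c), 0)
  structure(list(
    accuracy = sum(tp) / length(truth),
    precision = mean(precision_c),
    recall = mean(recall_c),
    f1 = mean(f1_c),
    per_class = data.frame(class = lv, precision = precision_c,
                           recall = recall_c, f1 = f1_c,
                           support = rowSums(confusion), row.names = NULL),
    confusion = confusion,
    averaging = "macro"
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f (%s)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$averaging))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Supervised fine-tuning of the classification head
#'
#' Attaches (or reuses) the two-hidden-layer softmax head and trains with
#' cross-entropy on the fine-tune split using Adam with step size `1e-4`
#' and decay rates `(0.9, 0.99)`. The gentle step size matters beyond
#' optimization speed: aggressive fine-tuning simply retrains the network
#' from any initialization, erasing whatever the contrastive stage learned.
#' By default the whole network (encoder included) is updated; set
#' `freeze_encoder = TRUE` to train the head only. Training stops early when
#' the epoch training loss has not improved for `patience` epochs.
#'
#' @param model a [init_model()] model (typically pre-trained).
#' @param data the labeled fine-tune [window_batch()].
#' @param head_cfg a [head_config()]; default derives `n_classes` from the
#'   labels.
#' @param epochs maximum epochs (default 50).
#' @param batch_size minibatch size (default 32, capped at `N`).
#' @param learning_rate Adam step size (default `1e-4`).
#' @param adam_betas Adam decay rates (default `c(0.9, 0.99)`).
#' @param freeze_encoder train only the head (default `FALSE`).
#' @param patience early-stopping patience in epochs (default 10).
#' @param seed integer seed (shuffling, dropout, head init).
#' @return The fine-tuned model with a `finetune_history` element (mean
#'   cross-entropy per epoch).
#' @export
finetune <- function(model, data, head_cfg = NULL, epochs = 50L,
                     batch_size = 32L, learning_rate = 1e-4,
                     adam_betas = c(0.9, 0.99), freeze_encoder = FALSE,
                     patience = 10L, seed = 1L) {
  n_cl <- length(unique(data$y))
  if (is.null(head_cfg)) head_cfg <- head_config(n_classes = max(data$y) + 1L)
  if (head_cfg$n_classes < n_cl) {
    stop_invalid("head has %d classes but data contains %d",
                 head_cfg$n_classes, n_cl)
  }
  if (is.null(model$params$head)) {
    model <- with_seed(mix_seed(seed, 8111L), attach_head(model, head_cfg))
  }
  N <- n_windows(data)
  batch_size <- min(batch_size, N)
  trainable <- if (freeze_encoder) list(head = model$params$head) else
    list(encoder = model$params$encoder, head = model$params$head)
  opt <- adam_init(trainable)
  history <- numeric(0)
  best <- Inf
  stall <- 0L
  with_seed(mix_seed(seed, 8999L), {
    for (epoch in seq_len(epochs)) {
      perm <- sample.int(N)
      n_batches <- ceiling(N / batch_size)
      losses <- numeric(n_batches)
      for (bi in seq_len(n_batches)) {
        idx <- perm[(((bi - 1L) * batch_size + 1L):min(bi * batch_size, N))]
        xb <- subset_windows(data, idx)
        enc <- encoder_fwd(model, batch_to_ctn(xb), training = !freeze_encoder)
        if (!freeze_encoder) model$state$encoder <- enc$state
        hd <- head_fwd(model, enc$emb, training = TRUE)
        nb <- length(idx)
        onehot <- cbind(seq_len(nb), xb$y + 1L)
        losses[bi] <- -mean(log(pmax(hd$probs[onehot], 1e-12)))
        dlogits <- hd$probs
        dlogits[onehot] <- dlogits[onehot] - 1
        dlogits <- dlogits / nb
        hb <- head_bwd(model, dlogits, hd$cache)
        grads <- if (freeze_encoder) list(head = hb$grads) else
          list(encoder = encoder_bwd(model, hb$dx, enc$cache)$grads,
               head = hb$grads)
        trainable <- if (freeze_encoder) list(head = model$params$head) else
          list(encoder = model$params$encoder, head = model$params$head)
        upd <- adam_step(trainable, grads, opt, lr = learning_rate,
                         beta1 = adam_betas[1L], beta2 = adam_betas[2L])
        opt <- upd$opt
        model$params$head <- upd$params$head
        if (!freeze_encoder) model$params$encoder <- upd$params$encoder
      }
      history <- c(history, mean(losses))
      if (mean(losses) < best - 1e-6) {
        best <- mean(losses)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  })
  model <- calibrate_bn(model, data)
  model$finetune_history <- history
  model
}

#' Evaluate a fine-tuned model on a labeled test set
#'
#' Predictions are the row-wise argmax of [classify()] over the encoder
#' embeddings (evaluation mode: running batch-norm statistics, dropout off).
#'
#' @param model a fine-tuned [init_model()] model.
#' @param test a labeled [window_batch()].
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, test) {
  if (!n_windows(test)) stop_invalid("empty test set")
  probs <- classify(encode(test, model), model)
  pred <- max.col(probs, ties.method = "first") - 1L
  metrics_report(test$y, pred, n_classes = model$head_cfg$n_classes)
}
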
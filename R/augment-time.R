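#' Time-domain augmentation configuration
#'
#' Parameters of the four-member time-domain bank. Each operator is applied
#' to each window independently with probability `p_apply`; the experimental
#' constants are a jitter standard deviation of 0.01, scaling factors drawn
#' uniformly from (0.9, 1.1), and masking of 10% of the time points.
#'
#' @param p_apply per-operator firing probability (default 0.25, i.e. one of
#'   the four operators fires per window in expectation).
#' @param jitter_sd Gaussian noise sd (default 0.01).
#' @param scale_low,scale_high bounds of the uniform scaling factor
#'   (default 0.9, 1.1).
#' @param n_segments segment count for permutation (default 4).
#' @param mask_fraction fraction of time points masked (default 0.10).
#' @param mask_value value written into masked positions (default 0).
#' @param per_channel_mask mask each channel independently instead of
#'   sharing masked time points across channels (default `FALSE`).
#' @param seed integer RNG seed for the bank.
#' @return A list of class `time_aug_config`.
#' @export
time_aug_config <- function(p_apply = 0.25, jitter_sd = 0.01,
                            scale_low = 0.9, scale_high = 1.1,
                            n_segments = 4L, mask_fraction = 0.10,
                            mask_value = 0, per_channel_mask = FALSE,
                            seed = 1L) {
  if (p_apply < 0 || p_apply > 1) stop_invalid("p_apply must be in [0, 1]")
  if (jitter_sd < 0) stop_invalid("jitter_sd must be >= 0")
  if (scale_low > scale_high) stop_invalid("scale_low must be <= scale_high")
  if (n_segments < 1L) stop_invalid("n_segments must be >= 1")
  if (mask_fraction < 0 || mask_fraction > 1) stop_invalid("mask_fraction must be in [0, 1]")
  structure(list(p_apply = p_apply, jitter_sd = jitter_sd,
                 scale_low = scale_low, scale_high = scale_high,
                 n_segments = as.integer(n_segments),
                 mask_fraction = mask_fraction, mask_value = mask_value,
                 per_channel_mask = per_channel_mask,
                 seed = as.integer(seed)),
            class = "time_aug_config")
}

#' Jittering: add Gaussian noise
#'
#' Adds i.i.d. `N(0, sd^2)` noise to every sample, drawn from the current
#' RNG stream.
#'
#' @param batch a [window_batch()].
#' @param sd noise standard deviation (>= 0).
#' @return A [window_batch()] of identical shape.
#' @export
jitter <- function(batch, sd = 0.01) {
  if (sd < 0) stop_invalid("sd must be >= 0")
  if (sd == 0) return(batch)
  d <- dim(batch$X)
  batch$X <- batch$X + array(stats::rnorm(prod(d), sd = sd), dim = d)
  batch
}

#' Scaling: multiply each window by a random scalar
#'
#' One factor `s ~ Uniform(low, high)` is drawn per window and multiplies
#' every sample of that window across all channels.
#'
#' @param batch a [window_batch()].
#' @param low,high bounds of the uniform factor distribution.
#' @return A [window_batch()] of identical shape.
#' @export
scale_windows <- function(batch, low = 0.9, high = 1.1) {
  if (low > high) stop_invalid("low must be <= high")
  N <- n_windows(batch)
  s <- stats::runif(N, low, high)
  batch$X <- batch$X * s  # N is the first axis: s recycles per window
  batch
}

# Cut `T` into n near-equal contiguous segments (lengths differ by <= 1,
# longer segments first) and return the list of index vectors.
segment_bounds <- function(T_len, n_segments) {
  base <- T_len %/% n_segments
  extra <- T_len %% n_segments
  lens <- rep(base, n_segments) + c(rep(1L, extra), rep(0L, n_segments - extra))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

# Apply a fixed segment ordering to one S x T window matrix.
apply_segment_order <- function(win, segs, ord) {
  win[, unlist(segs[ord]), drop = FALSE]
}

#' Permutation: shuffle contiguous segments of the time axis
#'
#' The time axis is cut into `n_segments` near-equal contiguous intervals
#' (lengths differ by at most one); a uniform random permutation of the
#' intervals is drawn per window and applied identically to all channels.
#'
#' @param batch a [window_batch()].
#' @param n_segments number of intervals (`1 <= n_segments <= T`).
#' @return A [window_batch()] of identical shape.
#' @export
permute_segments <- function(batch, n_segments = 4L) {
  T_len <- dim(batch$X)[3L]
  if (n_segments < 1L || n_segments > T_len) {
    stop_invalid("n_segments must be in [1, T]")
  }
  if (n_segments == 1L) return(batch)
  segs <- segment_bounds(T_len, n_segments)
  for (i in seq_len(n_windows(batch))) {
    ord <- sample.int(n_segments)
    batch$X[i, , ] <- apply_segment_order(win_matrix(batch, i), segs, ord)
  }
  batch
}

#' Masking: obscure a fraction of time points
#'
#' Exactly `floor(fraction * T)` time indices per window, chosen uniformly
#' without replacement, are overwritten with `value`. By default the masked
#' indices are shared across channels (point-in-time dropout); set
#' `per_channel = TRUE` to draw them independently per channel.
#'
#' @param batch a [window_batch()].
#' @param fraction fraction of time points to mask, in `[0, 1]`.
#' @param value mask value (default 0).
#' @param per_channel mask channels independently (default `FALSE`).
#' @return A [window_batch()] of identical shape.
#' @export
mask_time <- function(batch, fraction = 0.10, value = 0, per_channel = FALSE) {
  if (fraction < 0 || fraction > 1) stop_invalid("fraction must be in [0, 1]")
  T_len <- dim(batch$X)[3L]
  m <- floor(fraction * T_len)
  if (m == 0L) return(batch)
  S <- dim(batch$X)[2L]
  for (i in seq_len(n_windows(batch))) {
    if (per_channel) {
      for (s in seq_len(S)) {
        batch$X[i, s, sample.int(T_len, m)] <- value
      }
    } else {
      batch$X[i, , sample.int(T_len, m)] <- value
    }
  }
  batch
}

#' Apply the time-domain augmentation bank
#'
#' For each window independently, each of the four operators fires with
#' probability `cfg$p_apply`, composed in the fixed order
#' jitter -> scale -> permute -> mask. Each window draws from its own RNG
#' substream derived from `(cfg$seed, stream, window index)`, so the result
#' for a given window does not depend on how the batch was partitioned.
#'
#' @param batch a [window_batch()].
#' @param cfg a [time_aug_config()].
#' @param stream integer substream id (e.g. the training epoch) so repeated
#'   applications draw fresh, but reproducible, augmentations (default 0).
#' @param indices integer ids used to key each window's RNG substream
#'   (default `1:N`); pass absolute dataset indices so a window's draw does
#'   not depend on batch composition.
#' @return A [window_batch()] of identical shape. The logical `N x 4` matrix
#'   of operator firings is attached as attribute `"fired"`.
#' @export
apply_time_bank <- function(batch, cfg = time_aug_config(), stream = 0L,
                            indices = NULL) {
  stopifnot(inherits(cfg, "time_aug_config"))
  N <- n_windows(batch)
  if (is.null(indices)) indices <- seq_len(N)
  fired <- matrix(FALSE, N, 4L,
                  dimnames = list(NULL, c("jitter", "scale", "permute", "mask")))
  for (i in seq_len(N)) {
    one <- subset_windows(batch, i)
    res <- with_seed(mix_seed(cfg$seed, 1009L, stream, indices[i]), {
      f <- stats::runif(4L) < cfg$p_apply
      if (f[1L]) one <- jitter(one, cfg$jitter_sd)
      if (f[2L]) one <- scale_windows(one, cfg$scale_low, cfg$scale_high)
      if (f[3L]) one <- permute_segments(one, cfg$n_segments)
      if (f[4L]) one <- mask_time(one, cfg$mask_fraction, cfg$mask_value,
                                  cfg$per_channel_mask)
      list(one = one, f = f)
    })
    fired[i, ] <- res$f
    batch$X[i, , ] <- res$one$X[1L, , ]
  }
  attr(batch, "fired") <- fired
  batch
}
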
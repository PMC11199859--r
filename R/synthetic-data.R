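#' Deterministic class template for the synthetic generator
#'
#' Each class is defined by two cues a classifier could exploit: a spectral
#' cue (a unit-amplitude sinusoid at a class-specific frequency bin, classes
#' spaced three bins apart so their spectra do not leak into one another) and
#' a temporal cue (a localized square pulse whose position depends on the
#' class). The template is a deterministic function of `(seed, class_id)`:
#' the sinusoid phase and the exact pulse position are drawn from a seeded
#' substream so different seeds give different, but reproducible, templates.
#'
#' @param class_id integer class id in `0..n_classes-1`.
#' @param n_classes number of classes.
#' @param n_channels number of signal channels `S`.
#' @param window window length `T`.
#' @param seed integer seed.
#' @param cues which class cues to include: `"both"` (default), `"spectral"`
#'   (classes differ only in frequency content) or `"temporal"` (classes
#'   differ only in pulse position).
#' @return An `S x T` numeric matrix.
#' @export
class_template <- function(class_id, n_classes, n_channels = 1L, window = 128L,
                           seed = 1L, cues = c("both", "spectral", "temporal")) {
  cues <- match.arg(cues)
  S <- as.integer(n_channels)
  T_len <- as.integer(window)
  c_id <- as.integer(class_id)
  # class frequency bins start at 3 and are spaced 3 bins apart, capped
  # below Nyquist so every class keeps a distinct spectral line
  f_max <- floor(T_len / 2) - 1L
  f_c <- min(3L + 3L * c_id, f_max)
  with_seed(mix_seed(seed, 211L, c_id), {
    phase <- stats::runif(1L, 0, 2 * pi)
    pulse_w <- max(4L, T_len %/% 8L)
    slot <- (T_len - pulse_w) / max(1L, n_classes)
    pulse_start <- 1L + floor(c_id * slot + stats::runif(1L, 0, max(1, slot / 2)))
    tmpl <- matrix(0, nrow = S, ncol = T_len)
    t_idx <- seq_len(T_len) - 1L
    for (s in seq_len(S)) {
      chan_phase <- phase + (s - 1L) * pi / 7
      spectral <- sin(2 * pi * f_c * t_idx / T_len + chan_phase)
      temporal <- numeric(T_len)
      temporal[pulse_start:min(T_len, pulse_start + pulse_w - 1L)] <- 1
      tmpl[s, ] <- switch(cues,
        both     = spectral + temporal,
        spectral = spectral,
        temporal = temporal
      )
    }
    tmpl
  })
}

#' Generate a labeled synthetic window batch
#'
#' Produces `n_per_class` windows for each of `n_classes` classes. Every
#' window of class `c` equals the class template ([class_template()]) plus
#' i.i.d. Gaussian noise of standard deviation `noise_sd`. Labels are
#' balanced and reruns with the same arguments are bit-identical.
#'
#' @param n_per_class windows per class.
#' @param n_classes number of classes (>= 2).
#' @param n_channels channels `S` (default 1).
#' @param window window length `T` (>= 16, default 128).
#' @param noise_sd additive Gaussian noise standard deviation (>= 0,
#'   default 0.5 -- roughly half the amplitude of each class cue, in the
#'   range of noise levels seen in scalp EEG relative to band-limited
#'   rhythms).
#' @param seed integer seed.
#' @inheritParams class_template
#' @return A [window_batch()] with `n_per_class * n_classes` windows.
#' @export
generate_dataset <- function(n_per_class, n_classes, n_channels = 1L,
                             window = 128L, noise_sd = 0.5, seed = 1L,
                             cues = c("both", "spectral", "temporal")) {
  cues <- match.arg(cues)
  if (n_per_class < 1L || n_classes < 2L || n_channels < 1L) {
    stop_invalid("counts must be positive and n_classes >= 2")
  }
  if (window < 16L) stop_invalid("window must be >= 16")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  S <- as.integer(n_channels)
  T_len <- as.integer(window)
  N <- as.integer(n_per_class * n_classes)

  templates <- lapply(seq_len(n_classes) - 1L, class_template,
                      n_classes = n_classes, n_channels = S, window = T_len,
                      seed = seed, cues = cues)
  y <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  X <- array(0, dim = c(N, S, T_len))
  for (i in seq_len(N)) {
    X[i, , ] <- templates[[y[i] + 1L]]
  }
  if (noise_sd > 0) {
    noise <- with_seed(mix_seed(seed, 977L),
                       stats::rnorm(N * S * T_len, sd = noise_sd))
    X <- X + array(noise, dim = c(N, S, T_len))
  }
  window_batch(X, y, window = T_len, overlap = 0, seed = as.integer(seed))
}

#' Segment a raw recording into fixed-length overlapping windows
#'
#' Windows start at offsets `0, stride, 2*stride, ...` with
#' `stride = max(1, round(T * (1 - overlap)))` and are emitted while they fit
#' entirely inside the recording; trailing partial windows are dropped so
#' every window has exactly `T` samples. All windows inherit the recording's
#' label.
#'
#' @param rec a [raw_recording()].
#' @param window window length `T` (must not exceed the recording length).
#' @param overlap overlap fraction in `[0, 1)`.
#' @return A [window_batch()]; window start offsets (0-based) are attached as
#'   attribute `"starts"` for provenance.
#' @export
sliding_windows <- function(rec, window, overlap = 0) {
  stopifnot(inherits(rec, "raw_recording"))
  T_len <- as.integer(window)
  L <- ncol(rec$values)
  if (overlap < 0 || overlap >= 1) stop_invalid("overlap must be in [0, 1)")
  if (T_len > L) stop_invalid("window (%d) exceeds recording length (%d)", T_len, L)
  stride <- max(1L, as.integer(round(T_len * (1 - overlap))))
  starts <- seq.int(0L, L - T_len, by = stride)
  S <- nrow(rec$values)
  X <- array(0, dim = c(length(starts), S, T_len))
  for (i in seq_along(starts)) {
    X[i, , ] <- rec$values[, (starts[i] + 1L):(starts[i] + T_len), drop = FALSE]
  }
  out <- window_batch(X, rep(rec$label, length(starts)),
                      window = T_len, overlap = overlap)
  attr(out, "starts") <- starts
  out
}

#' Stratified pretrain / finetune / test split
#'
#' Splits a window batch into three disjoint subsets whose union is the
#' input, stratified by class with a seeded shuffle. Per-class counts use
#' largest-remainder rounding so the realized proportions match the requested
#' fractions as closely as integer counts allow.
#'
#' @param batch a [window_batch()].
#' @param fractions numeric length-3 vector `(pretrain, finetune, test)`;
#'   each in `(0, 1)`, summing to 1 (default `c(0.6, 0.2, 0.2)`).
#' @param seed integer seed for the shuffle.
#' @return A list with elements `pretrain`, `finetune`, `test`, each a
#'   [window_batch()].
#' @export
split_dataset <- function(batch, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1)) {
    stop_invalid("each split fraction must lie strictly inside (0, 1)")
  }
  if (abs(sum(fractions) - 1) > 1e-8) stop_invalid("fractions must sum to 1")
  classes <- sort(unique(batch$y))
  idx_split <- list(integer(0), integer(0), integer(0))
  for (cl in classes) {
    idx <- which(batch$y == cl)
    n_c <- length(idx)
    if (n_c < 3L) stop_invalid("class %d has %d window(s); need >= 3 to stratify", cl, n_c)
    idx <- with_seed(mix_seed(seed, 389L, cl), sample(idx))
    base <- floor(fractions * n_c)
    rem <- fractions * n_c - base
    short <- n_c - sum(base)
    if (short > 0) {
      base[order(rem, decreasing = TRUE)[seq_len(short)]] <-
        base[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
    }
    if (any(base == 0L)) {
      stop_invalid("class %d too small to give every split at least one window", cl)
    }
    bounds <- cumsum(base)
    idx_split[[1L]] <- c(idx_split[[1L]], idx[seq_len(bounds[1L])])
    idx_split[[2L]] <- c(idx_split[[2L]], idx[(bounds[1L] + 1L):bounds[2L]])
    idx_split[[3L]] <- c(idx_split[[3L]], idx[(bounds[2L] + 1L):bounds[3L]])
  }
  list(
    pretrain = subset_windows(batch, sort(idx_split[[1L]])),
    finetune = subset_windows(batch, sort(idx_split[[2L]])),
    test     = subset_windows(batch, sort(idx_split[[3L]]))
  )
}
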
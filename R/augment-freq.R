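#' One-sided spectrum batch
#'
#' Complex one-sided discrete Fourier coefficients of a window batch:
#' an `N x S x K` array with `K = floor(T/2) + 1` non-redundant bins
#' (bin 1 is DC; for even `T` bin `K` is the Nyquist bin). `origin_length`
#' stores `T` so the inverse transform is exact.
#'
#' @param coeffs complex array `N x S x K`.
#' @param origin_length original window length `T`.
#' @param y,meta labels and metadata carried through from the batch.
#' @return An object of class `spectrum_batch`.
#' @export
spectrum_batch <- function(coeffs, origin_length, y = NULL, meta = NULL) {
  K <- dim(coeffs)[3L]
  if (K != floor(origin_length / 2) + 1L) {
    stop_invalid("bin count %d inconsistent with origin length %d", K, origin_length)
  }
  structure(list(coeffs = coeffs, origin_length = as.integer(origin_length),
                 y = y, meta = meta),
            class = "spectrum_batch")
}

#' @export
print.spectrum_batch <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("<spectrum_batch> %d windows x %d channel(s) x %d bins (T = %d)\n",
              d[1L], d[2L], d[3L], x$origin_length))
  invisible(x)
}

#' Forward transform: windows to one-sided spectra
#'
#' Discrete Fourier transform along the time axis of every channel of every
#' window, keeping the `K = floor(T/2) + 1` non-redundant bins of the
#' real-input transform.
#'
#' @param batch a [window_batch()].
#' @return A [spectrum_batch()].
#' @export
forward_transform <- function(batch) {
  if (!all(is.finite(batch$X))) stop_invalid("input contains non-finite values")
  d <- dim(batch$X)
  N <- d[1L]; S <- d[2L]; T_len <- d[3L]
  if (T_len < 2L) stop_invalid("window length must be >= 2")
  K <- floor(T_len / 2) + 1L
  # batch the FFT: time axis first, all window-channels as columns
  M <- aperm(batch$X, c(3L, 2L, 1L))   # T x S x N
  dim(M) <- c(T_len, S * N)
  Fm <- stats::mvfft(M)[seq_len(K), , drop = FALSE]
  coeffs <- array(Fm, dim = c(K, S, N))
  coeffs <- aperm(coeffs, c(3L, 2L, 1L))
  spectrum_batch(coeffs, T_len, y = batch$y, meta = batch$meta)
}

# Rebuild the full (two-sided) spectrum from one-sided coefficients and
# return the complex inverse DFT. The imaginary part of the result is the
# symmetry residual; `inverse_transform` discards it, tests may inspect it.
ifft_complex <- function(spec) {
  d <- dim(spec$coeffs)
  N <- d[1L]; S <- d[2L]; K <- d[3L]
  T_len <- spec$origin_length
  M <- aperm(spec$coeffs, c(3L, 2L, 1L))  # K x S x N
  dim(M) <- c(K, S * N)
  full <- matrix(0i, T_len, S * N)
  full[seq_len(K), ] <- M
  # conjugate-symmetric upper half; for even T the Nyquist bin K maps to
  # itself and is not mirrored
  hi <- K - (T_len %% 2L == 0L)
  if (hi >= 2L) {
    idx <- 2L:hi
    full[T_len - idx + 2L, ] <- Conj(M[idx, , drop = FALSE])
  }
  x <- stats::mvfft(full, inverse = TRUE) / T_len
  out <- array(x, dim = c(T_len, S, N))
  aperm(out, c(3L, 2L, 1L))
}

#' Inverse transform: one-sided spectra back to time-domain windows
#'
#' Reconstructs the two-sided spectrum by conjugate symmetry and inverts it.
#' The real part is returned; for spectra whose DC (and Nyquist, for even
#' `T`) bins are real the imaginary residual is at floating-point level.
#'
#' @param spec a [spectrum_batch()].
#' @return A [window_batch()] with windows of length `origin_length`.
#' @export
inverse_transform <- function(spec) {
  stopifnot(inherits(spec, "spectrum_batch"))
  x <- Re(ifft_complex(spec))
  y <- if (is.null(spec$y)) rep(0L, dim(x)[1L]) else spec$y
  out <- window_batch(x, y, window = spec$origin_length,
                      overlap = if (is.null(spec$meta)) NA_real_ else spec$meta$overlap,
                      seed = if (is.null(spec$meta)) NA_integer_ else spec$meta$seed)
  out
}

#' Frequency-domain augmentation configuration
#'
#' Parameters of the four-member spectral bank. The experimental constants
#' are: each operator fires with probability 0.25; remove-frequency and
#' add-frequency each touch 10% of the spectral bins.
#'
#' @param p_apply per-operator firing probability (default 0.25).
#' @param cutoff_fraction fraction of low bins kept by the low-pass filter
#'   (default 0.5).
#' @param phase_noise_sd sd of the per-bin Gaussian phase perturbation in
#'   radians (default 0.1).
#' @param remove_fraction fraction of bins zeroed (default 0.10).
#' @param add_fraction fraction of bins perturbed additively (default 0.10).
#' @param add_noise_scale additive perturbation magnitude relative to the
#'   per-channel maximum bin magnitude (default 0.1).
#' @param seed integer RNG seed for the bank.
#' @return A list of class `freq_aug_config`.
#' @export
freq_aug_config <- function(p_apply = 0.25, cutoff_fraction = 0.5,
                            phase_noise_sd = 0.1, remove_fraction = 0.10,
                            add_fraction = 0.10, add_noise_scale = 0.1,
                            seed = 1L) {
  fracs <- c(p_apply, cutoff_fraction, remove_fraction, add_fraction)
  if (any(fracs < 0) || any(fracs > 1)) stop_invalid("fractions must be in [0, 1]")
  if (phase_noise_sd < 0 || add_noise_scale < 0) {
    stop_invalid("noise scales must be >= 0")
  }
  structure(list(p_apply = p_apply, cutoff_fraction = cutoff_fraction,
                 phase_noise_sd = phase_noise_sd,
                 remove_fraction = remove_fraction,
                 add_fraction = add_fraction,
                 add_noise_scale = add_noise_scale,
                 seed = as.integer(seed)),
            class = "freq_aug_config")
}

#' Ideal low-pass filter on a spectrum batch
#'
#' Brick-wall filter: one-sided bins with 0-based index at or above
#' `ceiling(cutoff_fraction * K)` are zeroed; lower bins pass untouched.
#'
#' @param spec a [spectrum_batch()].
#' @param cutoff_fraction fraction of bins kept, in `[0, 1]`.
#' @return A [spectrum_batch()].
#' @export
lowpass <- function(spec, cutoff_fraction = 0.5) {
  if (cutoff_fraction < 0 || cutoff_fraction > 1) {
    stop_invalid("cutoff_fraction must be in [0, 1]")
  }
  K <- dim(spec$coeffs)[3L]
  n_keep <- ceiling(cutoff_fraction * K)
  if (n_keep < K) {
    spec$coeffs[, , (n_keep + 1L):K] <- 0i
  }
  spec
}

#' Phase perturbation preserving the magnitude spectrum
#'
#' Per window and channel, every perturbable bin's phase receives i.i.d.
#' Gaussian noise of sd `noise_sd`, and a single global shift drawn uniformly
#' from `(-pi, pi)` per window is added on top. Magnitudes are untouched.
#' The DC bin (and the Nyquist bin for even `T`) must stay real for the
#' inverse to be a real signal, so they are excluded from perturbation.
#'
#' @param spec a [spectrum_batch()].
#' @param noise_sd Gaussian phase noise sd in radians (>= 0).
#' @param global_shift draw the additional uniform `(-pi, pi)` per-window
#'   shift (default `TRUE`).
#' @return A [spectrum_batch()] with identical magnitude spectrum.
#' @export
phase_shift <- function(spec, noise_sd = 0.1, global_shift = TRUE) {
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  d <- dim(spec$coeffs)
  N <- d[1L]; S <- d[2L]; K <- d[3L]
  even <- spec$origin_length %% 2L == 0L
  bins <- setdiff(seq_len(K), c(1L, if (even) K))
  if (!length(bins)) return(spec)
  for (i in seq_len(N)) {
    delta <- if (global_shift) stats::runif(1L, -pi, pi) else 0
    for (s in seq_len(S)) {
      z <- spec$coeffs[i, s, bins]
      eps <- if (noise_sd > 0) stats::rnorm(length(bins), sd = noise_sd) else 0
      spec$coeffs[i, s, bins] <- z * exp(1i * (eps + delta))
    }
  }
  spec
}

#' Remove frequency components
#'
#' Exactly `floor(fraction * K)` bins per window-channel, chosen uniformly
#' without replacement, are zeroed.
#'
#' @param spec a [spectrum_batch()].
#' @param fraction fraction of bins removed, in `[0, 1]`.
#' @return A [spectrum_batch()].
#' @export
remove_frequency <- function(spec, fraction = 0.10) {
  if (fraction < 0 || fraction > 1) stop_invalid("fraction must be in [0, 1]")
  d <- dim(spec$coeffs)
  K <- d[3L]
  m <- floor(fraction * K)
  if (m == 0L) return(spec)
  for (i in seq_len(d[1L])) {
    for (s in seq_len(d[2L])) {
      spec$coeffs[i, s, sample.int(K, m)] <- 0i
    }
  }
  spec
}

#' Add frequency components
#'
#' Exactly `floor(fraction * K)` bins per window-channel receive an additive
#' complex perturbation of magnitude `noise_scale` times the channel's
#' maximum bin magnitude, at a uniform random phase. Perturbations to the DC
#' bin (and Nyquist bin for even `T`) are real-valued so the inverse remains
#' a real signal.
#'
#' @param spec a [spectrum_batch()].
#' @param fraction fraction of bins perturbed, in `[0, 1]`.
#' @param noise_scale perturbation magnitude relative to the per-channel
#'   maximum bin magnitude (>= 0).
#' @return A [spectrum_batch()].
#' @export
add_frequency <- function(spec, fraction = 0.10, noise_scale = 0.1) {
  if (fraction < 0 || fraction > 1) stop_invalid("fraction must be in [0, 1]")
  if (noise_scale < 0) stop_invalid("noise_scale must be >= 0")
  d <- dim(spec$coeffs)
  K <- d[3L]
  m <- floor(fraction * K)
  if (m == 0L) return(spec)
  even <- spec$origin_length %% 2L == 0L
  real_bins <- c(1L, if (even) K)
  for (i in seq_len(d[1L])) {
    for (s in seq_len(d[2L])) {
      idx <- sample.int(K, m)
      amp <- noise_scale * max(Mod(spec$coeffs[i, s, ]))
      phi <- stats::runif(m, 0, 2 * pi)
      pert <- amp * exp(1i * phi)
      pert[idx %in% real_bins] <- amp * cos(phi[idx %in% real_bins])
      spec$coeffs[i, s, idx] <- spec$coeffs[i, s, idx] + pert
    }
  }
  spec
}

#' Apply the frequency-domain augmentation bank
#'
#' Transforms each window to its one-sided spectrum, fires each of the four
#' spectral operators independently with probability `cfg$p_apply` in the
#' fixed order low-pass -> phase shift -> remove -> add, and inverse
#' transforms back to the time domain. Per-window RNG substreams are derived
#' from `(cfg$seed, stream, window index)` as in the time bank.
#'
#' @param batch a [window_batch()].
#' @param cfg a [freq_aug_config()].
#' @param stream integer substream id (default 0).
#' @param indices integer ids used to key each window's RNG substream
#'   (default `1:N`); pass absolute dataset indices so a window's draw does
#'   not depend on batch composition.
#' @return A real-valued [window_batch()] of the original shape, with the
#'   `N x 4` firing matrix attached as attribute `"fired"`.
#' @export
apply_freq_bank <- function(batch, cfg = freq_aug_config(), stream = 0L,
                            indices = NULL) {
  stopifnot(inherits(cfg, "freq_aug_config"))
  N <- n_windows(batch)
  if (is.null(indices)) indices <- seq_len(N)
  spec <- forward_transform(batch)
  fired <- matrix(FALSE, N, 4L,
                  dimnames = list(NULL, c("lowpass", "phase", "remove", "add")))
  for (i in seq_len(N)) {
    one <- spectrum_batch(spec$coeffs[i, , , drop = FALSE], spec$origin_length)
    res <- with_seed(mix_seed(cfg$seed, 2027L, stream, indices[i]), {
      f <- stats::runif(4L) < cfg$p_apply
      if (f[1L]) one <- lowpass(one, cfg$cutoff_fraction)
      if (f[2L]) one <- phase_shift(one, cfg$phase_noise_sd)
      if (f[3L]) one <- remove_frequency(one, cfg$remove_fraction)
      if (f[4L]) one <- add_frequency(one, cfg$add_fraction, cfg$add_noise_scale)
      list(one = one, f = f)
    })
    fired[i, ] <- res$f
    spec$coeffs[i, , ] <- res$one$coeffs[1L, , ]
  }
  out <- inverse_transform(spec)
  out$y <- batch$y
  out$meta <- batch$meta
  attr(out, "fired") <- fired
  out
}
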
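make_cosine_batch <- function(m, T_len = 64L, amp = 1) {
  t_idx <- 0:(T_len - 1L)
  x <- amp * cos(2 * pi * m * t_idx / T_len)
  window_batch(array(x, c(1L, 1L, T_len)), 0L)
}

test_that("forward transform has the closed-form DFT of simple signals", {
  T_len <- 64L
  const <- window_batch(array(3, c(1L, 1L, T_len)), 0L)
  sp <- forward_transform(const)
  expect_equal(dim(sp$coeffs)[3L], T_len / 2 + 1L)
  expect_equal(Mod(sp$coeffs[1, 1, 1]), 3 * T_len, tolerance = 1e-9)
  expect_lt(max(Mod(sp$coeffs[1, 1, -1])), 1e-9)

  cosb <- make_cosine_batch(5L, T_len)
  spc <- forward_transform(cosb)
  mags <- Mod(spc$coeffs[1, 1, ])
  expect_equal(mags[6L], T_len / 2, tolerance = 1e-9)   # bin m = 5 (0-based)
  expect_lt(max(mags[-6L]), 1e-9)
})

test_that("forward and inverse are mutual inverses with Parseval equality", {
  for (T_len in c(33L, 64L)) {                # odd and even lengths
    set.seed(T_len)
    b <- window_batch(array(rnorm(5 * 2 * T_len), c(5L, 2L, T_len)),
                      rep(0L, 5L))
    sp <- forward_transform(b)
    rt <- inverse_transform(sp)
    expect_lt(max(abs(rt$X - b$X)), 1e-9)
    # Parseval: sum |x|^2 = (1/T) sum over full two-sided spectrum
    x <- as.vector(b$X[1, 1, ])
    full <- stats::fft(x)
    expect_equal(sum(x^2), sum(Mod(full)^2) / T_len, tolerance = 1e-9)
    K <- dim(sp$coeffs)[3L]
    w <- c(1, rep(2, K - 2L), if (T_len %% 2L == 0L) 1 else 2)
    expect_equal(sum(x^2), sum(w * Mod(sp$coeffs[1, 1, ])^2) / T_len,
                 tolerance = 1e-9)
  }
})

test_that("all-zero and DC-only spectra invert to the expected signals", {
  z <- spectrum_batch(array(0i, c(2L, 1L, 17L)), 32L, y = c(0L, 1L))
  out <- inverse_transform(z)
  expect_true(all(out$X == 0))
  dc <- spectrum_batch(array(c(64 * 2 + 0i, rep(0i, 16L)) , c(1L, 1L, 17L)),
                       32L, y = 0L)
  dc$coeffs[1, 1, ] <- c(2 * 32 + 0i, rep(0i, 16L))
  outc <- inverse_transform(dc)
  expect_equal(as.vector(outc$X), rep(2, 32L), tolerance = 1e-9)
})

test_that("lowpass keeps the stated bin count and kills high cosines", {
  cosb <- make_cosine_batch(20L, 64L)        # bin 20 of K = 33
  sp <- forward_transform(cosb)
  filtered <- lowpass(sp, 1)
  expect_identical(filtered$coeffs, sp$coeffs)        # identity at 1
  half <- lowpass(sp, 0.5)                   # keeps bins 0..16
  expect_lt(max(Mod(half$coeffs)), 1e-9)     # bin 20 was the only energy
  sig <- inverse_transform(half)
  expect_lt(max(abs(sig$X)), 1e-9)
  lowcos <- forward_transform(make_cosine_batch(5L, 64L))
  expect_equal(lowpass(lowcos, 0.5)$coeffs, lowcos$coeffs)
})

test_that("phase shift preserves magnitudes and yields a real inverse", {
  set.seed(8)
  b <- window_batch(array(rnorm(4 * 2 * 64), c(4L, 2L, 64L)), rep(0L, 4L))
  sp <- forward_transform(b)
  set.seed(9)
  out <- phase_shift(sp, noise_sd = 0.3)
  expect_equal(Mod(out$coeffs), Mod(sp$coeffs), tolerance = 1e-9)
  # conjugate-symmetry preserved: complex inverse has negligible imaginary part
  z <- tffc:::ifft_complex(out)
  expect_lt(max(abs(Im(z))) / max(abs(Re(z))), 1e-9)
  # zero noise without the global shift is the identity
  same <- phase_shift(sp, noise_sd = 0, global_shift = FALSE)
  expect_equal(same$coeffs, sp$coeffs, tolerance = 1e-12)
  expect_error(phase_shift(sp, -0.1), "noise_sd")
})

test_that("remove_frequency zeroes exactly floor(fraction*K) bins", {
  set.seed(10)
  b <- window_batch(array(rnorm(6 * 2 * 38), c(6L, 2L, 38L)), rep(0L, 6L))
  sp <- forward_transform(b)                  # K = 20
  out <- remove_frequency(sp, 0.1)
  for (i in 1:6) {
    for (s in 1:2) {
      zeroed <- sum(out$coeffs[i, s, ] == 0i & sp$coeffs[i, s, ] != 0i)
      expect_equal(zeroed, 2L)                # floor(0.1 * 20)
    }
  }
  # zeroing never increases spectral energy
  expect_lte(sum(Mod(out$coeffs)^2), sum(Mod(sp$coeffs)^2))
  expect_identical(remove_frequency(sp, 0)$coeffs, sp$coeffs)
})

test_that("add_frequency perturbs exactly floor(fraction*K) bins at the set scale", {
  set.seed(11)
  b <- window_batch(array(rnorm(5 * 1 * 38), c(5L, 1L, 38L)), rep(0L, 5L))
  sp <- forward_transform(b)                  # K = 20
  out <- add_frequency(sp, 0.1, noise_scale = 0.1)
  K <- dim(sp$coeffs)[3L]
  for (i in 1:5) {
    diffs <- Mod(out$coeffs[i, 1, ] - sp$coeffs[i, 1, ])
    changed <- which(diffs > 1e-12)
    expect_equal(length(changed), 2L)
    # interior bins get the full complex perturbation magnitude; DC/Nyquist
    # receive its real part (to keep the inverse real), so bound those
    amp <- 0.1 * max(Mod(sp$coeffs[i, 1, ]))
    interior <- setdiff(changed, c(1L, K))
    expect_equal(unname(diffs[interior]), rep(amp, length(interior)),
                 tolerance = 1e-9)
    expect_true(all(diffs[changed] <= amp + 1e-9))
  }
  expect_identical(add_frequency(sp, 0)$coeffs, sp$coeffs)
  same <- add_frequency(sp, 0.5, noise_scale = 0)
  expect_equal(same$coeffs, sp$coeffs, tolerance = 1e-12)
})

test_that("the spectral bank at p = 0 is a round-trip identity and output is real", {
  b <- tiny_batch(window = 50L, n_channels = 2L)
  none <- apply_freq_bank(b, freq_aug_config(p_apply = 0, seed = 4))
  expect_lt(max(abs(none$X - b$X)), 1e-9)
  out <- apply_freq_bank(b, freq_aug_config(p_apply = 1, seed = 4))
  expect_identical(dim(out$X), dim(b$X))
  expect_true(all(is.finite(out$X)))
  expect_true(all(attr(out, "fired")))
  again <- apply_freq_bank(b, freq_aug_config(p_apply = 1, seed = 4))
  expect_identical(out$X, again$X)
})

test_that("full spectral bank preserves conjugate symmetry for any firing", {
  b <- tiny_batch(window = 64L)
  cfg <- freq_aug_config(p_apply = 1, seed = 6)
  spec <- forward_transform(b)
  # replicate the bank's per-window pipeline and check the complex inverse
  out <- apply_freq_bank(b, cfg)
  spec_out <- forward_transform(out)
  z <- tffc:::ifft_complex(spec_out)
  expect_lt(max(abs(Im(z))) / max(1, max(abs(Re(z)))), 1e-9)
})
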
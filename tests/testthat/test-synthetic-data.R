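test_that("zero-noise windows equal their class templates exactly", {
  b <- generate_dataset(3, 2, n_channels = 2L, window = 64L, noise_sd = 0,
                        seed = 11)
  for (cl in 0:1) {
    tmpl <- class_template(cl, 2, n_channels = 2L, window = 64L, seed = 11)
    for (i in which(b$y == cl)) {
      expect_equal(matrix(b$X[i, , ], nrow = 2), tmpl)
    }
  }
})

test_that("generation is bit-identical under a fixed seed and balanced", {
  a <- generate_dataset(5, 3, window = 32L, noise_sd = 0.4, seed = 42)
  b <- generate_dataset(5, 3, window = 32L, noise_sd = 0.4, seed = 42)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  expect_equal(unname(table(a$y)), rep(5L, 3L), ignore_attr = TRUE)
  c <- generate_dataset(5, 3, window = 32L, noise_sd = 0.4, seed = 43)
  expect_false(identical(a$X, c$X))
})

test_that("additive noise matches the stated Gaussian law", {
  sd0 <- 0.1
  b <- generate_dataset(200, 2, window = 64L, noise_sd = sd0, seed = 5)
  resid <- c()
  for (cl in 0:1) {
    tmpl <- class_template(cl, 2, window = 64L, seed = 5)
    idx <- which(b$y == cl)
    resid <- c(resid, as.vector(b$X[idx, , ] -
      matrix(tmpl, length(idx), 64L, byrow = TRUE)))
  }
  # variance of n iid N(0, sd^2) samples: SE(var) ~ sd^2 * sqrt(2/n)
  n <- length(resid)
  expect_lt(abs(var(resid) - sd0^2), 3 * sd0^2 * sqrt(2 / n))
  expect_lt(abs(mean(resid)), 3 * sd0 / sqrt(n))
})

test_that("generator rejects invalid arguments", {
  expect_error(generate_dataset(0, 3), "positive")
  expect_error(generate_dataset(5, 1), "positive|n_classes")
  expect_error(generate_dataset(5, 2, noise_sd = -0.1), "noise_sd")
  expect_error(generate_dataset(5, 2, window = 8L), "window")
})

test_that("sliding windows enumerate the documented start offsets", {
  rec <- raw_recording(matrix(rnorm(3000), nrow = 1), label = 2L)
  w <- sliding_windows(rec, 3000, overlap = 0.5)
  expect_equal(n_windows(w), 1L)

  rec2 <- raw_recording(matrix(seq_len(356), nrow = 1), label = 1L)
  w2 <- sliding_windows(rec2, 178, overlap = 0.75)   # stride 44
  expect_equal(n_windows(w2), 5L)
  expect_equal(attr(w2, "starts"), seq.int(0L, 176L, by = 44L))
  expect_true(all(dim(w2$X)[3] == 178L))
  expect_true(all(w2$y == 1L))
  # every window is the contiguous slice its start offset claims
  for (i in seq_len(5)) {
    s <- attr(w2, "starts")[i]
    expect_equal(as.vector(w2$X[i, 1, ]), as.numeric((s + 1):(s + 178)))
  }
})

test_that("sliding windows reject windows longer than the recording", {
  rec <- raw_recording(matrix(rnorm(100), nrow = 1))
  expect_error(sliding_windows(rec, 101), "exceeds")
  expect_error(sliding_windows(rec, 50, overlap = 1), "overlap")
})

test_that("stratified split matches 60/20/20, partitions exactly, is seeded", {
  b <- generate_dataset(50, 2, window = 32L, seed = 3)   # N = 100
  sp <- split_dataset(b, c(0.6, 0.2, 0.2), seed = 9)
  expect_equal(n_windows(sp$pretrain), 60L)
  expect_equal(n_windows(sp$finetune), 20L)
  expect_equal(n_windows(sp$test), 20L)
  # stratification: class balance preserved in every split
  for (s in sp) expect_equal(unname(table(s$y)[1]), unname(table(s$y)[2]))
  # exact partition: window multiset identical to the input
  key <- function(batch) sort(apply(flatten_windows(batch), 1, paste, collapse = ","))
  expect_identical(key(b),
                   sort(c(key(sp$pretrain), key(sp$finetune), key(sp$test))))
  sp2 <- split_dataset(b, c(0.6, 0.2, 0.2), seed = 9)
  expect_identical(sp$pretrain$X, sp2$pretrain$X)
  sp3 <- split_dataset(b, c(0.6, 0.2, 0.2), seed = 10)
  expect_false(identical(sp$pretrain$X, sp3$pretrain$X))
})

test_that("degenerate split fractions are rejected", {
  b <- generate_dataset(10, 2, window = 32L, seed = 3)
  expect_error(split_dataset(b, c(1, 0, 0)), "inside")
  expect_error(split_dataset(b, c(0.5, 0.3, 0.3)), "sum")
  tiny <- generate_dataset(2, 2, window = 32L, seed = 3)
  expect_error(split_dataset(tiny), "stratify")
})

test_that("nearest-template classification is perfect at zero noise", {
  b <- generate_dataset(10, 4, window = 64L, noise_sd = 0, seed = 21)
  tmpl <- sapply(0:3, function(cl)
    as.vector(class_template(cl, 4, window = 64L, seed = 21)))
  flat <- flatten_windows(b)
  pred <- apply(flat, 1, function(x)
    which.min(colSums((tmpl - x)^2)) - 1L)
  expect_equal(pred, b$y)
})

test_that("spectral-only and temporal-only cue modes isolate their cue", {
  sp0 <- class_template(0, 3, window = 128L, seed = 2, cues = "spectral")
  sp1 <- class_template(1, 3, window = 128L, seed = 2, cues = "spectral")
  # spectral-only templates have class-distinct dominant frequencies
  dom <- function(x) which.max(Mod(stats::fft(as.vector(x))[2:64]))
  expect_false(dom(sp0) == dom(sp1))
  te0 <- class_template(0, 3, window = 128L, seed = 2, cues = "temporal")
  # temporal-only templates are 0/1 pulses
  expect_setequal(unique(as.vector(te0)), c(0, 1))
})

test_that("dataset round-trips through the CSV format", {
  b <- generate_dataset(4, 2, n_channels = 2L, window = 32L, noise_sd = 0.2,
                        seed = 13)
  path <- tempfile(fileext = ".csv")
  write_window_batch(b, path)
  r <- read_window_batch(path)
  expect_equal(r$X, b$X, tolerance = 1e-12)
  expect_identical(r$y, b$y)
  expect_identical(r$meta$window, b$meta$window)
  unlink(path)
})
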
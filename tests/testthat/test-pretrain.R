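test_that("single-pair loss has its closed-form values", {
  # N = 1: the denominator holds only the positive term, so the loss is 0
  Z <- rbind(c(1, 0), c(1, 0))
  expect_equal(nt_xent_pair(1L, 2L, Z, temperature = 0.7), 0, tolerance = 1e-12)
  # tau = 1, N = 2, views {e, e} and {e', e'}: every pair loss log(1 + 2/e)
  Z4 <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  want <- log(1 + 2 / exp(1))
  expect_equal(nt_xent_pair(1L, 3L, Z4, 1), want, tolerance = 1e-9)
  expect_equal(nt_xent_pair(3L, 1L, Z4, 1), want, tolerance = 1e-9)
  expect_equal(nt_xent_batch(Z4[1:2, ], Z4[3:4, ], 1), want, tolerance = 1e-9)
})

test_that("identical projections give loss log(2N - 1)", {
  for (N in c(2L, 5L, 9L)) {
    v <- matrix(rep(c(0.3, -0.2, 0.5), each = N), N, 3L)
    expect_equal(nt_xent_batch(v, v, temperature = 0.37), log(2 * N - 1),
                 tolerance = 1e-9)
  }
})

test_that("batch loss matches the brute-force double-loop oracle", {
  set.seed(31)
  for (rep in 1:8) {
    N <- sample(2:16, 1)
    P <- sample(2:8, 1)
    tau <- runif(1, 0.1, 1)
    a <- matrix(rnorm(N * P), N, P)
    b <- matrix(rnorm(N * P), N, P)
    expect_equal(nt_xent_batch(a, b, tau), ntxent_oracle_batch(a, b, tau),
                 tolerance = 1e-9)
  }
})

test_that("loss falls as the positive similarity rises, negatives fixed", {
  base <- rbind(c(1, 0), c(0, 1))
  angles <- c(pi / 2, pi / 3, pi / 6, 0.01)
  losses <- sapply(angles, function(a) {
    v2 <- rbind(c(cos(a), sin(a)), c(0, 1))
    nt_xent_pair(1L, 3L, rbind(base, v2), 0.5)
  })
  expect_true(all(diff(losses) < 0))
})

test_that("loss is invariant to joint pair permutation and rotation", {
  set.seed(32)
  N <- 6L
  a <- matrix(rnorm(N * 4), N)
  b <- matrix(rnorm(N * 4), N)
  perm <- sample(N)
  expect_equal(nt_xent_batch(a, b, 0.2),
               nt_xent_batch(a[perm, ], b[perm, ], 0.2), tolerance = 1e-12)
  # common rotation of all projections (cosine similarity is rotation-invariant)
  Q <- qr.Q(qr(matrix(rnorm(16), 4L)))
  expect_equal(nt_xent_batch(a, b, 0.2),
               nt_xent_batch(a %*% Q, b %*% Q, 0.2), tolerance = 1e-9)
})

test_that("loss gradient matches finite differences and flags zero vectors", {
  set.seed(33)
  a <- matrix(rnorm(12), 4L)
  b <- matrix(rnorm(12), 4L)
  g <- nt_xent_batch(a, b, 0.3, grad = TRUE)
  h <- 1e-6
  for (idx in sample(12L, 4L)) {
    ap <- a; ap[idx] <- a[idx] + h
    am <- a; am[idx] <- a[idx] - h
    num <- (nt_xent_batch(ap, b, 0.3) - nt_xent_batch(am, b, 0.3)) / (2 * h)
    expect_equal(g$grad_a[idx], num, tolerance = 1e-5)
  }
  azero <- a; azero[2, ] <- 0
  expect_error(nt_xent_batch(azero, b, 0.3), "zero-norm")
  expect_error(nt_xent_batch(a, b, 0), "temperature")
  expect_error(nt_xent_batch(a, b[1:3, ], 0.3), "dimensions")
})

make_pretrain_fixture <- function(seed = 51, n_per_class = 20L) {
  b <- generate_dataset(n_per_class, 3L, window = 32L, noise_sd = 0.5,
                        seed = seed)
  tc <- time_aug_config(seed = seed + 1L)
  fc <- freq_aug_config(seed = seed + 2L)
  fm <- fit_fusion_on_pretrain(b, fusion_model(fit_seed = seed), tc, fc)
  m <- init_model(1L, tiny_encoder_config(), seed = seed + 3L)
  list(b = b, tc = tc, fc = fc, fm = fm, m = m)
}

test_that("pre-training records one loss per epoch and decreases it", {
  fx <- make_pretrain_fixture(n_per_class = 100L)
  cfg <- pretrain_config(batch_size = 128L, epochs = 15L, mode = "tf-fc",
                         seed = 61)
  m <- pretrain(fx$b, fx$m, cfg, fx$fm, fx$tc, fx$fc)
  expect_length(m$pretrain_history, 15L)
  expect_lt(m$pretrain_history[15L], m$pretrain_history[1L])
})

test_that("pre-training is bit-reproducible under a fixed seed", {
  fx <- make_pretrain_fixture()
  cfg <- pretrain_config(batch_size = 30L, epochs = 3L, mode = "time-only",
                         seed = 62)
  m1 <- pretrain(fx$b, fx$m, cfg, NULL, fx$tc, fx$fc)
  m2 <- pretrain(fx$b, fx$m, cfg, NULL, fx$tc, fx$fc)
  expect_identical(m1$pretrain_history, m2$pretrain_history)
  expect_identical(m1$params$encoder$fc$W, m2$params$encoder$fc$W)
})

test_that("tf-fc mode insists on a fitted fusion model", {
  fx <- make_pretrain_fixture()
  cfg <- pretrain_config(batch_size = 30L, epochs = 1L, mode = "tf-fc", seed = 63)
  expect_error(pretrain(fx$b, fx$m, cfg, NULL, fx$tc, fx$fc), "fusion")
  expect_error(pretrain(fx$b, fx$m, cfg, fusion_model(), fx$tc, fx$fc), "fusion")
})

test_that("pre-trained embeddings beat random-init under a linear probe", {
  skip_if_not_installed("nnet")
  # conditions where the property is measurable: moderate noise (so the
  # class cues survive the augmentation banks) and a contrastive batch
  # small enough that 40 epochs give the pretext optimizer several hundred
  # updates; at high noise the banks perturb exactly the discriminative
  # structure and the embedding's linear geometry stops improving
  accs <- matrix(0, 3L, 2L)
  for (s in 1:3) {
    b <- generate_dataset(60L, 3L, window = 64L, noise_sd = 0.5,
                          seed = 70 + s)
    sp <- split_dataset(b, seed = 80 + s)
    tc <- time_aug_config(seed = s)
    fc <- freq_aug_config(seed = s + 1L)
    fm <- fit_fusion_on_pretrain(sp$pretrain, fusion_model(fit_seed = s), tc, fc)
    m0 <- init_model(1L, bench_encoder_config(), seed = 90 + s)
    m0c <- calibrate_bn(m0, sp$pretrain)
    cfg <- pretrain_config(batch_size = 16L, epochs = 40L, mode = "tf-fc",
                           seed = 100 + s)
    m1 <- pretrain(sp$pretrain, m0, cfg, fm, tc, fc)
    probe_acc <- function(model) {
      tr <- as.data.frame(encode(sp$finetune, model))
      te <- as.data.frame(encode(sp$test, model))
      fit <- nnet::multinom(y ~ ., cbind(y = factor(sp$finetune$y), tr),
                            trace = FALSE, MaxNWts = 5000)
      mean(predict(fit, te) == factor(sp$test$y))
    }
    accs[s, ] <- c(probe_acc(m1), probe_acc(m0c))
  }
  expect_gt(mean(accs[, 1L]), mean(accs[, 2L]))
})
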
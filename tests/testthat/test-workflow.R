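# A configuration small enough for repeated end-to-end runs in tests.
smoke_config <- function(seed = 1L, mode = "tf-fc") {
  default_config(
    seed = seed,
    data = list(n_per_class = 15L, n_classes = 2L, window = 32L),
    model = list(channels = c(4L, 6L, 8L), kernel = 3L,
                 embed_dim = 8L, proj_dim = 4L),
    fusion = list(n_components = 8L),
    pretrain = list(mode = mode, batch_size = 16L, epochs = 2L),
    finetune = list(epochs = 5L)
  )
}

test_that("a full run produces a report and all persisted artifacts", {
  out <- tempfile("run")
  res <- run_experiment(smoke_config(), out_dir = out)
  expect_s3_class(res$report, "metrics_report")
  expect_true(res$report$accuracy >= 0 && res$report$accuracy <= 1)
  files <- c("dataset.csv", "model.rds", "pretrain_loss.csv",
             "report.json", "confusion.csv", "manifest.json")
  expect_true(all(file.exists(file.path(out, files))))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$mode, "tf-fc")
  expect_equal(manifest$seed, 1L)
  expect_match(manifest$config_hash, "^[0-9a-f]{32}$")
  unlink(out, recursive = TRUE)
})

test_that("identical configurations reproduce bit-identical reports", {
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  run_experiment(smoke_config(seed = 5L), out_dir = out1)
  run_experiment(smoke_config(seed = 5L), out_dir = out2)
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  expect_identical(tools::md5sum(file.path(out1, "dataset.csv"))[[1]],
                   tools::md5sum(file.path(out2, "dataset.csv"))[[1]])
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("a failing stage names itself", {
  cfg <- smoke_config()
  cfg$data$n_per_class <- 2L      # too few windows to stratify 60/20/20
  expect_error(run_experiment(cfg), "stage 'generate'")
})

test_that("the ablation table covers each mode on the shared dataset", {
  cfg <- smoke_config(seed = 9L)
  tab <- ablate(cfg, c("time-only", "freq-only"))
  expect_equal(tab$mode, c("time-only", "freq-only"))
  expect_named(tab, c("mode", "accuracy", "precision", "f1"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_match(attr(tab, "dataset_hash"), "^[0-9a-f]{32}$")
  expect_error(ablate(cfg, "tf-fc"), "two modes")
  expect_error(ablate(cfg, c("tf-fc", "nope")), "unknown mode")
})

test_that("frequency cues favor the frequency-only mode on spectral-only data", {
  # classes that differ only in spectral content: the frequency bank
  # perturbs exactly the discriminative cue, time-only leaves it intact
  accs <- matrix(0, 2L, 2L,
                 dimnames = list(NULL, c("freq-only", "time-only")))
  for (s in 1:2) {
    cfg <- smoke_config(seed = 20L + s)
    cfg$data$cues <- "spectral"
    cfg$data$n_per_class <- 30L
    cfg$pretrain$epochs <- 8L
    for (mode in colnames(accs)) {
      cfg$pretrain$mode <- mode
      accs[s, mode] <- run_experiment(cfg)$report$accuracy
    }
  }
  expect_gte(mean(accs[, "freq-only"]), mean(accs[, "time-only"]) - 0.02)
})

test_that("YAML configs round-trip through read_config", {
  cfg <- smoke_config(seed = 3L)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 3L,
                        data = list(n_per_class = 15L, n_classes = 2L,
                                    window = 32L),
                        pretrain = list(epochs = 2L)), path)
  got <- read_config(path)
  expect_s3_class(got, "run_config")
  expect_equal(got$data$n_per_class, 15L)
  expect_equal(got$pretrain$epochs, 2L)
  expect_equal(got$pretrain$mode, "tf-fc")      # default preserved
  expect_equal(got$augment$time$p, 0.25)
  unlink(path)
})

test_that("the CLI chains pretrain, finetune and evaluate on files", {
  script <- system.file("cli", "tffc.R", package = "tffc")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  wd <- tempfile("clichain"); dir.create(wd)
  data_csv <- file.path(wd, "data.csv")
  cfg_file <- file.path(wd, "cfg.yaml")
  yaml::write_yaml(list(
    model = list(channels = c(4L, 6L, 8L), kernel = 3L,
                 embed_dim = 8L, proj_dim = 4L),
    fusion = list(n_components = 8L)
  ), cfg_file)
  run <- function(...) system2("Rscript", c(script, ...), env = env,
                               stdout = TRUE, stderr = TRUE)
  run("generate", "--classes", "2", "--per-class", "10", "--window", "32",
      "--seed", "3", "--out", data_csv)
  ckpt <- file.path(wd, "ckpt.rds")
  run("pretrain", "--data", data_csv, "--mode", "tf-fc", "--epochs", "2",
      "--batch", "16", "--seed", "3", "--config", cfg_file, "--out", ckpt)
  expect_true(file.exists(ckpt))
  expect_true(file.exists(file.path(wd, "ckpt_loss.csv")))
  model_rds <- file.path(wd, "model.rds")
  run("finetune", "--ckpt", ckpt, "--data", data_csv, "--epochs", "5",
      "--seed", "3", "--out", model_rds)
  report_json <- file.path(wd, "report.json")
  run("evaluate", "--model", model_rds, "--data", data_csv,
      "--report", report_json)
  expect_true(file.exists(report_json))
  rep <- jsonlite::read_json(report_json)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_equal(rep$averaging, "macro")
  expect_length(rep$confusion, 2L)
  unlink(wd, recursive = TRUE)
})

test_that("the CLI generates deterministic datasets from a subprocess", {
  script <- system.file("cli", "tffc.R", package = "tffc")
  expect_true(nzchar(script))
  out1 <- tempfile(fileext = ".csv"); out2 <- tempfile(fileext = ".csv")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  for (out in c(out1, out2)) {
    status <- system2("Rscript", c(script, "generate", "--classes", "2",
                                   "--per-class", "5", "--window", "32",
                                   "--seed", "4", "--out", out),
                      env = env, stdout = TRUE, stderr = TRUE)
  }
  expect_true(file.exists(out1) && file.exists(out2))
  expect_identical(tools::md5sum(out1)[[1]], tools::md5sum(out2)[[1]])
  b <- read_window_batch(out1)
  expect_equal(n_windows(b), 10L)
  unlink(c(out1, out2))
})
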
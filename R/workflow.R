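#' Default end-to-end run configuration
#'
#' Nested configuration for [run_experiment()]. Every experimental constant
#' of the method appears here as a default: per-operator firing probability
#' 0.25, jitter sd 0.01, scaling range (0.9, 1.1), 10% mask/remove/add
#' fractions, pretext Adam with learning rate `1e-4` and decay rates
#' (0.9, 0.99) for 100 epochs with L2 regularization, a 256/128 ReLU head
#' with dropout 0.2, and a 60/20/20 pretrain/finetune/test split.
#'
#' @param ... named overrides merged recursively into the defaults, e.g.
#'   `default_config(pretrain = list(epochs = 5))`.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    data = list(n_per_class = 100L, n_classes = 3L, n_channels = 1L,
                window = 128L, noise_sd = 0.5, cues = "both",
                split = c(0.6, 0.2, 0.2)),
    augment = list(
      time = list(p = 0.25, jitter_sd = 0.01, scale_range = c(0.9, 1.1),
                  n_segments = 4L, mask_fraction = 0.10, mask_value = 0),
      freq = list(p = 0.25, cutoff_fraction = 0.5, phase_noise_sd = 0.1,
                  remove_fraction = 0.10, add_fraction = 0.10,
                  add_noise_scale = 0.1)
    ),
    fusion = list(kernel = "rbf", gamma = NULL, n_components = NULL,
                  fit_cap = 1000L),
    model = list(channels = c(32L, 64L, 128L), kernel = 7L,
                 embed_dim = 128L, proj_dim = 64L),
    pretrain = list(mode = "tf-fc", temperature = 0.2, batch_size = 128L,
                    epochs = 100L, learning_rate = 1e-4,
                    l2_coefficient = 1e-5),
    finetune = list(epochs = 50L, batch_size = 32L, learning_rate = 1e-4,
                    freeze_encoder = FALSE, patience = 10L)
  )
  structure(merge_config(cfg, list(...)), class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration from a YAML file
#' @param path YAML file; keys mirror [default_config()].
#' @return A `run_config` with file values layered over the defaults.
#' @export
read_config <- function(path) {
  override <- yaml::read_yaml(path)
  structure(merge_config(default_config(), override), class = "run_config")
}

config_objects <- function(cfg) {
  list(
    time_cfg = time_aug_config(
      p_apply = cfg$augment$time$p, jitter_sd = cfg$augment$time$jitter_sd,
      scale_low = cfg$augment$time$scale_range[1L],
      scale_high = cfg$augment$time$scale_range[2L],
      n_segments = cfg$augment$time$n_segments,
      mask_fraction = cfg$augment$time$mask_fraction,
      mask_value = cfg$augment$time$mask_value,
      seed = mix_seed(cfg$seed, 11L)),
    freq_cfg = freq_aug_config(
      p_apply = cfg$augment$freq$p,
      cutoff_fraction = cfg$augment$freq$cutoff_fraction,
      phase_noise_sd = cfg$augment$freq$phase_noise_sd,
      remove_fraction = cfg$augment$freq$remove_fraction,
      add_fraction = cfg$augment$freq$add_fraction,
      add_noise_scale = cfg$augment$freq$add_noise_scale,
      seed = mix_seed(cfg$seed, 13L)),
    fusion = fusion_model(kernel = cfg$fusion$kernel, gamma = cfg$fusion$gamma,
                          n_components = cfg$fusion$n_components,
                          fit_cap = cfg$fusion$fit_cap,
                          fit_seed = mix_seed(cfg$seed, 17L)),
    enc_cfg = encoder_config(channels = cfg$model$channels,
                             kernel = cfg$model$kernel,
                             embed_dim = cfg$model$embed_dim,
                             proj_dim = cfg$model$proj_dim)
  )
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

report_to_list <- function(report, extra = list()) {
  c(list(accuracy = report$accuracy, precision = report$precision,
         recall = report$recall, f1 = report$f1,
         averaging = report$averaging,
         confusion = apply(report$confusion, 1L, identity, simplify = FALSE)),
    extra)
}

#' Run the full pipeline: generate, pretrain, fine-tune, evaluate
#'
#' Executes the end-to-end study on synthetic data: dataset generation,
#' stratified 60/20/20 split, kernel-PCA fusion fit (in `"tf-fc"` mode),
#' contrastive pre-training, supervised fine-tuning, and evaluation on the
#' held-out test split. All stages derive their seeds from `cfg$seed`, so a
#' repeated run reproduces the metrics report bit-for-bit.
#'
#' @param cfg a [default_config()] / [read_config()] configuration.
#' @param out_dir optional directory; when given, the dataset
#'   (`dataset.csv`), checkpoint (`ckpt.rds`), fine-tuned model
#'   (`model.rds`), per-epoch loss log (`pretrain_loss.csv`), metrics report
#'   (`report.json`, plus `confusion.csv`) and a manifest (`manifest.json`,
#'   config hash + seeds + package version) are persisted there.
#' @param pretrained optionally reuse an already pre-trained model and skip
#'   the generation/pretrain stages' model fitting (internal use by
#'   [ablate()]).
#' @return A list with `report` ([metrics_report()]), `model`, `splits`,
#'   `config` and `manifest`.
#' @export
run_experiment <- function(cfg = default_config(), out_dir = NULL,
                           pretrained = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "generate"
  timings <- c()
  tick <- function() Sys.time()
  tock <- function(t0, name) {
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  }
  result <- tryCatch({
    t0 <- tick()
    obj <- config_objects(cfg)
    dataset <- generate_dataset(cfg$data$n_per_class, cfg$data$n_classes,
                                cfg$data$n_channels, cfg$data$window,
                                cfg$data$noise_sd, seed = cfg$seed,
                                cues = cfg$data$cues)
    splits <- split_dataset(dataset, cfg$data$split,
                            seed = mix_seed(cfg$seed, 19L))
    tock(t0, "generate")
    stage <- "pretrain"
    t0 <- tick()
    fusion <- NULL
    if (is.null(pretrained)) {
      if (cfg$pretrain$mode == "tf-fc") {
        fusion <- fit_fusion_on_pretrain(splits$pretrain, obj$fusion,
                                         obj$time_cfg, obj$freq_cfg)
      }
      model <- init_model(cfg$data$n_channels, obj$enc_cfg,
                          seed = mix_seed(cfg$seed, 23L))
      pcfg <- pretrain_config(
        temperature = cfg$pretrain$temperature,
        batch_size = min(cfg$pretrain$batch_size, n_windows(splits$pretrain)),
        epochs = cfg$pretrain$epochs,
        learning_rate = cfg$pretrain$learning_rate,
        l2_coefficient = cfg$pretrain$l2_coefficient,
        mode = cfg$pretrain$mode, seed = mix_seed(cfg$seed, 29L))
      model <- pretrain(splits$pretrain, model, pcfg, fusion,
                        obj$time_cfg, obj$freq_cfg)
    } else {
      model <- pretrained
    }
    tock(t0, "pretrain")
    stage <- "finetune"
    t0 <- tick()
    model <- finetune(model, splits$finetune,
                      head_cfg = head_config(cfg$data$n_classes),
                      epochs = cfg$finetune$epochs,
                      batch_size = cfg$finetune$batch_size,
                      learning_rate = cfg$finetune$learning_rate,
                      freeze_encoder = cfg$finetune$freeze_encoder,
                      patience = cfg$finetune$patience,
                      seed = mix_seed(cfg$seed, 31L))
    tock(t0, "finetune")
    stage <- "evaluate"
    t0 <- tick()
    report <- evaluate_model(model, splits$test)
    tock(t0, "evaluate")
    manifest <- list(config_hash = config_hash(unclass(cfg)),
                     seed = cfg$seed, mode = cfg$pretrain$mode,
                     package_version = as.character(utils::packageVersion("tffc")),
                     n_pretrain = n_windows(splits$pretrain),
                     n_finetune = n_windows(splits$finetune),
                     n_test = n_windows(splits$test),
                     stage_seconds = as.list(timings))
    list(report = report, model = model, splits = splits, config = cfg,
         manifest = manifest, dataset = dataset)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_window_batch(result$dataset, file.path(out_dir, "dataset.csv"))
    saveRDS(result$model, file.path(out_dir, "model.rds"))
    utils::write.csv(
      data.frame(epoch = seq_along(result$model$pretrain_history),
                 loss = result$model$pretrain_history),
      file.path(out_dir, "pretrain_loss.csv"), row.names = FALSE)
    jsonlite::write_json(report_to_list(result$report,
                                        extra = result$manifest["mode"]),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(result$report$confusion),
                     file.path(out_dir, "confusion.csv"), row.names = FALSE)
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result[c("report", "model", "splits", "config", "manifest")]
}

#' Ablation sweep over augmentation modes
#'
#' Runs [run_experiment()] once per mode with the identical dataset, splits
#' and seeds (only the augmented-view construction differs) and tabulates
#' accuracy, macro precision and macro F1 side by side.
#'
#' @param cfg a [default_config()] configuration.
#' @param modes character vector of at least two of
#'   `"tf-fc"`, `"time-only"`, `"freq-only"`.
#' @return A data frame with one row per mode and columns
#'   `mode`, `accuracy`, `precision`, `f1`, plus the shared dataset MD5 in
#'   attribute `"dataset_hash"`.
#' @export
ablate <- function(cfg = default_config(),
                   modes = c("tf-fc", "time-only", "freq-only")) {
  if (length(modes) < 2L) stop_invalid("need at least two modes")
  bad <- setdiff(modes, c("tf-fc", "time-only", "freq-only"))
  if (length(bad)) stop_invalid("unknown mode '%s'", bad[1L])
  rows <- vector("list", length(modes))
  hash <- NULL
  for (m in seq_along(modes)) {
    cfg_m <- cfg
    cfg_m$pretrain$mode <- modes[m]
    res <- run_experiment(cfg_m)
    tmp <- tempfile(fileext = ".csv")
    write_window_batch(res$splits$pretrain, tmp)
    h <- unname(tools::md5sum(tmp))
    unlink(tmp)
    if (is.null(hash)) hash <- h
    stopifnot(identical(hash, h))  # modes must share the data
    rows[[m]] <- data.frame(mode = modes[m],
                            accuracy = res$report$accuracy,
                            precision = res$report$precision,
                            f1 = res$report$f1)
  }
  out <- do.call(rbind, rows)
  attr(out, "dataset_hash") <- hash
  out
}
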
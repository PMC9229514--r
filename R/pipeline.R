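# --- pipeline stages and configuration ------------------------------------
#
# Single entry point wiring the modules: simulate -> preprocess -> summarize
# -> train -> evaluate (plus dump-patches for debugging). Configuration is a
# JSON file; every stage writes its artifacts under `output_dir` together
# with a run manifest (config snapshot, seeds, package version, timestamps)
# so outputs are traceable to the configuration that produced them.

pipeline_stages <- c("simulate", "preprocess", "summarize", "train",
                     "evaluate", "dump-patches")

read_config <- function(config_path) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  required <- c("seed", "output_dir")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing required key(s): ", paste(missing, collapse = ", "))
  cfg
}

cfg_get <- function(cfg, section, key, default) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

write_run_manifest <- function(cfg, stage, dir) {
  manifest <- list(stage = stage,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package_version = as.character(utils::packageVersion("unet3d")),
                   seed = cfg$seed,
                   config = cfg)
  jsonlite::write_json(manifest, file.path(dir, paste0("run_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

cfg_phantom_config <- function(cfg) {
  phantom_config(
    volume_shape = cfg_get(cfg, "simulate", "volume_shape", c(96L, 96L, 96L)),
    n_volumes = cfg_get(cfg, "simulate", "n_volumes", 10L),
    tumor_radius_range = cfg_get(cfg, "simulate", "tumor_radius_range", c(5, 12)),
    tumor_count_range = cfg_get(cfg, "simulate", "tumor_count_range", c(1L, 3L)),
    noise_sd = cfg_get(cfg, "simulate", "noise_sd", 0.3),
    seed = cfg$seed)
}

cfg_network_spec <- function(cfg) {
  ps <- cfg_get(cfg, "network", "patch_size", 64L)
  network_spec(input_shape = c(rep(as.integer(ps), 3L),
                               cfg_get(cfg, "network", "channels", 4L)),
               base_channels = cfg_get(cfg, "network", "base_channels", 32L),
               leaky_slope = cfg_get(cfg, "network", "leaky_slope", 0))
}

cfg_patch_spec <- function(cfg) {
  patch_spec(
    patch_size = cfg_get(cfg, "network", "patch_size", 64L),
    patches_per_image = cfg_get(cfg, "train", "patches_per_image", 16L),
    batch_size = cfg_get(cfg, "train", "mini_batch_size", 8L))
}

cfg_train_config <- function(cfg) {
  train_config(
    initial_lr = cfg_get(cfg, "train", "initial_lr", 5e-4),
    max_epochs = cfg_get(cfg, "train", "max_epochs", 100L),
    lr_drop_period = cfg_get(cfg, "train", "lr_drop_period", 5L),
    lr_drop_factor = cfg_get(cfg, "train", "lr_drop_factor", 0.95),
    validation_frequency = cfg_get(cfg, "train", "validation_frequency", 400L),
    mini_batch_size = cfg_get(cfg, "train", "mini_batch_size", 8L),
    seed = cfg$seed,
    verbose = cfg_get(cfg, "train", "verbose", FALSE))
}

stage_simulate <- function(cfg) {
  dir <- file.path(cfg$output_dir, "phantoms")
  make_phantom_dataset(cfg_phantom_config(cfg), dir)
  dir
}

stage_preprocess <- function(cfg) {
  src <- cfg_get(cfg, "preprocess", "input_dir",
                 file.path(cfg$output_dir, "phantoms"))
  samples <- read_phantom_dataset(src)
  dir <- file.path(cfg$output_dir, "preprocessed")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in samples) write_sample(preprocess_sample(s), dir)
  split <- split_dataset(vapply(samples, `[[`, "", "id"), seed = cfg$seed)
  jsonlite::write_json(split, file.path(dir, "split.json"),
                       auto_unbox = FALSE, digits = NA)
  dir
}

stage_summarize <- function(cfg, csv = NULL) {
  tab <- analyze_network(cfg_network_spec(cfg))
  out <- tab[, c("index", "name", "type", "activations", "learnable")]
  names(out)[5] <- "total_learnable"
  write.table(out, stdout(), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  invisible(out)
}

load_split_samples <- function(dir, which) {
  split <- jsonlite::read_json(file.path(dir, "split.json"),
                               simplifyVector = TRUE)
  lapply(split[[which]], function(id) read_sample(dir, id))
}

stage_train <- function(cfg) {
  pre <- cfg_get(cfg, "train", "input_dir",
                 file.path(cfg$output_dir, "preprocessed"))
  train_samples <- load_split_samples(pre, "train")
  val_samples <- load_split_samples(pre, "validation")
  net <- build_network(cfg_network_spec(cfg), seed = cfg$seed)
  fit <- train_network(net, train_samples, val_samples,
                       config = cfg_train_config(cfg),
                       pspec = cfg_patch_spec(cfg))
  dir <- file.path(cfg$output_dir, "model")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(fit$network, file.path(dir, "checkpoint_best.rds"))
  saveRDS(fit$final, file.path(dir, "checkpoint_final.rds"))
  write.csv(fit$history, file.path(dir, "history.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(base_channels = fit$network$spec$base_channels,
         input_shape = fit$network$spec$input_shape,
         parameters = count_parameters(fit$network),
         epochs = max(fit$history$epoch),
         iterations = max(fit$history$iteration),
         final_train_loss = fit$history$train_loss[nrow(fit$history)]),
    file.path(dir, "checkpoint_meta.json"), auto_unbox = TRUE, digits = NA)
  dir
}

stage_evaluate <- function(cfg) {
  pre <- cfg_get(cfg, "evaluate", "input_dir",
                 file.path(cfg$output_dir, "preprocessed"))
  model_path <- cfg_get(cfg, "evaluate", "checkpoint",
                        file.path(cfg$output_dir, "model", "checkpoint_best.rds"))
  if (!file.exists(model_path)) stop("checkpoint not found: ", model_path)
  net <- readRDS(model_path)
  test_samples <- load_split_samples(pre, "test")
  tile <- cfg_get(cfg, "evaluate", "tile_size", net$spec$input_shape[1])
  report <- evaluate_testset(net, test_samples, tile_size = tile)
  dir <- file.path(cfg$output_dir, "evaluation")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report_csv(report, file.path(dir, "metrics.csv"))
  if (isTRUE(cfg_get(cfg, "evaluate", "write_masks", FALSE))) {
    for (s in test_samples) {
      pred <- segment_volume(net, s, tile_size = tile)
      write_nifti(pred, file.path(dir, paste0(s$id, "_pred.nii.gz")),
                  datatype = "uint8")
    }
  }
  if (isTRUE(cfg_get(cfg, "evaluate", "boxplot", FALSE)))
    plot_dice_distribution(report, file.path(dir, "dice_boxplot.png"))
  report
}

stage_dump_patches <- function(cfg) {
  pre <- cfg_get(cfg, "preprocess", "input_dir",
                 file.path(cfg$output_dir, "preprocessed"))
  samples <- load_split_samples(pre, "train")
  pspec <- cfg_patch_spec(cfg)
  dir <- file.path(cfg$output_dir, "patches")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- min(cfg_get(cfg, "dump", "n_patches", 4L), pspec$patches_per_image)
  pats <- sample_patches(samples[[1]], pspec, seed = cfg$seed)[seq_len(n)]
  for (i in seq_along(pats)) {
    write_nifti(pats[[i]]$image,
                file.path(dir, sprintf("patch%02d_img.nii.gz", i)))
    write_nifti(pats[[i]]$label,
                file.path(dir, sprintf("patch%02d_lab.nii.gz", i)),
                datatype = "uint8")
  }
  dir
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (phantom dataset), `preprocess` (crop + normalize +
#' split), `summarize` (44-row network analysis table to stdout),
#' `train` (Adam training, checkpoints + history CSV), `evaluate` (test-set
#' metrics CSV, optional masks and box plot), `dump-patches` (sample patches
#' as NIfTI for inspection). Each stage is deterministic given the config's
#' seed, writes only its own outputs under `output_dir`, and records a run
#' manifest. The installed `unet3d` script exposes the same stages on the
#' command line.
#'
#' @param stage One of the stage names above.
#' @param config_path Path to a JSON configuration file; required keys `seed`
#'   and `output_dir`, optional sections `simulate`, `network`, `train`,
#'   `preprocess`, `evaluate`, `dump`.
#' @return The stage's primary artifact (directory path or report object),
#'   invisibly.
#' @export
run_stage <- function(stage, config_path) {
  stage <- match.arg(stage, pipeline_stages)
  cfg <- read_config(config_path)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(stage,
                "simulate" = stage_simulate(cfg),
                "preprocess" = stage_preprocess(cfg),
                "summarize" = stage_summarize(cfg),
                "train" = stage_train(cfg),
                "evaluate" = stage_evaluate(cfg),
                "dump-patches" = stage_dump_patches(cfg))
  write_run_manifest(cfg, stage, cfg$output_dir)
  invisible(out)
}
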
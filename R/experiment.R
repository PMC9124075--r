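# End-to-end experiment driver: data (scan or synthesize) -> subset
# sampling -> stratified split -> stain normalization (fit on a training
# image) -> training-split augmentation -> network -> training ->
# evaluation, with every stage seeded and logged to the output directory.

#' Default experiment configuration
#'
#' Returns the configuration list accepted by [run_experiment()], with the
#' standard protocol as defaults. Any entry may be overridden via `...`
#' (or by editing the returned list); [read_experiment_config()] loads the
#' same structure from YAML.
#'
#' @param ... named overrides of top-level entries.
#' @return nested configuration list.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    out_dir = "mfscnet-run",
    seed = 0L,
    data = list(root = NULL,              # existing tree; NULL -> synthesize
                synth = list(n_classes = 2L, per_class = 100L, image_size = 64L)),
    task = "binary",
    per_class = NULL,                     # NULL -> keep all scanned records
    split_ratios = c(0.7, 0.1, 0.2),
    normalize = list(enabled = TRUE, od_threshold = 0.15, sparsity = 0.1),
    augment = list(enabled = TRUE, ops = c("rot90", "rot180", "rot270", "hflip", "vflip")),
    arch = list(variant = "A", growth_rate = 32L, block_config = c(6L, 12L, 24L, 16L),
                se_reduction = 16L, head_width = NULL),
    train = list(optimizer = "adam", learning_rate = 1e-4, batch_size = 32L,
                 epochs = 10L, image_size = 224L))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read an experiment configuration from YAML
#' @param path YAML file with the [experiment_config()] structure.
#' @return configuration list (missing entries filled with defaults).
#' @export
read_experiment_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- experiment_config()
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_into(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_into(cfg, user)
}

#' Run a full classification experiment
#'
#' Executes the pipeline: scan (or synthesize) the dataset, sample a
#' per-class subset, assign stratified 7:1:2 splits, fit a stain model on
#' the first training image and normalize every image to it, augment the
#' training split only, build the requested architecture variant, train,
#' and evaluate on the test split. All artifacts (manifest CSV, stain
#' target JSON, architecture JSON, history CSV, metrics JSON) are written
#' under `config$out_dir`; the stain target and augmentation use training
#' data only.
#'
#' @param config an [experiment_config()] list, or a YAML path.
#' @param verbose log each stage.
#' @return list with `manifest`, `model`, `history`, `report`,
#'   `target_stain`, and `out_dir`.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_experiment_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  manifest <- run_stage("data", {
    if (!is.null(config$data$root)) {
      say("data", "scanning %s", config$data$root)
      scan_dataset(config$data$root, layout = "breakhis")
    } else {
      s <- config$data$synth
      say("data", "synthesizing %d classes x %d images (%dpx)",
          s$n_classes, s$per_class, s$image_size)
      params <- synth_params(image_size = s$image_size, n_classes = s$n_classes,
                             seed = config$seed)
      generate_dataset(params, s$per_class, file.path(out_dir, "images"))
    }
  })
  if (!is.null(config$per_class)) {
    manifest <- run_stage("sample", sample_subset(manifest, config$task,
                                                  config$per_class, seed = config$seed))
    say("sample", "%d records after sampling", manifest_size(manifest))
  }
  manifest <- run_stage("split", make_splits(manifest, config$split_ratios, seed = config$seed))
  say("split", "%s", paste(capture_split_counts(manifest), collapse = "/"))

  target_stain <- NULL
  if (isTRUE(config$normalize$enabled)) {
    res <- run_stage("normalize", {
      target_path <- manifest$records$path[manifest$records$split == "train"][1]
      say("normalize", "stain target: %s", target_path)
      tgt <- estimate_stain_model(read_patch(target_path),
                                  od_threshold = config$normalize$od_threshold,
                                  sparsity = config$normalize$sparsity,
                                  seed = config$seed)
      write_stain_model(tgt, file.path(out_dir, "stain_target.json"))
      norm_dir <- file.path(out_dir, "normalized")
      rec <- manifest$records
      for (i in seq_len(nrow(rec))) {
        img <- read_patch(rec$path[i])
        src <- estimate_stain_model(img, od_threshold = config$normalize$od_threshold,
                                    sparsity = config$normalize$sparsity,
                                    seed = config$seed)
        out <- normalize_image(img, src, tgt)
        new_path <- file.path(norm_dir, sprintf("%06d_%s", i, basename(rec$path[i])))
        write_patch(out, new_path)
        rec$path[i] <- new_path
      }
      m <- manifest; m$records <- rec
      list(manifest = m, target = tgt)
    })
    manifest <- res$manifest
    target_stain <- res$target
  }
  if (isTRUE(config$augment$enabled)) {
    manifest <- run_stage("augment",
      expand_training_set(manifest, config$augment$ops, file.path(out_dir, "augmented")))
    say("augment", "train split now %d records",
        sum(manifest$records$split == "train"))
  }
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))

  spec <- run_stage("build", architecture_spec(
    variant = config$arch$variant, num_classes = if (config$task == "binary") 2L else 8L,
    growth_rate = config$arch$growth_rate, block_config = config$arch$block_config,
    se_reduction = config$arch$se_reduction, head_width = config$arch$head_width,
    input_size = config$train$image_size))
  write_architecture_spec(spec, file.path(out_dir, "architecture.json"))
  model <- run_stage("build", build_network(spec, seed = config$seed))
  say("build", "variant %s, %d parameters", spec$variant, model$parameter_count)

  tc <- train_config(optimizer = config$train$optimizer,
                     learning_rate = config$train$learning_rate,
                     batch_size = config$train$batch_size,
                     epochs = config$train$epochs,
                     image_size = config$train$image_size,
                     seed = config$seed)
  fit <- run_stage("train", train_network(model, manifest, tc, verbose = verbose))
  write.csv(fit$history, file.path(out_dir, "history.csv"), row.names = FALSE)

  report <- run_stage("evaluate",
    evaluate_network(fit$model, manifest, split = "test", image_size = tc$image_size))
  write_metrics_report(report, file.path(out_dir, "metrics.json"))
  say("evaluate", "test accuracy %.4f, auc %.4f", report$accuracy, report$auc)

  list(manifest = manifest, model = fit$model, history = fit$history,
       report = report, target_stain = target_stain, out_dir = out_dir)
}

capture_split_counts <- function(manifest) {
  vapply(c("train", "val", "test"),
         function(s) sum(manifest$records$split == s), integer(1))
}
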
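#' Pipeline configuration
#'
#' Describes one end-to-end run: the input scene (either a cube/mask pair on
#' disk or a synthetic [scene_spec()]), the preprocessing parameters, the
#' model choice, and the training regime. Defaults are the package-wide
#' study conditions: 3 factor bands, 3 x 3 patches, a 15/15/70
#' train/validation/test split, and 50 epochs of Adam at learning rate 0.001
#' with batch size 256.
#'
#' @param cube_path,mask_path paths to a stored cube and label mask
#'   (mutually exclusive with `scene`).
#' @param scene a [scene_spec()] for a synthetic run.
#' @param library optional [make_spectral_library()] result for synthetic
#'   runs; by default one is built with `separation = 10` at the config seed.
#' @param model `"scs"`, `"cnn2d"`, or `"lenet"`.
#' @param n_factors factor bands retained by [reduce_bands_fa()].
#' @param patch_size odd patch side.
#' @param padding `"zero"` or `"mirror"`.
#' @param fractions train/val/test fractions summing to 1.
#' @param training a [training_config()]; its seed is overridden by `seed`.
#' @param layer_cfg an [scs_layer_config()] for the SCS model.
#' @param seed master seed for every stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cube_path = NULL, mask_path = NULL, scene = NULL,
                            library = NULL, model = "scs", n_factors = 3L,
                            patch_size = 3L, padding = "zero",
                            fractions = c(0.15, 0.15, 0.70),
                            training = training_config(),
                            layer_cfg = scs_layer_config(), seed = 1L) {
  has_files <- !is.null(cube_path) || !is.null(mask_path)
  has_scene <- !is.null(scene)
  if (has_files && has_scene)
    stop("give either cube/mask paths or a synthetic scene spec, not both",
         call. = FALSE)
  if (!has_files && !has_scene)
    stop("one of cube/mask paths or a synthetic scene spec is required",
         call. = FALSE)
  if (has_files && (is.null(cube_path) || is.null(mask_path)))
    stop("both `cube_path` and `mask_path` are required for a file run",
         call. = FALSE)
  model <- match.arg(model, c("scs", "cnn2d", "lenet"))
  training$seed <- as.integer(seed)
  structure(list(cube_path = cube_path, mask_path = mask_path, scene = scene,
                 library = library, model = model,
                 n_factors = as.integer(n_factors),
                 patch_size = as.integer(patch_size), padding = padding,
                 fractions = fractions, training = training,
                 layer_cfg = layer_cfg, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_snapshot <- function(config) {
  list(model = config$model, n_factors = config$n_factors,
       patch_size = config$patch_size, padding = config$padding,
       fractions = config$fractions, seed = config$seed,
       epochs = config$training$epochs,
       batch_size = config$training$batch_size,
       learning_rate = config$training$learning_rate,
       optimizer = config$training$optimizer, loss = config$training$loss,
       input = if (is.null(config$scene)) list(cube = config$cube_path,
                                               mask = config$mask_path)
               else list(synthetic = sprintf("%dx%dx%d", config$scene$M,
                                             config$scene$N, config$scene$B),
                         labeled_fraction = config$scene$labeled_fraction))
}

# order-independent fingerprint of a split (md5 of its serialized indices)
split_hash <- function(split) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(paste(split$train, collapse = ","),
               paste(split$val, collapse = ","),
               paste(split$test, collapse = ",")), f)
  unname(tools::md5sum(f))
}

load_inputs <- function(config) {
  if (!is.null(config$scene)) {
    library <- config$library
    if (is.null(library))
      library <- make_spectral_library(C = length(config$scene$class_names),
                                       B = config$scene$B, separation = 10,
                                       seed = config$seed)
    sc <- generate_scene(config$scene, library)
    list(cube = sc$cube, mask = sc$mask, truth = sc$truth)
  } else {
    cube <- read_cube(config$cube_path)
    mask <- read_label_mask(config$mask_path)
    check_pair(cube, mask)
    list(cube = cube, mask = mask, truth = NULL)
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

build_model_spec <- function(config, input_shape, n_classes) {
  if (config$model == "scs")
    build_scs_classifier(input_shape, n_classes, config$layer_cfg)
  else
    build_baseline(config$model, input_shape, n_classes)
}

#' Run the end-to-end classification pipeline
#'
#' Stages, in order: load or generate the scene; reduce bands by factor
#' analysis; extract patches at labeled pixels; split per class 15/15/70;
#' train the configured model; evaluate on the held-out test split; predict
#' and render the full-scene classification map. All artifacts (metrics JSON
#' and CSV, training history CSV, map PNG, resolved-config snapshot, log)
#' are written into `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if missing.
#' @return Invisibly, a list with `report` (a [metrics_report()]), `model`
#'   (the `trained_model`), `split`, `split_hash`, `map` (predicted
#'   [label_mask]), and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("scsmap-run-")) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }

  logf("loading inputs")
  inp <- stage("input", load_inputs(config))
  d <- dim(inp$cube$data)
  logf("scene %d x %d x %d, %d labeled pixels", d[1L], d[2L], d[3L],
       sum(inp$mask$labels != inp$mask$unlabeled_value))

  logf("factor analysis: %d bands -> %d factors", d[3L], config$n_factors)
  reduced <- stage("factor-analysis",
                   reduce_bands_fa(inp$cube, config$n_factors,
                                   seed = config$seed))

  logf("extracting %d x %d patches", config$patch_size, config$patch_size)
  pset <- stage("patch-extraction",
                extract_patches(reduced, inp$mask, s = config$patch_size,
                                padding = config$padding))

  split <- stage("split",
                 stratified_split(pset, config$fractions, seed = config$seed))
  sh <- split_hash(split)
  logf("split train/val/test = %d/%d/%d (hash %s)",
       length(split$train), length(split$val), length(split$test), sh)

  spec <- stage("model-build",
                build_model_spec(config, dim(pset$patches)[2:4],
                                 length(pset$class_names)))
  t0 <- proc.time()[["elapsed"]]
  model <- stage("training", train_model(spec, pset, split, config$training))
  train_time <- proc.time()[["elapsed"]] - t0
  logf("trained '%s' in %.1f s; final val acc %s", config$model, train_time,
       format(model$history$val_acc[nrow(model$history)], digits = 3))

  t0 <- proc.time()[["elapsed"]]
  pred <- stage("evaluation",
                predict_labels(model, pset$patches[split$test, , , ,
                                                   drop = FALSE]))
  test_time <- proc.time()[["elapsed"]] - t0
  report <- stage("evaluation",
                  metrics_report(true_labels = pset$labels[split$test],
                                 pred_labels = pred$labels,
                                 class_names = pset$class_names))
  logf("test metrics: kappa %.4f, OA %.4f, AA %.4f, F1 macro %.4f",
       report$kappa, report$overall_accuracy, report$average_accuracy,
       report$f1_macro)

  logf("rendering full-scene classification map")
  map <- stage("map", predict_map(model, reduced, s = config$patch_size,
                                  padding = config$padding))

  write_metrics(report, file.path(out_dir, "metrics.json"))
  write_metrics(report, file.path(out_dir, "metrics.csv"))
  write_history(model, file.path(out_dir, "history.csv"))
  write_classification_map(map, file.path(out_dir, "map.png"))
  snap <- config_snapshot(config)
  snap$split_hash <- sh
  snap$train_time_s <- train_time
  snap$test_time_s <- test_time
  jsonlite::write_json(snap, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("artifacts written to %s", out_dir)
  invisible(list(report = report, model = model, split = split,
                 split_hash = sh, map = map, pset = pset, out_dir = out_dir))
}

#' Train and evaluate several models on one identical split
#'
#' Runs the shared stages (scene, factor analysis, patches, split) once,
#' then trains and evaluates every requested model on the byte-identical
#' split — the single-sample-set protocol for fair comparison. The split
#' fingerprint is recorded in every row.
#'
#' @param config a [pipeline_config()]; its `model` field is ignored.
#' @param model_list character vector of at least two of `"scs"`,
#'   `"cnn2d"`, `"lenet"`.
#' @param out_dir optional directory for the comparison CSV.
#' @return A data frame with one row per model: kappa, OA, AA, macro and
#'   weighted F1, train/test wall time (s), and the split hash.
#' @export
compare_models <- function(config, model_list = c("scs", "cnn2d"),
                           out_dir = NULL) {
  if (length(model_list) < 2L)
    stop("`model_list` needs at least 2 models", call. = FALSE)
  known <- c("scs", "cnn2d", "lenet")
  bad <- setdiff(model_list, known)
  if (length(bad))
    stop(sprintf("unknown model(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  inp <- stage("input", load_inputs(config))
  reduced <- stage("factor-analysis",
                   reduce_bands_fa(inp$cube, config$n_factors,
                                   seed = config$seed))
  pset <- stage("patch-extraction",
                extract_patches(reduced, inp$mask, s = config$patch_size,
                                padding = config$padding))
  split <- stage("split",
                 stratified_split(pset, config$fractions, seed = config$seed))
  sh <- split_hash(split)
  rows <- lapply(model_list, function(m) {
    spec <- build_model_spec(utils::modifyList(config, list(model = m)),
                             dim(pset$patches)[2:4],
                             length(pset$class_names))
    t0 <- proc.time()[["elapsed"]]
    model <- train_model(spec, pset, split, config$training)
    t_train <- proc.time()[["elapsed"]] - t0
    t0 <- proc.time()[["elapsed"]]
    pred <- predict_labels(model,
                           pset$patches[split$test, , , , drop = FALSE])
    t_test <- proc.time()[["elapsed"]] - t0
    rep <- metrics_report(true_labels = pset$labels[split$test],
                          pred_labels = pred$labels,
                          class_names = pset$class_names)
    data.frame(model = m, kappa = rep$kappa,
               overall_accuracy = rep$overall_accuracy,
               average_accuracy = rep$average_accuracy,
               f1_macro = rep$f1_macro, f1_weighted = rep$f1_weighted,
               train_time_s = t_train, test_time_s = t_test,
               split_hash = sh, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  out
}
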
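#' Pipeline configuration
#'
#' One configuration object driving the full pipeline: image source
#' (synthetic generator config, or a manifest of saved images),
#' preprocessing, GLCM, wavelet, boosting and split parameters. A single
#' master `seed` determines every stage: the generator uses `seed`, the
#' train/test split `seed + 1`, and any stochastic stage utility
#' `seed + 2`.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when `manifest` is
#'   given.
#' @param manifest Path to a dataset manifest (alternative to `synthetic`).
#' @param wiener_window Odd Wiener window (default 3).
#' @param gabor_frequencies,gabor_orientations,gabor_combine Gabor bank
#'   parameters (see [gabor_bank()]).
#' @param glcm_levels,glcm_delta GLCM quantization levels and offset
#'   distance.
#' @param wavelet,wavelet_levels Wavelet family and decomposition depth.
#' @param rounds Boosting rounds T.
#' @param test_fraction Held-out fraction for the stratified split.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            manifest = NULL,
                            wiener_window = 3,
                            gabor_frequencies = c(0.1, 0.2, 0.3, 0.4),
                            gabor_orientations = c(0, pi / 4, pi / 2,
                                                   3 * pi / 4),
                            gabor_combine = "max",
                            glcm_levels = 32, glcm_delta = 1,
                            wavelet = "db2", wavelet_levels = 1,
                            rounds = 50, test_fraction = 0.3, seed = 0L) {
  if (is.null(synthetic) && is.null(manifest)) {
    stop_config("synthetic/manifest", "exactly one image source is required")
  }
  structure(
    list(synthetic = synthetic, manifest = manifest,
         wiener_window = wiener_window,
         gabor_frequencies = gabor_frequencies,
         gabor_orientations = gabor_orientations,
         gabor_combine = gabor_combine,
         glcm_levels = glcm_levels, glcm_delta = glcm_delta,
         wavelet = wavelet, wavelet_levels = wavelet_levels,
         rounds = rounds, test_fraction = test_fraction,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_recursive(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: config '%s' does not exist", path),
         call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    mk_spec <- function(ts) {
      texture_spec(ts$base_intensity, ts$correlation_length,
                   ts$contrast_amplitude, ts$orientation_deg)
    }
    syn <- synthetic_config(
      image_size = unlist(s$image_size), n_benign = s$n_benign,
      n_malignant = s$n_malignant,
      benign_texture = mk_spec(s$benign_texture),
      malignant_texture = mk_spec(s$malignant_texture),
      speckle_shape = s$speckle_shape,
      gaussian_noise_sd = s$gaussian_noise_sd,
      speckle = s$speckle, seed = s$seed
    )
  }
  pipeline_config(
    synthetic = syn, manifest = y$manifest,
    wiener_window = y$wiener_window,
    gabor_frequencies = unlist(y$gabor_frequencies),
    gabor_orientations = unlist(y$gabor_orientations),
    gabor_combine = y$gabor_combine,
    glcm_levels = y$glcm_levels, glcm_delta = y$glcm_delta,
    wavelet = y$wavelet, wavelet_levels = y$wavelet_levels,
    rounds = y$rounds, test_fraction = y$test_fraction, seed = y$seed
  )
}

#' Feature table of a labeled image set
#'
#' Runs preprocessing and feature extraction on every image: hybrid
#' Wiener--Gabor enhancement, then the ten orientation-averaged GLCM
#' features concatenated with the normalized wavelet subband energies.
#'
#' @param dataset A [labeled_image_set()].
#' @param config A [pipeline_config()].
#' @return Data frame with a `label` column followed by the feature
#'   columns (`AC ... MP`, `E_LL_l1 ...`).
#' @export
compute_feature_table <- function(dataset, config) {
  bank <- gabor_bank(config$gabor_frequencies, config$gabor_orientations,
                     combine = config$gabor_combine)
  rows <- lapply(seq_along(dataset$images), function(i) {
    enhanced <- hwgf_preprocess(dataset$images[[i]],
                                wiener_window = config$wiener_window,
                                bank = bank)
    c(extract_fglcm(enhanced, levels = config$glcm_levels,
                    delta = config$glcm_delta),
      extract_awt(enhanced, wavelet = config$wavelet,
                  levels = config$wavelet_levels))
  })
  feats <- do.call(rbind, rows)
  data.frame(label = dataset$labels, feats, check.names = FALSE)
}

#' Write / read a feature table as CSV
#'
#' Columns `label, AC, CT, CR, CP, CS, D, EN, ET, H, MP, E_LL_l1, ...` with
#' header; numbers are written with a fixed 12-significant-digit format so
#' identical runs produce byte-identical files.
#'
#' @param table Data frame from [compute_feature_table()].
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (names(out)[j] != "label") out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: feature table '%s' does not exist", path),
         call. = FALSE)
  }
  utils::read.csv(path, check.names = FALSE)
}

log_line <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
}

run_stage <- function(stage, log_path, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  log_line(log_path, stage, sprintf("done in %.2f s", elapsed))
  attr(res, "elapsed") <- elapsed
  res
}

load_or_generate <- function(config, log_path) {
  if (!is.null(config$manifest)) {
    run_stage("load", log_path, load_dataset(config$manifest))
  } else {
    syn <- config$synthetic
    syn$seed <- config$seed  # master seed drives the generator
    run_stage("simulate", log_path, generate_dataset(syn))
  }
}

#' Run the full diagnosis pipeline
#'
#' Generate (or load) images, enhance with the hybrid Wiener--Gabor filter,
#' extract GLCM + wavelet features, train the AdaBoost ensemble on a
#' stratified training split and evaluate on the held-out split. Fully
#' deterministic given the config (including its master seed).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for artifacts (feature table, model,
#'   metric report, ROC curve, config snapshot, log).
#' @return Object of class `run_record`: `config_hash`, `timings`,
#'   `artifacts` (named paths), `log`, and the in-memory `report`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("sonotex_run_")) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("config", "must be a pipeline_config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  timings <- numeric(0)

  dataset <- load_or_generate(config, log_path)
  timings["images"] <- attr(dataset, "elapsed")
  log_line(log_path, "images",
           sprintf("%d images (%d benign / %d malignant), %d x %d",
                   length(dataset$images), sum(dataset$labels == 0L),
                   sum(dataset$labels == 1L),
                   nrow(dataset$images[[1]]), ncol(dataset$images[[1]])))

  features <- run_stage("featurize", log_path,
                        compute_feature_table(dataset, config))
  timings["featurize"] <- attr(features, "elapsed")
  feat_path <- file.path(out_dir, "features.csv")
  write_feature_table(features, feat_path)

  if (length(unique(dataset$labels)) < 2) {
    stop("pipeline stage 'train' failed: single-class data (both benign and malignant images are required)",
         call. = FALSE)
  }
  split <- stratified_split(dataset$labels, config$test_fraction,
                            seed = config$seed + 1L)
  X <- as.matrix(features[, -1, drop = FALSE])
  y <- features$label
  model <- run_stage("train", log_path,
                     train_adaboost(X[split$train, , drop = FALSE],
                                    y[split$train], rounds = config$rounds))
  timings["train"] <- attr(model, "elapsed")
  model_path <- file.path(out_dir, "model.json")
  write_model(model, model_path)

  report <- run_stage("evaluate", log_path,
                      evaluate_pipeline(model, X[split$test, , drop = FALSE],
                                        y[split$test]))
  timings["evaluate"] <- attr(report, "elapsed")

  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(
    list(accuracy = report$accuracy, sensitivity = report$sensitivity,
         specificity = report$specificity, auc = report$auc,
         accuracy_pct = report$accuracy_pct,
         sensitivity_pct = report$sensitivity_pct,
         specificity_pct = report$specificity_pct,
         counts = unclass(report$counts),
         n_train = length(split$train), n_test = length(split$test),
         rounds = model$rounds, config_hash = config_hash),
    metrics_path, auto_unbox = TRUE, digits = NA
  )
  roc_path <- file.path(out_dir, "roc.csv")
  utils::write.csv(
    data.frame(threshold = fmt_num(report$roc$thresholds),
               fpr = fmt_num(report$roc$fpr), tpr = fmt_num(report$roc$tpr)),
    roc_path, row.names = FALSE, quote = FALSE
  )

  structure(
    list(config_hash = config_hash, timings = timings,
         artifacts = c(config = cfg_path, features = feat_path,
                       model = model_path, metrics = metrics_path,
                       roc = roc_path),
         log = log_path, report = report, model = model, split = split),
    class = "run_record"
  )
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("pipeline run %s\n", x$config_hash))
  print(x$report)
  cat("artifacts:\n")
  for (nm in names(x$artifacts)) cat(sprintf("  %s: %s\n", nm,
                                             x$artifacts[nm]))
  invisible(x)
}

#' Run the pipeline up to feature extraction only
#'
#' @inheritParams run_pipeline
#' @return Path to the written feature table CSV.
#' @export
featurize_only <- function(config, out_dir = tempfile("sonotex_feat_")) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("config", "must be a pipeline_config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  dataset <- load_or_generate(config, log_path)
  features <- run_stage("featurize", log_path,
                        compute_feature_table(dataset, config))
  feat_path <- file.path(out_dir, "features.csv")
  write_feature_table(features, feat_path)
  feat_path
}
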
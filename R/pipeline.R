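# Configuration, artifact writing, and the top-level pipeline.

config_defaults <- function() {
  list(
    # synthetic data
    n_per_class = 200L, side = 64L, gland_count = 3L,
    regularity_benign = 0.9, regularity_malignant = 0.2, noise_sd = 8,
    # degradation / restoration
    restore = TRUE, degrade_factor = 2L, degrade_noise_sd = 4,
    tau = 0.1, window_radius = 1L,
    a = 0.8, gamma_i = 100, gamma_d = 1e4, delta = 0,
    # features
    m_colors = 64L, d_set = c(1L, 3L, 5L, 7L), patch_side = 5L,
    sigma = "median", sample_cap = 512L, k_bands = 16L,
    # classifier / evaluation
    tile_side = 32L, stride = 16L, capacity = 64L, train_fraction = 0.7,
    seed = 42L)
}

#' Pipeline configuration
#'
#' All module parameters in one validated list. Defaults define the standard
#' synthetic study conditions: 64 px two-class tissue images (regularity 0.9
#' benign / 0.2 malignant), factor-2 degradation and restoration, 64-color
#' autocorrelogram at distances 1/3/5/7 plus 16 graph-frequency bands, a
#' 64-cell memory classifier and a 70/30 stratified split. `tile_side` and
#' `stride` apply to heatmaps on larger images; dataset images are the
#' classification unit.
#'
#' @param ... overrides of the default fields; unknown names are rejected.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_per_class < 1) stop("n_per_class must be >= 1")
    if (side < 32) stop("side must be >= 32")
    if (regularity_benign < 0 || regularity_benign > 1 ||
        regularity_malignant < 0 || regularity_malignant > 1) {
      stop("regularity must lie in [0, 1]")
    }
    if (noise_sd < 0 || degrade_noise_sd < 0) stop("noise sd must be >= 0")
    if (degrade_factor < 2 || side %% degrade_factor != 0) {
      stop("degrade_factor must be >= 2 and divide side")
    }
    if (tau < 0) stop("tau must be >= 0")
    if (window_radius < 1) stop("window_radius must be >= 1")
    if (a < 0 || a >= 1) stop("a must lie in [0, 1)")
    if (gamma_i < 0 || gamma_d < 0 || delta < 0) stop("negative weight parameter")
    if (m_colors < 2) stop("m_colors must be >= 2")
    if (any(d_set < 1)) stop("distances must be >= 1")
    if (patch_side %% 2 == 0) stop("patch_side must be odd")
    if (sample_cap < 2) stop("sample_cap must be >= 2")
    if (k_bands < 1) stop("k_bands must be >= 1")
    if (capacity < 2) stop("capacity must be >= 2")
    if (train_fraction <= 0 || train_fraction >= 1) {
      stop("train_fraction must lie in (0, 1)")
    }
  })
  cfg
}

#' Write a configuration to a YAML file
#'
#' @param config a [pipeline_config()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected (catching typos among the many numeric
#' parameters); missing keys take their defaults.
#'
#' @param path YAML file.
#' @return validated `"pipeline_config"`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ints <- c("n_per_class", "side", "gland_count", "degrade_factor",
            "window_radius", "m_colors", "d_set", "patch_side", "sample_cap",
            "k_bands", "tile_side", "stride", "capacity", "seed")
  for (k in intersect(names(raw), ints)) raw[[k]] <- as.integer(raw[[k]])
  do.call(pipeline_config, raw)
}

cfg_feature_config <- function(cfg) {
  feature_config(m_colors = cfg$m_colors, d_set = cfg$d_set,
                 patch_side = cfg$patch_side,
                 sigma = if (identical(cfg$sigma, "median")) NULL else cfg$sigma,
                 sample_cap = cfg$sample_cap, k_bands = cfg$k_bands,
                 seed = cfg$seed)
}

#' Run the full synthetic pipeline
#'
#' Generates the two-class synthetic dataset, optionally degrades and
#' restores every image through the reliability-guided ordered filter,
#' extracts per-image features (autocorrelogram + graph-frequency energies),
#' performs a seeded stratified split, trains the memory-cell classifier and
#' evaluates it on the held-out images. All randomness derives from
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for artifacts (see [write_outputs()]).
#' @param force overwrite an existing output directory.
#' @param dry_run print the execution plan and return without computing or
#'   writing anything.
#' @param verbose print stage timings.
#' @return object of class `"histotile_run"`: `metrics`
#'   (a `"metrics_report"`), `model`, `features`, `labels`, `split`,
#'   `scores`, `predictions`, `config`, `timings`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         force = FALSE, dry_run = FALSE, verbose = FALSE) {
  config <- validate_config(config)
  if (dry_run) {
    cat("Plan: simulate", 2 * config$n_per_class, "images of side", config$side,
        if (config$restore) sprintf("| degrade x%d + restore", config$degrade_factor)
        else "| no restoration",
        "| features -> split", sprintf("%.0f/%.0f", 100 * config$train_fraction,
                                       100 * (1 - config$train_fraction)),
        "| memory-cell train + evaluate\n")
    return(invisible(NULL))
  }
  timings <- c()
  tick <- function(stage, t0) {
    el <- as.numeric(Sys.time()) - t0
    timings[stage] <<- el
    if (verbose) message(sprintf("[%s] %.2fs", stage, el))
  }

  t0 <- as.numeric(Sys.time())
  ds <- generate_dataset(config$n_per_class,
                         tissue_spec(side_length = config$side,
                                     gland_count = config$gland_count,
                                     noise_sd = config$noise_sd),
                         seed = config$seed,
                         regularity_benign = config$regularity_benign,
                         regularity_malignant = config$regularity_malignant)
  tick("simulate", t0)

  t0 <- as.numeric(Sys.time())
  imgs <- vector("list", length(ds$labels))
  for (i in seq_along(imgs)) {
    if (config$restore) {
      low <- degrade_image(ds$images[[i]], config$degrade_factor,
                           config$degrade_noise_sd, seed = ds$seeds[i])
      imgs[[i]] <- restore_image(as_unit(low), config$degrade_factor,
                                 tau = config$tau,
                                 window_radius = config$window_radius,
                                 a = config$a, gamma_i = config$gamma_i,
                                 gamma_d = config$gamma_d,
                                 delta = config$delta)$image
    } else {
      imgs[[i]] <- as_unit(ds$images[[i]])
    }
  }
  tick("restore", t0)

  t0 <- as.numeric(Sys.time())
  fc <- cfg_feature_config(config)
  f1 <- tile_features(imgs[[1]], fc)
  feats <- matrix(0, length(imgs), length(f1))
  feats[1, ] <- f1
  for (i in seq_along(imgs)[-1]) feats[i, ] <- tile_features(imgs[[i]], fc)
  colnames(feats) <- names(f1)
  tick("features", t0)

  t0 <- as.numeric(Sys.time())
  split <- split_dataset(ds$labels, config$train_fraction, seed = config$seed + 1L)
  model <- memcell(feats[split$train, , drop = FALSE], ds$labels[split$train],
                   capacity = config$capacity, seed = config$seed + 2L)
  pred <- predict(model, feats[split$test, , drop = FALSE], type = "both")
  metrics <- evaluate_classifier(pred$class, pred$score, ds$labels[split$test],
                                 positive = model$positive)
  tick("classify", t0)

  res <- structure(list(metrics = metrics, model = model, features = feats,
                        labels = ds$labels, split = split,
                        scores = pred$score, predictions = pred$class,
                        config = config, timings = timings),
                   class = "histotile_run")
  if (!is.null(out_dir)) write_outputs(res, out_dir, force = force)
  res
}

#' @export
print.histotile_run <- function(x, ...) {
  cat(sprintf("histotile pipeline run: %d images (%d test)\n",
              length(x$labels), length(x$split$test)))
  print(x$metrics)
  cat(sprintf("  memory cells: %d, similarity threshold %.4f\n",
              nrow(x$model$cells), x$model$threshold))
  invisible(x)
}

#' Write pipeline artifacts with a manifest
#'
#' Writes `config.yaml`, `metrics.json`, `roc.csv`, `predictions.csv` and a
#' `manifest.json` listing every artifact with its MD5 checksum and the
#' configuration hash. Deterministic: identical runs produce byte-identical
#' files. Refuses to overwrite an existing manifest unless `force = TRUE`.
#'
#' @param run a `"histotile_run"`.
#' @param out_dir output directory.
#' @param force overwrite existing outputs.
#' @return the manifest as a list, invisibly.
#' @export
write_outputs <- function(run, out_dir, force = FALSE) {
  stopifnot(inherits(run, "histotile_run"))
  if (file.exists(file.path(out_dir, "manifest.json")) && !force) {
    stop("output directory already contains a manifest; use force = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(run$config, file.path(out_dir, "config.yaml"))
  m <- run$metrics
  jsonlite::write_json(
    list(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
         f1 = m$f1, auc = m$auc, confusion = as.list(m$confusion),
         n_test = m$n, n_cells = nrow(run$model$cells),
         similarity_threshold = run$model$threshold),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(m$roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(index = run$split$test, label = run$labels[run$split$test],
               prediction = run$predictions, score = run$scores),
    file.path(out_dir, "predictions.csv"), row.names = FALSE)
  files <- c("config.yaml", "metrics.json", "roc.csv", "predictions.csv")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    artifacts = mapply(function(f, s) list(file = f, md5 = unname(s)),
                       files, sums, SIMPLIFY = FALSE, USE.NAMES = FALSE),
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
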
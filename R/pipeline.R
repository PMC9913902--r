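#' Default pipeline configuration
#'
#' Encodes the reference experimental setup: 250x250 phantoms (60 normal +
#' 60 tumor), binarization threshold 0.05, C = 5 regions with entropic
#' index q = 0.8, SVD energy fraction 0.99, repeated stratified 70/30
#' holdout with 20 repetitions (or 10-fold CV).
#'
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    log_level = "INFO",
    phantom = list(image_size = 250L, n_normal = 60L, n_tumor = 60L,
                   noise_sd = 3),
    preprocess = list(threshold = 0.05, downsample = TRUE),
    segment = list(C = 5L, q = 0.8),
    sso = list(population_size = 25L, max_iterations = 100L, r_a = 1.0,
               p_c = 0.7, p_m = 0.1),
    features = list(energy_fraction = 0.99),
    ensemble = list(standardize = FALSE, cost = 1.0),
    evaluate = list(mode = "holdout", reps = 20L, train_frac = 0.7, k = 10L)
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys fall back to [default_config()].
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return `pipeline_config` list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (!sec %in% names(cfg))
        stop("unknown config section: ", sec, call. = FALSE)
      if (is.list(cfg[[sec]])) {
        extra <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
        if (length(extra))
          stop("unknown config key: ", sec, ".", extra[1], call. = FALSE)
        cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
      } else cfg[[sec]] <- user[[sec]]
    }
  }
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  stopifnot(cfg$segment$C >= 2, cfg$segment$q > 0, cfg$segment$q != 1,
            cfg$preprocess$threshold > 0, cfg$preprocess$threshold < 1,
            cfg$features$energy_fraction > 0, cfg$features$energy_fraction <= 1,
            cfg$evaluate$train_frac > 0, cfg$evaluate$train_frac < 1,
            cfg$evaluate$reps >= 1, cfg$evaluate$k >= 2,
            cfg$evaluate$mode %in% c("holdout", "cv"),
            cfg$sso$population_size >= 2, cfg$sso$r_a > 0)
  cfg
}

pipe_log <- function(cfg, level, fmt, ...) {
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)
  if (levels[[level]] >= levels[[cfg$log_level %||% "INFO"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess and segment a set of images into a data matrix
#'
#' Runs background removal and SSO thresholding segmentation per image
#' (each image is processed independently; no information crosses samples,
#' so this can safely happen before any train/test split) and flattens the
#' label maps into the rows of a sample-by-pixel matrix.
#'
#' @param images list of integer image matrices.
#' @param config `pipeline_config`.
#' @return list with `X` (P x S matrix of region labels), `thresholds`
#'   (per-image list), `dims` (common segmented image dims).
#' @export
prepare_data_matrix <- function(images, config = default_config()) {
  segs <- vector("list", length(images))
  for (i in seq_along(images)) {
    pp <- preprocess_image(images[[i]], config$preprocess$threshold,
                           config$preprocess$downsample)
    m <- config$segment$C - 1L
    sc <- sso_config(bounds = matrix(rep(c(1, 254), each = m), m, 2L),
                     population_size = config$sso$population_size,
                     max_iterations = config$sso$max_iterations,
                     r_a = config$sso$r_a, p_c = config$sso$p_c,
                     p_m = config$sso$p_m,
                     seed = derive_seed(config$seed, paste0("segment/", i)))
    segs[[i]] <- segment_image(pp$image, C = config$segment$C,
                               q = config$segment$q, config = sc)
    pipe_log(config, "DEBUG", "image %d: thresholds %s fitness %.5f", i,
             paste(segs[[i]]$thresholds, collapse = ","), segs[[i]]$fitness)
  }
  dims <- lapply(segs, function(s) dim(s$labels))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1L)
    stop("images must share a common size", call. = FALSE)
  X <- do.call(rbind, lapply(segs, function(s) as.vector(s$labels)))
  list(X = X, thresholds = lapply(segs, `[[`, "thresholds"),
       dims = dims[[1]])
}

#' Run the full pipeline: phantoms (or manifest) to evaluation report
#'
#' Stages run in order: preprocessing (binarize, largest component, hole
#' fill, foreground, 2x2 averaging), SSO multilevel Tsallis segmentation,
#' SVD feature extraction (fit on training rows of each split only), and
#' the three-classifier voting ensemble under repeated stratified holdout
#' or stratified k-fold CV.
#'
#' @param config `pipeline_config` (see [default_config()]).
#' @param manifest optional path to a `filename,label` CSV; when `NULL`,
#'   phantoms are simulated in memory from the config's `phantom` section.
#' @param out_dir optional directory for artifacts (report JSON,
#'   per-repetition accuracies CSV, feature CSV).
#' @return the `eval_report`.
#' @export
run_pipeline <- function(config = default_config(), manifest = NULL,
                         out_dir = NULL) {
  config <- validate_config(config)
  if (is.null(manifest)) {
    spec <- phantom_spec(image_size = config$phantom$image_size,
                         n_normal = config$phantom$n_normal,
                         n_tumor = config$phantom$n_tumor,
                         noise_sd = config$phantom$noise_sd,
                         seed = derive_seed(config$seed, "phantom"))
    samples <- generate_samples(spec)
    images <- lapply(samples, `[[`, "image")
    labels <- vapply(samples, `[[`, character(1), "label")
  } else {
    man <- read_manifest(manifest)
    images <- lapply(man$path, read_gray_image)
    labels <- man$label
  }
  pipe_log(config, "INFO", "loaded %d images (%d tumor)", length(images),
           sum(labels == "tumor"))

  prep <- prepare_data_matrix(images, config)
  pipe_log(config, "INFO", "segmented to %dx%d label maps, C = %d",
           prep$dims[1], prep$dims[2], config$segment$C)

  ev_seed <- derive_seed(config$seed, "evaluate")
  report <- if (config$evaluate$mode == "holdout") {
    repeated_holdout(prep$X, labels, reps = config$evaluate$reps,
                     train_frac = config$evaluate$train_frac, seed = ev_seed,
                     energy_fraction = config$features$energy_fraction,
                     standardize = config$ensemble$standardize)
  } else {
    kfold_cv(prep$X, labels, k = config$evaluate$k, seed = ev_seed,
             energy_fraction = config$features$energy_fraction,
             standardize = config$ensemble$standardize)
  }
  pipe_log(config, "INFO", "ensemble mean accuracy %.2f%%",
           report$mean_acc[["ensemble"]])

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(protocol = report$protocol,
           mean_acc = as.list(report$mean_acc),
           min_acc = as.list(report$min_acc),
           max_acc = as.list(report$max_acc),
           sd_acc = as.list(report$sd_acc),
           pooled_cm = unclass(report$pooled_cm),
           sensitivity = report$sensitivity,
           specificity = report$specificity,
           accuracy = report$accuracy, auc = report$auc),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write.csv(as.data.frame(report$per_rep_acc),
              file.path(out_dir, "accuracies.csv"), row.names = FALSE)
  }
  report
}
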
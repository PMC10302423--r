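# End-to-end orchestration: simulate -> extract -> train -> evaluate ->
# predict, with manifest handling, flip augmentation, config round-tripping
# and artifact persistence.

#' Default pipeline configuration
#'
#' Nested list of every stage parameter; round-trips losslessly through
#' YAML via [write_config()] / [read_config()].
#'
#' `gha$n` defaults to 40 and the adaptive-threshold block to 75, both
#' matched to the default synthetic rendering scale (flask diameter around
#' 280 px); full-resolution tablet captures with a flask diameter around
#' 600 px should use the module defaults (80 and 151). A window that spans
#' most of the flask stops being local: on curved intensity profiles its
#' mean sits far enough above the center pixels to breach the `c` offset.
#'
#' @param seed master seed.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_per_class = 100, image_size = c(320, 320),
                    cell_size_px = 48, moire_prob = 0.3, tint_prob = 0.3,
                    noise_sigma = 2),
    roi = circle_detector_params(),
    moire = list(enabled = TRUE, denoise = denoise_params(),
                 contrast = contrast_params()),
    gha = list(n = 40),
    paa = list(adaptive = adaptive_threshold_params(block_size = 75),
               gabor = gabor_params(), rim_margin = 5),
    sa = list(detector = check_detector_params(), nms_radius = 25),
    classifier = list(dnn = dnn_config(), svm = svm_config(), k = 10),
    augment = FALSE
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

flip_v <- function(img) {
  if (is.matrix(img)) img[rev(seq_len(nrow(img))), , drop = FALSE]
  else img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
}

flip_h <- function(img) {
  if (is.matrix(img)) img[, rev(seq_len(ncol(img))), drop = FALSE]
  else img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
}

#' Flip augmentation of a paired capture
#'
#' Per background image: identity, vertical flip, horizontal flip, and
#' combined flip, so one white/checked sample combination yields eight
#' images (applied to training data only by default).
#'
#' @param white,checked the two captures (matrix or RGB array).
#' @return list of 8 images named `white_id`, `white_v`, `white_h`,
#'   `white_vh`, `checked_id`, ... .
#' @export
augment_sample <- function(white, checked) {
  list(white_id = white, white_v = flip_v(white), white_h = flip_h(white),
       white_vh = flip_v(flip_h(white)),
       checked_id = checked, checked_v = flip_v(checked),
       checked_h = flip_h(checked), checked_vh = flip_v(flip_h(checked)))
}

#' Extract the nine features from one white/checked image pair
#'
#' Preprocess both captures (gray, circle detection, masking), run Moire
#' suppression when enabled, then grid homogeneity + radial profile +
#' particle analyses on the white capture and superposition analysis on the
#' checked capture.
#'
#' @param white,checked RGB arrays or gray matrices (8-bit scale).
#' @param config [default_config()].
#' @return named numeric vector of the nine features in canonical order
#'   ([FEATURE_NAMES]).
#' @export
extract_pair_features <- function(white, checked, config = default_config()) {
  process <- function(img) {
    g <- to_gray(img)
    roi <- detect_solution_circle(g, config$roi)
    m <- apply_mask(g, roi)
    if (isTRUE(config$moire$enabled)) {
      m <- remove_moire(m, config$moire$denoise, config$moire$contrast)
    }
    m
  }
  mw <- process(white)
  mc <- process(checked)

  gha <- compute_gha(mw$image, build_grid(mw$roi, config$gha$n))
  rpa <- rpa_features(extract_profiles(mw))
  paa <- paa_features(mw, config$paa$adaptive, config$paa$gabor,
                      config$paa$rim_margin)
  sa <- sa_features(mc, config$sa$detector, config$sa$nms_radius)

  c(gha,
    minimum_value = unname(rpa["minimum_value"]),
    curvature = unname(rpa["curvature"]),
    mse = unname(rpa["mse"]),
    number_of_particles = paa$count,
    superposition_ratio = sa$ratio)
}

read_image_8bit <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img * 255
}

#' Extract a feature table from a manifest
#'
#' One row of nine features per manifest sample (plus flip-augmented copies
#' when `config$augment` is TRUE). Per-row failures are recorded with their
#' reason and do not abort the batch.
#'
#' @param manifest data frame from [read_manifest()] (or with the same
#'   columns).
#' @param config [default_config()].
#' @return data frame with `sample_id`, the nine feature columns, `label`;
#'   failed rows are attached as the `failures` attribute.
#' @export
extract_features <- function(manifest, config = default_config()) {
  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    res <- tryCatch({
      white <- read_image_8bit(rec$white_path)
      checked <- read_image_8bit(rec$checked_path)
      variants <- if (isTRUE(config$augment)) {
        aug <- augment_sample(white, checked)
        list(id = list(aug$white_id, aug$checked_id),
             v = list(aug$white_v, aug$checked_v),
             h = list(aug$white_h, aug$checked_h),
             vh = list(aug$white_vh, aug$checked_vh))
      } else {
        list(id = list(white, checked))
      }
      lapply(names(variants), function(tag) {
        fv <- extract_pair_features(variants[[tag]][[1]],
                                    variants[[tag]][[2]], config)
        sid <- if (tag == "id") rec$sample_id else paste0(rec$sample_id, "_", tag)
        cbind(data.frame(sample_id = sid, stringsAsFactors = FALSE),
              as.data.frame(as.list(fv)),
              data.frame(label = rec$label, stringsAsFactors = FALSE))
      })
    }, error = function(e) {
      failures[[length(failures) + 1]] <<- data.frame(
        sample_id = rec$sample_id, reason = conditionMessage(e),
        stringsAsFactors = FALSE)
      NULL
    })
    if (!is.null(res)) rows <- c(rows, res)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sample_id = character(0))
  attr(out, "failures") <- if (length(failures) > 0) do.call(rbind, failures)
    else data.frame(sample_id = character(0), reason = character(0))
  out
}

#' Train a classifier on a feature table
#'
#' Fits the scaler on all provided rows, trains the requested model, and
#' returns everything needed for prediction.
#'
#' @param features feature table from [extract_features()].
#' @param model `"dnn"` or `"svm"`.
#' @param config [default_config()].
#' @return list with `model`, `scaler`, `model_type`, `train_report`.
#' @export
train_classifier <- function(features, model = c("dnn", "svm"),
                             config = default_config()) {
  model <- match.arg(model)
  x <- as.matrix(features[, FEATURE_NAMES])
  scaler <- fit_scaler(x)
  xs <- transform_features(scaler, x)
  fit <- if (model == "dnn") {
    cfg <- config$classifier$dnn
    cfg$seed <- config$seed
    train_dnn(xs, features$label, cfg)
  } else {
    train_svm(xs, features$label, config$classifier$svm)
  }
  pred <- predict(fit, xs)
  list(model = fit, scaler = scaler, model_type = model,
       train_report = evaluate_predictions(pred, features$label))
}

#' Classify one white/checked image pair
#'
#' Supports the real-time screening use case: one pair in, one dissolution
#' class (with class probabilities for the network) out.
#'
#' @param white_path,checked_path PNG paths.
#' @param trained output of [train_classifier()].
#' @param config [default_config()].
#' @return list with `class` and, for the DNN, `probabilities`.
#' @export
predict_pair <- function(white_path, checked_path, trained,
                         config = default_config()) {
  fv <- extract_pair_features(read_image_8bit(white_path),
                              read_image_8bit(checked_path), config)
  xs <- transform_features(trained$scaler, matrix(fv, 1,
                                                  dimnames = list(NULL, names(fv))))
  cls <- as.character(predict(trained$model, xs))
  probs <- if (trained$model_type == "dnn") {
    drop(predict(trained$model, xs, type = "prob"))
  } else NULL
  list(class = cls, probabilities = probs)
}

#' Run the full pipeline end to end
#'
#' Simulates (or loads) a dataset, extracts features, cross-validates and
#' trains the classifier, and writes four artifacts under `out_dir`:
#' `features.csv`, `model.rds`, `report.json`, and `config_used.yaml` (a
#' log of every stage parameter actually used).
#'
#' @param config [default_config()].
#' @param out_dir output directory.
#' @param model `"dnn"` or `"svm"`.
#' @param manifest optional existing manifest data frame; when `NULL` a
#'   synthetic dataset is generated under `out_dir/images`.
#' @param features optional pre-computed feature table (skips extraction;
#'   reruns from a persisted table reproduce the identical report).
#' @return list with `features`, `cv`, `trained`, `report`.
#' @export
run_end_to_end <- function(config = default_config(), out_dir = tempfile("solscreen_"),
                           model = c("dnn", "svm"), manifest = NULL,
                           features = NULL) {
  model <- match.arg(model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(features)) {
    if (is.null(manifest)) {
      samples <- sample_dataset(config$simulate$n_per_class,
                                seed = config$seed,
                                image_size = config$simulate$image_size,
                                cell_size_px = config$simulate$cell_size_px,
                                moire_prob = config$simulate$moire_prob,
                                tint_prob = config$simulate$tint_prob,
                                noise_sigma = config$simulate$noise_sigma)
      manifest <- write_dataset(samples, file.path(out_dir, "images"),
                                seed = config$seed)
    }
    features <- extract_features(manifest, config)
  }
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  cv <- kfold_cv(features[, FEATURE_NAMES], features$label,
                 k = config$classifier$k, model = model, seed = config$seed,
                 dnn_cfg = config$classifier$dnn,
                 svm_cfg = config$classifier$svm)
  trained <- train_classifier(features, model, config)
  saveRDS(trained, file.path(out_dir, "model.rds"))
  report <- list(model = model,
                 cv_mean_accuracy = cv$mean_accuracy,
                 cv_sd_accuracy = cv$sd_accuracy,
                 cv_fold_accuracy = cv$fold_accuracy,
                 train_accuracy = trained$train_report$accuracy,
                 confusion = unclass(trained$train_report$confusion),
                 tpr = trained$train_report$tpr,
                 ppv = trained$train_report$ppv)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(out_dir, "config_used.yaml"))
  list(features = features, cv = cv, trained = trained, report = report)
}

#' Composition of the validation datasets behind the screening method
#'
#' Sample-combination counts of the copper-salt training set (solutes
#' CuSO4, CuOAc, CuBr, Pd(OAc)2 in deionized water) and the
#' industrial-solute test set (2-bromo-4-phenylpyridine, 4-methoxyphenol,
#' naphthalic anhydride, and
#' 4,4'-bis(alpha,alpha-dimethylbenzyl)diphenylamine in toluene, methylene
#' chloride or hexane) used to validate this screening approach, together
#' with the augmented image counts: each sample combination is captured
#' over two backgrounds and flip-augmented four ways, i.e. eight training
#' images per combination.
#'
#' @return list with `train` and `test` composition tables,
#'   `train_combinations`, `test_combinations`, `augmentation_factor`,
#'   `train_images_augmented`.
#' @export
reference_dataset_counts <- function() {
  train <- data.frame(
    solute = c("CuSO4", "CuOAc", "CuBr", "Pd(OAc)2"),
    solvent = rep("DI water", 4),
    n_samples = c(43L, 41L, 30L, 37L),
    stringsAsFactors = FALSE)
  test <- data.frame(
    solute = c("2-bromo-4-phenylpyridine", "4-methoxyphenol",
               "naphthalic anhydride", "naphthalic anhydride",
               "naphthalic anhydride",
               "4,4'-bis(a,a-dimethylbenzyl)diphenylamine"),
    solvent = c("toluene", "toluene", "toluene", "methylene chloride",
                "hexane", "toluene"),
    n_samples = c(10L, 65L, 5L, 3L, 2L, 12L),
    stringsAsFactors = FALSE)
  backgrounds <- 2L
  flips <- 4L
  list(train = train, test = test,
       train_combinations = sum(train$n_samples),
       test_combinations = sum(test$n_samples),
       augmentation_factor = backgrounds * flips,
       train_images_augmented = sum(train$n_samples) * backgrounds * flips)
}
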
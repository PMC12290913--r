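#' Pipeline configuration
#'
#' One document configuring every stage of the workflow; CLI flags override
#' these values. Defaults reproduce the package's standard demonstration
#' conditions: 20 subjects per class, 50-slice sequences, 64 stub features,
#' between-class separation 6 noise-sd units, positional signal 1, 10
#' stratified folds, global seed 17.
#'
#' @param workdir Working directory holding every stage's outputs.
#' @param n_per_class Subjects per class for the synthetic generators.
#' @param plane Sectioning plane for the image path.
#' @param k_slices Central slices kept per subject.
#' @param image_side Slice side length after resizing.
#' @param feature_dim Encoder output dimension.
#' @param separation,positional_signal Feature-generator knobs.
#' @param n_folds,val_frac Cross-validation controls.
#' @param model [model_config()] overrides as a named list (e.g.
#'   `list(max_epochs = 30)`).
#' @param phantom_shape Voxel grid for phantom subjects.
#' @param seed Global seed propagated to every stage.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(workdir = tempfile("sliceformer_"),
                            n_per_class = 20L,
                            plane = "axial",
                            k_slices = 50L,
                            image_side = 224L,
                            feature_dim = 64L,
                            separation = 6,
                            positional_signal = 1,
                            n_folds = 10L,
                            val_frac = 0.2,
                            model = list(),
                            phantom_shape = c(32L, 32L, 64L),
                            seed = 17L) {
  structure(list(workdir = workdir, n_per_class = check_count(n_per_class, "n_per_class"),
                 plane = match.arg(plane, c("axial", "coronal", "sagittal")),
                 k_slices = check_count(k_slices, "k_slices"),
                 image_side = check_count(image_side, "image_side"),
                 feature_dim = check_count(feature_dim, "feature_dim"),
                 separation = separation,
                 positional_signal = positional_signal,
                 n_folds = check_count(n_folds, "n_folds", min = 2L),
                 val_frac = val_frac, model = model,
                 phantom_shape = as.integer(phantom_shape),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline config from JSON
#'
#' @param path JSON file with fields named as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, vals[intersect(names(vals), known)])
}

demo_model_config <- function(config) {
  defaults <- list(feature_dim = config$feature_dim, seq_len = config$k_slices,
                   n_classes = 3L, seed = config$seed)
  do.call(model_config, utils::modifyList(defaults, config$model))
}

#' Run the full cross-validated demonstration
#'
#' Generates a seeded synthetic cohort, splits it into stratified folds,
#' trains one sequence transformer per fold, evaluates each on its held-out
#' test subjects and aggregates the metrics. Two modes:
#'
#' * `"features"` (default): class-conditional slice-feature sequences from
#'   [make_feature_dataset()] — the conditions under which the classifier's
#'   recovery properties are stated (separation and positional-signal knobs
#'   apply here).
#' * `"phantom"`: the full image path — phantom volumes, plane slicing,
#'   central-slice selection, resizing, PNG folders, stub encoding — then the
#'   same folds/training/evaluation. Class signal comes from the
#'   stage-dependent cavity size.
#'
#' @param config A [pipeline_config()].
#' @param mode `"features"` or `"phantom"`.
#' @param verbose Log per-stage progress to stderr.
#'
#' @return An `eval_report` with one entry per fold; per-fold trained-model
#'   summaries are attached as attribute `"fold_models"` (a tibble) and the
#'   generating config as `"config"`.
#' @export
run_demo <- function(config = pipeline_config(), mode = c("features", "phantom"),
                     verbose = FALSE) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  if (mode == "features") {
    spec <- synthetic_feature_spec(
      n_per_class = config$n_per_class, seq_len = config$k_slices,
      feature_dim = config$feature_dim, separation = config$separation,
      positional_signal = config$positional_signal, seed = config$seed)
    sequences <- make_feature_dataset(spec)
    say("stage fixtures: %d feature sequences (%d x %d)",
        length(sequences), config$k_slices, config$feature_dim)
  } else {
    sequences <- phantom_cohort_features(config, say)
  }
  ds <- as_feature_dataset(sequences)
  folds <- make_folds(ds, n_folds = config$n_folds, val_frac = config$val_frac,
                      seed = config$seed)
  say("stage split-folds: %d folds over %d subjects", length(folds),
      length(ds$subject_ids))
  mcfg <- demo_model_config(config)
  reports <- vector("list", length(folds))
  fold_rows <- vector("list", length(folds))
  for (f in folds) {
    model <- train_fold(dataset_subset(ds, f$train_ids),
                        dataset_subset(ds, f$val_ids), mcfg)
    test <- dataset_subset(ds, f$test_ids)
    pred <- predict(model, test, type = "class")
    reports[[f$fold_index]] <- evaluate_fold(as.character(test$labels),
                                             as.character(pred), f$fold_index)
    fold_rows[[f$fold_index]] <- dplyr::bind_cols(tibble(fold = f$fold_index),
                                                  glance(model))
    say("stage train-eval: fold %d accuracy %.3f (%d epochs)",
        f$fold_index, reports[[f$fold_index]]$metrics$accuracy,
        nrow(model$history))
  }
  report <- aggregate_folds(reports)
  attr(report, "fold_models") <- dplyr::bind_rows(fold_rows)
  attr(report, "config") <- config
  say("demo complete in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  report
}

# phantom-mode cohort: volumes -> slices -> stub features, in memory, with
# PNG folders written under config$workdir so the image path is exercised.
phantom_cohort_features <- function(config, say = function(...) NULL) {
  backend <- encoder_backend("stub_projection", feature_dim = config$feature_dim,
                             seed = config$seed, input_side = config$image_side)
  root <- file.path(config$workdir, "prepared_data")
  sequences <- list()
  idx <- 0L
  for (cls in class_levels()) {
    for (j in seq_len(config$n_per_class)) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      vol <- make_phantom_volume(phantom_spec(
        cls, shape = config$phantom_shape, seed = subject_seed(config$seed, idx)))
      stack <- select_central(extract_plane_slices(vol, config$plane, sid),
                              k = config$k_slices)
      stack$slices <- lapply(stack$slices, resize_slice, side = config$image_side)
      save_slice_folder(stack, root)
      seqs <- extract_subject_features(file.path(root, sid, config$plane),
                                       backend, cls, seq_len = config$k_slices)
      sequences[[idx]] <- seqs
    }
  }
  say("stage prepare-slices + extract-features: %d subjects via %s", idx, root)
  sequences
}

# ---- stage runner -------------------------------------------------------

stage_paths <- function(config) {
  w <- config$workdir
  list(raw = file.path(w, "raw"),
       prepared = file.path(w, "prepared_data"),
       features = file.path(w, "features"),
       folds = file.path(w, "kfold_splits"),
       results = file.path(w, "results"),
       manifests = file.path(w, "manifests"))
}

stage_manifest_path <- function(config, stage) {
  file.path(stage_paths(config)$manifests, paste0(stage, ".json"))
}

write_stage_manifest <- function(config, stage, inputs, outputs, extra = list()) {
  p <- stage_paths(config)
  dir.create(p$manifests, recursive = TRUE, showWarnings = FALSE)
  inputs <- inputs[file.exists(inputs)]
  man <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                seed = config$seed,
                inputs = lapply(inputs, function(f) {
                  list(path = f, md5 = unname(tools::md5sum(f)))
                }),
                outputs = as.list(outputs)),
           extra)
  jsonlite::write_json(man, stage_manifest_path(config, stage),
                       auto_unbox = TRUE)
  invisible(man)
}

require_stage <- function(config, stage, needed) {
  missing <- needed[!file.exists(needed)]
  if (length(missing) > 0) {
    abort(sprintf("stage %s: missing prerequisite output(s): %s (run the previous stage first)",
                  stage, paste(missing, collapse = ", ")),
          class = "sliceformer_dependency_error")
  }
}

check_overwrite <- function(stage, paths, overwrite) {
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0 && !overwrite) {
    stop_param("stage %s: output(s) already exist (%s); rerun with overwrite = TRUE",
               stage, paste(utils::head(existing, 3), collapse = ", "))
  }
  unlink(existing, recursive = TRUE)
}

#' Run a single pipeline stage
#'
#' Executes exactly one stage against the config's working directory, writing
#' a per-stage manifest (inputs with MD5 hashes, outputs, seed) under
#' `workdir/manifests/`. Stages must run in order; a missing prerequisite is
#' a dependency error naming the missing files.
#'
#' Stages: `"make-fixtures"` (phantom NIfTIs + labels table under `raw/`),
#' `"prepare-slices"` (`prepared_data/<id>/<plane>/slice_*.png`),
#' `"extract-features"` (flat `features/` directory of per-subject arrays),
#' `"split-folds"` (`kfold_splits/` fold files) and `"train-eval"`
#' (`results/` metrics JSON + CSV and training histories).
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @param overwrite Replace existing stage outputs instead of erroring.
#' @param verbose Log progress.
#'
#' @return A manifest tibble or list describing the stage outputs.
#' @export
run_stage <- function(stage = c("make-fixtures", "prepare-slices",
                                "extract-features", "split-folds", "train-eval"),
                      config = pipeline_config(), overwrite = FALSE,
                      verbose = FALSE) {
  stage <- match.arg(stage)
  p <- stage_paths(config)
  say <- function(fmt, ...) if (verbose) message(sprintf("[%s] ", stage), sprintf(fmt, ...))
  t0 <- Sys.time()
  out <- switch(
    stage,
    "make-fixtures" = {
      check_overwrite(stage, p$raw, overwrite)
      dir.create(p$raw, recursive = TRUE, showWarnings = FALSE)
      idx <- 0L
      rows <- list()
      for (cls in class_levels()) {
        for (j in seq_len(config$n_per_class)) {
          idx <- idx + 1L
          sid <- sprintf("S%03d", idx)
          vol <- make_phantom_volume(phantom_spec(
            cls, shape = config$phantom_shape,
            seed = subject_seed(config$seed, idx)))
          path <- file.path(p$raw, paste0(sid, ".nii.gz"))
          write_volume_nifti(vol, path)
          rows[[idx]] <- tibble(subject_id = sid, label = cls, path = path)
        }
      }
      manifest <- dplyr::bind_rows(rows)
      data.table::fwrite(manifest[, c("subject_id", "label")],
                         file.path(p$raw, "labels.csv"))
      write_stage_manifest(config, stage, character(0),
                           c(p$raw, file.path(p$raw, "labels.csv")),
                           list(n_subjects = idx))
      manifest
    },
    "prepare-slices" = {
      require_stage(config, stage, c(p$raw, file.path(p$raw, "labels.csv")))
      check_overwrite(stage, p$prepared, overwrite)
      labels <- data.table::fread(file.path(p$raw, "labels.csv"))
      paths <- character(0)
      for (i in seq_len(nrow(labels))) {
        sid <- labels$subject_id[i]
        vol <- load_volume(file.path(p$raw, paste0(sid, ".nii.gz")))
        stack <- select_central(extract_plane_slices(vol, config$plane, sid),
                                k = config$k_slices)
        stack$slices <- lapply(stack$slices, resize_slice, side = config$image_side)
        paths <- c(paths, save_slice_folder(stack, p$prepared))
      }
      say("wrote %d slice files for %d subjects", length(paths), nrow(labels))
      write_stage_manifest(config, stage, file.path(p$raw, "labels.csv"),
                           p$prepared, list(n_files = length(paths)))
      tibble(path = paths)
    },
    "extract-features" = {
      require_stage(config, stage, p$prepared)
      check_overwrite(stage, p$features, overwrite)
      labels <- data.table::fread(file.path(p$raw, "labels.csv"))
      backend <- encoder_backend("stub_projection",
                                 feature_dim = config$feature_dim,
                                 seed = config$seed,
                                 input_side = config$image_side)
      written <- list()
      for (i in seq_len(nrow(labels))) {
        sid <- labels$subject_id[i]
        seqs <- extract_subject_features(
          file.path(p$prepared, sid, config$plane), backend, labels$label[i],
          seq_len = config$k_slices)
        written[[i]] <- save_features(seqs, p$features, backend)
      }
      write_stage_manifest(config, stage, file.path(p$raw, "labels.csv"),
                           p$features, list(n_subjects = nrow(labels)))
      tibble(subject_id = labels$subject_id,
             data_file = vapply(written, `[[`, character(1), "data"))
    },
    "split-folds" = {
      require_stage(config, stage, p$features)
      check_overwrite(stage, p$folds, overwrite)
      sequences <- load_feature_dataset(p$features)
      folds <- make_folds(sequences, n_folds = config$n_folds,
                          val_frac = config$val_frac, seed = config$seed)
      manifest <- write_fold_files(folds, sequences, p$folds)
      write_stage_manifest(config, stage,
                           list.files(p$features, full.names = TRUE),
                           p$folds, list(n_folds = config$n_folds))
      manifest
    },
    "train-eval" = {
      require_stage(config, stage, c(p$folds, file.path(p$folds, "manifest.json")))
      check_overwrite(stage, p$results, overwrite)
      dir.create(p$results, recursive = TRUE, showWarnings = FALSE)
      mcfg <- demo_model_config(config)
      reports <- list()
      histories <- list()
      for (i in seq_len(config$n_folds)) {
        fd <- read_fold_files(p$folds, i)
        model <- train_fold(fd$train, fd$validation, mcfg)
        pred <- predict(model, fd$test, type = "class")
        reports[[i]] <- evaluate_fold(as.character(fd$test$labels),
                                      as.character(pred), i)
        histories[[i]] <- dplyr::bind_cols(tibble(fold = i), model$history)
        say("fold %d accuracy %.3f", i, reports[[i]]$metrics$accuracy)
      }
      report <- aggregate_folds(reports)
      write_eval_report(report, p$results)
      jsonlite::write_json(dplyr::bind_rows(histories),
                           file.path(p$results, "training_history.json"),
                           auto_unbox = TRUE, digits = NA)
      write_stage_manifest(config, stage, file.path(p$folds, "manifest.json"),
                           p$results, list(n_folds = config$n_folds))
      report
    })
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}
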
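#' Stratified k-fold subject splits
#'
#' Subject-level stratified cross-validation by an explicit, library-free
#' algorithm: within each class the subject ids are shuffled once with the
#' seed and dealt round-robin into `n_folds` test buckets, so the test sets
#' partition the subjects and per-fold class proportions deviate from the
#' global proportions by at most one subject per class. For fold `i`, each
#' class's remaining (non-test) subjects are split into train/validation with
#' validation size `round(val_frac * remainder)` (at least 1 when the
#' remainder has >= 2 subjects, and always leaving >= 1 training subject).
#' Splitting is at subject level only — slices from one subject never cross
#' subsets.
#'
#' @param sequences List of [feature_sequence()]s (or a dataset from
#'   `as_feature_dataset`).
#' @param n_folds Number of folds (default 10, >= 2).
#' @param val_frac Validation fraction of each fold's non-test remainder
#'   (default 0.2, in (0, 1)).
#' @param seed Integer seed; identical seeds give identical folds.
#'
#' @return List of `n_folds` `fold_split` objects (fields `fold_index`,
#'   `train_ids`, `val_ids`, `test_ids`), with the seed and roster attached
#'   as attributes.
#' @export
#' @examples
#' ds <- make_feature_dataset(synthetic_feature_spec(3, seq_len = 4, feature_dim = 3))
#' folds <- make_folds(ds, n_folds = 3, seed = 1)
#' folds[[1]]$test_ids
make_folds <- function(sequences, n_folds = 10L, val_frac = 0.2, seed = 17L) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  if (!is.numeric(val_frac) || val_frac <= 0 || val_frac >= 1) {
    stop_param("`val_frac` must lie strictly between 0 and 1")
  }
  ds <- as_feature_dataset(sequences)
  ids <- ds$subject_ids
  if (anyDuplicated(ids)) stop_data("duplicate subject ids in the dataset")
  labels <- as_class_factor(as.character(ds$labels))
  classes <- levels(droplevels(labels))
  counts <- table(droplevels(labels))
  short <- names(counts)[counts < n_folds]
  if (length(short) > 0) {
    abort(sprintf("class %s has %d subject(s), fewer than n_folds = %d: stratified splitting impossible",
                  short[1], counts[[short[1]]], n_folds),
          class = "sliceformer_stratification_error")
  }
  perms <- withr::with_seed(as.integer(seed), {
    lapply(classes, function(cl) sample(ids[labels == cl]))
  })
  names(perms) <- classes
  buckets <- lapply(seq_len(n_folds), function(i) character(0))
  for (cl in classes) {
    p <- perms[[cl]]
    for (j in seq_along(p)) {
      k <- ((j - 1L) %% n_folds) + 1L
      buckets[[k]] <- c(buckets[[k]], p[j])
    }
  }
  folds <- lapply(seq_len(n_folds), function(i) {
    test <- buckets[[i]]
    train <- character(0); val <- character(0)
    for (cl in classes) {
      rem <- setdiff(perms[[cl]], test)  # keeps permuted order
      n_rem <- length(rem)
      n_val <- round(val_frac * n_rem)
      if (n_rem >= 2) n_val <- max(1L, n_val)
      n_val <- min(n_val, n_rem - 1L)
      if (n_rem <= 1) n_val <- 0L
      val <- c(val, rem[seq_len(n_val)])
      train <- c(train, rem[setdiff(seq_len(n_rem), seq_len(n_val))])
    }
    structure(list(fold_index = i, train_ids = train, val_ids = val,
                   test_ids = test),
              class = "fold_split")
  })
  attr(folds, "seed") <- as.integer(seed)
  attr(folds, "n_folds") <- n_folds
  attr(folds, "val_frac") <- val_frac
  attr(folds, "subject_ids") <- ids
  folds
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> fold %d: %d train / %d val / %d test subjects\n",
              x$fold_index, length(x$train_ids), length(x$val_ids),
              length(x$test_ids)))
  invisible(x)
}

#' Tidy a list of fold splits
#'
#' @param folds Output of [make_folds()].
#' @return Tibble with one row per subject per fold: `fold`, `subject_id`,
#'   `subset`.
#' @export
tidy_folds <- function(folds) {
  purrr::map_dfr(folds, function(f) {
    tibble(fold = f$fold_index,
           subject_id = c(f$train_ids, f$val_ids, f$test_ids),
           subset = rep(c("train", "validation", "test"),
                        c(length(f$train_ids), length(f$val_ids),
                          length(f$test_ids))))
  })
}

# subset a dataset by subject ids, preserving the requested order
dataset_subset <- function(ds, ids) {
  pos <- match(ids, ds$subject_ids)
  if (anyNA(pos)) {
    stop_data("subject(s) missing from the feature set: %s",
              paste(ids[is.na(pos)], collapse = ", "))
  }
  list(features = ds$features[pos],
       labels = ds$labels[pos],
       subject_ids = ds$subject_ids[pos])
}

#' Write per-fold array files
#'
#' Emits, for each fold `i`, six files in the persisted-array convention:
#' `traindata_Fold<i>.csv`, `trainlbl_Fold<i>.csv`, `validdata_Fold<i>.csv`,
#' `validlbl_Fold<i>.csv`, `testdata_Fold<i>.csv`, `testlbl_Fold<i>.csv`.
#' A data file is the fold subset's `n_subjects x seq_len x feature_dim`
#' array flattened subject-major (`n_subjects * seq_len` rows of
#' `feature_dim` columns); its label file lists `subject_id,label` rows in
#' the same subject order. A `manifest.json` records the seed, fold count,
#' sequence geometry and per-fold subject ids.
#'
#' @param folds Output of [make_folds()].
#' @param sequences The feature dataset the folds index into.
#' @param out_dir Writable output directory (created if needed).
#'
#' @return Tibble manifest: `fold`, `subset`, `data_file`, `label_file`,
#'   `n_subjects`.
#' @export
write_fold_files <- function(folds, sequences, out_dir) {
  ds <- as_feature_dataset(sequences)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_format("cannot create %s", out_dir)
  stems <- c(train = "train", validation = "valid", test = "test")
  rows <- list()
  for (f in folds) {
    parts <- list(train = f$train_ids, validation = f$val_ids,
                  test = f$test_ids)
    for (nm in names(parts)) {
      sub <- dataset_subset(ds, parts[[nm]])
      data_file <- file.path(out_dir, sprintf("%sdata_Fold%d.csv", stems[[nm]],
                                              f$fold_index))
      lbl_file <- file.path(out_dir, sprintf("%slbl_Fold%d.csv", stems[[nm]],
                                             f$fold_index))
      fwrite_matrix(do.call(rbind, sub$features), data_file)
      data.table::fwrite(data.table::data.table(subject_id = sub$subject_ids,
                                                label = as.character(sub$labels)),
                         lbl_file)
      rows[[length(rows) + 1L]] <- tibble(
        fold = f$fold_index, subset = nm, data_file = data_file,
        label_file = lbl_file, n_subjects = length(parts[[nm]]))
    }
  }
  seq_len_ <- nrow(ds$features[[1]])
  feature_dim <- ncol(ds$features[[1]])
  manifest <- list(
    seed = attr(folds, "seed"), n_folds = attr(folds, "n_folds"),
    val_frac = attr(folds, "val_frac"),
    seq_len = seq_len_, feature_dim = feature_dim,
    folds = lapply(folds, function(f) {
      list(fold = f$fold_index, train_ids = f$train_ids,
           val_ids = f$val_ids, test_ids = f$test_ids)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  dplyr::bind_rows(rows)
}

#' Read one fold's train/validation/test datasets back
#'
#' Inverse of [write_fold_files()] for a single fold.
#'
#' @param dir Directory written by [write_fold_files()].
#' @param fold Fold index.
#'
#' @return List with elements `train`, `validation`, `test`, each a dataset
#'   (features list, labels factor, subject_ids).
#' @export
read_fold_files <- function(dir, fold) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop_format("missing manifest.json in %s", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  s <- man$seq_len
  stems <- c(train = "train", validation = "valid", test = "test")
  out <- lapply(names(stems), function(nm) {
    data_file <- file.path(dir, sprintf("%sdata_Fold%d.csv", stems[[nm]], fold))
    lbl_file <- file.path(dir, sprintf("%slbl_Fold%d.csv", stems[[nm]], fold))
    if (!file.exists(data_file) || !file.exists(lbl_file)) {
      stop_format("missing fold file(s) for fold %d (%s subset) in %s",
                  fold, nm, dir)
    }
    flat <- fread_matrix(data_file)
    lbl <- data.table::fread(lbl_file)
    n <- nrow(lbl)
    if (nrow(flat) != n * s) {
      stop_format("fold file %s has %d rows, expected %d subjects x %d slices",
                  data_file, nrow(flat), n, s)
    }
    feats <- lapply(seq_len(n), function(j) flat[((j - 1) * s + 1):(j * s), , drop = FALSE])
    list(features = feats, labels = as_class_factor(lbl$label),
         subject_ids = lbl$subject_id)
  })
  names(out) <- names(stems)
  out
}
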
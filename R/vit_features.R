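#' Split an image into non-overlapping patches
#'
#' Divides a square image of side `S` into an `(S/patch_side) x (S/patch_side)`
#' grid of square patches, enumerated in row-major order (left-to-right, then
#' top-to-bottom); each patch is flattened column-major, channels last. This
#' is the geometry a patch-16 image transformer applies to its 224 x 224
#' input: 14 x 14 patches of 16 x 16 pixels.
#'
#' @param image 2D matrix or 3-channel array with equal, square spatial dims.
#' @param patch_side Patch side length in pixels (default 16).
#'
#' @return An object of class `patch_grid`: list with `patches` (matrix,
#'   `n_patches x patch_side^2 * channels`), `grid_shape`, `patch_side`,
#'   `channels` and `side`.
#' @export
#' @examples
#' pg <- patchify(matrix(runif(224^2), 224, 224))
#' pg$grid_shape
patchify <- function(image, patch_side = 16L) {
  patch_side <- check_count(patch_side, "patch_side")
  dims <- dim(image)
  if (is.null(dims) || !length(dims) %in% c(2, 3)) {
    stop_param("`image` must be a 2D matrix or a 3D (H x W x channels) array")
  }
  if (dims[1] != dims[2]) stop_param("`image` must be square")
  s <- dims[1]
  ch <- if (length(dims) == 3) dims[3] else 1L
  if (s %% patch_side != 0) {
    stop_param("image side %d is not divisible by patch side %d", s, patch_side)
  }
  g <- s %/% patch_side
  patches <- matrix(0, g * g, patch_side^2 * ch)
  img <- if (ch == 1L) array(image, dim = c(s, s, 1L)) else image
  for (r in seq_len(g)) {
    rows <- ((r - 1L) * patch_side + 1L):(r * patch_side)
    for (co in seq_len(g)) {
      cols <- ((co - 1L) * patch_side + 1L):(co * patch_side)
      patches[(r - 1L) * g + co, ] <- as.vector(img[rows, cols, , drop = FALSE])
    }
  }
  structure(list(patches = patches, grid_shape = c(g, g),
                 patch_side = patch_side, channels = ch, side = s),
            class = "patch_grid")
}

#' Reassemble an image from a patch grid
#'
#' Exact inverse of [patchify()].
#'
#' @param grid A `patch_grid`.
#'
#' @return The original 2D matrix (1 channel) or 3D array.
#' @export
unpatchify <- function(grid) {
  if (!inherits(grid, "patch_grid")) stop_format("`grid` must be a patch_grid")
  g <- grid$grid_shape[1]
  ps <- grid$patch_side
  ch <- grid$channels
  if (!is.matrix(grid$patches) || nrow(grid$patches) != g * grid$grid_shape[2] ||
      ncol(grid$patches) != ps^2 * ch) {
    stop_format("inconsistent patch grid: %d patches of length %d do not match grid %dx%d, patch side %d, %d channel(s)",
                nrow(grid$patches), ncol(grid$patches),
                grid$grid_shape[1], grid$grid_shape[2], ps, ch)
  }
  img <- array(0, dim = c(grid$side, grid$side, ch))
  for (r in seq_len(g)) {
    rows <- ((r - 1L) * ps + 1L):(r * ps)
    for (co in seq_len(grid$grid_shape[2])) {
      cols <- ((co - 1L) * ps + 1L):(co * ps)
      img[rows, cols, ] <- array(grid$patches[(r - 1L) * g + co, ],
                                 dim = c(ps, ps, ch))
    }
  }
  if (ch == 1L) img[, , 1] else img
}

#' Construct a slice-encoder backend
#'
#' Two backends share one interface:
#' * `"stub_projection"` — a seeded random linear map of per-patch mean
#'   intensities (one mean per patch, 196 for the default geometry) to
#'   `feature_dim`. Deterministic, cheap, order-sensitive; makes the whole
#'   pipeline runnable and testable offline.
#' * `"pretrained_vit"` — a pluggable slot for an externally supplied
#'   pretrained image-transformer encoder. Pass `encode_fun`, a function
#'   taking a 224 x 224 x 3 array and returning a length-`feature_dim`
#'   vector (e.g. the encoder's pooled/class-token output).
#'
#' @param name Backend name.
#' @param feature_dim Output feature dimension.
#' @param seed Seed for the stub projection matrix.
#' @param input_side Expected slice side in pixels.
#' @param patch_side Patch side for the stub's patch means.
#' @param encode_fun Encoder function for `"pretrained_vit"`.
#'
#' @return An object of class `encoder_backend`.
#' @export
encoder_backend <- function(name = c("stub_projection", "pretrained_vit"),
                            feature_dim = 64L, seed = 17L,
                            input_side = 224L, patch_side = 16L,
                            encode_fun = NULL) {
  name <- match.arg(name)
  feature_dim <- check_count(feature_dim, "feature_dim")
  input_side <- check_count(input_side, "input_side")
  patch_side <- check_count(patch_side, "patch_side")
  if (input_side %% patch_side != 0) {
    stop_param("input side %d not divisible by patch side %d", input_side, patch_side)
  }
  n_patches <- (input_side %/% patch_side)^2
  if (name == "stub_projection") {
    W <- withr::with_seed(as.integer(seed),
                          matrix(rnorm(n_patches * feature_dim), n_patches,
                                 feature_dim) / sqrt(n_patches))
    b <- structure(list(name = name, feature_dim = feature_dim,
                        seed = as.integer(seed), input_side = input_side,
                        patch_side = patch_side, W = W),
                   class = "encoder_backend")
  } else {
    if (!is.function(encode_fun)) {
      stop_param(paste0("the pretrained_vit backend needs `encode_fun`: pretrained ",
                        "encoder weights are not bundled and must be supplied ",
                        "externally"))
    }
    b <- structure(list(name = name, feature_dim = feature_dim,
                        input_side = input_side, patch_side = patch_side,
                        encode_fun = encode_fun),
                   class = "encoder_backend")
  }
  b
}

#' @export
print.encoder_backend <- function(x, ...) {
  cat(sprintf("<encoder_backend> %s, feature_dim %d, input %dx%d, patch %d\n",
              x$name, x$feature_dim, x$input_side, x$input_side, x$patch_side))
  invisible(x)
}

#' Encode one slice into a feature vector
#'
#' Grayscale input is replicated to 3 channels before encoding (pretrained
#' natural-image encoders expect 3 channels; the stub averages channels back
#' out, so replication is a no-op for it numerically but keeps one contract).
#'
#' @param image 2D matrix (or `side x side x 3` array) matching the backend's
#'   `input_side`.
#' @param backend An [encoder_backend()].
#'
#' @return Numeric vector of length `backend$feature_dim`, finite,
#'   deterministic given the backend state.
#' @export
encode_slice <- function(image, backend) {
  stopifnot(inherits(backend, "encoder_backend"))
  dims <- dim(image)
  side <- backend$input_side
  if (is.null(dims) || !length(dims) %in% c(2, 3) ||
      dims[1] != side || dims[2] != side) {
    stop_param("`image` must be %dx%d (got %s)", side, side,
               paste(dims %||% length(image), collapse = "x"))
  }
  if (length(dims) == 2) {
    image <- array(rep(image, 3L), dim = c(side, side, 3L))
  }
  if (backend$name == "stub_projection") {
    pg <- patchify(image, backend$patch_side)
    m <- rowMeans(pg$patches)
    v <- as.numeric(m %*% backend$W)
  } else {
    v <- as.numeric(backend$encode_fun(image))
  }
  if (length(v) != backend$feature_dim || any(!is.finite(v))) {
    stop_format("backend returned an invalid feature vector (length %d, expected %d)",
                length(v), backend$feature_dim)
  }
  v
}

#' Encode a subject's prepared slice folder into a feature sequence
#'
#' Reads the PNG slices in filename (= anatomical) order and encodes each;
#' row `i` of the result is the encoding of the `i`-th slice.
#'
#' @param slice_dir Directory holding one subject's prepared slices for one
#'   plane (the `save_slice_folder()` layout).
#' @param backend An [encoder_backend()].
#' @param label The subject's diagnosis label.
#' @param seq_len Required slice count (default 50); a folder with a
#'   different count is a shape error.
#' @param subject_id Subject id; defaults to the folder's parent name.
#' @param plane Plane tag; defaults to the folder name.
#'
#' @return A [feature_sequence()] of shape `seq_len x feature_dim`.
#' @export
extract_subject_features <- function(slice_dir, backend, label, seq_len = 50L,
                                     subject_id = basename(dirname(slice_dir)),
                                     plane = basename(slice_dir)) {
  stack <- load_slice_folder(slice_dir, plane = plane, subject_id = subject_id)
  n <- length(stack$slices)
  if (n != seq_len) {
    stop_shape("folder %s holds %d slices but the configured sequence length is %d",
               slice_dir, n, seq_len)
  }
  feats <- t(vapply(stack$slices, encode_slice, numeric(backend$feature_dim),
                    backend = backend))
  feature_sequence(feats, label, subject_id, plane)
}

#' Persist / load one subject's feature sequence
#'
#' `save_features()` writes three files per subject into a flat directory,
#' keyed by subject id: `<id>_scan_data.csv` (the `n_slices x feature_dim`
#' matrix, full-precision text), `<id>_scan_labels.txt` (the single diagnosis
#' label) and `<id>_meta.json` (feature_dim, backend name, seed, plane).
#' `load_features()` inverts it exactly.
#'
#' @param seq A [feature_sequence()].
#' @param out_dir Writable output directory (created if needed).
#' @param backend Optional [encoder_backend()] recorded in the metadata
#'   sidecar.
#'
#' @return `save_features()`: named character vector of the written paths.
#' @export
save_features <- function(seq, out_dir, backend = NULL) {
  stopifnot(inherits(seq, "feature_sequence"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_format("cannot create %s", out_dir)
  stem <- file.path(out_dir, seq$subject_id)
  data_path <- paste0(stem, "_scan_data.csv")
  lbl_path <- paste0(stem, "_scan_labels.txt")
  meta_path <- paste0(stem, "_meta.json")
  fwrite_matrix(seq$features, data_path)
  writeLines(seq$label, lbl_path)
  meta <- list(subject_id = seq$subject_id, plane = seq$plane,
               n_slices = nrow(seq$features), feature_dim = ncol(seq$features))
  if (!is.null(backend)) {
    meta$backend <- backend$name
    meta$seed <- backend$seed
  }
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, null = "null")
  c(data = data_path, labels = lbl_path, meta = meta_path)
}

#' @rdname save_features
#' @param dir Directory written by `save_features()`.
#' @param subject_id Subject to load.
#' @return `load_features()`: the reconstructed [feature_sequence()].
#' @export
load_features <- function(dir, subject_id) {
  stem <- file.path(dir, subject_id)
  data_path <- paste0(stem, "_scan_data.csv")
  lbl_path <- paste0(stem, "_scan_labels.txt")
  if (!file.exists(data_path)) {
    stop_format("missing feature data file %s", data_path)
  }
  if (!file.exists(lbl_path)) {
    stop_format("missing companion labels file %s", lbl_path)
  }
  feats <- fread_matrix(data_path)
  label <- readLines(lbl_path, warn = FALSE)[1]
  meta_path <- paste0(stem, "_meta.json")
  plane <- NA_character_
  if (file.exists(meta_path)) {
    plane <- jsonlite::read_json(meta_path)$plane %||% NA_character_
    if (is.null(plane)) plane <- NA_character_
  }
  feature_sequence(feats, label, subject_id, plane)
}

#' List subjects present in a feature directory
#'
#' @param dir A directory written by [save_features()].
#' @return Sorted character vector of subject ids.
#' @export
list_feature_subjects <- function(dir) {
  files <- list.files(dir, pattern = "_scan_data\\.csv$")
  sort(sub("_scan_data\\.csv$", "", files))
}

#' Load every subject's features from a directory
#'
#' @param dir A directory written by [save_features()].
#' @return List of [feature_sequence()] objects, sorted by subject id.
#' @export
load_feature_dataset <- function(dir) {
  ids <- list_feature_subjects(dir)
  if (length(ids) == 0) stop_format("no *_scan_data.csv files in %s", dir)
  lapply(ids, function(id) load_features(dir, id))
}
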
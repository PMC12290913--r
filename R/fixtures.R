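#' Specification for a synthetic structural-MRI phantom
#'
#' Describes one subject's phantom: an ellipsoidal "brain" of elevated
#' intensity containing a concentric low-intensity cavity standing in for the
#' ventricular system. The cavity radius grows with disease stage
#' (NC < MCI < AD in the default preset), mimicking the direction of atrophy,
#' so class signal propagates through slicing and feature extraction.
#'
#' @param class_label One of `"NC"`, `"MCI"`, `"AD"`.
#' @param shape Integer triple, voxel grid dimensions; every component >= 8.
#' @param ventricle_scale Cavity semi-axes as a fraction of the brain
#'   semi-axes. `NULL` selects the class preset (NC 0.15, MCI 0.25, AD 0.35).
#' @param noise_sd Standard deviation of additive Gaussian voxel noise (>= 0).
#' @param seed Integer seed; identical specs yield bitwise-identical volumes.
#'
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' phantom_spec("AD", shape = c(32, 32, 32), noise_sd = 0)
phantom_spec <- function(class_label,
                         shape = c(48L, 48L, 64L),
                         ventricle_scale = NULL,
                         noise_sd = 0.02,
                         seed = 1L) {
  class_label <- match.arg(class_label, class_levels())
  if (length(shape) != 3 || any(shape != as.integer(shape)) || any(shape < 8)) {
    stop_param("`shape` must be three integers, each >= 8")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop_param("`noise_sd` must be a single non-negative number")
  }
  if (is.null(ventricle_scale)) {
    ventricle_scale <- c(NC = 0.15, MCI = 0.25, AD = 0.35)[[class_label]]
  }
  if (!is.numeric(ventricle_scale) || length(ventricle_scale) != 1 ||
      ventricle_scale < 0 || ventricle_scale >= 1) {
    stop_param("`ventricle_scale` must be a single number in [0, 1)")
  }
  structure(
    list(class_label = class_label, shape = as.integer(shape),
         ventricle_scale = ventricle_scale, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a phantom brain volume
#'
#' Builds a 3D intensity grid containing an ellipsoidal brain (intensity 0.8)
#' with semi-axes at 40% of each grid dimension, an internal concentric
#' cavity (intensity 0.1) whose semi-axes are `ventricle_scale` times the
#' brain semi-axes, zero background, additive Gaussian noise of sd
#' `noise_sd`, and final clipping to [0, 1].
#'
#' @param spec A [phantom_spec()].
#'
#' @return A `volume_image` (see [load_volume()]) with 1 mm isotropic spacing
#'   and RAS axis labels (sagittal, coronal, axial), plus the generating spec
#'   attached as attribute `"spec"`.
#' @export
#' @examples
#' vol <- make_phantom_volume(phantom_spec("NC", shape = c(16, 16, 16)))
#' dim(vol$data)
make_phantom_volume <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_param("`spec` must be a phantom_spec")
  shp <- spec$shape
  # normalized coordinates in [-1, 1] per axis, voxel centers
  ax <- lapply(shp, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  # squared ellipsoid radius with brain semi-axes 0.8 (fraction of half-width)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  brain <- r2 <= 0.8^2
  vol <- array(0, dim = shp)
  vol[brain] <- 0.8
  if (spec$ventricle_scale > 0) {
    cavity <- r2 <= (0.8 * spec$ventricle_scale)^2
    vol[cavity] <- 0.1
  }
  if (spec$noise_sd > 0) {
    vol <- vol + withr::with_seed(
      spec$seed, array(rnorm(prod(shp), sd = spec$noise_sd), dim = shp))
  }
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  out <- volume_image(vol, spacing = c(1, 1, 1),
                      axis_labels = c("sagittal", "coronal", "axial"))
  attr(out, "spec") <- spec
  out
}

#' Write a phantom volume as NIfTI
#'
#' @param volume A `volume_image`, e.g. from [make_phantom_volume()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#'
#' @return `path`, invisibly. The header declares the volume's voxel spacing
#'   (1 mm isotropic for phantoms).
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Specification for a synthetic slice-feature dataset
#'
#' Describes a class-balanced set of per-subject feature sequences emulating
#' what the slice encoder produces from real volumes: one `seq_len x
#' feature_dim` matrix per subject. Class `c` rows are drawn as
#' `separation * e_c + positional term + N(0, 1)` noise, where the `e_c` are
#' fixed orthonormal directions (the first `n_classes` coordinate axes), and
#' the positional term is `positional_signal * sin(2 * pi * p / seq_len)`
#' along the normalised all-ones direction at slice index `p` (0-based), so
#' slice order carries signal when `positional_signal > 0`.
#'
#' @param n_per_class Subjects per class (> 0).
#' @param seq_len Slices per subject (default 50).
#' @param feature_dim Feature dimension; must be >= the number of classes.
#' @param separation Between-class mean offset in units of the noise sd.
#' @param positional_signal Amplitude of the slice-index-dependent component.
#' @param seed Integer seed; subject `i` uses sub-seed `seed + i - 1`.
#' @param classes Label set (default the full NC/MCI/AD panel).
#'
#' @return An object of class `synthetic_feature_spec`.
#' @export
synthetic_feature_spec <- function(n_per_class,
                                   seq_len = 50L,
                                   feature_dim = 64L,
                                   separation = 6,
                                   positional_signal = 1,
                                   seed = 17L,
                                   classes = class_levels()) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  seq_len <- check_count(seq_len, "seq_len")
  feature_dim <- check_count(feature_dim, "feature_dim")
  if (!all(classes %in% class_levels()) || anyDuplicated(classes)) {
    stop_param("`classes` must be distinct labels from %s",
               paste(class_levels(), collapse = "/"))
  }
  if (feature_dim < length(classes)) {
    stop_param(paste0("`feature_dim` (%d) must be >= number of classes (%d): ",
                      "orthogonal class directions are impossible otherwise"),
               feature_dim, length(classes))
  }
  if (separation < 0 || positional_signal < 0) {
    stop_param("`separation` and `positional_signal` must be non-negative")
  }
  structure(
    list(n_per_class = n_per_class, seq_len = seq_len,
         feature_dim = feature_dim, separation = separation,
         positional_signal = positional_signal, seed = as.integer(seed),
         classes = classes),
    class = "synthetic_feature_spec"
  )
}

#' One subject's ordered slice-feature matrix
#'
#' @param features Numeric matrix, `n_slices x feature_dim`, finite.
#' @param label Class label (`"NC"`, `"MCI"` or `"AD"`).
#' @param subject_id Subject identifier.
#' @param plane Sectioning plane the features came from, or `NA`.
#'
#' @return An object of class `feature_sequence`.
#' @export
feature_sequence <- function(features, label, subject_id, plane = NA_character_) {
  if (!is.matrix(features) || !is.numeric(features)) {
    stop_param("`features` must be a numeric matrix")
  }
  if (any(!is.finite(features))) stop_data("`features` contains non-finite entries")
  structure(
    list(features = features,
         label = as.character(as_class_factor(label)),
         subject_id = as.character(subject_id),
         plane = plane),
    class = "feature_sequence"
  )
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence> subject %s, label %s, %d slices x %d features\n",
              x$subject_id, x$label, nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Generate a synthetic slice-feature dataset
#'
#' @param spec A [synthetic_feature_spec()].
#'
#' @return A list of [feature_sequence()] objects, exactly
#'   `n_per_class` per class, in class-major order with subject ids
#'   `S001, S002, ...`. Reproducible: the same spec (including seed) gives
#'   bitwise-identical output.
#' @export
#' @examples
#' ds <- make_feature_dataset(synthetic_feature_spec(2, seq_len = 5, feature_dim = 4))
#' length(ds)
make_feature_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_feature_spec")) {
    stop_param("`spec` must be a synthetic_feature_spec")
  }
  s <- spec$seq_len; d <- spec$feature_dim
  pos_dir <- rep(1, d) / sqrt(d)
  pos_wave <- sin(2 * pi * (seq_len(s) - 1) / s)
  pos_term <- spec$positional_signal * outer(pos_wave, pos_dir)
  idx <- 0L
  out <- vector("list", spec$n_per_class * length(spec$classes))
  for (cls_i in seq_along(spec$classes)) {
    mu <- numeric(d)
    mu[cls_i] <- spec$separation
    for (j in seq_len(spec$n_per_class)) {
      idx <- idx + 1L
      noise <- withr::with_seed(subject_seed(spec$seed, idx),
                                matrix(rnorm(s * d), s, d))
      feats <- matrix(mu, s, d, byrow = TRUE) + pos_term + noise
      out[[idx]] <- feature_sequence(feats, spec$classes[cls_i],
                                     sprintf("S%03d", idx))
    }
  }
  out
}
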
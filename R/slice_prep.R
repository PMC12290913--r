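#' 3D volume container
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing Positive real triple, voxel spacing in mm.
#' @param axis_labels Character triple naming the sectioning plane each array
#'   axis corresponds to, a permutation of `c("sagittal","coronal","axial")`.
#'
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1),
                         axis_labels = c("sagittal", "coronal", "axial")) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_format("volume data must be a 3D array (got %d dimension(s))",
                length(dim(data) %||% length(data)))
  }
  if (any(dim(data) < 1)) stop_format("all volume dimensions must be >= 1")
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop_param("`spacing` must be three positive numbers")
  }
  if (!setequal(axis_labels, c("sagittal", "coronal", "axial"))) {
    stop_param("`axis_labels` must be a permutation of sagittal/coronal/axial")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 axis_labels = axis_labels),
            class = "volume_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm, axes %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(x$axis_labels, collapse = "/")))
  invisible(x)
}

# Map a NIfTI orientation string (e.g. "RAS", "LPI") to per-axis plane labels.
# R/L vary along the sagittal axis, A/P along the coronal, S/I along the axial.
orientation_to_planes <- function(code) {
  lut <- c(R = "sagittal", L = "sagittal", A = "coronal", P = "coronal",
           S = "axial", I = "axial")
  lab <- unname(lut[strsplit(code, "")[[1]]])
  if (length(lab) != 3 || anyNA(lab) ||
      !setequal(lab, c("sagittal", "coronal", "axial"))) {
    return(NULL)
  }
  lab
}

#' Load a registered 3D volume from NIfTI
#'
#' Reads a skull-stripped, spatially normalised T1 volume. Voxel spacing comes
#' from the header `pixdim`; the mapping of array axes to anatomical planes is
#' derived from the header orientation codes. Volumes without usable
#' orientation metadata are assumed RAS (axis 1 sagittal, 2 coronal, 3 axial)
#' with a warning. Intensities are passed through unmodified.
#'
#' @param path Path to a readable 3D NIfTI file (`.nii`, `.nii.gz`).
#'
#' @return A [volume_image()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop_format("cannot read NIfTI file: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_format("not a readable NIfTI file: %s (%s)",
                                                  path, conditionMessage(e)))
  dims <- dim(img)
  if (length(dims) != 3) {
    stop_format("expected a 3D volume but %s has %d dimensions", path, length(dims))
  }
  lab <- tryCatch(orientation_to_planes(RNifti::orientation(img)),
                  error = function(e) NULL)
  if (is.null(lab)) {
    warn(sprintf("no usable orientation metadata in %s; assuming RAS", path))
    lab <- c("sagittal", "coronal", "axial")
  }
  volume_image(array(as.numeric(img), dim = dims),
               spacing = RNifti::pixdim(img)[1:3],
               axis_labels = lab)
}

#' Ordered stack of 2D slices from one subject
#'
#' @param slices List of 2D numeric matrices, all the same shape, anatomical
#'   order.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param source_indices 0-based positions of each slice along the sectioning
#'   axis; strictly increasing and consecutive.
#' @param subject_id Subject identifier.
#'
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, plane, source_indices, subject_id = "subject") {
  plane <- match.arg(plane, c("axial", "coronal", "sagittal"))
  if (length(slices) == 0) stop_param("`slices` must be nonempty")
  shp <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1)))) {
    stop_shape("all slices must share one shape")
  }
  si <- as.integer(source_indices)
  if (length(si) != length(slices) ||
      (length(si) > 1 && !all(diff(si) == 1L))) {
    stop_param("`source_indices` must be consecutive increasing integers, one per slice")
  }
  structure(list(slices = slices, plane = plane, source_indices = si,
                 subject_id = as.character(subject_id)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> subject %s, %d %s slices (%s), indices %d..%d\n",
              x$subject_id, length(x$slices), x$plane,
              paste(dim(x$slices[[1]]), collapse = "x"),
              min(x$source_indices), max(x$source_indices)))
  invisible(x)
}

#' Section a volume along an anatomical plane
#'
#' Produces one 2D slice per index along the sectioning axis, ascending.
#' Axial slicing sections along the volume's axial (inferior-superior) axis,
#' and likewise for coronal and sagittal; the axis is looked up from the
#' volume's `axis_labels`.
#'
#' @param volume A [volume_image()].
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param subject_id Subject identifier carried on the stack.
#'
#' @return A [slice_stack()] whose slice count equals the sectioning axis's
#'   dimension, `source_indices` `0..n-1`.
#' @export
extract_plane_slices <- function(volume, plane, subject_id = "subject") {
  stopifnot(inherits(volume, "volume_image"))
  if (length(plane) != 1 || !plane %in% c("axial", "coronal", "sagittal")) {
    stop_param("`plane` must be one of axial/coronal/sagittal (got %s)",
               paste(format(plane), collapse = ","))
  }
  axis <- which(volume$axis_labels == plane)
  n <- dim(volume$data)[axis]
  slices <- lapply(seq_len(n), function(i) {
    switch(axis,
           `1` = volume$data[i, , , drop = TRUE],
           `2` = volume$data[, i, , drop = TRUE],
           `3` = volume$data[, , i, drop = TRUE])
  })
  slice_stack(slices, plane, seq_len(n) - 1L, subject_id)
}

#' Keep the central k slices of a stack
#'
#' With `N` input slices the window starts at offset `floor((N - k) / 2)`
#' (0-based), so when `N - k` is odd the extra discarded slice comes from the
#' top of the stack. Source indices are preserved from the input. Idempotent
#' for fixed `k`.
#'
#' @param stack A [slice_stack()].
#' @param k Number of slices to keep (default 50).
#'
#' @return A [slice_stack()] of exactly `k` contiguous, centred slices.
#' @export
#' @examples
#' vol <- make_phantom_volume(phantom_spec("NC", shape = c(16, 16, 60), noise_sd = 0))
#' st <- select_central(extract_plane_slices(vol, "axial"), k = 50)
#' range(st$source_indices)
select_central <- function(stack, k = 50L) {
  stopifnot(inherits(stack, "slice_stack"))
  k <- check_count(k, "k")
  n <- length(stack$slices)
  if (n < k) {
    abort(sprintf("stack has %d slices but %d are required", n, k),
          class = "sliceformer_insufficient_slices_error", n = n, k = k)
  }
  start <- (n - k) %/% 2L  # 0-based offset
  sel <- seq.int(start + 1L, start + k)
  slice_stack(stack$slices[sel], stack$plane, stack$source_indices[sel],
              stack$subject_id)
}

#' Resize a 2D slice with bilinear interpolation
#'
#' Center-aligned bilinear resampling to a square `side x side` grid, with
#' the output clamped to the input's intensity range so interpolation never
#' overshoots. An input already of the target shape is returned unchanged.
#'
#' @param slice Nonempty 2D numeric matrix.
#' @param side Output side length in pixels (default 224, the input
#'   resolution of patch-16 pretrained image encoders).
#'
#' @return A `side x side` numeric matrix.
#' @export
resize_slice <- function(slice, side = 224L) {
  if (!is.matrix(slice) || any(dim(slice) < 1)) {
    stop_param("`slice` must be a nonempty 2D matrix")
  }
  if (length(side) != 1 || !is.numeric(side) || side <= 0 || side != as.integer(side)) {
    stop_param("`side` must be a single positive integer (got %s)",
               paste(format(side), collapse = ","))
  }
  side <- as.integer(side)
  if (all(dim(slice) == side)) return(slice)
  out <- EBImage::imageData(
    EBImage::resize(EBImage::Image(slice), w = side, h = side, filter = "bilinear"))
  lo <- min(slice); hi <- max(slice)
  out[out < lo] <- lo
  out[out > hi] <- hi
  out
}

#' Write a prepared stack as a per-subject PNG folder
#'
#' Writes `root/<subject_id>/<plane>/slice_<index>.png`, one 8-bit grayscale
#' PNG per slice, intensities min-max scaled per slice to \[0, 255\] (a
#' constant slice maps to mid-gray). Indices in filenames are the stack's
#' source indices, zero-padded to a fixed width so lexicographic filename
#' order equals anatomical order.
#'
#' @param stack A prepared [slice_stack()] (central-selected, resized).
#' @param root Output root directory (created if needed).
#'
#' @return Character vector of written file paths, in anatomical order.
#' @export
save_slice_folder <- function(stack, root) {
  stopifnot(inherits(stack, "slice_stack"))
  dir <- file.path(root, stack$subject_id, stack$plane)
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_format("cannot create output directory %s", dir)
  width <- max(3L, nchar(as.character(max(stack$source_indices))))
  paths <- character(length(stack$slices))
  for (i in seq_along(stack$slices)) {
    s <- stack$slices[[i]]
    rng <- range(s)
    g <- if (rng[1] == rng[2]) {
      matrix(0.5, nrow(s), ncol(s))
    } else {
      (s - rng[1]) / (rng[2] - rng[1])
    }
    p <- file.path(dir, sprintf("slice_%0*d.png", width, stack$source_indices[i]))
    png::writePNG(g, p)
    paths[i] <- p
  }
  paths
}

#' Read a PNG slice folder back into a stack
#'
#' Inverse of [save_slice_folder()] up to 8-bit quantisation: files are read
#' in lexicographic (= anatomical) order and source indices are recovered
#' from the filenames.
#'
#' @param dir Directory containing `slice_*.png` files.
#' @param plane Plane tag for the resulting stack.
#' @param subject_id Subject identifier.
#'
#' @return A [slice_stack()] with intensities in \[0, 1\].
#' @export
load_slice_folder <- function(dir, plane = "axial", subject_id = basename(dirname(dir))) {
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.png$", full.names = TRUE))
  if (length(files) == 0) stop_format("no slice_*.png files in %s", dir)
  slices <- lapply(files, function(f) {
    img <- tryCatch(png::readPNG(f),
                    error = function(e) stop_format("corrupt slice file %s", f))
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  idx <- as.integer(sub("^slice_(\\d+)\\.png$", "\\1", basename(files)))
  slice_stack(slices, plane, idx, subject_id)
}
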
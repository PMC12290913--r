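test_that("patchify produces the patch-16 grid geometry on 224-pixel slices", {
  pg <- patchify(matrix(runif(224^2), 224, 224), 16)
  expect_equal(pg$grid_shape, c(14, 14))
  expect_equal(nrow(pg$patches), 196)
  expect_equal(ncol(pg$patches), 256)
})

test_that("a patch-sized image is its own single flattened patch", {
  x <- matrix(runif(256), 16, 16)
  pg <- patchify(x, 16)
  expect_equal(pg$grid_shape, c(1, 1))
  expect_equal(as.vector(pg$patches[1, ]), as.vector(x))
  expect_identical(unpatchify(pg), x)
})

test_that("patchify and unpatchify are mutual inverses on random images", {
  withr::with_seed(3, {
    for (side in c(32, 64, 224)) {
      x <- matrix(runif(side^2), side, side)
      expect_identical(unpatchify(patchify(x, 16)), x)
    }
    x3 <- array(runif(32 * 32 * 3), c(32, 32, 3))
    expect_identical(unpatchify(patchify(x3, 16)), x3)
  })
})

test_that("patch order matters to reassembly", {
  x <- matrix(seq_len(32^2) / 32^2, 32, 32)
  pg <- patchify(x, 16)
  pg$patches <- pg$patches[c(2, 1, 3, 4), ]
  expect_false(identical(unpatchify(pg), x))
})

test_that("indivisible image sides and inconsistent grids are rejected", {
  expect_error(patchify(matrix(0, 100, 100), 16), "100.*16",
               class = "sliceformer_param_error")
  pg <- patchify(matrix(runif(32^2), 32, 32), 16)
  pg$patches <- pg$patches[, 1:100]
  expect_error(unpatchify(pg), class = "sliceformer_format_error")
})

test_that("the stub encoder is a deterministic seeded projection of patch means", {
  backend <- encoder_backend("stub_projection", feature_dim = 12, seed = 4,
                             input_side = 32, patch_side = 16)
  x <- matrix(runif(32^2), 32, 32)
  v1 <- encode_slice(x, backend)
  expect_length(v1, 12)
  expect_identical(v1, encode_slice(x, backend))
  # one-pixel perturbation changes the features
  x2 <- x
  x2[5, 5] <- x2[5, 5] + 0.5
  expect_false(identical(v1, encode_slice(x2, backend)))
  # matrix-multiply oracle: per-patch means computed by hand, then projected
  means <- numeric(4)
  k <- 0
  for (r in 0:1) for (co in 0:1) {
    k <- k + 1
    means[(r * 2) + co + 1] <- mean(x[(r * 16 + 1):(r * 16 + 16),
                                      (co * 16 + 1):(co * 16 + 16)])
  }
  expect_equal(v1, as.numeric(means %*% backend$W), tolerance = 1e-12)
  expect_error(encode_slice(matrix(0, 16, 16), backend),
               class = "sliceformer_param_error")
})

test_that("grayscale slices encode identically to their 3-channel replication", {
  backend <- encoder_backend("stub_projection", feature_dim = 6, seed = 1,
                             input_side = 32, patch_side = 16)
  x <- matrix(runif(32^2), 32, 32)
  x3 <- array(rep(x, 3), c(32, 32, 3))
  expect_equal(encode_slice(x, backend), encode_slice(x3, backend))
})

test_that("the pretrained backend slot demands an external encoder", {
  expect_error(encoder_backend("pretrained_vit", feature_dim = 8),
               class = "sliceformer_param_error")
  b <- encoder_backend("pretrained_vit", feature_dim = 2, input_side = 16,
                       encode_fun = function(img) c(mean(img), max(img)))
  v <- encode_slice(matrix(runif(256), 16, 16), b)
  expect_length(v, 2)
})

test_that("subject folders encode to ordered feature matrices", {
  backend <- encoder_backend("stub_projection", feature_dim = 7, seed = 2,
                             input_side = 16, patch_side = 16)
  root <- tempfile()
  slices <- lapply(1:5, function(i) matrix(runif(256), 16, 16))
  st <- slice_stack(slices, "axial", 10:14, "P77")
  save_slice_folder(st, root)
  dir <- file.path(root, "P77", "axial")
  seqs <- extract_subject_features(dir, backend, "MCI", seq_len = 5)
  expect_equal(dim(seqs$features), c(5, 7))
  expect_equal(seqs$label, "MCI")
  expect_equal(seqs$subject_id, "P77")
  # rows equal per-slice encodings of the stored (quantized) slices
  back <- load_slice_folder(dir, "axial", "P77")
  for (i in 1:5) {
    expect_equal(seqs$features[i, ], encode_slice(back$slices[[i]], backend))
  }
  # wrong slice count is a shape error
  expect_error(extract_subject_features(dir, backend, "MCI", seq_len = 50),
               class = "sliceformer_shape_error")
})

test_that("reversing slice file order reverses feature rows", {
  backend <- encoder_backend("stub_projection", feature_dim = 4, seed = 2,
                             input_side = 16, patch_side = 16)
  root1 <- tempfile(); root2 <- tempfile()
  slices <- lapply(1:4, function(i) matrix(runif(256), 16, 16))
  save_slice_folder(slice_stack(slices, "axial", 0:3, "A"), root1)
  save_slice_folder(slice_stack(rev(slices), "axial", 0:3, "A"), root2)
  f1 <- extract_subject_features(file.path(root1, "A", "axial"), backend, "NC",
                                 seq_len = 4)
  f2 <- extract_subject_features(file.path(root2, "A", "axial"), backend, "NC",
                                 seq_len = 4)
  expect_equal(f1$features, f2$features[4:1, ])
})

test_that("feature persistence is lossless and guards its companion files", {
  sq <- make_feature_dataset(tiny_feature_spec())[[4]]
  dir <- tempfile()
  paths <- save_features(sq, dir,
                         backend = encoder_backend(feature_dim = 5, seed = 1))
  expect_true(all(file.exists(paths)))
  back <- load_features(dir, sq$subject_id)
  expect_identical(back$features, sq$features)
  expect_identical(back$label, sq$label)
  # dropping the labels file is a format error
  unlink(paths[["labels"]])
  expect_error(load_features(dir, sq$subject_id),
               class = "sliceformer_format_error")
})

test_that("a feature directory lists and reloads its full cohort", {
  ds <- make_feature_dataset(tiny_feature_spec(n_per_class = 2))
  dir <- tempfile()
  for (sq in ds) save_features(sq, dir)
  expect_equal(list_feature_subjects(dir),
               sort(vapply(ds, `[[`, character(1), "subject_id")))
  back <- load_feature_dataset(dir)
  expect_equal(length(back), length(ds))
  expect_identical(back[[1]]$features, ds[[1]]$features)
})
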
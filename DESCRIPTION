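Package: sliceformer
Title: Slice-Sequence Transformer Classification of Volumetric Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for classifying skull-stripped, spatially
    normalised T1-weighted brain MRI volumes into diagnostic groups (normal
    control, mild cognitive impairment, Alzheimer's disease). Stage one
    sections a 3D volume along an anatomical plane, keeps the central 50
    slices, resizes each to 224 x 224 pixels and encodes every slice into a
    feature vector with a pluggable patch-based encoder. Stage two classifies
    the ordered sequence of slice features with a transformer encoder
    (sinusoidal positional encoding, multi-head self-attention blocks,
    sequence pooling, softmax head) trained with categorical cross-entropy
    under stratified 10-fold cross-validation. Includes seeded synthetic
    phantom-volume and feature-sequence generators so the whole pipeline is
    testable without clinical data, plus per-fold and cross-fold evaluation
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
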
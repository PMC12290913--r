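# Small shared fixtures, built in code.

tiny_feature_spec <- function(n_per_class = 3L, seq_len = 8L, feature_dim = 5L,
                              separation = 4, positional_signal = 1,
                              seed = 101L) {
  synthetic_feature_spec(n_per_class = n_per_class, seq_len = seq_len,
                         feature_dim = feature_dim, separation = separation,
                         positional_signal = positional_signal, seed = seed)
}

tiny_model_config <- function(...) {
  defaults <- list(feature_dim = 5L, seq_len = 8L, n_classes = 3L,
                   n_blocks = 1L, n_heads = 2L, head_dim = 3L, ff_dim = 8L,
                   dropout = 0, max_epochs = 5L, batch_size = 4L, seed = 7L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# nearest-centroid classifier on sequence-mean vectors; the independent
# brute-force oracle for separability checks
nearest_centroid_accuracy <- function(sequences) {
  means <- t(vapply(sequences, function(s) colMeans(s$features),
                    numeric(ncol(sequences[[1]]$features))))
  labels <- vapply(sequences, `[[`, character(1), "label")
  centroids <- sapply(unique(labels), function(cl) {
    colMeans(means[labels == cl, , drop = FALSE])
  })
  pred <- unique(labels)[apply(means, 1, function(v) {
    which.min(colSums((centroids - v)^2))
  })]
  mean(pred == labels)
}

# brute-force per-sample metric computation used as the oracle for
# metrics_from_confusion
brute_force_metrics <- function(y_true, y_pred, classes) {
  per_class <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec = prec, rec = rec, f1 = f1)
  })
  m <- do.call(rbind, per_class)
  list(accuracy = mean(y_true == y_pred),
       balanced_accuracy = mean(m[, "rec"]),
       macro_precision = mean(m[, "prec"]),
       macro_recall = mean(m[, "rec"]),
       macro_f1 = mean(m[, "f1"]))
}
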
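#' Confusion matrix from true and predicted labels
#'
#' @param y_true,y_pred Equal-length label vectors (character or factor) with
#'   values in `class_order`.
#' @param class_order Fixed class ordering (default NC, MCI, AD).
#'
#' @return An object of class `confusion_matrix`: an integer
#'   `n_classes x n_classes` matrix, rows = true class, columns = predicted
#'   class. Empty inputs give an all-zero matrix.
#' @export
#' @examples
#' confusion(c("NC", "AD"), c("NC", "MCI"))
confusion <- function(y_true, y_pred, class_order = class_levels()) {
  if (length(y_true) != length(y_pred)) {
    stop_data("y_true has %d elements but y_pred has %d",
              length(y_true), length(y_pred))
  }
  t_ <- as_class_factor(as.character(y_true), class_order)
  p_ <- as_class_factor(as.character(y_pred), class_order)
  cm <- table(true = t_, predicted = p_)
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm),
              dimnames = list(true = class_order, predicted = class_order))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = true, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy = trace / total. Per class: precision = diagonal / column sum,
#' recall = diagonal / row sum, F1 = harmonic mean of the two. Macro metrics
#' are unweighted class means; balanced accuracy is the mean per-class
#' recall. Any 0/0 ratio (a class never predicted, never present, or with
#' zero precision + recall) is defined as 0 with a warning.
#'
#' @param cm A [confusion()] matrix with positive total.
#'
#' @return A one-row tibble of class `metric_set`: `accuracy`,
#'   `balanced_accuracy`, `macro_precision`, `macro_recall`, `macro_f1`, all
#'   in \[0, 1\].
#' @export
#' @examples
#' cm <- confusion(rep(c("NC", "AD"), c(8, 10)),
#'                 rep(c("NC", "AD", "NC", "AD"), c(6, 2, 1, 9)))
#' metrics_from_confusion(cm)
metrics_from_confusion <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    stop_param("`cm` must be a confusion_matrix from confusion()")
  }
  total <- sum(cm)
  if (total == 0) stop_data("confusion matrix total is zero")
  m <- unclass(cm)
  diag_ <- diag(m)
  col_s <- colSums(m)
  row_s <- rowSums(m)
  safe_div <- function(num, den, what) {
    out <- numeric(length(num))
    zero <- den == 0
    if (any(zero)) {
      warn(sprintf("0/0 in %s for class(es) %s; defining as 0",
                   what, paste(rownames(m)[zero], collapse = ", ")))
    }
    out[!zero] <- num[!zero] / den[!zero]
    out
  }
  precision <- safe_div(diag_, col_s, "precision")
  recall <- safe_div(diag_, row_s, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  structure(
    tibble(accuracy = sum(diag_) / total,
           balanced_accuracy = mean(recall),
           macro_precision = mean(precision),
           macro_recall = mean(recall),
           macro_f1 = mean(f1)),
    class = c("metric_set", "tbl_df", "tbl", "data.frame"),
    per_class = tibble(class = rownames(m), precision = precision,
                       recall = recall, f1 = f1)
  )
}

#' Per-class precision/recall/F1 of a metric set
#'
#' @param metrics A `metric_set` from [metrics_from_confusion()].
#' @return Tibble with one row per class.
#' @export
per_class_metrics <- function(metrics) attr(metrics, "per_class")

#' Evaluate predictions for one fold
#'
#' @param y_true,y_pred Label vectors.
#' @param fold_index Fold number recorded in the result.
#' @param class_order Fixed class ordering.
#' @return List with `fold_index`, `confusion` and `metrics`.
#' @export
evaluate_fold <- function(y_true, y_pred, fold_index = 1L,
                          class_order = class_levels()) {
  cm <- confusion(y_true, y_pred, class_order)
  list(fold_index = as.integer(fold_index), confusion = cm,
       metrics = metrics_from_confusion(cm))
}

#' Aggregate per-fold metrics into a cross-validation report
#'
#' Computes the arithmetic mean and sample standard deviation of every metric
#' across folds, retaining the per-fold records.
#'
#' @param reports Nonempty list of [evaluate_fold()] results (or of bare
#'   `metric_set` rows).
#'
#' @return An object of class `eval_report`: list with `per_fold` (tibble,
#'   one row per fold), `summary` (tibble: metric, mean, sd) and
#'   `confusions` (list of per-fold confusion matrices, possibly empty).
#' @export
aggregate_folds <- function(reports) {
  if (length(reports) == 0) stop_data("no fold reports to aggregate")
  per_fold <- purrr::map_dfr(seq_along(reports), function(i) {
    r <- reports[[i]]
    if (inherits(r, "metric_set")) {
      dplyr::bind_cols(tibble(fold = i), as_tibble(r))
    } else {
      dplyr::bind_cols(tibble(fold = r$fold_index), as_tibble(r$metrics))
    }
  })
  summary <- per_fold |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     .groups = "drop")
  confusions <- purrr::map(reports, function(r) {
    if (inherits(r, "metric_set")) NULL else r$confusion
  })
  structure(list(per_fold = per_fold, summary = summary,
                 confusions = confusions),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d fold(s)\n", nrow(x$per_fold)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %.4f (sd %.4f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_fold

#' @export
glance.eval_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble(n_folds = nrow(x$per_fold)), wide)
}

#' @export
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a confusion matrix as a heatmap
#'
#' @param object A [confusion()] matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame(unclass(object)), rownames = "true") |>
    tidyr::pivot_longer(-"true", names_to = "predicted", values_to = "count")
  lev <- rownames(object)
  df$true <- factor(df$true, levels = rev(lev))
  df$predicted <- factor(df$predicted, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to disk
#'
#' One JSON document (per-fold metrics, aggregates, confusion counts) and a
#' flat CSV of per-fold metrics.
#'
#' @param report An `eval_report`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_eval_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "eval_report.json")
  csv_path <- file.path(out_dir, "per_fold_metrics.csv")
  payload <- list(
    per_fold = report$per_fold,
    summary = report$summary,
    confusions = purrr::map(report$confusions, function(cm) {
      if (is.null(cm)) NULL else unclass(cm)
    }))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  data.table::fwrite(report$per_fold, csv_path)
  invisible(c(json = json_path, csv = csv_path))
}
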
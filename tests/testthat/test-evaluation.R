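test_that("confusion counts true-by-predicted cells", {
  y <- c("NC", "NC", "MCI", "AD", "AD")
  cm <- confusion(y, y)
  expect_equal(unname(diag(unclass(cm))), c(2L, 1L, 2L))
  expect_equal(sum(cm), 5)
  off <- confusion(c("NC", "NC"), c("MCI", "AD"))
  expect_equal(unclass(off)["NC", "MCI"], 1L, ignore_attr = TRUE)
  expect_equal(sum(diag(unclass(off))), 0)
  # empty vectors give the all-zero matrix
  empty <- confusion(character(0), character(0))
  expect_equal(sum(empty), 0)
  expect_equal(dim(empty), c(3, 3))
  expect_error(confusion(c("NC"), c("NC", "AD")), class = "sliceformer_data_error")
  expect_error(confusion("NC", "bad"), class = "sliceformer_data_error")
})

test_that("metrics match hand-enumerated values on the 18-sample toy", {
  # two classes: 8 true NC, 10 true AD; 2 NC->AD false negatives for NC and
  # 1 AD->NC: confusion [[6,2],[1,9]] in (NC, AD) order
  y_true <- rep(c("NC", "AD"), c(8, 10))
  y_pred <- c(rep("NC", 6), rep("AD", 2), "NC", rep("AD", 9))
  cm <- confusion(y_true, y_pred, class_order = c("NC", "AD"))
  expect_equal(unclass(cm), matrix(c(6L, 1L, 2L, 9L), 2, 2,
                                   dimnames = dimnames(cm)),
               ignore_attr = TRUE)
  ms <- metrics_from_confusion(cm)
  expect_equal(ms$accuracy, 15 / 18)
  pc <- per_class_metrics(ms)
  expect_equal(pc$precision[pc$class == "NC"], 6 / 7)
  expect_equal(pc$recall[pc$class == "NC"], 6 / 8)
  expect_equal(ms$balanced_accuracy, (6 / 8 + 9 / 10) / 2)
})

test_that("a perfect diagonal confusion matrix scores 1 everywhere", {
  cm <- confusion(rep(class_levels(), 4), rep(class_levels(), 4))
  ms <- metrics_from_confusion(cm)
  expect_equal(unlist(ms[1, ]), rep(1, 5), ignore_attr = TRUE)
})

test_that("never-predicted classes follow the 0/0-as-zero rule with a warning", {
  cm <- confusion(c("NC", "MCI", "AD"), c("NC", "NC", "NC"))
  warns <- capture_warnings(ms <- metrics_from_confusion(cm))
  expect_true(any(grepl("0/0", warns)))
  pc <- per_class_metrics(ms)
  expect_equal(pc$precision[pc$class == "MCI"], 0)
  expect_true(all(is.finite(unlist(ms[1, ]))))
  expect_error(metrics_from_confusion(confusion(character(0), character(0))),
               class = "sliceformer_data_error")
})

test_that("metrics agree with per-sample brute force on random label vectors", {
  withr::with_seed(99, {
    for (trial in 1:100) {
      n_cls <- if (trial %% 2 == 0) 2 else 3
      classes <- class_levels()[seq_len(n_cls)]
      n <- sample(5:40, 1)
      y_true <- sample(classes, n, replace = TRUE)
      y_pred <- sample(classes, n, replace = TRUE)
      ms <- suppressWarnings(
        metrics_from_confusion(confusion(y_true, y_pred, classes)))
      oracle <- brute_force_metrics(y_true, y_pred, classes)
      for (nm in names(oracle)) {
        expect_equal(ms[[nm]], oracle[[nm]], tolerance = 1e-12)
      }
    }
  })
})

test_that("metrics are invariant under consistent class relabeling", {
  withr::with_seed(7, {
    y_true <- sample(class_levels(), 30, replace = TRUE)
    y_pred <- sample(class_levels(), 30, replace = TRUE)
  })
  ms1 <- suppressWarnings(metrics_from_confusion(confusion(y_true, y_pred)))
  swap <- c(NC = "AD", MCI = "NC", AD = "MCI")
  ms2 <- suppressWarnings(metrics_from_confusion(
    confusion(swap[y_true], swap[y_pred])))
  expect_equal(ms1$accuracy, ms2$accuracy)
  expect_equal(ms1$balanced_accuracy, ms2$balanced_accuracy)
  expect_equal(ms1$macro_precision, ms2$macro_precision)
  expect_equal(ms1$macro_f1, ms2$macro_f1)
})

test_that("aggregation averages per-fold metrics with a sample sd", {
  mk <- function(acc) {
    y <- rep(c("NC", "AD"), 10)
    wrong <- round((1 - acc) * 20)
    pred <- y
    if (wrong > 0) pred[seq_len(wrong)] <- ifelse(y[seq_len(wrong)] == "NC", "AD", "NC")
    evaluate_fold(y, pred, 1L, class_order = c("NC", "AD"))
  }
  reps <- list(mk(0.8), mk(0.9))
  reps[[2]]$fold_index <- 2L
  agg <- aggregate_folds(reps)
  acc <- agg$summary[agg$summary$metric == "accuracy", ]
  expect_equal(acc$mean, 0.85)
  expect_equal(acc$sd, sd(c(0.8, 0.9)))
  # identical folds aggregate to zero spread
  same <- list(mk(0.9), mk(0.9))
  same[[2]]$fold_index <- 2L
  agg2 <- aggregate_folds(same)
  expect_true(all(agg2$summary$sd == 0))
  expect_error(aggregate_folds(list()), class = "sliceformer_data_error")
})

test_that("aggregate means stay within per-fold extremes", {
  withr::with_seed(41, {
    reps <- lapply(1:6, function(i) {
      y_true <- sample(class_levels(), 24, replace = TRUE)
      y_pred <- sample(class_levels(), 24, replace = TRUE)
      suppressWarnings(evaluate_fold(y_true, y_pred, i))
    })
  })
  agg <- aggregate_folds(reps)
  for (nm in setdiff(names(agg$per_fold), "fold")) {
    vals <- agg$per_fold[[nm]]
    m <- agg$summary$mean[agg$summary$metric == nm]
    expect_gte(m, min(vals))
    expect_lte(m, max(vals))
  }
})

test_that("reports tidy, glance and serialize", {
  reps <- lapply(1:3, function(i) {
    y <- rep(class_levels(), 4)
    evaluate_fold(y, y, i)
  })
  agg <- aggregate_folds(reps)
  expect_equal(nrow(tidy(agg)), 3)
  g <- glance(agg)
  expect_equal(g$n_folds, 3)
  expect_equal(g$mean_accuracy, 1)
  out <- tempfile()
  paths <- write_eval_report(agg, out)
  expect_true(all(file.exists(paths)))
  back <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(nrow(back$per_fold), 3)
  p <- autoplot(agg)
  expect_s3_class(p, "ggplot")
  pc <- autoplot(reps[[1]]$confusion)
  expect_s3_class(pc, "ggplot")
})
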
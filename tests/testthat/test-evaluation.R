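# Confusion matrices, metric definitions and the cross-validation harness.

test_that("confusion matrices tally labels correctly", {
  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "a", "b", "b"))
  expect_equal(diag(unclass(cm)), c(a = 2L, b = 2L), ignore_attr = FALSE)
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0L)

  # a 300-sample binary problem: 250 benign all correct, 50 melanoma of
  # which 6% (3) are missed
  truth <- c(rep("benign", 250), rep("melanoma", 50))
  pred <- c(rep("benign", 250), rep("benign", 3), rep("melanoma", 47))
  cm <- confusion_matrix(truth, pred, c("benign", "melanoma"))
  expect_equal(unclass(cm)["melanoma", ], c(benign = 3L, melanoma = 47L))

  # random tally against a dictionary-style loop
  set.seed(14)
  t3 <- sample(c("x", "y", "z"), 60, replace = TRUE)
  p3 <- sample(c("x", "y", "z"), 60, replace = TRUE)
  cm3 <- confusion_matrix(t3, p3, c("x", "y", "z"))
  for (i in c("x", "y", "z")) {
    for (j in c("x", "y", "z")) {
      expect_equal(unclass(cm3)[i, j], sum(t3 == i & p3 == j))
    }
  }
  expect_error(confusion_matrix("a", "q", classes = c("a", "b")),
               class = "sdpskin_validation_error")
})

test_that("metric formulas reproduce hand-computed values", {
  # symmetric binary matrix: everything is one half
  cm <- structure(matrix(c(25L, 25L, 25L, 25L), 2,
                         dimnames = list(truth = c("a", "b"),
                                         predicted = c("a", "b"))),
                  class = c("confusion_matrix", "matrix"),
                  classes = c("a", "b"))
  rep <- compute_metrics(cm)
  for (m in names(rep$macro)) expect_equal(rep$macro[[m]], 0.5)

  # TP=47, FN=3, TN=250, FP=0 (melanoma as positive class)
  cm2 <- confusion_matrix(c(rep("benign", 250), rep("melanoma", 50)),
                          c(rep("benign", 253), rep("melanoma", 47)),
                          c("benign", "melanoma"))
  rep2 <- compute_metrics(cm2)
  mel <- rep2$per_class[rep2$per_class$class == "melanoma", ]
  expect_equal(mel$sensitivity, 0.94)
  expect_equal(mel$specificity, 1)
  expect_equal(mel$positive_predictive_rate, 1)

  # harmonic mean of sensitivity and specificity, hand evaluation
  se <- 0.988; sp <- 0.996
  expect_equal(round(2 * se * sp / (se + sp), 4), 0.9920)

  # zero denominators surface as NA
  cm3 <- confusion_matrix(c("a", "a"), c("a", "a"), c("a", "b"))
  rep3 <- compute_metrics(cm3)
  b <- rep3$per_class[rep3$per_class$class == "b", ]
  expect_true(is.na(b$sensitivity))
  expect_true(is.na(b$positive_predictive_rate))
})

test_that("metrics are equivariant under class permutation", {
  set.seed(15)
  t3 <- sample(c("x", "y", "z"), 90, replace = TRUE)
  p3 <- sample(c("x", "y", "z"), 90, replace = TRUE)
  r1 <- compute_metrics(confusion_matrix(t3, p3, c("x", "y", "z")))
  r2 <- compute_metrics(confusion_matrix(t3, p3, c("z", "x", "y")))
  for (cl in c("x", "y", "z")) {
    expect_equal(r1$per_class[r1$per_class$class == cl, -1],
                 r2$per_class[r2$per_class$class == cl, -1])
  }
  expect_equal(r1$accuracy_overall, r2$accuracy_overall)
  # binary macro sensitivity equals the mean of the two class recalls
  tb <- sample(c("a", "b"), 50, replace = TRUE)
  pb <- sample(c("a", "b"), 50, replace = TRUE)
  rb <- compute_metrics(confusion_matrix(tb, pb, c("a", "b")))
  expect_equal(rb$macro$sensitivity, mean(rb$per_class$sensitivity))
})

test_that("cross-validation partitions, aggregates and stays leak-free", {
  set.seed(16)
  x <- rbind(matrix(rnorm(10 * 3, 0), 10), matrix(rnorm(10 * 3, 8), 10))
  y <- rep(c("lo", "hi"), each = 10)

  # leave-one-out on perfectly separable data with the k-NN baseline
  loo <- cross_validate(x, y, knn_classifier_spec(3), k = 20, seed = 1)
  expect_equal(glance(loo)$mean_accuracy, 1)

  # folds are a partition
  folds <- sdpskin:::stratified_folds(y, 5, seed = 2)
  expect_length(folds, 20)
  expect_true(all(table(folds) == 4))

  cv <- cross_validate(x, y, knn_classifier_spec(3), k = 5, seed = 2)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(sum(cv$folds$n), 20)
  # summary recomputable from the stored per-fold values
  expect_equal(cv$summary$accuracy[cv$summary$.stat == "mean"],
               mean(cv$folds$accuracy))
  expect_equal(cv$summary$accuracy[cv$summary$.stat == "sd"],
               sd(cv$folds$accuracy))
  # pooled confusion matrix accounts for every sample once
  expect_equal(sum(cv$pooled), 20)

  expect_error(cross_validate(x, y, knn_classifier_spec(3), k = 15),
               class = "sdpskin_validation_error")
})

test_that("the fractional-order sweep ranks orders by baseline accuracy", {
  set.seed(17)
  specs <- ph2like_specs()[c(1, 3)]
  samples <- unlist(lapply(specs, function(sp) {
    lapply(1:6, function(i) generate_sample(sp, c(64, 64), seed = 100 + i +
                                              60 * sp$n_hues))
  }), recursive = FALSE)
  labels <- vapply(samples, `[[`, character(1), "label")
  rois <- lapply(samples, function(s) {
    extract_roi(s$image, lesion_mask(s$lesion_mask), pad = 4)
  })
  sw <- sweep_alpha(rois, labels, alphas = c(0.5, 1),
                    config = sdp_config(grid = 2, bins = 8), k = 3, seed = 1)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$mean_accuracy >= 0 & sw$mean_accuracy <= 1))
})
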
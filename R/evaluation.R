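# Confusion matrices, the sensitivity/specificity metric suite, and the
# stratified k-fold cross-validation harness.

#' Confusion matrix
#'
#' Counts with rows = true class and columns = predicted class.
#'
#' @param truth,predicted equal-length label vectors drawn from `classes`.
#' @param classes class labels; defaults to the sorted union of observed
#'   labels.
#' @return a `confusion_matrix` (integer K x K matrix with a `classes`
#'   attribute).
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop_validation("label vectors differ in length")
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  if (!all(c(truth, predicted) %in% classes)) {
    stop_validation("labels outside the declared class set")
  }
  counts <- table(factor(truth, levels = classes),
                  factor(predicted, levels = classes))
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"), classes = classes)
}

#' Classification metrics from a confusion matrix
#'
#' Per class (one-vs-rest): accuracy `(TP+TN)/(TP+TN+FP+FN)`, specificity
#' `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, positive predictive rate
#' `TP/(TP+FP)`, F-score `2*SE*PP/(SE+PP)` and the sensitivity-specificity
#' harmonic mean `2*SE*SP/(SE+SP)`. Ratios with a zero denominator are
#' reported as `NA`, never silently as 0. Summary values are unweighted
#' (macro) averages over classes; the overall fraction of correctly
#' classified samples is reported alongside as `accuracy_overall`.
#'
#' @param cm a [confusion_matrix()].
#' @return a `metrics_report`: list with `macro` (named list of the six
#'   macro-averaged metrics), `per_class` (tibble), `accuracy_overall` and
#'   `n`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop_validation("empty confusion matrix")
  classes <- attr(cm, "classes")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  per <- purrr::map_dfr(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    se <- ratio(tp, tp + fn)
    sp <- ratio(tn, tn + fp)
    pp <- ratio(tp, tp + fp)
    f <- if (!is.na(se) && !is.na(pp) && se + pp > 0) {
      2 * se * pp / (se + pp)
    } else NA_real_
    hm <- if (!is.na(se) && !is.na(sp) && se + sp > 0) {
      2 * se * sp / (se + sp)
    } else NA_real_
    tibble::tibble(class = classes[i], tp = tp, tn = tn, fp = fp, fn = fn,
                   accuracy = ratio(tp + tn, total), specificity = sp,
                   sensitivity = se, positive_predictive_rate = pp,
                   f_score = f, harmonic_mean = hm)
  })
  macro <- lapply(c("accuracy", "specificity", "sensitivity",
                    "positive_predictive_rate", "f_score", "harmonic_mean"),
                  function(mname) mean(per[[mname]], na.rm = TRUE))
  names(macro) <- c("accuracy", "specificity", "sensitivity",
                    "positive_predictive_rate", "f_score", "harmonic_mean")
  structure(list(macro = macro, per_class = per,
                 accuracy_overall = sum(diag(cm)) / total, n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report n=%d overall accuracy %.3f>\n",
              x$n, x$accuracy_overall))
  print(tibble::as_tibble(x$macro))
  invisible(x)
}

#' Classifier specification for cross-validation
#'
#' A pair of closures: `fit(features, labels)` returning a model and
#' `predict(model, features)` returning labels.
#'
#' @param fit,predict the two closures.
#' @param label descriptive name.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(fit, predict, label = "classifier") {
  structure(list(fit = fit, predict = predict, label = label),
            class = "classifier_spec")
}

#' Stacked-RBM classifier specification
#'
#' @param layer_sizes hidden-layer widths, see [train_stacked_rbm()].
#' @param hp an [rbm_hyperparams()].
#' @return a [classifier_spec()].
#' @export
rbm_classifier_spec <- function(layer_sizes = c(256, 64),
                                hp = rbm_hyperparams()) {
  classifier_spec(
    fit = function(x, y) train_stacked_rbm(x, y, layer_sizes, hp),
    predict = function(model, x) predict_labels(model, x)$.pred_class,
    label = "stacked_rbm")
}

#' k-NN classifier specification
#'
#' @param k neighbours.
#' @return a [classifier_spec()].
#' @export
knn_classifier_spec <- function(k = 3) {
  classifier_spec(
    fit = function(x, y) list(x = as.matrix(x), y = factor(y)),
    predict = function(model, x) {
      as.character(classify_knn(model$x, model$y, x, k = k))
    },
    label = sprintf("knn_k%d", k))
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin, continuing the fold counter across classes so fold sizes stay
# balanced (and k = n yields exact leave-one-out)
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  counter <- 0L
  with_local_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
      counter <- counter + length(idx)
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Seeded stratified folds, per-fold fit and evaluation of the classifier
#' (per-fold preprocessing such as feature scaling happens inside the
#' classifier's `fit`, on training folds only), and mean/SD aggregation of
#' the metric suite across folds.
#'
#' @param features samples x features matrix.
#' @param labels class labels; every class needs at least `k` samples.
#' @param spec a [classifier_spec()].
#' @param k number of folds, default 10.
#' @param seed fold-assignment seed, default 0.
#' @return a `cv_report`: list with `folds` (per-fold metric tibble),
#'   `summary` (mean and SD per metric), `confusions` (per-fold confusion
#'   matrices) and `pooled` (confusion matrix pooled over folds).
#' @export
cross_validate <- function(features, labels, spec = rbm_classifier_spec(),
                           k = 10, seed = 0) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  labels <- factor(labels)
  # k = n is exact leave-one-out; otherwise every class must fill all folds
  if (k != length(labels) && any(table(labels) < k)) {
    stop_validation(sprintf(
      "every class needs at least %d samples for %d folds; use a smaller k", k, k))
  }
  fold <- stratified_folds(labels, k, seed)
  classes <- levels(labels)
  fold_rows <- list()
  confusions <- list()
  for (f in seq_len(k)) {
    test <- fold == f
    model <- spec$fit(features[!test, , drop = FALSE], labels[!test])
    pred <- spec$predict(model, features[test, , drop = FALSE])
    cm <- confusion_matrix(labels[test], pred, classes)
    confusions[[f]] <- cm
    rep <- compute_metrics(cm)
    fold_rows[[f]] <- tibble::tibble(
      fold = f, n = rep$n, accuracy = rep$accuracy_overall,
      macro_accuracy = rep$macro$accuracy,
      specificity = rep$macro$specificity,
      sensitivity = rep$macro$sensitivity,
      positive_predictive_rate = rep$macro$positive_predictive_rate,
      f_score = rep$macro$f_score, harmonic_mean = rep$macro$harmonic_mean)
  }
  folds <- dplyr::bind_rows(fold_rows)
  metric_cols <- setdiff(names(folds), c("fold", "n"))
  summary <- dplyr::bind_rows(
    dplyr::summarise(folds, dplyr::across(dplyr::all_of(metric_cols),
                                          ~mean(.x, na.rm = TRUE)),
                     .stat = "mean"),
    dplyr::summarise(folds, dplyr::across(dplyr::all_of(metric_cols),
                                          ~stats::sd(.x, na.rm = TRUE)),
                     .stat = "sd"))
  pooled <- Reduce(`+`, lapply(confusions, unclass))
  pooled <- structure(pooled, class = c("confusion_matrix", "matrix"),
                      classes = classes)
  structure(list(folds = folds, summary = summary, confusions = confusions,
                 pooled = pooled, k = k, seed = seed,
                 classifier = spec$label),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  mean_acc <- x$summary$accuracy[x$summary$.stat == "mean"]
  sd_acc <- x$summary$accuracy[x$summary$.stat == "sd"]
  cat(sprintf("<cv_report %s, %d folds: accuracy %.3f +/- %.3f>\n",
              x$classifier, x$k, mean_acc, sd_acc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  m <- x$summary[x$summary$.stat == "mean", , drop = FALSE]
  s <- x$summary[x$summary$.stat == "sd", , drop = FALSE]
  tibble::tibble(k = x$k, classifier = x$classifier,
                 mean_accuracy = m$accuracy, sd_accuracy = s$accuracy,
                 mean_sensitivity = m$sensitivity,
                 mean_specificity = m$specificity)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  df <- tidyr_longer(object$folds)
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

# minimal long-format pivot of the per-fold metric table
tidyr_longer <- function(folds) {
  metric_cols <- setdiff(names(folds), c("fold", "n"))
  purrr::map_dfr(metric_cols, function(mc) {
    tibble::tibble(fold = folds$fold, metric = mc, value = folds[[mc]])
  })
}

#' Fractional-order sweep with the k-NN baseline
#'
#' Cross-validated accuracy of the k-nearest-neighbour baseline as a function
#' of the mask order `alpha`, the selection procedure used to pick the
#' descriptor's default order.
#'
#' @param images list of inputs accepted by [extract_sdp()].
#' @param labels class labels.
#' @param alphas orders to evaluate.
#' @param config base [sdp_config()]; its `alpha` is overridden per sweep
#'   point.
#' @param k folds for cross-validation.
#' @param seed fold seed.
#' @param knn_k neighbours for the baseline.
#' @return tibble with `alpha`, `mean_accuracy`, `sd_accuracy`.
#' @export
sweep_alpha <- function(images, labels, alphas = seq(0.1, 1, by = 0.1),
                        config = sdp_config(), k = 5, seed = 0, knn_k = 3) {
  purrr::map_dfr(alphas, function(a) {
    cfg <- config
    cfg$alpha <- a
    feats <- sdp_feature_matrix(images, cfg)
    rep <- cross_validate(feats, labels, knn_classifier_spec(knn_k),
                          k = k, seed = seed)
    g <- glance(rep)
    tibble::tibble(alpha = a, mean_accuracy = g$mean_accuracy,
                   sd_accuracy = g$sd_accuracy)
  })
}
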
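# Pipeline orchestration: preprocess -> segment -> features -> cross-validated
# classification as a single configured run with artifact provenance.

#' Pipeline configuration
#'
#' All stage toggles and module defaults in one validated list. Unknown keys
#' are rejected. The configuration hash recorded in every artifact is
#' `rlang::hash()` of the canonicalized list.
#'
#' @param remove_hair run hair removal?
#' @param segment run segmentation (otherwise masks must be supplied)?
#' @param hair see [hair_config()].
#' @param segmentation see [segment_config()].
#' @param sdp see [sdp_config()].
#' @param layer_sizes stacked-RBM hidden-layer widths.
#' @param hp see [rbm_hyperparams()].
#' @param folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @param ... must be empty; unknown keys raise an error.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(remove_hair = TRUE, segment = TRUE,
                            hair = hair_config(),
                            segmentation = segment_config(),
                            sdp = sdp_config(),
                            layer_sizes = c(256, 64),
                            hp = rbm_hyperparams(),
                            folds = 10, seed = 0, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop_validation(paste0("unknown configuration keys: ",
                           paste(names(extra), collapse = ", ")))
  }
  cfg <- list(remove_hair = remove_hair, segment = segment, hair = hair,
              segmentation = segmentation, sdp = sdp,
              layer_sizes = layer_sizes, hp = hp, folds = folds, seed = seed)
  structure(cfg, class = "pipeline_config", hash = rlang::hash(cfg))
}

#' Configuration hash
#'
#' @param config a [pipeline_config()].
#' @return character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  attr(config, "hash")
}

# resolve manifest rows (path,label) or in-memory samples to images + labels
resolve_inputs <- function(x, image_dir = NULL) {
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, logical(1),
                                                    "synthetic_sample"))) {
    return(list(images = lapply(x, `[[`, "image"),
                labels = vapply(x, `[[`, character(1), "label"),
                masks = lapply(x, `[[`, "lesion_mask")))
  }
  stopifnot(is.data.frame(x), all(c("path", "label") %in% names(x)))
  paths <- if (is.null(image_dir)) x$path else file.path(image_dir, x$path)
  list(images = lapply(paths, load_image), labels = x$label, masks = NULL)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on every input image: hair removal,
#' lesion segmentation (or externally supplied masks), SDP feature
#' extraction on the masked ROI, then stratified k-fold cross-validation of
#' the stacked-RBM classifier on the features. Per-stage counts are logged
#' via `message()`; artifacts carry the configuration hash.
#'
#' @param x a manifest data frame (columns path, label) or a list of
#'   `synthetic_sample` objects.
#' @param config a [pipeline_config()].
#' @param image_dir directory that manifest paths are relative to.
#' @param masks optional list of binary lesion masks, used when
#'   `config$segment` is `FALSE` (or to bypass the internal segmenter).
#' @param out_dir optional directory; when set, features, the report and the
#'   manifest of failures are written there together with the config hash.
#' @return a `pipeline_result`: list with `cv` (a `cv_report`),
#'   `features`, `labels`, `dice` (per-image Dice against supplied
#'   ground-truth masks, if any), `config_hash` and `failures`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), image_dir = NULL,
                         masks = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- resolve_inputs(x, image_dir)
  n <- length(inputs$images)
  message(sprintf("pipeline: %d images, config %s", n, config_hash(config)))
  t0 <- Sys.time()
  feats <- vector("list", n)
  dice <- rep(NA_real_, n)
  failures <- character(0)
  for (i in seq_len(n)) {
    img <- inputs$images[[i]]
    res <- tryCatch({
      if (config$remove_hair) img <- remove_hair(img, config$hair)
      lm <- if (config$segment) {
        segment_lesion(img, config$segmentation)
      } else {
        if (is.null(masks)) stop_validation("segment = FALSE requires masks")
        lesion_mask(masks[[i]])
      }
      if (!is.null(inputs$masks)) {
        dice[i] <- dice_overlap(lm$mask, inputs$masks[[i]])
      }
      roi <- extract_roi(img, lm, config$segmentation$pad)
      extract_sdp(roi, config$sdp)
    }, sdpskin_error = function(e) e)
    if (inherits(res, "condition")) {
      failures <- c(failures, sprintf("image %d: %s", i, conditionMessage(res)))
      feats[[i]] <- NULL
    } else {
      feats[[i]] <- as.numeric(res)
    }
  }
  ok <- !vapply(feats, is.null, logical(1))
  if (length(failures)) {
    message(sprintf("pipeline: %d image(s) failed a stage", sum(!ok)))
  }
  if (sum(ok) < 2) stop_validation("too few images survived the pipeline")
  features <- do.call(rbind, feats[ok])
  labels <- inputs$labels[ok]
  message(sprintf("pipeline: features %d x %d extracted in %.1fs",
                  nrow(features), ncol(features),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  cv <- cross_validate(features, labels,
                       rbm_classifier_spec(config$layer_sizes, config$hp),
                       k = config$folds, seed = config$seed)
  result <- structure(list(cv = cv, features = features, labels = labels,
                           dice = dice, config_hash = config_hash(config),
                           failures = failures),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(data.frame(label = labels, features),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    report <- list(config_hash = result$config_hash,
                   summary = cv$summary, folds = cv$folds,
                   dice = dice, failures = failures)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$cv)
  if (any(!is.na(x$dice))) {
    cat(sprintf("  mean segmentation Dice %.3f\n", mean(x$dice, na.rm = TRUE)))
  }
  invisible(x)
}
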
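# Stacked Bernoulli Restricted Boltzmann Machines trained layer-wise with
# persistent contrastive divergence (PCD), topped by a multinomial logistic
# layer fitted by maximum likelihood. Inference uses mean-field activation
# probabilities throughout, so predictions are deterministic.

sigmoid <- function(x) 1 / (1 + exp(-x))

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' RBM hyperparameters
#'
#' Defaults follow the training schedule used throughout the package:
#' learning rate 0.1, momentum 0.7, at most 300 epochs, mini-batches of 25,
#' early stopping after 3 epochs without improvement of the mean
#' reconstruction error, one Gibbs step per PCD update.
#'
#' @param learning_rate gradient step size.
#' @param momentum velocity coefficient in `[0, 1)`.
#' @param max_epochs maximum training epochs.
#' @param batch_size mini-batch size (also the number of persistent chains).
#' @param early_stop_patience epochs without improvement before stopping.
#' @param pcd_steps Gibbs steps per parameter update.
#' @param seed RNG seed controlling initialization and sampling.
#' @return parameter list of class `rbm_hyperparams`.
#' @export
rbm_hyperparams <- function(learning_rate = 0.1, momentum = 0.7,
                            max_epochs = 300, batch_size = 25,
                            early_stop_patience = 3, pcd_steps = 1,
                            seed = 1) {
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = max_epochs, batch_size = batch_size,
                 early_stop_patience = early_stop_patience,
                 pcd_steps = pcd_steps, seed = seed),
            class = "rbm_hyperparams")
}

#' Min-max feature normalization
#'
#' Per-feature min-max scaling to `[0, 1]` using statistics of the training
#' matrix only; columns constant in training map to 0.5 and values of the
#' apply matrix are clipped to `[0, 1]`.
#'
#' @param train numeric matrix (samples x features).
#' @param apply optional matrix scaled with the training statistics.
#' @return list with `train`, `apply` (or `NULL`), `mins`, `ranges`.
#' @export
normalize_features <- function(train, apply = NULL) {
  train <- as.matrix(train)
  if (length(train) == 0) stop_validation("empty feature matrix")
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  ranges <- maxs - mins
  scale_mat <- function(m) {
    m <- sweep(m, 2, mins, "-")
    m <- sweep(m, 2, ifelse(ranges > 0, ranges, 1), "/")
    m[, ranges == 0] <- 0.5
    pmin(pmax(m, 0), 1)
  }
  list(train = scale_mat(train),
       apply = if (!is.null(apply)) scale_mat(as.matrix(apply)),
       mins = mins, ranges = ranges)
}

apply_normalization <- function(m, mins, ranges) {
  m <- sweep(as.matrix(m), 2, mins, "-")
  m <- sweep(m, 2, ifelse(ranges > 0, ranges, 1), "/")
  m[, ranges == 0] <- 0.5
  pmin(pmax(m, 0), 1)
}

#' Train one Bernoulli RBM layer with persistent contrastive divergence
#'
#' Stochastic gradient ascent on the PCD approximation of the likelihood
#' gradient: persistent fantasy chains (one per mini-batch slot) are advanced
#' `pcd_steps` Gibbs steps per update; updates are momentum-smoothed; training
#' stops at `max_epochs` or once the mean one-step reconstruction error fails
#' to improve for `early_stop_patience` consecutive epochs. Fully reproducible
#' for a fixed seed.
#'
#' @param data samples x n_visible matrix with values in `[0, 1]`.
#' @param n_hidden number of hidden units.
#' @param hp an [rbm_hyperparams()].
#' @return an `rbm_layer`: `weights` (n_visible x n_hidden), `visible_bias`,
#'   `hidden_bias`, `training_trace` (per-epoch mean reconstruction error).
#' @export
train_rbm_layer <- function(data, n_hidden, hp = rbm_hyperparams()) {
  data <- as.matrix(data)
  if (min(data) < 0 || max(data) > 1) stop_validation("data must lie in [0, 1]")
  if (n_hidden < 1) stop_validation("n_hidden must be at least 1")
  nv <- ncol(data); n <- nrow(data)
  with_local_seed(hp$seed, {
    W <- matrix(stats::rnorm(nv * n_hidden, sd = 0.01), nv, n_hidden)
    b <- numeric(nv); cc <- numeric(n_hidden)
    vW <- matrix(0, nv, n_hidden); vb <- numeric(nv); vc <- numeric(n_hidden)
    chains <- matrix(as.numeric(stats::runif(hp$batch_size * nv) < 0.5),
                     hp$batch_size, nv)
    trace <- numeric(0)
    best <- Inf; streak <- 0L
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = hp$batch_size)
      errs <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        rows <- ord[starts[bi]:min(starts[bi] + hp$batch_size - 1, n)]
        v0 <- data[rows, , drop = FALSE]
        nb <- nrow(v0)
        ph0 <- sigmoid(sweep(v0 %*% W, 2, cc, "+"))
        ch <- chains[seq_len(nb), , drop = FALSE]
        for (s in seq_len(hp$pcd_steps)) {
          phc <- sigmoid(sweep(ch %*% W, 2, cc, "+"))
          hs <- (matrix(stats::runif(length(phc)), nrow(phc)) < phc) * 1
          pvc <- sigmoid(sweep(hs %*% t(W), 2, b, "+"))
          ch <- (matrix(stats::runif(length(pvc)), nrow(pvc)) < pvc) * 1
        }
        chains[seq_len(nb), ] <- ch
        phn <- sigmoid(sweep(ch %*% W, 2, cc, "+"))
        gW <- crossprod(v0, ph0) / nb - crossprod(ch, phn) / nb
        gb <- colMeans(v0) - colMeans(ch)
        gc <- colMeans(ph0) - colMeans(phn)
        vW <- hp$momentum * vW + hp$learning_rate * gW
        vb <- hp$momentum * vb + hp$learning_rate * gb
        vc <- hp$momentum * vc + hp$learning_rate * gc
        W <- W + vW; b <- b + vb; cc <- cc + vc
        vrec <- sigmoid(sweep(ph0 %*% t(W), 2, b, "+"))
        errs[bi] <- mean((v0 - vrec)^2)
      }
      err <- mean(errs)
      trace <- c(trace, err)
      if (err < best - 1e-9) {
        best <- err; streak <- 0L
      } else {
        streak <- streak + 1L
        if (streak >= hp$early_stop_patience) break
      }
    }
    structure(list(weights = W, visible_bias = b, hidden_bias = cc,
                   training_trace = trace),
              class = "rbm_layer")
  })
}

is_rbm_layer <- function(x) inherits(x, "rbm_layer")

#' RBM energy
#'
#' `E(v, h) = -v' W h - b' v - c' h` for one visible/hidden configuration.
#'
#' @param layer an `rbm_layer`.
#' @param v visible vector; `h` hidden vector.
#' @param h hidden vector.
#' @return scalar energy.
#' @export
rbm_energy <- function(layer, v, h) {
  -as.numeric(t(v) %*% layer$weights %*% h) -
    sum(layer$visible_bias * v) - sum(layer$hidden_bias * h)
}

#' RBM free energy of visible vectors
#'
#' `F(v) = -b'v - sum_j log(1 + exp(c_j + (W'v)_j))`, one value per row.
#'
#' @param layer an `rbm_layer`.
#' @param v matrix of visible vectors (rows) or a single vector.
#' @return numeric vector of free energies.
#' @export
rbm_free_energy <- function(layer, v) {
  v <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  act <- sweep(v %*% layer$weights, 2, layer$hidden_bias, "+")
  -as.numeric(v %*% layer$visible_bias) - rowSums(log1p(exp(act)))
}

rbm_forward <- function(layer, data) {
  sigmoid(sweep(as.matrix(data) %*% layer$weights, 2, layer$hidden_bias, "+"))
}

#' Train a stacked RBM classifier
#'
#' Greedy layer-wise pre-training: each RBM layer is trained on the previous
#' layer's hidden activation probabilities; a multinomial logistic top layer
#' is then fitted by maximum likelihood on the final hidden probabilities.
#' With `layer_sizes = integer(0)` the model degenerates to plain multinomial
#' logistic regression on the normalized features.
#'
#' @param features samples x features matrix.
#' @param labels class labels (coerced to factor; at least 2 classes and 2
#'   samples per class).
#' @param layer_sizes integer vector of hidden-layer widths; default
#'   `c(256, 64)`.
#' @param hp an [rbm_hyperparams()].
#' @return a `stacked_rbm` model.
#' @export
train_stacked_rbm <- function(features, labels, layer_sizes = c(256, 64),
                              hp = rbm_hyperparams()) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop_validation("need at least 2 classes")
  if (any(table(labels) < 2)) stop_validation("need at least 2 samples per class")
  if (nrow(features) != length(labels)) {
    stop_validation("features and labels disagree in length")
  }
  norm <- normalize_features(features)
  cur <- norm$train
  layers <- list()
  for (i in seq_along(layer_sizes)) {
    lay_hp <- hp
    lay_hp$seed <- hp$seed + i
    layer <- train_rbm_layer(cur, layer_sizes[i], lay_hp)
    layers[[i]] <- layer
    cur <- rbm_forward(layer, cur)
  }
  df <- data.frame(cur)
  df$.label <- labels
  nw <- (ncol(cur) + 1) * (nlevels(labels)) + nlevels(labels)
  fit <- nnet::multinom(.label ~ ., data = df, trace = FALSE,
                        MaxNWts = max(1000, 2 * nw), maxit = 300)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  B <- rbind(0, cf)  # K x (p + 1), baseline class in row 1
  structure(list(layers = layers,
                 top = list(coefficients = B),
                 classes = levels(labels),
                 feature_scaling = list(mins = norm$mins, ranges = norm$ranges),
                 layer_sizes = layer_sizes, hp = hp),
            class = "stacked_rbm")
}

#' @export
print.stacked_rbm <- function(x, ...) {
  cat(sprintf("<stacked_rbm: %s -> classes [%s]>\n",
              paste(c(length(x$feature_scaling$mins), x$layer_sizes),
                    collapse = " -> "),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# deterministic mean-field forward pass to class scores
stacked_rbm_scores <- function(model, features) {
  cur <- apply_normalization(as.matrix(features), model$feature_scaling$mins,
                             model$feature_scaling$ranges)
  for (layer in model$layers) cur <- rbm_forward(layer, cur)
  eta <- cbind(1, cur) %*% t(model$top$coefficients)
  eta <- eta - apply(eta, 1, max)
  ex <- exp(eta)
  ex / rowSums(ex)
}

#' Predict labels and class probabilities
#'
#' Deterministic forward pass through the stack using activation
#' probabilities (no sampling); the label is the argmax class with ties going
#' to the first class in the model's class list.
#'
#' @param model a `stacked_rbm`.
#' @param features matrix (or single vector) of raw features.
#' @return tibble with `.pred_class` and one probability column per class.
#' @export
predict_labels <- function(model, features) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$feature_scaling$mins)) {
    stop_validation("feature length does not match the model")
  }
  probs <- stacked_rbm_scores(model, features)
  colnames(probs) <- model$classes
  lab <- model$classes[max.col(probs, ties.method = "first")]
  dplyr::bind_cols(tibble::tibble(.pred_class = lab),
                   tibble::as_tibble(probs))
}

#' k-nearest-neighbour baseline classifier
#'
#' Thin wrapper over `class::knn` used for the fractional-order sweep.
#'
#' @param train_x,train_y training features and labels.
#' @param test_x test features.
#' @param k neighbours, default 3.
#' @return factor of predicted labels.
#' @export
classify_knn <- function(train_x, train_y, test_x, k = 3) {
  class::knn(as.matrix(train_x), as.matrix(test_x), factor(train_y), k = k)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.stacked_rbm <- function(x, ...) {
  if (!length(x$layers)) {
    return(tibble::tibble(layer = integer(0), n_visible = integer(0),
                          n_hidden = integer(0), epochs = integer(0),
                          final_reconstruction_error = numeric(0)))
  }
  tibble::tibble(
    layer = seq_along(x$layers),
    n_visible = vapply(x$layers, function(l) nrow(l$weights), numeric(1)),
    n_hidden = vapply(x$layers, function(l) ncol(l$weights), numeric(1)),
    epochs = vapply(x$layers, function(l) length(l$training_trace), numeric(1)),
    final_reconstruction_error =
      vapply(x$layers, function(l) utils::tail(l$training_trace, 1), numeric(1)))
}

#' @exportS3Method generics::glance
glance.stacked_rbm <- function(x, ...) {
  tibble::tibble(n_layers = length(x$layers),
                 n_features = length(x$feature_scaling$mins),
                 n_classes = length(x$classes))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.rbm_layer <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$training_trace),
                       reconstruction_error = object$training_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$reconstruction_error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean reconstruction error")
}
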
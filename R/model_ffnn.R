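# Feed-forward component classifier on group-pair composition features.
#
# Four linear layers with rectifier activations, following the narrowing
# 16-8-4 hidden-width pattern; the input layer is sized to the feature
# dimension and the output layer to the number of classes. Trained
# full-batch by stochastic-gradient-style descent on the cross-entropy
# loss. Inputs are standardized (per-feature centre/scale learned on the
# training set) so the step size is comparable across feature blocks.

#' Feed-forward network configuration
#'
#' @param hidden_dims Descending widths of the hidden layers (default
#'   `c(16, 8, 4)`, giving four linear layers in total).
#' @param epochs Full-batch gradient steps (default 1000; on
#'   standardized inputs the loss typically plateaus well before this).
#' @param learning_rate Step size (default 0.1).
#' @param standardize Centre and scale features before training (stored
#'   with the model and reapplied at prediction).
#' @param seed Integer seed for initialization.
#' @return An object of class `ffnn_config`.
#' @export
ffnn_config <- function(hidden_dims = c(16L, 8L, 4L), epochs = 1000L,
                        learning_rate = 0.1, standardize = TRUE,
                        seed = 1L) {
  if (length(hidden_dims) < 1L || any(hidden_dims < 1L)) {
    stopf("hidden_dims must be positive integers")
  }
  if (is.unsorted(rev(hidden_dims))) stopf("hidden_dims must be descending")
  structure(list(hidden_dims = as.integer(hidden_dims),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "ffnn_config")
}

#' @noRd
ffnn_forward <- function(X, params) {
  nlayer <- length(params$W)
  act <- vector("list", nlayer + 1L)
  act[[1L]] <- X
  for (l in seq_len(nlayer)) {
    Z <- act[[l]] %*% params$W[[l]] + rep(params$b[[l]], each = nrow(X))
    if (l < nlayer) Z[Z < 0] <- 0
    act[[l + 1L]] <- Z
  }
  probs <- softmax_rows(act[[nlayer + 1L]])
  list(act = act, probs = probs)
}

#' Train the feed-forward component classifier
#'
#' @param features A feature matrix (rows aligned with `labels`),
#'   typically [cksaagp()] output.
#' @param labels Class labels; at least two classes must be present.
#' @param config An [ffnn_config()].
#' @return A fitted component model of class `c("ros_ffnn",
#'   "ros_component")`.
#' @export
train_ffnn <- function(features, labels, config = ffnn_config()) {
  stopifnot(inherits(config, "ffnn_config"), is.matrix(features))
  n <- nrow(features)
  if (n == 0L) stopf("cannot train on an empty input")
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (length(labels) != n) stopf("labels must align with feature rows")
  if (nlevels(labels) < 2L) stopf("training data contains a single class")
  classes <- levels(labels)
  y <- as.integer(labels)
  D <- ncol(features)
  if (config$standardize) {
    center <- colMeans(features)
    scale <- apply(features, 2L, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
    X <- sweep(sweep(features, 2L, center), 2L, scale, `/`)
  } else {
    center <- numeric(D); scale <- rep(1, D)
    X <- features
  }
  dims <- c(D, config$hidden_dims, length(classes))
  nlayer <- length(dims) - 1L
  Y <- matrix(0, n, length(classes))
  Y[cbind(seq_len(n), y)] <- 1
  history <- numeric(config$epochs)
  params <- NULL
  with_seed(config$seed, {
    params <- list(
      W = lapply(seq_len(nlayer), function(l) {
        matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
               dims[l], dims[l + 1L])
      }),
      b = lapply(seq_len(nlayer), function(l) numeric(dims[l + 1L])))
    for (epoch in seq_len(config$epochs)) {
      fw <- ffnn_forward(X, params)
      history[epoch] <- -mean(log(pmax(fw$probs[cbind(seq_len(n), y)], 1e-12)))
      delta <- (fw$probs - Y) / n
      for (l in rev(seq_len(nlayer))) {
        gW <- t(fw$act[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(params$W[[l]])) * (fw$act[[l]] > 0)
        }
        params$W[[l]] <- params$W[[l]] - config$learning_rate * gW
        params$b[[l]] <- params$b[[l]] - config$learning_rate * gb
      }
    }
  })
  structure(list(kind = "ffnn", params = params, config = config,
                 classes = classes, n_classes = length(classes),
                 feature_spec = "cksaagp", n_features = D,
                 center = center, scale = scale, history = history),
            class = c("ros_ffnn", "ros_component"))
}

#' @rdname predict_proba
#' @export
predict_proba.ros_ffnn <- function(model, newdata, ...) {
  if (!is.matrix(newdata)) stopf("newdata must be a feature matrix")
  if (ncol(newdata) != model$n_features) {
    stopf("feature dimension mismatch: model expects %d, got %d",
          model$n_features, ncol(newdata))
  }
  if (nrow(newdata) == 0L) {
    return(matrix(numeric(0), 0L, model$n_classes,
                  dimnames = list(NULL, model$classes)))
  }
  X <- sweep(sweep(newdata, 2L, model$center), 2L, model$scale, `/`)
  out <- ffnn_forward(X, model$params)$probs
  colnames(out) <- model$classes
  out
}
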
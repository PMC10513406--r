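# Gradient-boosted tree component classifier on residue-pair composition
# features, backed by xgboost.

#' Gradient-boosted tree configuration
#'
#' Defaults are the framework's stated boosted-tree hyperparameters:
#' learning rate 0.1, maximum depth 20, 150 trees, gamma 0 and row
#' subsampling 0.9.
#'
#' @param learning_rate Shrinkage (eta).
#' @param max_depth Maximum tree depth.
#' @param n_estimators Number of boosting rounds.
#' @param gamma Minimum loss reduction to split.
#' @param subsample Row subsampling fraction per tree.
#' @param seed Integer seed for the booster's sampling.
#' @return An object of class `gbt_config`.
#' @export
gbt_config <- function(learning_rate = 0.1, max_depth = 20L,
                       n_estimators = 150L, gamma = 0, subsample = 0.9,
                       seed = 1L) {
  stopifnot(learning_rate > 0, max_depth >= 1, n_estimators >= 1,
            gamma >= 0, subsample > 0, subsample <= 1)
  structure(list(learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 n_estimators = as.integer(n_estimators),
                 gamma = gamma, subsample = subsample,
                 seed = as.integer(seed)),
            class = "gbt_config")
}

#' Train the boosted-tree component classifier
#'
#' @param features A feature matrix (rows aligned with `labels`),
#'   typically [cksaap()] output.
#' @param labels Class labels; at least two classes must be present.
#' @param config A [gbt_config()].
#' @return A fitted component model of class `c("ros_gbt",
#'   "ros_component")`.
#' @export
train_gbt <- function(features, labels, config = gbt_config()) {
  stopifnot(inherits(config, "gbt_config"), is.matrix(features))
  n <- nrow(features)
  if (n == 0L) stopf("cannot train on an empty input")
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (length(labels) != n) stopf("labels must align with feature rows")
  if (nlevels(labels) < 2L) stopf("training data contains a single class")
  classes <- levels(labels)
  dtrain <- xgboost::xgb.DMatrix(unname(features),
                                 label = as.integer(labels) - 1L)
  params <- list(objective = "multi:softprob",
                 num_class = length(classes),
                 eta = config$learning_rate,
                 max_depth = config$max_depth,
                 gamma = config$gamma,
                 subsample = config$subsample,
                 tree_method = "hist",
                 nthread = 1L,
                 seed = config$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$n_estimators, verbose = 0)
  structure(list(kind = "gbt", booster = booster, config = config,
                 classes = classes, n_classes = length(classes),
                 feature_spec = "cksaap", n_features = ncol(features)),
            class = c("ros_gbt", "ros_component"))
}

#' @rdname predict_proba
#' @export
predict_proba.ros_gbt <- function(model, newdata, ...) {
  if (!is.matrix(newdata)) stopf("newdata must be a feature matrix")
  if (ncol(newdata) != model$n_features) {
    stopf("feature dimension mismatch: model expects %d, got %d",
          model$n_features, ncol(newdata))
  }
  if (nrow(newdata) == 0L) {
    return(matrix(numeric(0), 0L, model$n_classes,
                  dimnames = list(NULL, model$classes)))
  }
  pred <- predict(model$booster, xgboost::xgb.DMatrix(unname(newdata)))
  out <- matrix(pred, nrow = nrow(newdata), ncol = model$n_classes,
                byrow = !is.matrix(pred))
  if (is.matrix(pred)) out <- pred
  colnames(out) <- model$classes
  out <- out / rowSums(out)
  out
}
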
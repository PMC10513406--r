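# Shared component-model surface: the probability contract and bundle
# (de)serialization.

MODEL_FORMAT_VERSION <- 1L

#' Class-probability predictions from a component model
#'
#' All three component kinds (`cnn`, `ffnn`, `gbt`) honour the same
#' contract: one row per input, one column per class (named), entries
#' non-negative and each row summing to 1 within 1e-6, so the models are
#' interchangeable behind the voting ensemble. The hard vote of a model
#' is the argmax of its row.
#'
#' @param model A fitted component model.
#' @param newdata Encoded inputs matching the model's `feature_spec`
#'   (token matrix for `cnn`, CKSAAGP features for `ffnn`, CKSAAP
#'   features for `gbt`).
#' @param ... Unused.
#' @return Numeric matrix `n x n_classes` of class probabilities.
#' @export
predict_proba <- function(model, newdata, ...) UseMethod("predict_proba")

#' @export
print.ros_component <- function(x, ...) {
  cat(sprintf("Component classifier (%s) on '%s' features: %d classes [%s]\n",
              x$kind, x$feature_spec, x$n_classes,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Save a component model to a directory
#'
#' Writes a `metadata.json` (kind, classes, feature spec, configuration,
#' seed, format version) next to a parameter blob, so a saved model can
#' be inspected without loading it.
#'
#' @param model A fitted component model.
#' @param directory Target directory (created if absent).
#' @return Invisibly, `directory`.
#' @seealso [load_model()]
#' @export
save_model <- function(model, directory) {
  stopifnot(inherits(model, "ros_component"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = MODEL_FORMAT_VERSION,
               kind = model$kind,
               n_classes = model$n_classes,
               classes = model$classes,
               feature_spec = model$feature_spec,
               config = unclass(model$config),
               seed = model$config$seed)
  jsonlite::write_json(meta, file.path(directory, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  obj <- unclass(model)
  if (model$kind == "gbt") {
    obj$booster_raw <- xgboost::xgb.save.raw(model$booster)
    obj$booster <- NULL
  }
  saveRDS(obj, file.path(directory, "params.rds"))
  invisible(directory)
}

#' Load a component model saved by [save_model()]
#'
#' @param directory Directory containing `metadata.json` and
#'   `params.rds`.
#' @return The fitted component model; its [predict_proba()] output is
#'   bit-identical to the saved model's.
#' @export
load_model <- function(directory) {
  meta_path <- file.path(directory, "metadata.json")
  blob_path <- file.path(directory, "params.rds")
  if (!file.exists(meta_path) || !file.exists(blob_path)) {
    stopf("not a model directory (missing metadata.json or params.rds): %s",
          directory)
  }
  meta <- tryCatch(jsonlite::read_json(meta_path),
                   error = function(e) stopf("corrupt model metadata: %s",
                                             conditionMessage(e)))
  if (!identical(as.integer(meta$format_version), MODEL_FORMAT_VERSION)) {
    stopf("unsupported model format version: %s", meta$format_version)
  }
  if (!meta$kind %in% c("cnn", "ffnn", "gbt")) {
    stopf("unknown model kind in metadata: %s", meta$kind)
  }
  obj <- readRDS(blob_path)
  if (!identical(obj$kind, meta$kind)) {
    stopf("metadata/parameter mismatch in %s", directory)
  }
  if (obj$kind == "gbt") {
    obj$booster <- xgboost::xgb.load.raw(obj$booster_raw)
    obj$booster_raw <- NULL
  }
  class(obj) <- c(paste0("ros_", obj$kind), "ros_component")
  obj
}
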
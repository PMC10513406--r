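# Evaluation machinery: binary gate metrics, per-class accuracy/recall,
# and the three-method unique-correct Venn attribution.

#' Binary confusion counts
#'
#' Standard 2x2 tabulation with `"pos"` (ROSes) as the positive label.
#'
#' @param truth,predicted Equal-length binary label vectors over
#'   `c("pos", "neg")`.
#' @return A list of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn` summing to the number of examples.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stopf("truth and predicted differ in length (%d vs %d)",
          length(truth), length(predicted))
  }
  if (length(truth) == 0L) stopf("cannot tabulate zero examples")
  if (!all(c(truth, predicted) %in% c("pos", "neg"))) {
    stopf("labels must be 'pos' or 'neg'")
  }
  structure(list(tp = sum(truth == "pos" & predicted == "pos"),
                 fp = sum(truth == "neg" & predicted == "pos"),
                 fn = sum(truth == "pos" & predicted == "neg"),
                 tn = sum(truth == "neg" & predicted == "neg")),
            class = "confusion_counts")
}

#' @noRd
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s is undefined (zero denominator); reported as NA", what),
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy, precision, recall (identical to sensitivity for a binary
#' task, so reported as one field), specificity and F1. Ratios with a
#' zero denominator are reported as `NA` with a warning, never coerced
#' to 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return A list of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `specificity`, `f1` and `n_evaluated`.
#' @examples
#' m <- binary_metrics(structure(list(tp = 3, fp = 2, fn = 1, tn = 4),
#'                               class = "confusion_counts"))
#' m$accuracy  # 0.7
#' @export
binary_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total == 0L) stopf("cannot compute metrics over zero examples")
  precision <- safe_ratio(counts$tp, counts$tp + counts$fp, "precision")
  recall <- safe_ratio(counts$tp, counts$tp + counts$fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (!is.na(precision) && !is.na(recall)) {
      warning("f1 is undefined (precision + recall = 0); reported as NA",
              call. = FALSE)
    }
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(accuracy = (counts$tp + counts$tn) / total,
                 precision = precision,
                 recall = recall,
                 specificity = safe_ratio(counts$tn, counts$tn + counts$fp,
                                          "specificity"),
                 f1 = f1,
                 n_evaluated = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Binary metrics over %d examples\n", x$n_evaluated))
  for (m in c("accuracy", "precision", "recall", "specificity", "f1")) {
    cat(sprintf("  %-11s %s\n", m,
                if (is.na(x[[m]])) "NA (undefined)" else sprintf("%.4f", x[[m]])))
  }
  invisible(x)
}

#' Per-class accuracy and recall
#'
#' For each class `c`: recall is the fraction of truth-`c` examples
#' predicted as `c`, and accuracy the one-vs-rest accuracy of the
#' indicator for `c`. Classes with no truth members get `NA` recall.
#'
#' @param truth,predicted Class label vectors. `predicted` may contain
#'   labels outside `class_names` (e.g. the `"non-ROSes"` sentinel for
#'   gate-rejected positives); those predictions are wrong for every
#'   class but are not themselves evaluated as classes.
#' @param class_names The class set to evaluate.
#' @return A `data.frame` with columns `class`, `n_truth`, `accuracy`
#'   and `recall`.
#' @export
per_class_recall <- function(truth, predicted, class_names) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stopf("truth and predicted differ in length")
  }
  if (!all(truth %in% class_names)) {
    stopf("unknown truth class label: %s",
          paste(setdiff(unique(truth), class_names), collapse = ", "))
  }
  out <- lapply(class_names, function(cl) {
    in_truth <- truth == cl
    in_pred <- predicted == cl
    rec <- if (sum(in_truth) == 0L) NA_real_ else sum(in_truth & in_pred) / sum(in_truth)
    data.frame(class = cl,
               n_truth = sum(in_truth),
               accuracy = mean(in_truth == in_pred),
               recall = rec,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Three-set correctness Venn attribution
#'
#' Partitions the evaluation universe into the 7 regions of the Venn
#' diagram of the three methods' correctly classified id sets, plus the
#' all-wrong remainder. Region counts always sum to the universe size.
#'
#' @param correct_a,correct_b,correct_c Id sets (character vectors) of
#'   examples each method classified correctly; each must be a subset
#'   of `universe`.
#' @param universe All evaluated ids.
#' @return A named list of class `venn_attribution` with counts
#'   `only_a`, `only_b`, `only_c`, `ab_not_c`, `ac_not_b`, `bc_not_a`,
#'   `abc` and `none`.
#' @export
unique_correct_attribution <- function(correct_a, correct_b, correct_c,
                                       universe) {
  sets <- list(a = unique(as.character(correct_a)),
               b = unique(as.character(correct_b)),
               c = unique(as.character(correct_c)))
  universe <- unique(as.character(universe))
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], universe)
    if (length(extra) > 0L) {
      stopf("set '%s' contains id(s) outside the universe: %s",
            nm, paste(utils::head(extra, 3L), collapse = ", "))
    }
  }
  ina <- universe %in% sets$a
  inb <- universe %in% sets$b
  inc <- universe %in% sets$c
  structure(list(only_a = sum(ina & !inb & !inc),
                 only_b = sum(!ina & inb & !inc),
                 only_c = sum(!ina & !inb & inc),
                 ab_not_c = sum(ina & inb & !inc),
                 ac_not_b = sum(ina & !inb & inc),
                 bc_not_a = sum(!ina & inb & inc),
                 abc = sum(ina & inb & inc),
                 none = sum(!ina & !inb & !inc)),
            class = "venn_attribution")
}
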
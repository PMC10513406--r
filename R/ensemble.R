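# Two-level hierarchical ensemble: a hard-voted binary gate (ROSes vs
# non-ROSes) over three heterogeneous component classifiers, followed by
# a soft-voted multiclass assignment for gated-positive sequences.

ENSEMBLE_FORMAT_VERSION <- 1L
COMPONENT_KINDS <- c("cnn", "ffnn", "gbt")

#' Hard (majority) vote over three binary labels
#'
#' @param votes Exactly three labels (character); with three binary
#'   voters a strict 2-of-3 majority always exists.
#' @return The majority label.
#' @export
hard_vote <- function(votes) {
  votes <- as.character(votes)
  if (length(votes) != 3L) stopf("hard_vote requires exactly 3 votes, got %d",
                                 length(votes))
  tab <- sort(table(votes), decreasing = TRUE)
  if (tab[1L] < 2L) stopf("no majority among votes: %s",
                          paste(votes, collapse = ", "))
  names(tab)[1L]
}

#' Soft (probability-averaging) vote over three class distributions
#'
#' Averages the three probability vectors without weights and returns
#' the argmax of the mean; ties are broken by the lowest class index.
#'
#' @param prob_rows A 3-row numeric matrix (columns = classes, in a
#'   fixed shared order) or a list of three equal-length probability
#'   vectors, each summing to 1 within 1e-6.
#' @return A list with `class` (winning class name, or index as a
#'   character if unnamed) and `probabilities` (the averaged vector).
#' @export
soft_vote <- function(prob_rows) {
  if (is.list(prob_rows) && !is.data.frame(prob_rows)) {
    if (length(prob_rows) != 3L) stopf("soft_vote requires exactly 3 probability vectors")
    if (length(unique(lengths(prob_rows))) != 1L) {
      stopf("probability vectors differ in length")
    }
    prob_rows <- do.call(rbind, prob_rows)
  }
  if (!is.matrix(prob_rows) || nrow(prob_rows) != 3L) {
    stopf("soft_vote requires exactly 3 probability vectors")
  }
  sums <- rowSums(prob_rows)
  if (any(abs(sums - 1) > 1e-6) || any(prob_rows < -1e-12)) {
    stopf("inputs to soft_vote must be probability vectors summing to 1")
  }
  mean_p <- colMeans(prob_rows)
  j <- which.max(mean_p)            # which.max takes the lowest index on ties
  cls <- colnames(prob_rows)[j] %||% as.character(j)
  list(class = cls, probabilities = mean_p)
}

#' Fit the two-level ROS-scavenging-enzyme classifier
#'
#' Trains six component models: three binary gate models (convolutional
#' network on tokens, feed-forward network on CKSAAGP features, boosted
#' trees on CKSAAP features) on the full training set, and the same
#' three architectures as multiclass models on the positive examples
#' only. At prediction time the gate is a hard 2-of-3 majority vote and
#' the class assignment a soft (probability-averaging) vote.
#'
#' @param data Labeled training examples: a `data.frame` with columns
#'   `id`, `sequence`, `level1` (`"pos"`/`"neg"`) and `level2` (class
#'   name for positives, `NA` for negatives), e.g. a join of
#'   [read_fasta()] and [read_label_table()] or the output of
#'   [generate_benchmark()].
#' @param encoder An [encoder_config()]. The token pad length actually
#'   used is the smaller of `pad_length` and the longest training
#'   sequence.
#' @param cnn,ffnn,gbt Component configurations ([cnn_config()],
#'   [ffnn_config()], [gbt_config()]); their seeds are overridden by
#'   per-model seeds derived from `seed`.
#' @param seed Integer seed making training reproducible end to end.
#' @return An object of class `ros_classifier` with [predict][predict.ros_classifier],
#'   [print][print.ros_classifier] and [summary][summary.ros_classifier]
#'   methods.
#' @examples
#' \donttest{
#' bench <- generate_benchmark(synthetic_spec(
#'   class_sizes = c(12, 12), motifs = c("WWHKDCEY", "FYMNPQRD"),
#'   negative_ratio = 1, mutation_rate = 0, seed = 7))
#' fit <- ros_classifier(bench,
#'   cnn = cnn_config(embedding_dim = 8, conv_filters = 8, epochs = 4),
#'   seed = 7)
#' predict(fit, bench[1:3, ])
#' }
#' @export
ros_classifier <- function(data, encoder = encoder_config(),
                           cnn = cnn_config(), ffnn = ffnn_config(),
                           gbt = gbt_config(), seed = 1L) {
  stopifnot(is.data.frame(data),
            all(c("id", "sequence", "level1", "level2") %in% names(data)),
            inherits(encoder, "encoder_config"))
  if (nrow(data) == 0L) stopf("cannot train on an empty dataset")
  if (!all(data$level1 %in% c("pos", "neg"))) {
    stopf("level1 labels must be 'pos' or 'neg'")
  }
  pos <- data[data$level1 == "pos", , drop = FALSE]
  if (nrow(pos) == 0L) stopf("training data contains no positive examples")
  if (nrow(pos) == nrow(data)) stopf("training data contains no negative examples")
  if (anyNA(pos$level2)) stopf("every positive example needs a level-2 class")
  class_names <- sort(unique(pos$level2))
  if (length(class_names) < 2L) {
    stopf("at least 2 level-2 classes are required, got %d", length(class_names))
  }
  seed <- as.integer(seed)

  vocab <- build_vocabulary(data)
  pad_len <- min(encoder$pad_length, max(nchar(data$sequence)))
  tokens <- encode_tokens(data, vocab, pad_len)
  feats_gp <- cksaagp(data, encoder$k_max, encoder$group_scheme)
  feats_ap <- cksaap(data, encoder$k_max)

  y1 <- factor(data$level1, levels = c("neg", "pos"))
  cnn$seed <- seed + 11L; ffnn$seed <- seed + 12L; gbt$seed <- seed + 13L
  level1 <- list(cnn  = train_cnn(tokens, y1, cnn),
                 ffnn = train_ffnn(feats_gp, y1, ffnn),
                 gbt  = train_gbt(feats_ap, y1, gbt))

  ipos <- which(data$level1 == "pos")
  y2 <- factor(data$level2[ipos], levels = class_names)
  cnn$seed <- seed + 21L; ffnn$seed <- seed + 22L; gbt$seed <- seed + 23L
  level2 <- list(cnn  = train_cnn(tokens[ipos, , drop = FALSE], y2, cnn),
                 ffnn = train_ffnn(feats_gp[ipos, , drop = FALSE], y2, ffnn),
                 gbt  = train_gbt(feats_ap[ipos, , drop = FALSE], y2, gbt))

  structure(list(level1_models = level1, level2_models = level2,
                 vocab = vocab, encoder = encoder, pad_length = pad_len,
                 class_names = class_names, seed = seed,
                 n_train = nrow(data), n_positive = nrow(pos),
                 call = match.call()),
            class = "ros_classifier")
}

# Encode records into the three representations; rows whose sequence is
# too short for the pair descriptors get an error message instead.
#' @noRd
encode_all <- function(object, records) {
  k_max <- object$encoder$k_max
  ok <- nchar(records$sequence) >= k_max + 2L
  err <- ifelse(ok, NA_character_,
                sprintf("sequence too short (%d residues) for spacing k = %d",
                        nchar(records$sequence),
                        pmax(nchar(records$sequence) - 1L, 0L)))
  tokens <- encode_tokens(records, object$vocab, object$pad_length)
  feats_gp <- matrix(NA_real_, nrow(records), 25L * (k_max + 1L))
  feats_ap <- matrix(NA_real_, nrow(records), 400L * (k_max + 1L))
  if (any(ok)) {
    sub <- records[ok, , drop = FALSE]
    feats_gp[ok, ] <- cksaagp(sub, k_max, object$encoder$group_scheme)
    feats_ap[ok, ] <- cksaap(sub, k_max)
  }
  list(ok = ok, error = err, tokens = tokens,
       cksaagp = feats_gp, cksaap = feats_ap)
}

#' @noRd
component_probs <- function(models, enc, ok) {
  lapply(COMPONENT_KINDS, function(kind) {
    m <- models[[kind]]
    input <- switch(m$feature_spec,
                    tokens = enc$tokens[ok, , drop = FALSE],
                    cksaagp = enc$cksaagp[ok, , drop = FALSE],
                    cksaap = enc$cksaap[ok, , drop = FALSE])
    predict_proba(m, input)
  })
}

#' Hierarchical predictions for new sequences
#'
#' Each record is encoded into all three representations; the level-1
#' gate is the hard majority vote of the three binary models' argmax
#' votes. Gate-rejected records receive the sentinel class
#' `"non-ROSes"` and no level-2 probabilities; gate-accepted records
#' get the soft-voted class over the three level-2 models. Records that
#' cannot be encoded (shorter than `k_max + 2`) yield a per-record
#' `error` entry and do not abort the batch.
#'
#' @param object A fitted [ros_classifier()].
#' @param newdata Records `data.frame` (columns `id`, `sequence`) or a
#'   character vector of sequences.
#' @param ... Unused.
#' @return A `data.frame` with columns `id`, `level1_decision`,
#'   `level1_votes` (`cnn|ffnn|gbt`), `level2_class`,
#'   `level2_probabilities` (formatted `class=prob` pairs) and `error`.
#'   The numeric level-2 probability matrix for gate-accepted rows is
#'   attached as attribute `"level2_prob_matrix"`.
#' @export
predict.ros_classifier <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) {
    newdata <- data.frame(id = sprintf("seq%d", seq_along(newdata)),
                          sequence = as.character(newdata),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(newdata)))
  n <- nrow(newdata)
  out <- data.frame(id = newdata$id,
                    level1_decision = rep(NA_character_, n),
                    level1_votes = rep(NA_character_, n),
                    level2_class = rep(NA_character_, n),
                    level2_probabilities = rep("", n),
                    error = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  enc <- encode_all(object, newdata)
  out$error <- enc$error
  ok <- enc$ok
  if (!any(ok)) return(out)

  p1 <- component_probs(object$level1_models, enc, ok)
  votes <- vapply(p1, function(pm) colnames(pm)[max.col(pm, ties.method = "first")],
                  character(sum(ok)))
  votes <- matrix(votes, ncol = 3L)
  decision <- apply(votes, 1L, hard_vote)
  out$level1_decision[ok] <- decision
  out$level1_votes[ok] <- apply(votes, 1L, paste, collapse = "|")
  out$level2_class[ok] <- NON_ROSES_SENTINEL

  idx_ok <- which(ok)
  accept <- decision == "pos"
  prob_mat <- NULL
  if (any(accept)) {
    ok2 <- logical(n)
    ok2[idx_ok[accept]] <- TRUE
    p2 <- component_probs(object$level2_models, enc, ok2)
    prob_mat <- matrix(NA_real_, sum(accept), length(object$class_names),
                       dimnames = list(newdata$id[ok2], object$class_names))
    for (r in seq_len(sum(accept))) {
      sv <- soft_vote(rbind(p2[[1L]][r, ], p2[[2L]][r, ], p2[[3L]][r, ]))
      prob_mat[r, ] <- sv$probabilities
      i <- idx_ok[accept][r]
      out$level2_class[i] <- sv$class
      out$level2_probabilities[i] <- format_prob_string(
        stats::setNames(sv$probabilities, object$class_names))
    }
  }
  attr(out, "level2_prob_matrix") <- prob_mat
  out
}

#' @export
print.ros_classifier <- function(x, ...) {
  cat("Hierarchical ROS-scavenging-enzyme classifier\n")
  cat(sprintf("  level 1: 3 binary gate models (%s), hard 2-of-3 vote\n",
              paste(COMPONENT_KINDS, collapse = ", ")))
  cat(sprintf("  level 2: 3 multiclass models over %d classes, soft vote\n",
              length(x$class_names)))
  cat(sprintf("  trained on %d examples (%d positive), seed %d\n",
              x$n_train, x$n_positive, x$seed))
  invisible(x)
}

#' @export
summary.ros_classifier <- function(object, ...) {
  cat("Hierarchical ROS-scavenging-enzyme classifier\n\n")
  cat(sprintf("Training set: %d examples, %d positive across %d classes\n",
              object$n_train, object$n_positive, length(object$class_names)))
  cat(sprintf("Classes: %s\n", paste(object$class_names, collapse = ", ")))
  cat(sprintf("Encoder: k_max = %d, effective pad length = %d, vocabulary %d tokens\n",
              object$encoder$k_max, object$pad_length, object$vocab$max_index))
  for (lvl in c("level1_models", "level2_models")) {
    cat(sprintf("\n%s:\n", sub("_models", "", lvl)))
    for (kind in COMPONENT_KINDS) {
      m <- object[[lvl]][[kind]]
      extra <- if (!is.null(m$history)) {
        sprintf(", final training loss %.4f", m$history[length(m$history)])
      } else ""
      cat(sprintf("  %-4s on %-7s (%d classes%s)\n", m$kind, m$feature_spec,
                  m$n_classes, extra))
    }
  }
  invisible(object)
}

#' Save a fitted hierarchical classifier to a directory
#'
#' Writes one subdirectory per component model (see [save_model()]) plus
#' an `ensemble.json` with the class names, encoder configuration,
#' vocabulary and seed.
#'
#' @param object A fitted [ros_classifier()].
#' @param directory Target directory.
#' @return Invisibly, `directory`.
#' @export
save_classifier <- function(object, directory) {
  stopifnot(inherits(object, "ros_classifier"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (kind in COMPONENT_KINDS) {
    save_model(object$level1_models[[kind]],
               file.path(directory, paste0("level1_", kind)))
    save_model(object$level2_models[[kind]],
               file.path(directory, paste0("level2_", kind)))
  }
  meta <- list(format_version = ENSEMBLE_FORMAT_VERSION,
               class_names = object$class_names,
               encoder = list(k_max = object$encoder$k_max,
                              pad_length = object$encoder$pad_length,
                              group_scheme = object$encoder$group_scheme),
               pad_length_effective = object$pad_length,
               vocab = as.list(object$vocab$rank_of),
               seed = object$seed,
               n_train = object$n_train, n_positive = object$n_positive)
  jsonlite::write_json(meta, file.path(directory, "ensemble.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(directory)
}

#' Load a hierarchical classifier saved by [save_classifier()]
#'
#' @param directory Bundle directory.
#' @return A `ros_classifier` giving predictions identical to the saved
#'   fit.
#' @export
load_classifier <- function(directory) {
  meta_path <- file.path(directory, "ensemble.json")
  if (!file.exists(meta_path)) stopf("not a classifier bundle: %s", directory)
  meta <- jsonlite::read_json(meta_path)
  if (!identical(as.integer(meta$format_version), ENSEMBLE_FORMAT_VERSION)) {
    stopf("unsupported bundle format version: %s", meta$format_version)
  }
  rank_of <- unlist(meta$vocab)
  vocab <- structure(list(rank_of = stats::setNames(as.integer(rank_of),
                                                    names(rank_of)),
                          pad_index = 0L, max_index = length(rank_of)),
                     class = "token_vocabulary")
  scheme <- lapply(meta$encoder$group_scheme, function(g) unlist(g))
  enc <- encoder_config(k_max = meta$encoder$k_max,
                        pad_length = meta$encoder$pad_length,
                        group_scheme = scheme)
  level1 <- level2 <- list()
  for (kind in COMPONENT_KINDS) {
    level1[[kind]] <- load_model(file.path(directory, paste0("level1_", kind)))
    level2[[kind]] <- load_model(file.path(directory, paste0("level2_", kind)))
  }
  structure(list(level1_models = level1, level2_models = level2,
                 vocab = vocab, encoder = enc,
                 pad_length = as.integer(meta$pad_length_effective),
                 class_names = unlist(meta$class_names),
                 seed = as.integer(meta$seed),
                 n_train = as.integer(meta$n_train),
                 n_positive = as.integer(meta$n_positive),
                 call = NULL),
            class = "ros_classifier")
}
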
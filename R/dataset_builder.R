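# Training-set construction: redundancy reduction by greedy identity
# clustering, hard-negative selection by similarity ranking against the
# positive set, and stratified train/test splitting. The external
# clustering and search binaries of the original pipeline are replaced by
# exactly testable in-package algorithms: dynamic-programming global
# alignment identity and alignment-free k-mer cosine similarity.

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and
#' linear gap penalty -1; identity is the number of matched positions
#' divided by the alignment length. Symmetric, in `[0, 1]`, and 1
#' exactly for identical sequences.
#'
#' @param a,b Non-empty residue strings.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  .nw_identity(a, b)
}

#' Greedy incremental identity clustering
#'
#' Records are processed by decreasing sequence length (ties by id,
#' ascending); each record joins the first existing cluster whose
#' representative it matches at identity at least `threshold`, otherwise
#' it founds a new cluster. This mirrors the greedy longest-first
#' strategy of standard redundancy-reduction tools.
#'
#' @param records Records `data.frame` with `id` and `sequence`.
#' @param threshold Identity fraction in `(0, 1]` (0.99 is the
#'   redundancy-reduction default of the framework).
#' @return A list of class `cluster_result`: `representatives` (ids in
#'   founding order), `member_of` (named character vector mapping every
#'   id to its representative id) and `threshold`.
#' @export
greedy_cluster <- function(records, threshold = 0.99) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stopf("threshold must be in (0, 1]")
  }
  ord <- order(-nchar(records$sequence), records$id)
  ids <- records$id[ord]
  seqs <- records$sequence[ord]
  rep_ids <- character(0)
  rep_seqs <- character(0)
  member_of <- character(length(ids))
  names(member_of) <- ids
  for (i in seq_along(ids)) {
    joined <- FALSE
    for (r in seq_along(rep_ids)) {
      # exact-match shortcut avoids the DP for duplicates
      ident <- if (seqs[i] == rep_seqs[r]) 1 else pairwise_identity(seqs[i], rep_seqs[r])
      if (ident >= threshold) {
        member_of[[ids[i]]] <- rep_ids[r]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      rep_ids <- c(rep_ids, ids[i])
      rep_seqs <- c(rep_seqs, seqs[i])
      member_of[[ids[i]]] <- ids[i]
    }
  }
  structure(list(representatives = rep_ids, member_of = member_of,
                 threshold = threshold),
            class = "cluster_result")
}

#' @noRd
kmer_profile <- function(sequence, k) {
  n <- nchar(sequence)
  starts <- seq_len(n - k + 1L)
  table(substring(sequence, starts, starts + k - 1L))
}

#' Alignment-free k-mer cosine similarity
#'
#' Cosine similarity between the k-mer count profiles of two sequences:
#' 1 for identical sequences, 0 when they share no k-mer.
#'
#' @param a,b Residue strings of length at least `k`.
#' @param k Word size (default 3).
#' @return Similarity in `[0, 1]`.
#' @export
kmer_similarity <- function(a, b, k = 3L) {
  if (nchar(a) < k || nchar(b) < k) {
    stopf("sequences must be at least k = %d residues long", k)
  }
  pa <- kmer_profile(a, k)
  pb <- kmer_profile(b, k)
  shared <- intersect(names(pa), names(pb))
  if (length(shared) == 0L) return(0)
  num <- sum(as.numeric(pa[shared]) * as.numeric(pb[shared]))
  num / sqrt(sum(as.numeric(pa)^2) * sum(as.numeric(pb)^2))
}

#' Select hard negatives by similarity ranking against the positives
#'
#' Scores every candidate by its best k-mer cosine similarity against
#' any positive sequence and keeps the top `n` (descending score, ties
#' by id ascending) — negatives deliberately chosen to resemble the
#' positive set so the gate must learn a sharp boundary.
#'
#' @param candidates,positives Records `data.frame`s.
#' @param n Number of candidates to select (`n <=` candidate count).
#' @param k k-mer word size for the similarity (default 3).
#' @return A list of class `hard_negative_selection`: `selected` (the
#'   chosen candidate records, ranked) and `ranking` (a `data.frame` of
#'   all candidates with `id` and `score`, in selection order).
#' @export
mine_hard_negatives <- function(candidates, positives, n, k = 3L) {
  stopifnot(is.data.frame(candidates), is.data.frame(positives))
  if (!is_count(n) || n > nrow(candidates)) {
    stopf("n must be a count not exceeding the number of candidates (%d)",
          nrow(candidates))
  }
  scores <- vapply(candidates$sequence, function(s) {
    max(vapply(positives$sequence, function(p) kmer_similarity(s, p, k),
               numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-scores, candidates$id)
  ranking <- data.frame(id = candidates$id[ord], score = scores[ord],
                        stringsAsFactors = FALSE)
  structure(list(selected = candidates[ord[seq_len(n)], , drop = FALSE],
                 ranking = ranking),
            class = "hard_negative_selection")
}

#' Stratified train/test split
#'
#' Splits a labeled dataset into disjoint train and test sets,
#' stratified jointly on the level-1 label and the level-2 class, so
#' every class keeps (approximately) the requested test fraction.
#' Strata with fewer than 2 members cannot be split and are kept in the
#' training set with a warning.
#'
#' @param dataset Labeled examples `data.frame` (columns `id`,
#'   `level1`, `level2`, ...).
#' @param test_fraction Fraction in `(0, 1)` assigned to the test set
#'   per stratum (rounded).
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return A list with elements `train` and `test`, disjoint with union
#'   equal to the input.
#' @export
stratified_split <- function(dataset, test_fraction, seed = 1L) {
  stopifnot(is.data.frame(dataset),
            all(c("id", "level1") %in% names(dataset)))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must be in (0, 1)")
  }
  lvl2 <- dataset$level2 %||% rep(NA_character_, nrow(dataset))
  stratum <- paste(dataset$level1, ifelse(is.na(lvl2), "", lvl2), sep = "/")
  test_idx <- integer(0)
  with_seed(seed, {
    for (s in sort(unique(stratum))) {
      idx <- which(stratum == s)
      if (length(idx) < 2L) {
        warning(sprintf("stratum '%s' has %d member(s) and cannot be split; kept in training",
                        s, length(idx)), call. = FALSE)
        next
      }
      n_test <- round(length(idx) * test_fraction)
      n_test <- max(min(n_test, length(idx) - 1L), 0L)
      if (n_test > 0L) test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  list(train = dataset[setdiff(seq_len(nrow(dataset)), test_idx), , drop = FALSE],
       test = dataset[test_idx, , drop = FALSE])
}
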
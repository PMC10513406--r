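# Sequence feature encoders: frequency-ranked tokenization (convolutional
# network input), CKSAAP residue-pair compositions (boosted-tree input) and
# CKSAAGP group-pair compositions (feed-forward-network input).

#' Default physicochemical residue grouping
#'
#' The standard 5-group partition used by group-pair composition
#' descriptors: aliphatic (G, A, V, L, M, I), aromatic (F, Y, W),
#' positively charged (K, R, H), negatively charged (D, E) and uncharged
#' polar (S, T, C, P, N, Q). Ambiguous residues (X, B, Z) belong to no
#' group and are excluded from pair numerators.
#'
#' @return Named list of character vectors partitioning the 20 standard
#'   residues.
#' @export
default_group_scheme <- function() {
  list(g1 = c("G", "A", "V", "L", "M", "I"),
       g2 = c("F", "Y", "W"),
       g3 = c("K", "R", "H"),
       g4 = c("D", "E"),
       g5 = c("S", "T", "C", "P", "N", "Q"))
}

#' Encoder configuration
#'
#' @param k_max Maximum pair spacing (number of residues between the two
#'   members of a pair); spacings `0..k_max` are used. Default 5, giving a
#'   2,400-dimensional CKSAAP and a 150-dimensional CKSAAGP descriptor.
#' @param pad_length Fixed token-sequence length `L`; shorter sequences
#'   are post-padded with 0, longer ones truncated. Default 1000.
#' @param group_scheme Named partition of the 20 standard residues, as
#'   [default_group_scheme()].
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(k_max = 5L, pad_length = 1000L,
                           group_scheme = default_group_scheme()) {
  if (!is_count(k_max)) stopf("k_max must be a non-negative integer")
  if (!is_count(pad_length, min = 1L)) stopf("pad_length must be >= 1")
  members <- sort(unlist(group_scheme, use.names = FALSE))
  if (!identical(members, sort(STANDARD_RESIDUES))) {
    stopf("group_scheme must partition the 20 standard residues exactly once")
  }
  structure(list(k_max = as.integer(k_max),
                 pad_length = as.integer(pad_length),
                 group_scheme = group_scheme),
            class = "encoder_config")
}

#' Build a frequency-ranked token vocabulary
#'
#' Counts character frequencies over the whole corpus and assigns rank 1
#' to the most frequent character, rank 2 to the next, and so on; ties are
#' broken lexicographically. Rank 0 is reserved for padding. The unknown
#' residue `X` is always included (with count 0 if unobserved) so unseen
#' characters can be mapped at prediction time.
#'
#' @param records A records `data.frame` (see [read_fasta()]) or a
#'   character vector of sequences.
#' @return An object of class `token_vocabulary`: a list with `rank_of`
#'   (named integer vector), `pad_index` (0) and `max_index`.
#' @export
build_vocabulary <- function(records) {
  seqs <- if (is.data.frame(records)) records$sequence else as.character(records)
  if (length(seqs) == 0L) stopf("cannot build a vocabulary from an empty corpus")
  counts <- table(unlist(seq_chars(seqs), use.names = FALSE))
  chars <- names(counts)
  if (!"X" %in% chars) {
    chars <- c(chars, "X")
    counts <- c(as.vector(counts), 0L)
  } else {
    counts <- as.vector(counts)
  }
  ord <- order(-counts, chars)
  rank_of <- seq_along(chars)
  names(rank_of) <- chars[ord]
  structure(list(rank_of = rank_of, pad_index = 0L,
                 max_index = length(rank_of)),
            class = "token_vocabulary")
}

#' Encode sequences as fixed-length integer token rows
#'
#' Maps each residue to its vocabulary rank (unseen characters map to the
#' rank of `X`), post-pads with 0 up to `pad_length` and truncates longer
#' sequences to their first `pad_length` residues.
#'
#' @param records Records `data.frame` or character vector of sequences.
#' @param vocab A `token_vocabulary` from [build_vocabulary()].
#' @param pad_length Fixed output length `L`.
#' @return Integer matrix with one row per sequence and `pad_length`
#'   columns, class `token_matrix`.
#' @export
encode_tokens <- function(records, vocab, pad_length = 1000L) {
  stopifnot(inherits(vocab, "token_vocabulary"))
  if (!is_count(pad_length, min = 1L)) stopf("pad_length must be >= 1")
  seqs <- if (is.data.frame(records)) records$sequence else as.character(records)
  L <- as.integer(pad_length)
  x_rank <- vocab$rank_of[["X"]]
  out <- matrix(0L, nrow = length(seqs), ncol = L)
  chars <- seq_chars(seqs)
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (length(ch) > L) ch <- ch[seq_len(L)]
    r <- unname(vocab$rank_of[ch])
    r[is.na(r)] <- x_rank
    out[i, seq_along(r)] <- r
  }
  if (is.data.frame(records)) rownames(out) <- records$id
  class(out) <- c("token_matrix", class(out))
  attr(out, "max_index") <- vocab$max_index
  out
}

# Count ordered pairs (s[i], s[i + k + 1]) over `levels` for one spacing k.
# Pairs with either member outside `levels` contribute to no cell; the
# denominator is the total number of positions, length - k - 1.
#' @noRd
pair_block <- function(ch, k, levels) {
  n <- length(ch)
  n_pairs <- n - k - 1L
  a <- ch[seq_len(n_pairs)]
  b <- ch[seq_len(n_pairs) + k + 1L]
  keep <- a %in% levels & b %in% levels
  counts <- table(factor(a[keep], levels = levels),
                  factor(b[keep], levels = levels))
  # row = first member, column order varies fastest over second member
  as.vector(t(counts)) / n_pairs
}

#' @noRd
ckspaced <- function(sequences, k_max, levels, map_fun, tag, sep = "") {
  seqs <- if (is.data.frame(sequences)) sequences$sequence else as.character(sequences)
  if (!is_count(k_max)) stopf("k_max must be a non-negative integer")
  nl <- length(levels)
  pair_names <- as.vector(t(outer(levels, levels, paste, sep = sep)))
  feat_names <- unlist(lapply(0:k_max, function(k) paste0(pair_names, "|", k)))
  out <- matrix(NA_real_, nrow = length(seqs), ncol = nl * nl * (k_max + 1L))
  colnames(out) <- feat_names
  chars <- seq_chars(seqs)
  for (i in seq_along(chars)) {
    ch <- map_fun(chars[[i]])
    if (length(ch) < k_max + 2L) {
      k_fail <- max(length(ch) - 1L, 0L)  # smallest spacing with no valid pair
      stopf("sequence %d is too short (%d residues) for spacing k = %d (needs length >= k + 2)",
            i, length(ch), k_fail)
    }
    row <- numeric(0)
    for (k in 0:k_max) row <- c(row, pair_block(ch, k, levels))
    out[i, ] <- row
  }
  if (is.data.frame(sequences)) rownames(out) <- sequences$id
  attr(out, "descriptor") <- tag
  out
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each ordered residue pair (a, b) over the 20 standard residues and
#' each spacing k in `0..k_max`, the count of positions i with
#' `seq[i] == a` and `seq[i + k + 1] == b`, divided by the number of
#' k-spaced positions in the sequence (length − k − 1). Pairs involving
#' an ambiguous residue (X, B, Z) contribute to the denominator but to no
#' numerator cell, so a k-block sums to exactly 1 only for ambiguity-free
#' sequences.
#'
#' @param sequences Records `data.frame` or character vector of sequences.
#' @param k_max Maximum spacing (default 5; descriptor dimension
#'   `400 * (k_max + 1)`).
#' @return Numeric matrix, one row per sequence, with feature names
#'   `"ab|k"`.
#' @examples
#' cksaap("ACAC", k_max = 1)[, c("AA|1", "CC|1")]
#' @export
cksaap <- function(sequences, k_max = 5L) {
  ckspaced(sequences, k_max, STANDARD_RESIDUES, identity, "cksaap")
}

#' Composition of k-spaced amino-acid-group pairs (CKSAAGP)
#'
#' The same k-spaced pair composition as [cksaap()] computed over the 5
#' physicochemical residue groups instead of the 20 residues (25 ordered
#' group pairs per spacing). Ambiguous residues belong to no group and are
#' excluded from numerators.
#'
#' @inheritParams cksaap
#' @param group_scheme Named partition of the standard residues, as
#'   [default_group_scheme()].
#' @return Numeric matrix with feature names `"ga.gb|k"`.
#' @export
cksaagp <- function(sequences, k_max = 5L, group_scheme = default_group_scheme()) {
  groups <- names(group_scheme)
  res2grp <- rep(groups, lengths(group_scheme))
  names(res2grp) <- unlist(group_scheme, use.names = FALSE)
  map_fun <- function(ch) {
    g <- res2grp[ch]
    g[is.na(g)] <- "?"          # ambiguous residue: member of no group
    unname(g)
  }
  ckspaced(sequences, k_max, groups, map_fun, "cksaagp", sep = ".")
}
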
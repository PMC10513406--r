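# Independent oracles and fixture builders used across the suite. Each
# oracle is a deliberately naive re-derivation (brute-force loops, direct
# set enumeration) kept separate from the package's implementation path.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequences <- function(n, len_range = c(10L, 50L),
                             alphabet = AAS) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(len_range[1]:len_range[2], 1L),
                 replace = TRUE), collapse = "")
  }, character(1))
}

as_records <- function(seqs, prefix = "s") {
  data.frame(id = sprintf("%s%03d", prefix, seq_along(seqs)),
             description = rep("", length(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}

# Brute-force k-spaced pair composition: explicit double loop over
# positions and spacings.
oracle_ckspaced <- function(seq, k_max, level_of, levels, sep = "") {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- numeric(0)
  for (k in 0:k_max) {
    block <- matrix(0, length(levels), length(levels),
                    dimnames = list(levels, levels))
    n_pairs <- length(ch) - k - 1L
    for (i in seq_len(n_pairs)) {
      a <- level_of(ch[i]); b <- level_of(ch[i + k + 1L])
      if (!is.na(a) && !is.na(b)) block[a, b] <- block[a, b] + 1
    }
    v <- as.vector(t(block)) / n_pairs
    names(v) <- paste0(rep(levels, each = length(levels)), sep,
                       rep(levels, times = length(levels)), "|", k)
    out <- c(out, v)
  }
  out
}

oracle_cksaap <- function(seq, k_max) {
  oracle_ckspaced(seq, k_max,
                  function(ch) if (ch %in% AAS) ch else NA_character_, AAS)
}

oracle_group_of <- function() {
  scheme <- list(g1 = c("G", "A", "V", "L", "M", "I"),
                 g2 = c("F", "Y", "W"),
                 g3 = c("K", "R", "H"),
                 g4 = c("D", "E"),
                 g5 = c("S", "T", "C", "P", "N", "Q"))
  lookup <- rep(names(scheme), lengths(scheme))
  names(lookup) <- unlist(scheme)
  function(ch) if (ch %in% names(lookup)) lookup[[ch]] else NA_character_
}

oracle_cksaagp <- function(seq, k_max) {
  oracle_ckspaced(seq, k_max, oracle_group_of(),
                  paste0("g", 1:5), sep = ".")
}

# Independent pure-R Needleman-Wunsch (match +1, mismatch 0, gap -1)
# with the same deterministic tie-break order (diagonal, up, left).
oracle_nw_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  score <- matrix(0, n + 1L, m + 1L)
  dir <- matrix(0L, n + 1L, m + 1L)   # 0 diag, 1 up, 2 left
  score[1L, ] <- -(0:m); dir[1L, ] <- 2L
  score[, 1L] <- -(0:n); dir[, 1L] <- 1L
  dir[1L, 1L] <- 0L
  for (i in 1:n) for (j in 1:m) {
    cand <- c(score[i, j] + (x[i] == y[j]), score[i, j + 1L] - 1, score[i + 1L, j] - 1)
    best <- which.max(cand)
    score[i + 1L, j + 1L] <- cand[best]
    dir[i + 1L, j + 1L] <- best - 1L
  }
  i <- n + 1L; j <- m + 1L; matches <- 0L; len <- 0L
  while (i > 1L || j > 1L) {
    len <- len + 1L
    d <- dir[i, j]
    if (d == 0L) { matches <- matches + (x[i - 1L] == y[j - 1L]); i <- i - 1L; j <- j - 1L }
    else if (d == 1L) i <- i - 1L
    else j <- j - 1L
  }
  matches / len
}

# Build a linearly separable two-class fixture: two exclusive motifs
# implanted in random backgrounds, encoded as requested.
separable_fixture <- function(n_per_class = 20L, len_range = c(60L, 80L),
                              motifs = c("WWWWW", "HHHHH"), seed = 1L) {
  f1 <- generate_family(motifs[1], n_per_class, len_range, 0,
                        seed = seed, id_prefix = "a")
  f2 <- generate_family(motifs[2], n_per_class, len_range, 0,
                        seed = seed + 1L, id_prefix = "b")
  recs <- rbind(f1, f2)
  list(records = recs,
       labels = factor(rep(c("a", "b"), each = n_per_class)))
}

# A fast, tiny labeled benchmark for contract-level ensemble tests.
tiny_benchmark <- function(seed = 7L, n = 14L) {
  generate_benchmark(synthetic_spec(
    n_classes = 2L, class_sizes = c(n, n),
    motifs = c(alpha = "WWHKDCEY", beta = "FYMNPQRD"),
    seq_length_range = c(40L, 70L), mutation_rate = 0,
    negative_ratio = 1, hard_negative_fraction = 0.5, seed = seed))
}

tiny_cnn <- function(seed = 1L) {
  cnn_config(embedding_dim = 8L, conv_filters = 8L, epochs = 6L,
             batch_size = 16L, seed = seed)
}

tiny_ffnn <- function(seed = 1L) ffnn_config(epochs = 300L, seed = seed)

tiny_gbt <- function(seed = 1L) gbt_config(n_estimators = 20L, max_depth = 6L,
                                           seed = seed)

# Running log of every hierarchical prediction frame the suite emits,
# so the gate-consistency property can be asserted globally.
.prediction_log <- new.env(parent = emptyenv())
.prediction_log$frames <- list()

log_predictions <- function(pred) {
  .prediction_log$frames[[length(.prediction_log$frames) + 1L]] <- pred
  invisible(pred)
}

expect_gate_consistent <- function(pred) {
  neg <- !is.na(pred$level1_decision) & pred$level1_decision == "neg"
  expect_true(all(pred$level2_class[neg] == "non-ROSes"))
  expect_true(all(pred$level2_probabilities[neg] == ""))
}
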
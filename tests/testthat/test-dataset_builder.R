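test_that("alignment identity matches hand-derived cases and is symmetric", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("AAAT", "AAAA"), 0.75)
  expect_error(pairwise_identity("", "AA"), "non-empty")
})

test_that("alignment identity equals an independent dynamic-programming oracle", {
  set.seed(23)
  for (rep in 1:50) {
    a <- random_sequences(1L, c(3L, 30L))
    b <- if (rep %% 3 == 0) {
      # related pair: mutate + indel for non-trivial alignments
      paste0(substr(a, 1, nchar(a) %/% 2), random_sequences(1L, c(1L, 8L)))
    } else random_sequences(1L, c(3L, 30L))
    expect_equal(pairwise_identity(a, b), oracle_nw_identity(a, b))
  }
})

test_that("greedy clustering collapses near-duplicates and is a fixed point", {
  recs <- as_records(c("AAAA", "AAAA", "AAAT"))
  cl <- greedy_cluster(recs, 0.99)
  expect_length(cl$representatives, 2L)
  expect_equal(unname(cl$member_of[["s002"]]), cl$member_of[["s001"]])
  expect_true(all(cl$member_of[cl$representatives] == cl$representatives))

  # threshold 1.0 collapses exactly the duplicate sequences
  set.seed(31)
  seqs <- random_sequences(30L, c(8L, 15L))
  dup <- as_records(c(seqs, sample(seqs, 10L, replace = TRUE)), prefix = "d")
  cl <- greedy_cluster(dup, 1.0)
  expect_length(cl$representatives, length(unique(dup$sequence)))

  # all-distinct random records each found their own cluster at 1.0
  distinct <- as_records(unique(random_sequences(20L, c(10L, 20L))))
  cl2 <- greedy_cluster(distinct, 1.0)
  expect_length(cl2$representatives, nrow(distinct))

  # re-clustering the representatives yields no further merges
  reps <- dup[dup$id %in% cl$representatives, ]
  cl3 <- greedy_cluster(reps, 1.0)
  expect_length(cl3$representatives, length(cl$representatives))
  expect_error(greedy_cluster(recs, 0), "threshold")
})

test_that("members sit within the identity threshold of their representative", {
  set.seed(37)
  base <- random_sequences(8L, c(20L, 30L))
  variants <- vapply(base, function(s) mutate_sequence(s, 0.05), character(1))
  recs <- as_records(c(base, variants), prefix = "m")
  cl <- greedy_cluster(recs, 0.8)
  seqs <- setNames(recs$sequence, recs$id)
  for (id in names(cl$member_of)) {
    rep_id <- cl$member_of[[id]]
    expect_gte(pairwise_identity(seqs[[id]], seqs[[rep_id]]), 0.8)
  }
})

test_that("k-mer similarity matches a profile dot-product oracle", {
  expect_equal(kmer_similarity("AAAAAA", "AAAAAA"), 1.0)
  expect_equal(kmer_similarity("AAAA", "CCCC"), 0.0)
  expect_error(kmer_similarity("AA", "CCCC", k = 3), "at least k")
  set.seed(41)
  for (rep in 1:50) {
    a <- random_sequences(1L, c(4L, 25L))
    b <- random_sequences(1L, c(4L, 25L))
    oracle <- local({
      prof <- function(s) {
        st <- seq_len(nchar(s) - 2L)
        table(substring(s, st, st + 2L))
      }
      pa <- prof(a); pb <- prof(b)
      keys <- union(names(pa), names(pb))
      va <- as.numeric(pa[keys]); va[is.na(va)] <- 0
      vb <- as.numeric(pb[keys]); vb[is.na(vb)] <- 0
      if (sum(va * vb) == 0) 0 else sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
    })
    expect_equal(kmer_similarity(a, b, 3L), oracle)
  }
})

test_that("hard-negative mining selects the constructed near-positive first", {
  positives <- as_records("AAAAAA", prefix = "p")
  candidates <- as_records(c("AAAAAT", "TTTTTT"), prefix = "c")
  sel <- mine_hard_negatives(candidates, positives, n = 1L)
  expect_equal(sel$selected$sequence, "AAAAAT")
  # selected scores dominate unselected scores
  expect_true(min(sel$ranking$score[1]) >= max(sel$ranking$score[-1]))

  all_sel <- mine_hard_negatives(candidates, positives, n = 2L)
  expect_equal(nrow(all_sel$selected), 2L)
  expect_error(mine_hard_negatives(candidates, positives, n = 3L), "not exceeding")

  # equal scores break ties by ascending id
  tied <- data.frame(id = c("z1", "a1"), sequence = c("AAAAAA", "AAAAAA"),
                     stringsAsFactors = FALSE)
  sel <- mine_hard_negatives(tied, positives, n = 1L)
  expect_equal(sel$selected$id, "a1")
})

test_that("stratified splitting is seeded, disjoint, exhaustive and per-class exact", {
  spec <- synthetic_spec(n_classes = 5L, class_sizes = rep(20L, 5L),
                         negative_ratio = 0.5, seed = 2L)
  data <- generate_benchmark(spec)
  sp <- stratified_split(data, 0.2, seed = 7L)
  expect_equal(sort(c(sp$train$id, sp$test$id)), sort(data$id))
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  per_class <- table(sp$test$level2)
  expect_true(all(per_class == 4L))

  sp2 <- stratified_split(data, 0.2, seed = 7L)
  expect_identical(sp$test$id, sp2$test$id)
  sp3 <- stratified_split(data, 0.2, seed = 8L)
  expect_false(identical(sp$test$id, sp3$test$id))

  singleton <- data[c(which(data$level1 == "neg"),
                      which(data$level2 %in% "catalase")[1]), ]
  expect_warning(stratified_split(singleton, 0.2, seed = 1L), "cannot be split")
})
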
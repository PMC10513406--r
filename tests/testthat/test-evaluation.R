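test_that("confusion counts tabulate correctly and match a tally oracle", {
  t10 <- rep(c("pos", "neg"), c(10L, 5L))
  cc <- confusion_counts(t10, t10)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 10L, tn = 5L, fp = 0L, fn = 0L), ignore_attr = TRUE)
  cc <- confusion_counts(rep("pos", 7L), rep("neg", 7L))
  expect_equal(cc$fn, 7L)
  expect_error(confusion_counts(c("pos"), c("pos", "neg")), "length")

  set.seed(77)
  truth <- sample(c("pos", "neg"), 500L, replace = TRUE)
  pred <- sample(c("pos", "neg"), 500L, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  oracle <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (i in 1:500) {
    key <- if (truth[i] == "pos") {
      if (pred[i] == "pos") "tp" else "fn"
    } else {
      if (pred[i] == "pos") "fp" else "tn"
    }
    oracle[key] <- oracle[key] + 1L
  }
  expect_equal(unlist(unclass(cc))[names(oracle)], oracle)
  expect_equal(sum(unlist(unclass(cc))), 500L)
})

test_that("binary metrics reproduce the hand-evaluated confusion example", {
  cc <- confusion_counts(rep(c("pos", "neg"), c(4L, 6L)),
                         c("pos", "pos", "pos", "neg",      # tp=3 fn=1
                           "pos", "pos", "neg", "neg", "neg", "neg"))  # fp=2 tn=4
  m <- binary_metrics(cc)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.6)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$n_evaluated, 10L)
  expect_output(print(m), "accuracy")
})

test_that("perfect predictions yield all-ones metrics; order permutation is irrelevant", {
  truth <- rep(c("pos", "neg"), c(6L, 4L))
  m <- binary_metrics(confusion_counts(truth, truth))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "specificity", "f1")]),
               rep(1, 5L), ignore_attr = TRUE)
  set.seed(13)
  pred <- sample(c("pos", "neg"), 10L, replace = TRUE)
  perm <- sample.int(10L)
  expect_equal(binary_metrics(confusion_counts(truth, pred)),
               binary_metrics(confusion_counts(truth[perm], pred[perm])))
})

test_that("zero-denominator metrics are reported as absent, not zero", {
  cc <- confusion_counts(rep("neg", 5L), rep("neg", 5L))  # tp = fp = 0
  w <- capture_warnings(m <- binary_metrics(cc))
  expect_match(w, "undefined", all = TRUE)
  expect_length(w, 2L)   # precision and recall both flagged
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_equal(m$accuracy, 1)
})

test_that("per-class recall and one-vs-rest accuracy follow the direct counts", {
  pc <- per_class_recall(c("c1", "c1", "c2"), c("c1", "c2", "c2"), c("c1", "c2"))
  expect_equal(pc$recall[pc$class == "c1"], 0.5)
  expect_equal(pc$recall[pc$class == "c2"], 1.0)
  expect_equal(pc$accuracy[pc$class == "c1"], 2 / 3)

  truth <- c("a", "b", "c", "a")
  pc <- per_class_recall(truth, truth, c("a", "b", "c"))
  expect_equal(pc$recall, rep(1, 3L))
  # absent class: NA recall, not zero
  pc <- per_class_recall(c("a", "a"), c("a", "a"), c("a", "b"))
  expect_true(is.na(pc$recall[pc$class == "b"]))
  expect_error(per_class_recall(c("zz"), c("a"), c("a", "b")), "unknown")
  # the sentinel in predictions counts against the true class
  pc <- per_class_recall(c("a", "a"), c("a", "non-ROSes"), c("a", "b"))
  expect_equal(pc$recall[pc$class == "a"], 0.5)
})

test_that("Venn attribution is exact on the worked example and partitions the universe", {
  v <- unique_correct_attribution(c("1", "2", "3"), c("2", "3"), c("3", "4"),
                                  as.character(1:5))
  expect_equal(v$only_a, 1L)      # {1}
  expect_equal(v$ab_not_c, 1L)    # {2}
  expect_equal(v$abc, 1L)         # {3}
  expect_equal(v$only_c, 1L)      # {4}
  expect_equal(v$none, 1L)        # {5}
  expect_equal(v$only_b + v$ac_not_b + v$bc_not_a, 0L)

  u <- as.character(1:6)
  v <- unique_correct_attribution(u, u, u, u)
  expect_equal(v$abc, 6L)
  expect_equal(sum(unlist(v)) - v$abc, 0L)

  v <- unique_correct_attribution("1", "2", "3", as.character(1:3))
  expect_equal(unlist(v[c("only_a", "only_b", "only_c")]),
               c(only_a = 1L, only_b = 1L, only_c = 1L))

  expect_error(unique_correct_attribution("9", "2", "3", as.character(1:3)),
               "outside the universe")

  set.seed(55)
  for (rep in 1:100) {
    u <- as.character(seq_len(sample(3:40, 1L)))
    pick <- function() sample(u, sample(0:length(u), 1L))
    v <- unique_correct_attribution(pick(), pick(), pick(), u)
    expect_equal(sum(unlist(v)), length(u))
  }
})
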
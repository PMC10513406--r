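# Voting primitives and the two-level classifier contract.

test_that("hard vote equals the exhaustive majority oracle on all 8 triples", {
  expect_equal(hard_vote(c("pos", "pos", "neg")), "pos")
  expect_equal(hard_vote(c("neg", "neg", "neg")), "neg")
  grid <- expand.grid(a = c("pos", "neg"), b = c("pos", "neg"),
                      c = c("pos", "neg"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    votes <- unlist(grid[i, ])
    oracle <- if (sum(votes == "pos") >= 2L) "pos" else "neg"
    expect_equal(hard_vote(votes), oracle)
  }
  expect_error(hard_vote(c("pos", "neg")), "exactly 3")
})

test_that("soft vote is the unweighted mean with lowest-index tie-breaking", {
  sv <- soft_vote(rbind(c(0.6, 0.4), c(0.2, 0.8), c(0.4, 0.6)))
  expect_equal(sv$probabilities, c(0.4, 0.6))
  expect_equal(sv$class, "2")
  one_hot <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 1, 0))
  colnames(one_hot) <- c("a", "b", "c")
  sv <- soft_vote(one_hot)
  expect_equal(sv$class, "b")
  expect_equal(unname(sv$probabilities), c(0, 1, 0))
  # exact tie goes to the lower class index
  tie <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))
  colnames(tie) <- c("first", "second")
  expect_equal(soft_vote(tie)$class, "first")

  expect_error(soft_vote(rbind(c(1, 0), c(0.5, 0.6), c(0, 1))), "summing to 1")
  expect_error(soft_vote(list(c(1, 0), c(0, 1))), "exactly 3")
})

test_that("soft vote matches a mean-then-argmax oracle on random triples", {
  set.seed(9)
  for (rep in 1:200) {
    m <- matrix(stats::rexp(15), 3L, 5L)
    m <- m / rowSums(m)
    colnames(m) <- paste0("c", 1:5)
    sv <- soft_vote(m)
    oracle_mean <- (m[1, ] + m[2, ] + m[3, ]) / 3
    expect_equal(unname(sv$probabilities), unname(oracle_mean))
    expect_equal(sv$class, names(oracle_mean)[which.max(oracle_mean)])
  }
})

# one tiny trained hierarchy shared by the contract tests below
bench <- tiny_benchmark()
fit <- ros_classifier(bench, cnn = tiny_cnn(), ffnn = tiny_ffnn(),
                      gbt = tiny_gbt(), seed = 5L)

test_that("the fitted hierarchy carries the expected structure", {
  expect_s3_class(fit, "ros_classifier")
  expect_equal(fit$class_names, c("alpha", "beta"))
  expect_named(fit$level1_models, c("cnn", "ffnn", "gbt"))
  expect_named(fit$level2_models, c("cnn", "ffnn", "gbt"))
  expect_equal(fit$level1_models$gbt$classes, c("neg", "pos"))
  expect_equal(fit$level2_models$cnn$classes, c("alpha", "beta"))
  expect_output(print(fit), "hard 2-of-3 vote")
  expect_output(summary(fit), "level2")
})

test_that("training rejects degenerate datasets", {
  negs <- bench[bench$level1 == "neg", ]
  expect_error(ros_classifier(negs, seed = 1L), "no positive")
  pos <- bench[bench$level1 == "pos", ]
  expect_error(ros_classifier(pos, seed = 1L), "no negative")
  one_class <- bench[bench$level1 == "neg" | bench$level2 %in% "alpha", ]
  expect_error(ros_classifier(one_class, seed = 1L), "at least 2 level-2 classes")
  expect_error(ros_classifier(bench[0, ], seed = 1L), "empty")
})

test_that("predictions honour the gate contract and are deterministic given the seed", {
  pred <- log_predictions(predict(fit, bench))
  expect_equal(nrow(pred), nrow(bench))
  expect_gate_consistent(pred)
  # positive decisions carry a concrete class and normalized probabilities
  acc <- pred$level1_decision == "pos"
  expect_true(all(pred$level2_class[acc] %in% fit$class_names))
  pm <- attr(pred, "level2_prob_matrix")
  expect_lt(max(abs(rowSums(pm) - 1)), 1e-9)
  # votes column has one vote per component
  expect_true(all(grepl("^(pos|neg)\\|(pos|neg)\\|(pos|neg)$",
                        pred$level1_votes)))

  refit <- ros_classifier(bench, cnn = tiny_cnn(), ffnn = tiny_ffnn(),
                          gbt = tiny_gbt(), seed = 5L)
  pred2 <- log_predictions(predict(refit, bench))
  expect_identical(pred, pred2)
})

test_that("records too short to encode fail per-record without aborting the batch", {
  probe <- data.frame(id = c("ok", "short"),
                      sequence = c(bench$sequence[1], "MK"),
                      stringsAsFactors = FALSE)
  pred <- log_predictions(predict(fit, probe))
  expect_true(is.na(pred$error[1]))
  expect_match(pred$error[2], "too short")
  expect_true(is.na(pred$level1_decision[2]))
  expect_false(is.na(pred$level1_decision[1]))
})

test_that("a saved classifier bundle reloads and predicts identically", {
  dir <- withr::local_tempdir()
  save_classifier(fit, dir)
  expect_true(file.exists(file.path(dir, "ensemble.json")))
  expect_length(list.dirs(dir, recursive = FALSE), 6L)
  reloaded <- load_classifier(dir)
  p1 <- predict(fit, bench[1:10, ])
  p2 <- predict(reloaded, bench[1:10, ])
  expect_identical(p1, p2)
  expect_error(load_classifier(withr::local_tempdir()), "not a classifier bundle")
})
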
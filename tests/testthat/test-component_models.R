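# The three component classifiers behind the shared probability contract.

fixture <- separable_fixture(seed = 3L)
fix_vocab <- build_vocabulary(fixture$records)
fix_tokens <- encode_tokens(fixture$records, fix_vocab, 80L)
fix_gp <- cksaagp(fixture$records)
fix_ap <- cksaap(fixture$records)

train_accuracy <- function(model, inputs, labels) {
  p <- predict_proba(model, inputs)
  mean(colnames(p)[max.col(p, ties.method = "first")] == labels)
}

test_that("every component kind learns the separable motif fixture and is seed-reproducible", {
  models <- list(
    cnn = list(fit = function(seed) train_cnn(fix_tokens, fixture$labels,
                                              cnn_config(epochs = 20L, seed = seed)),
               inputs = fix_tokens),
    ffnn = list(fit = function(seed) train_ffnn(fix_gp, fixture$labels,
                                                ffnn_config(seed = seed)),
                inputs = fix_gp),
    gbt = list(fit = function(seed) train_gbt(fix_ap, fixture$labels,
                                              gbt_config(seed = seed)),
               inputs = fix_ap))
  for (kind in names(models)) {
    m1 <- models[[kind]]$fit(1L)
    expect_s3_class(m1, "ros_component")
    expect_equal(m1$kind, kind)
    expect_gte(train_accuracy(m1, models[[kind]]$inputs, fixture$labels), 0.95)
    p1 <- predict_proba(m1, models[[kind]]$inputs)
    # probability contract
    expect_true(all(p1 >= 0))
    expect_lt(max(abs(rowSums(p1) - 1)), 1e-6)
    expect_equal(colnames(p1), levels(fixture$labels))
    # purity on its own training points
    expect_gte(min(p1[cbind(seq_len(nrow(p1)),
                            as.integer(fixture$labels))][1:5]), 0.5)
    # seeded repeatability
    m2 <- models[[kind]]$fit(1L)
    expect_identical(p1, predict_proba(m2, models[[kind]]$inputs))
  }
})

test_that("neural net training loss decreases on a separable task", {
  m <- train_cnn(fix_tokens, fixture$labels, cnn_config(epochs = 10L, seed = 2L))
  expect_lt(m$history[10L], m$history[1L])
  mf <- train_ffnn(fix_gp, fixture$labels, ffnn_config(seed = 2L))
  expect_lt(mf$history[length(mf$history)], mf$history[1L])
})

test_that("degenerate training inputs are rejected", {
  expect_error(train_cnn(fix_tokens, rep("a", nrow(fix_tokens)),
                         cnn_config(seed = 1L)), "single class")
  expect_error(train_ffnn(fix_gp, rep("a", nrow(fix_gp))), "single class")
  expect_error(train_gbt(fix_ap, rep("a", nrow(fix_ap))), "single class")
  expect_error(train_cnn(fix_tokens[0, , drop = FALSE], character(0),
                         cnn_config(seed = 1L)), "empty")
  expect_error(cnn_config(kernel_widths = c(3L, 5L)), "exactly 3")
})

test_that("feature-dimension mismatches between train and predict are errors", {
  m <- train_ffnn(fix_gp, fixture$labels, ffnn_config(epochs = 10L))
  expect_error(predict_proba(m, fix_gp[, 1:10]), "dimension mismatch")
  g <- train_gbt(fix_ap, fixture$labels, tiny_gbt())
  expect_error(predict_proba(g, fix_ap[, 1:10]), "dimension mismatch")
})

test_that("zero-row prediction input yields an empty matrix with named class columns", {
  m <- train_ffnn(fix_gp, fixture$labels, ffnn_config(epochs = 10L))
  p <- predict_proba(m, fix_gp[0, , drop = FALSE])
  expect_equal(dim(p), c(0L, 2L))
  expect_equal(colnames(p), levels(fixture$labels))
})

test_that("boosted-tree defaults echo the stated hyperparameters", {
  cfg <- gbt_config()
  expect_equal(cfg$learning_rate, 0.1)
  expect_equal(cfg$max_depth, 20L)
  expect_equal(cfg$n_estimators, 150L)
  expect_equal(cfg$gamma, 0)
  expect_equal(cfg$subsample, 0.9)
})

test_that("saved models reload with bit-identical probe predictions", {
  probes <- list(
    cnn = list(m = train_cnn(fix_tokens, fixture$labels, tiny_cnn()),
               x = fix_tokens[1:7, , drop = FALSE]),
    ffnn = list(m = train_ffnn(fix_gp, fixture$labels, ffnn_config(epochs = 20L)),
                x = fix_gp[1:7, , drop = FALSE]),
    gbt = list(m = train_gbt(fix_ap, fixture$labels, tiny_gbt()),
               x = fix_ap[1:7, , drop = FALSE]))
  for (kind in names(probes)) {
    dir <- withr::local_tempdir()
    save_model(probes[[kind]]$m, dir)
    meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
    expect_equal(meta$kind, kind)
    expect_equal(meta$n_classes, 2L)
    expect_equal(meta$feature_spec, probes[[kind]]$m$feature_spec)
    expect_false(is.null(meta$seed))
    loaded <- load_model(dir)
    expect_identical(predict_proba(loaded, probes[[kind]]$x),
                     predict_proba(probes[[kind]]$m, probes[[kind]]$x))
  }
})

test_that("corrupt or missing model metadata is a load error", {
  dir <- withr::local_tempdir()
  m <- train_ffnn(fix_gp, fixture$labels, ffnn_config(epochs = 5L))
  save_model(m, dir)
  writeLines("{not json", file.path(dir, "metadata.json"))
  expect_error(load_model(dir), "corrupt")
  expect_error(load_model(file.path(dir, "missing")), "not a model directory")
})
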
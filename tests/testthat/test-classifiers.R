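test_that("trial splitting is reproducible and enforces the six-set protocol", {
  trials <- as.list(1:30)
  sp <- split_trials(trials, 6, seed = 4)
  expect_length(sp$train, 25)
  expect_length(sp$test, 5)
  expect_identical(sp, split_trials(trials, 6, seed = 4))
  sp2 <- split_trials(trials, 6, seed = 5)
  expect_false(identical(sp$assignment, sp2$assignment))
  expect_error(split_trials(as.list(1:5), 6, seed = 1), "at least 6")
  expect_setequal(c(unlist(sp$train), unlist(sp$test)), 1:30)
})

test_that("all four methods separate Gaussian blobs perfectly", {
  blobs <- make_blobs(30, sd = 0.02, seed = 10)
  test <- make_blobs(15, sd = 0.02, seed = 11)
  for (method in c("SVM", "KNN", "LDA", "ANN")) {
    grid <- switch(method, SVM = data.frame(cost = 8, gamma = 0.5),
                   KNN = data.frame(k = 3), NULL)
    spec <- classifier_spec(method, grid = grid, seed = 1)
    model <- tune_and_train(blobs$X, blobs$y, spec)
    pred <- predict_stream(model, test$X)
    expect_identical(as.character(pred), as.character(test$y))
  }
})

test_that("1-NN reproduces its own training labels", {
  blobs <- make_blobs(20, sd = 0.3, seed = 12)
  model <- tune_and_train(blobs$X, blobs$y,
                          classifier_spec("KNN", grid = data.frame(k = 1)))
  expect_identical(as.character(predict_stream(model, blobs$X)),
                   as.character(blobs$y))
})

test_that("cross-validated grid search picks a winning setting", {
  blobs <- make_blobs(20, sd = 0.05, seed = 13)
  spec <- classifier_spec("KNN", grid = data.frame(k = c(1, 5, 9)),
                          cv_folds = 5, seed = 2)
  model <- tune_and_train(blobs$X, blobs$y, spec)
  expect_s3_class(model, "gait_model")
  expect_true(model$tuned$k %in% c(1, 5, 9))
  expect_identical(nrow(model$cv), 3L)
  expect_gte(max(model$cv$cv_accuracy), 0.95)
  # deterministic under the spec seed
  model2 <- tune_and_train(blobs$X, blobs$y, spec)
  expect_identical(model$tuned, model2$tuned)
  expect_identical(model$cv, model2$cv)
})

test_that("streaming prediction is a pure per-row function", {
  blobs <- make_blobs(20, sd = 0.05, seed = 14)
  for (method in c("SVM", "ANN")) {
    grid <- if (method == "SVM") data.frame(cost = 8, gamma = 0.5) else NULL
    model <- tune_and_train(blobs$X, blobs$y,
                            classifier_spec(method, grid = grid, seed = 3))
    row <- blobs$X[5, , drop = FALSE]
    dup <- rbind(row, row, row)
    expect_length(unique(as.character(predict_stream(model, dup))), 1L)
    mid <- matrix(0.5, 1, 35)
    expect_true(as.character(predict_stream(model, mid)) %in% model$levels)
    expect_error(predict_stream(model, blobs$X[, 1:10]), "mismatch")
  }
})

test_that("ANN training is deterministic under the spec seed", {
  blobs <- make_blobs(15, sd = 0.1, seed = 15)
  spec <- classifier_spec("ANN", seed = 7, ann_maxit = 50)
  m1 <- tune_and_train(blobs$X, blobs$y, spec)
  m2 <- tune_and_train(blobs$X, blobs$y, spec)
  expect_identical(m1$fit$wts, m2$fit$wts)
})

test_that("training refuses degenerate inputs", {
  blobs <- make_blobs(10, seed = 16)
  expect_error(tune_and_train(blobs$X[1:10, ], blobs$y[1:5],
                              classifier_spec("LDA")), "differ")
})
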
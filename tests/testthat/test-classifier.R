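test_that("the learning-rate schedule decays by 0.8 each iteration from 5e-5", {
  toy <- toySequences(8, tSteps = 4L, d = 3L)
  cfg <- TrainingConfig(maxIterations = 5L, hiddenUnits = 4L, batchSize = 4L)
  m <- trainSequenceClassifier(toy$sequences, toy$labels, cfg)
  log <- m@trainingLog
  expect_equal(nrow(log), 5L)
  expect_equal(log$learningRate[1], 5e-5)
  expect_equal(log$learningRate[-1] / log$learningRate[-5], rep(0.8, 4))
  expect_true(all(is.finite(log$loss)))
})

test_that("training is deterministic for a fixed seed", {
  toy <- toySequences(8, tSteps = 4L, d = 3L)
  cfg <- TrainingConfig(maxIterations = 3L, hiddenUnits = 4L, rngSeed = 7L)
  m1 <- trainSequenceClassifier(toy$sequences, toy$labels, cfg)
  m2 <- trainSequenceClassifier(toy$sequences, toy$labels, cfg)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@trainingLog, m2@trainingLog)
})

test_that("predictions are proper probabilities and honour dimensions", {
  toy <- toySequences(10, tSteps = 5L, d = 4L)
  cfg <- TrainingConfig(maxIterations = 4L, hiddenUnits = 4L)
  m <- trainSequenceClassifier(toy$sequences, toy$labels, cfg)
  pred <- predict(m, toy$sequences)
  expect_equal(rowSums(as.matrix(pred[, m@classes])), rep(1, 10),
               tolerance = 1e-6)
  expect_true(all(pred$label %in% c("a", "b")))
  # a zero sequence still yields a valid label with finite probabilities
  z <- predict(m, matrix(0, 5, 4))
  expect_true(z$label %in% c("a", "b"))
  expect_true(all(is.finite(as.matrix(z[, m@classes]))))
  expect_error(predict(m, matrix(0, 5, 9)), "dimension mismatch")
})

test_that("a separable toy set is learned by the recurrent model", {
  toy <- toySequences(24, tSteps = 6L, d = 8L, sep = 2)
  m <- trainSequenceClassifier(toy$sequences, toy$labels,
                               TrainingConfig(hiddenUnits = 8L))
  fit <- evaluateClassifier(m, toy$sequences, toy$labels)
  expect_gte(fit$accuracy, 0.95) # training-set overfit check
})

test_that("the linear baseline beats chance and chance stays chance", {
  toy <- toySequences(40, tSteps = 6L, d = 8L, sep = 1)
  m <- trainSequenceClassifier(toy$sequences, toy$labels,
                               type = "logistic")
  expect_gte(evaluateClassifier(m, toy$sequences, toy$labels)$accuracy, 0.9)

  # permuted labels: held-out accuracy within the binomial chance band
  perm <- withr::with_seed(31, sample(toy$labels))
  mPerm <- trainSequenceClassifier(toy$sequences[1:30], perm[1:30],
                                   type = "logistic")
  acc <- evaluateClassifier(mPerm, toy$sequences[31:40], perm[31:40])$accuracy
  expect_gte(acc, 0.1)
  expect_lte(acc, 0.9)
})

test_that("degenerate training inputs are rejected", {
  toy <- toySequences(6, tSteps = 4L, d = 3L)
  expect_error(
    trainSequenceClassifier(toy$sequences, rep("a", 6)),
    "exactly two classes"
  )
  expect_error(
    trainSequenceClassifier(toy$sequences, toy$labels[1:3]),
    "one label per sequence"
  )
})

test_that("accuracy bookkeeping is plain counting", {
  toy <- toySequences(20, tSteps = 4L, d = 6L, sep = 3)
  m <- trainSequenceClassifier(toy$sequences, toy$labels,
                               type = "logistic")
  ev <- evaluateClassifier(m, toy$sequences, toy$labels)
  agree <- mean(ev$predictions$label == ev$predictions$truth)
  expect_equal(ev$accuracy, agree)
  expect_named(ev$perClass, c("a", "b"))
  expect_error(evaluateClassifier(m, list(), character()), "empty")
})
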
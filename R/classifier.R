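#' Training configuration for the sequence classifier
#'
#' Defaults follow the decoder's published training recipe: Adam with an
#' initial learning rate of 5e-5 decayed by 0.8 every iteration, at most 50
#' iterations, L2 regularization 0.1, and dropout on the readout during
#' training. Hidden width and minibatch size are free settings.
#'
#' @param initialLearningRate Adam initial learning rate.
#' @param lrDecayFactor multiplicative decay applied each iteration.
#' @param maxIterations maximum training iterations (epochs).
#' @param l2Penalty L2 weight penalty.
#' @param dropoutRate dropout rate on the readout, training only.
#' @param hiddenUnits LSTM width per direction.
#' @param batchSize minibatch size.
#' @param rngSeed integer seed for initialisation, shuffling and dropout.
#' @return a [TrainingConfig].
#' @export
TrainingConfig <- function(initialLearningRate = 5e-5, lrDecayFactor = 0.8,
                           maxIterations = 50L, l2Penalty = 0.1,
                           dropoutRate = 0.5, hiddenUnits = 64L,
                           batchSize = 16L, rngSeed = 1L) {
  new("TrainingConfig",
    initialLearningRate = initialLearningRate, lrDecayFactor = lrDecayFactor,
    maxIterations = as.integer(maxIterations), l2Penalty = l2Penalty,
    dropoutRate = dropoutRate, hiddenUnits = as.integer(hiddenUnits),
    batchSize = as.integer(batchSize), rngSeed = as.integer(rngSeed)
  )
}

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf(
    "TrainingConfig: Adam lr %g x %g^k, %d iterations, L2 %g, dropout %g, %d hidden\n",
    object@initialLearningRate, object@lrDecayFactor, object@maxIterations,
    object@l2Penalty, object@dropoutRate, object@hiddenUnits
  ))
})

# stack equal-length feature sequences into an (N, T, D) array
stackSequences <- function(sequences) {
  tt <- unique(vapply(sequences, nrow, integer(1)))
  stopIf(length(tt) != 1L,
         "all sequences must share the same number of time steps")
  d <- unique(vapply(sequences, ncol, integer(1)))
  stopIf(length(d) != 1L, "all sequences must share the feature dimension")
  x <- array(0, c(length(sequences), tt, d))
  for (i in seq_along(sequences)) x[i, , ] <- sequences[[i]]
  x
}

normalizeArray <- function(x, center, scale) {
  d <- dim(x)[3]
  for (j in seq_len(d)) x[, , j] <- (x[, , j] - center[j]) / scale[j]
  x
}

#' Train a two-class sequence classifier
#'
#' Trains a bidirectional LSTM (`type = "bilstm"`) or the deterministic
#' linear baseline (`type = "logistic"`, a ridge-penalised logistic
#' regression on time-averaged features) on labeled feature sequences.
#' Features are z-scored with training-set statistics stored in the model.
#' Training is deterministic for a fixed `rngSeed` on a single thread.
#'
#' @param sequences list of time-step x featureDim matrices, one per trial
#'   (all with identical dimensions), as produced by [slidingFeatures()].
#' @param labels character vector of class labels; exactly two distinct
#'   classes must be present.
#' @param config a [TrainingConfig].
#' @param type `"bilstm"` or `"logistic"`.
#' @return a fitted [SequenceClassifier].
#' @export
trainSequenceClassifier <- function(sequences, labels,
                                    config = TrainingConfig(),
                                    type = c("bilstm", "logistic")) {
  type <- match.arg(type)
  stopIf(length(sequences) != length(labels),
         "one label per sequence required")
  classes <- sort(unique(labels))
  stopIf(length(classes) != 2L,
         "exactly two classes required, got %d (%s)",
         length(classes), paste(classes, collapse = ", "))
  x <- stackSequences(sequences)
  d <- dim(x)[3]
  center <- apply(x, 3, mean)
  scale <- pmax(apply(x, 3, stats::sd), 1e-8)
  x <- normalizeArray(x, center, scale)
  y <- match(labels, classes)
  if (type == "bilstm") {
    fit <- bilstmTrain(x, y, config@hiddenUnits, config)
    weights <- fit$params
    log <- fit$log
  } else {
    xm <- apply(x, c(1, 3), mean) # time-averaged features, N x D
    # glmnet warns about small per-class counts on tiny fixtures; the fit
    # itself is well defined under the ridge penalty
    fit <- withSeed(config@rngSeed, suppressWarnings(glmnet::glmnet(
      xm, factor(y), family = "binomial", alpha = 0, lambda = 0.1,
      standardize = FALSE
    )))
    weights <- list(glmnet = fit)
    log <- data.frame(iteration = 1L,
                      learningRate = NA_real_, loss = NA_real_)
  }
  new("SequenceClassifier",
    type = type, weights = weights, classes = classes,
    featureDim = as.integer(d),
    normalization = list(center = center, scale = scale),
    config = config, trainingLog = log
  )
}

setMethod("show", "SequenceClassifier", function(object) {
  cat(sprintf(
    "SequenceClassifier (%s): %s vs %s, %d features\n",
    object@type, object@classes[1], object@classes[2], object@featureDim
  ))
})

#' Predict class probabilities for feature sequences
#'
#' Runs the fitted model (dropout inactive) on one sequence or a list of
#' sequences and returns the argmax label with both class probabilities.
#'
#' @param object a fitted [SequenceClassifier].
#' @param sequences a single time-step x featureDim matrix or a list of
#'   them.
#' @param ... unused.
#' @return a data.frame with one row per sequence: `label` and one
#'   probability column per class.
#' @export
setMethod("predict", "SequenceClassifier", function(object, sequences, ...) {
  if (is.matrix(sequences)) sequences <- list(sequences)
  bad <- vapply(sequences, function(s) ncol(s) != object@featureDim,
                logical(1))
  stopIf(any(bad), "feature dimension mismatch: expected %d",
         object@featureDim)
  x <- stackSequences(sequences)
  x <- normalizeArray(x, object@normalization$center,
                      object@normalization$scale)
  if (object@type == "bilstm") {
    probs <- bilstmPredict(x, object@weights, object@config@hiddenUnits)
  } else {
    xm <- apply(x, c(1, 3), mean)
    p2 <- as.numeric(stats::predict(object@weights$glmnet, xm,
                                    type = "response"))
    probs <- cbind(1 - p2, p2)
  }
  colnames(probs) <- object@classes
  data.frame(
    label = object@classes[max.col(probs, ties.method = "first")],
    probs, check.names = FALSE, stringsAsFactors = FALSE
  )
})

#' Evaluate a classifier on a labeled test set
#'
#' @param model a fitted [SequenceClassifier].
#' @param sequences list of feature sequences.
#' @param labels true labels parallel to `sequences`.
#' @return a list with `accuracy` (correct/total), `perClass` (success
#'   rate per true class) and the `predictions` data.frame.
#' @export
evaluateClassifier <- function(model, sequences, labels) {
  stopIf(length(sequences) == 0L, "empty test set")
  pred <- predict(model, sequences)
  correct <- pred$label == labels
  perClass <- vapply(
    model@classes,
    function(cl) {
      if (any(labels == cl)) mean(correct[labels == cl]) else NA_real_
    },
    numeric(1)
  )
  list(
    accuracy = mean(correct),
    perClass = perClass,
    predictions = cbind(pred, truth = labels)
  )
}
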
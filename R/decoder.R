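# seeded stratified train/test split over labels; returns logical "train"
stratifiedSplit <- function(labels, trainPerClass, seed) {
  withSeed(seed, {
    train <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      k <- min(trainPerClass, length(idx) - 1L)
      stopIf(k < 2L, "class '%s' has too few trials to split", cl)
      train[sample(idx, k)] <- TRUE
    }
    train
  })
}

# raw epoch -> re-referenced -> multiband (120 ch)
epochToMultiband <- function(epoch, bankSpec, referenceChannels) {
  applyFilterBank(rereference(epoch, referenceChannels), bankSpec)
}

# raw epoch -> feature sequence for one of the two decoders
epochToFeatures <- function(epoch, pipeline,
                            which = c("flexion", "leftright")) {
  which <- match.arg(which)
  bank <- if (which == "flexion") pipeline@flexionCSP else pipeline@lrCSP
  mb <- epochToMultiband(epoch, pipeline@bankSpec, pipeline@referenceChannels)
  slidingFeatures(applyCSPBank(mb, bank), pipeline@windowSpec)
}

fitOneDecoder <- function(trials, labels, classes, bankSpec, windowSpec,
                          referenceChannels, trainingConfig, trainPerClass,
                          classifierType, channelNames) {
  keep <- labels %in% classes
  trials <- trials[keep]
  labels <- labels[keep]
  train <- stratifiedSplit(labels, trainPerClass,
                           subSeed(trainingConfig@rngSeed, 3L))
  multiband <- lapply(trials, epochToMultiband, bankSpec = bankSpec,
                      referenceChannels = referenceChannels)
  csp <- fitCSPBank(multiband[train], labels[train], bankSpec, classes,
                    channelNames)
  feats <- lapply(multiband, function(mb) {
    slidingFeatures(applyCSPBank(mb, csp), windowSpec)
  })
  model <- trainSequenceClassifier(feats[train], labels[train],
                                   trainingConfig, classifierType)
  heldOut <- evaluateClassifier(model, feats[!train], labels[!train])
  list(csp = csp, model = model, accuracy = heldOut$accuracy,
       perClass = heldOut$perClass)
}

#' Fit the full offline decoder pipeline
#'
#' Trains the two decoders of the navigation system from a labeled trial
#' set: a two-hand flexion-vs-rest decoder on the 6 s epochs and a
#' left-vs-right clenching decoder on the 2 s epochs. Each decoder is the
#' chain re-reference, 20-band filter bank, per-band CSP (fitted on the
#' training split only), sliding-window features, and a sequence
#' classifier. Held-out accuracies on the stratified test split are stored
#' in the returned pipeline.
#'
#' @param trials a [TrialSet] containing all four classes.
#' @param trainingConfig a [TrainingConfig]; its seed also fixes the split.
#' @param thresholds a [Thresholds] carried into online decoding.
#' @param windowSpec a [FeatureWindowSpec].
#' @param referenceChannels the two mastoid reference channels.
#' @param trainPerClass training trials per class; the remainder is the
#'   held-out test split (default 50 of the 70 recorded).
#' @param classifierType `"bilstm"` (default) or `"logistic"`.
#' @return a fitted [DecoderPipeline].
#' @export
fitOfflineDecoder <- function(trials, trainingConfig = TrainingConfig(),
                              thresholds = Thresholds(),
                              windowSpec = FeatureWindowSpec(),
                              referenceChannels = c("TP9", "TP10"),
                              trainPerClass = 50L,
                              classifierType = c("bilstm", "logistic")) {
  classifierType <- match.arg(classifierType)
  stopIf(!is(trials, "TrialSet"), "trials must be a TrialSet")
  missing <- setdiff(MI_CLASSES, trialLabels(trials))
  stopIf(length(missing) > 0, "dataset is missing class(es): %s",
         paste(missing, collapse = ", "))
  first <- trials[[1]]
  fs <- samplingRate(first)
  montage <- channelNames(first)
  decodeChannels <- setdiff(montage, referenceChannels)
  bankSpec <- designFilterBank(fs)
  labels <- trialLabels(trials)
  flex <- fitOneDecoder(trials@trials, labels, c("flexion", "rest"),
                        bankSpec, windowSpec, referenceChannels,
                        trainingConfig, trainPerClass, classifierType,
                        decodeChannels)
  lr <- fitOneDecoder(trials@trials, labels, c("left", "right"),
                      bankSpec, windowSpec, referenceChannels,
                      trainingConfig, trainPerClass, classifierType,
                      decodeChannels)
  secondsOf <- function(lbl) {
    i <- which(labels == lbl)[1]
    ncol(epochData(trials[[i]])) / fs
  }
  new("DecoderPipeline",
    flexionCSP = flex$csp, lrCSP = lr$csp,
    flexionModel = flex$model, lrModel = lr$model,
    bankSpec = bankSpec, windowSpec = windowSpec, thresholds = thresholds,
    montage = montage, referenceChannels = referenceChannels,
    samplingRate = fs,
    epochLengths = c(flexion = secondsOf("flexion"),
                     leftright = secondsOf("left")),
    accuracies = c(flexion = flex$accuracy, leftright = lr$accuracy)
  )
}

#' @rdname DecoderPipeline-class
#' @param x a [DecoderPipeline].
#' @export
decoderAccuracies <- function(x) x@accuracies

setMethod("show", "DecoderPipeline", function(object) {
  cat("DecoderPipeline\n")
  cat(sprintf(
    " flexion-rest: %.2f s epochs, held-out accuracy %.3f\n",
    object@epochLengths[["flexion"]], object@accuracies[["flexion"]]
  ))
  cat(sprintf(
    " left-right:   %.2f s epochs, held-out accuracy %.3f\n",
    object@epochLengths[["leftright"]], object@accuracies[["leftright"]]
  ))
})

#' Create an online sample buffer
#'
#' @param channelNames channel order of the incoming stream.
#' @param samplingRate sampling rate in Hz.
#' @param capacitySeconds seconds of signal retained (must cover the
#'   longest decoding epoch; default 8 s).
#' @param updateInterval online update quantum in seconds (default 0.5).
#' @return an empty [OnlineBuffer].
#' @export
OnlineBuffer <- function(channelNames, samplingRate = 250,
                         capacitySeconds = 8, updateInterval = 0.5) {
  new("OnlineBuffer",
    data = matrix(0, length(channelNames), 0,
                  dimnames = list(channelNames, NULL)),
    channelNames = channelNames, samplingRate = samplingRate,
    capacity = as.integer(round(capacitySeconds * samplingRate)),
    updateInterval = updateInterval, clock = 0
  )
}

#' Append samples to an online buffer
#'
#' Appends a block of new samples (typically one 0.5 s update quantum) and
#' drops the oldest samples beyond the buffer capacity. Returns the
#' updated buffer; the input is unchanged.
#'
#' @param buffer an [OnlineBuffer].
#' @param samples channels x samples matrix in the buffer's channel order.
#' @return the updated [OnlineBuffer].
#' @export
pushSamples <- function(buffer, samples) {
  samples <- as.matrix(samples)
  stopIf(nrow(samples) != length(buffer@channelNames),
         "sample block must have %d channels", length(buffer@channelNames))
  data <- cbind(buffer@data, samples)
  if (ncol(data) > buffer@capacity) {
    data <- data[, (ncol(data) - buffer@capacity + 1L):ncol(data),
                 drop = FALSE]
  }
  new("OnlineBuffer",
    data = data, channelNames = buffer@channelNames,
    samplingRate = buffer@samplingRate, capacity = buffer@capacity,
    updateInterval = buffer@updateInterval,
    clock = buffer@clock + ncol(samples) / buffer@samplingRate
  )
}

setMethod("show", "OnlineBuffer", function(object) {
  cat(sprintf(
    "OnlineBuffer: %d/%d samples buffered, clock %.1f s\n",
    ncol(object@data), object@capacity, object@clock
  ))
})

#' One online decoding step
#'
#' Extracts the most recent epoch of the required length from the buffer
#' and classifies it. The artifact gate is applied to the re-referenced
#' epoch before any classification: supra-threshold epochs are returned as
#' `artifact-rejected` and never reach the classifier. An underfilled
#' buffer yields `no-decision`. The same feature path as offline training
#' is used, so identical epochs receive identical labels offline and
#' online.
#'
#' @param buffer an [OnlineBuffer] holding raw (unreferenced) samples.
#' @param pipeline a fitted [DecoderPipeline].
#' @param which which decoder to run: `"flexion"` or `"leftright"`.
#' @return a list with `decision` (a class label, `"artifact-rejected"`,
#'   or `"no-decision"`) and `probability` (named numeric or `NULL`).
#' @export
decodeStep <- function(buffer, pipeline, which = c("flexion", "leftright")) {
  which <- match.arg(which)
  needed <- as.integer(round(
    pipeline@epochLengths[[which]] * pipeline@samplingRate
  ))
  if (ncol(buffer@data) < needed) {
    return(list(decision = "no-decision", probability = NULL))
  }
  recent <- buffer@data[, (ncol(buffer@data) - needed + 1L):ncol(buffer@data),
                        drop = FALSE]
  epoch <- EEGEpoch(recent, buffer@channelNames, buffer@samplingRate)
  referenced <- rereference(epoch, pipeline@referenceChannels)
  if (rejectArtifact(referenced, pipeline@thresholds)) {
    return(list(decision = "artifact-rejected", probability = NULL))
  }
  feats <- epochToFeatures(epoch, pipeline, which)
  model <- if (which == "flexion") pipeline@flexionModel else pipeline@lrModel
  pred <- predict(model, feats)
  probs <- as.numeric(pred[1, model@classes])
  names(probs) <- model@classes
  list(decision = pred$label[1], probability = probs)
}
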
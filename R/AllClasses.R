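#' @import methods
NULL

MI_CLASSES <- c("rest", "flexion", "left", "right")

#' EEGEpoch: one multichannel EEG segment
#'
#' A fixed-duration multichannel EEG segment in microvolts, the atomic unit
#' of the decoding pipeline. Rows are channels (10-20 names), columns are
#' samples at a fixed sampling rate. An epoch may carry a task label (one of
#' `rest`, `flexion`, `left`, `right`) and onset/offset markers in samples.
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot channelNames character, ordered unique channel labels.
#' @slot samplingRate numeric scalar, Hz.
#' @slot label character, task label or `NA_character_` for unlabeled data.
#' @slot markers integer of length 2, onset/offset sample indices.
#' @aliases EEGEpoch
#' @exportClass EEGEpoch
setClass("EEGEpoch",
  representation(
    data = "matrix",
    channelNames = "character",
    samplingRate = "numeric",
    label = "character",
    markers = "integer"
  ),
  prototype(label = NA_character_, markers = integer(2))
)

setValidity("EEGEpoch", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) {
    msg <- c(msg, "data must be a numeric matrix")
  }
  if (any(!is.finite(object@data))) {
    msg <- c(msg, "data must be finite")
  }
  if (nrow(object@data) != length(object@channelNames)) {
    msg <- c(msg, "one channel name per data row required")
  }
  if (anyDuplicated(object@channelNames)) {
    msg <- c(msg, "channel names must be unique")
  }
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a positive scalar")
  }
  if (!is.na(object@label) && !object@label %in% MI_CLASSES) {
    msg <- c(msg, sprintf(
      "label must be one of %s", paste(MI_CLASSES, collapse = ", ")
    ))
  }
  if (length(msg)) msg else TRUE
})

#' TrialSet: a labeled collection of epochs
#'
#' Container for a labeled motor-imagery dataset: a list of [EEGEpoch]
#' objects plus parallel label and recording-session vectors. Two-hand
#' flexion (and rest) trials belong to sessions 1-2, left/right clenching
#' trials to sessions 3-4, mirroring the four-session offline recording
#' protocol.
#'
#' @slot trials list of [EEGEpoch].
#' @slot labels character vector parallel to `trials`.
#' @slot session integer vector parallel to `trials`.
#' @exportClass TrialSet
setClass("TrialSet",
  representation(
    trials = "list",
    labels = "character",
    session = "integer"
  )
)

setValidity("TrialSet", function(object) {
  n <- length(object@trials)
  if (length(object@labels) != n || length(object@session) != n) {
    return("trials, labels and session must have equal length")
  }
  if (n && !all(object@labels %in% MI_CLASSES)) {
    return("all labels must be valid motor-imagery classes")
  }
  if (n && !all(vapply(object@trials, is, logical(1), "EEGEpoch"))) {
    return("all trials must be EEGEpoch objects")
  }
  TRUE
})

#' SyntheticConfig: generator settings for surrogate EEG
#'
#' Parameters of the synthetic EEG generator. The generator produces
#' 1/f-shaped background noise plus narrow-band mu (8-12 Hz) and beta
#' (14-25 Hz) oscillations over sensorimotor channels; motor imagery scales
#' the oscillation amplitude at the contralateral channel by
#' `(1 - erdDepth)` (both channels for two-hand flexion). Defaults mirror
#' the recording protocol the decoder assumes: 8 dry electrodes at 250 Hz,
#' 70 trials per class, 6 s flexion and 2 s left/right epochs.
#'
#' @slot samplingRate numeric, Hz.
#' @slot montage character, ordered channel names (decoding channels plus
#'   the two mastoid references).
#' @slot referenceChannels character of length 2, mastoid references.
#' @slot trialCount integer, trials per class.
#' @slot durations named numeric, seconds per phase (`flexion`, `left`,
#'   `right`, `rest`, `break`, `instruction`).
#' @slot erdDepth numeric in \[0,1\], fractional amplitude reduction of the
#'   modulated oscillation during imagery.
#' @slot backgroundAmplitude numeric, RMS of 1/f background, microvolts.
#' @slot muAmplitude,betaAmplitude numeric, RMS of band oscillations at
#'   sensorimotor channels, microvolts.
#' @slot blinkAmplitude numeric, peak blink deflection at Fz, microvolts.
#' @slot artifactAmplitude numeric, peak amplitude of injected artifacts.
#' @slot rngSeed integer, seed fixing every generated sample.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    samplingRate = "numeric",
    montage = "character",
    referenceChannels = "character",
    trialCount = "integer",
    durations = "numeric",
    erdDepth = "numeric",
    backgroundAmplitude = "numeric",
    muAmplitude = "numeric",
    betaAmplitude = "numeric",
    blinkAmplitude = "numeric",
    artifactAmplitude = "numeric",
    rngSeed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@erdDepth < 0 || object@erdDepth > 1) {
    msg <- c(msg, "erdDepth must lie in [0, 1]")
  }
  if (any(object@durations <= 0)) {
    msg <- c(msg, "all durations must be positive")
  }
  # highest filter-bank edge is 44 Hz; Nyquist must clear it
  if (object@samplingRate <= 2 * 44) {
    msg <- c(msg, "samplingRate must exceed twice the 44 Hz filter edge")
  }
  if (!all(object@referenceChannels %in% object@montage)) {
    msg <- c(msg, "reference channels must be part of the montage")
  }
  if (object@trialCount < 0) {
    msg <- c(msg, "trialCount must be nonnegative")
  }
  need <- c("flexion", "left", "right", "rest", "break", "instruction")
  if (!all(need %in% names(object@durations))) {
    msg <- c(msg, paste("durations must name", paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Thresholds: amplitude gates for artifacts and blinks
#'
#' Amplitude thresholds of the online safety gates: an epoch whose absolute
#' value exceeds `artifactMax` anywhere is discarded unclassified; a blink
#' is flagged when the 4-40 Hz band-passed Fz trace exceeds `blinkMax`.
#' Both comparisons are strict (`>`).
#'
#' @slot artifactMax numeric, microvolts (default 200).
#' @slot blinkMax numeric, microvolts (default 100).
#' @slot blinkBand numeric of length 2, Hz (default 4-40).
#' @exportClass Thresholds
setClass("Thresholds",
  representation(
    artifactMax = "numeric",
    blinkMax = "numeric",
    blinkBand = "numeric"
  ),
  prototype(artifactMax = 200, blinkMax = 100, blinkBand = c(4, 40))
)

setValidity("Thresholds", function(object) {
  msg <- character()
  if (object@artifactMax <= 0 || object@blinkMax <= 0) {
    msg <- c(msg, "thresholds must be positive")
  }
  if (length(object@blinkBand) != 2L ||
      object@blinkBand[1] >= object@blinkBand[2]) {
    msg <- c(msg, "blinkBand must be an increasing (low, high) pair")
  }
  if (length(msg)) msg else TRUE
})

#' FilterBankSpec: the 20-band decomposition
#'
#' Band edges of the analysis filter bank: 19 overlapping 4 Hz-wide bands
#' starting at 4, 6, ..., 40 Hz, plus a final 4-40 Hz broadband filter, all
#' realised as causal Butterworth band-passes of the given order.
#'
#' @slot bands numeric matrix, nBands x 2 (low, high) in Hz, broadband last.
#' @slot order integer, Butterworth order (default 5).
#' @slot samplingRate numeric, Hz the filters are designed for.
#' @exportClass FilterBankSpec
setClass("FilterBankSpec",
  representation(
    bands = "matrix",
    order = "integer",
    samplingRate = "numeric"
  )
)

setValidity("FilterBankSpec", function(object) {
  msg <- character()
  if (ncol(object@bands) != 2L) {
    msg <- c(msg, "bands must be an nBands x 2 matrix")
  }
  if (any(object@bands[, 1] >= object@bands[, 2])) {
    msg <- c(msg, "each band must have low < high")
  }
  if (max(object@bands) >= object@samplingRate / 2) {
    msg <- c(msg, "band edges must lie below Nyquist")
  }
  if (object@order < 1L) msg <- c(msg, "order must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CSPBank: per-band pairs of spatial filters
#'
#' Fitted common-spatial-pattern decomposition: for every filter-bank band,
#' a channels x 2 spatial filter matrix (the two extreme generalized
#' eigenvectors) and the paired pattern (mixing) matrix, discriminating the
#' two classes in `classes`. Applying the bank compresses each band from
#' `nChannels` to 2 channels, i.e. 6 x 20 = 120 filter-bank channels down
#' to 40.
#'
#' @slot filters list of channels x 2 matrices, one per band.
#' @slot patterns list of channels x 2 matrices, one per band.
#' @slot eigenvalues list of length-2 numerics, variance-ratio eigenvalues
#'   of the retained filters.
#' @slot classes character of length 2, class pair the bank discriminates.
#' @slot channelNames character, input channel names.
#' @slot bankSpec the [FilterBankSpec] the bank was fitted under.
#' @exportClass CSPBank
setClass("CSPBank",
  representation(
    filters = "list",
    patterns = "list",
    eigenvalues = "list",
    classes = "character",
    channelNames = "character",
    bankSpec = "FilterBankSpec"
  )
)

setValidity("CSPBank", function(object) {
  msg <- character()
  nb <- nrow(object@bankSpec@bands)
  if (length(object@filters) != nb || length(object@patterns) != nb) {
    msg <- c(msg, "one filter/pattern pair per band required")
  }
  if (length(object@classes) != 2L) {
    msg <- c(msg, "a CSP bank discriminates exactly two classes")
  }
  ok <- vapply(object@filters, function(w) {
    is.matrix(w) && ncol(w) == 2L && nrow(w) == length(object@channelNames) &&
      all(is.finite(w))
  }, logical(1))
  if (!all(ok)) {
    msg <- c(msg, "each filter must be a finite channels x 2 matrix")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureWindowSpec: sliding-window geometry
#'
#' Geometry of the sliding feature window: `windowLength` samples advanced
#' by `hop` samples; only complete windows are evaluated, so a signal of
#' `S` samples yields `floor((S - windowLength)/hop) + 1` time steps.
#'
#' @slot windowLength integer, samples per window (default 200).
#' @slot hop integer, samples between window starts (default 15).
#' @exportClass FeatureWindowSpec
setClass("FeatureWindowSpec",
  representation(windowLength = "integer", hop = "integer"),
  prototype(windowLength = 200L, hop = 15L)
)

setValidity("FeatureWindowSpec", function(object) {
  if (object@hop <= 0L || object@windowLength <= object@hop) {
    return("require windowLength > hop > 0")
  }
  TRUE
})

#' TrainingConfig: sequence-classifier optimisation settings
#'
#' Hyperparameters of the recurrent classifier: Adam with an initial
#' learning rate of 5e-5 that decays by a factor of 0.8 every training
#' iteration (epoch), at most 50 iterations, L2 penalty 0.1, and dropout on
#' the readout during training only.
#'
#' @slot initialLearningRate numeric (default 5e-5).
#' @slot lrDecayFactor numeric (default 0.8).
#' @slot maxIterations integer (default 50).
#' @slot l2Penalty numeric (default 0.1).
#' @slot dropoutRate numeric in \[0,1) (default 0.5).
#' @slot hiddenUnits integer, LSTM width per direction (default 64).
#' @slot batchSize integer, minibatch size (default 16).
#' @slot rngSeed integer, seed for init, shuffling and dropout masks.
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(
    initialLearningRate = "numeric",
    lrDecayFactor = "numeric",
    maxIterations = "integer",
    l2Penalty = "numeric",
    dropoutRate = "numeric",
    hiddenUnits = "integer",
    batchSize = "integer",
    rngSeed = "integer"
  )
)

setValidity("TrainingConfig", function(object) {
  msg <- character()
  pos <- c(
    object@initialLearningRate, object@lrDecayFactor,
    as.numeric(object@maxIterations), object@l2Penalty,
    as.numeric(object@hiddenUnits), as.numeric(object@batchSize)
  )
  if (any(pos <= 0)) msg <- c(msg, "all settings must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1) {
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' SequenceClassifier: fitted sequence model over feature sequences
#'
#' A fitted two-class sequence classifier. `type = "bilstm"` is a
#' bidirectional LSTM over the feature sequence with a fully connected
#' softmax readout of the two final hidden states (dropout active during
#' training only); `type = "logistic"` is the deterministic linear baseline,
#' a ridge-regularised logistic regression on time-averaged features,
#' exposed behind the same contract.
#'
#' @slot type character, `"bilstm"` or `"logistic"`.
#' @slot weights list of parameter matrices (or the fitted glmnet object).
#' @slot classes character of length 2; first class is the positive logit.
#' @slot featureDim integer, expected feature dimension.
#' @slot normalization list with per-dimension `mean` and `sd` applied
#'   before the network.
#' @slot config the [TrainingConfig] used.
#' @slot trainingLog data.frame with one row per iteration: learning rate
#'   and loss.
#' @exportClass SequenceClassifier
setClass("SequenceClassifier",
  representation(
    type = "character",
    weights = "list",
    classes = "character",
    featureDim = "integer",
    normalization = "list",
    config = "TrainingConfig",
    trainingLog = "data.frame"
  )
)

setValidity("SequenceClassifier", function(object) {
  msg <- character()
  if (!object@type %in% c("bilstm", "logistic")) {
    msg <- c(msg, "type must be 'bilstm' or 'logistic'")
  }
  if (length(object@classes) != 2L) {
    msg <- c(msg, "exactly two classes required")
  }
  if (length(msg)) msg else TRUE
})

#' DecoderPipeline: the full offline-fitted decoder pair
#'
#' End-to-end decoder state: a two-hand flexion-vs-rest decoder (6 s
#' epochs) and a left-vs-right clenching decoder (2 s epochs), each a
#' fitted [CSPBank] plus [SequenceClassifier], sharing one montage, filter
#' bank, feature-window geometry and amplitude thresholds.
#'
#' @slot flexionCSP,lrCSP fitted [CSPBank] objects.
#' @slot flexionModel,lrModel fitted [SequenceClassifier] objects.
#' @slot bankSpec shared [FilterBankSpec].
#' @slot windowSpec shared [FeatureWindowSpec].
#' @slot thresholds shared [Thresholds].
#' @slot montage character, raw channel order expected at the input.
#' @slot referenceChannels character of length 2, mastoid references.
#' @slot samplingRate numeric, Hz.
#' @slot epochLengths named numeric, seconds (`flexion`, `leftright`).
#' @slot accuracies named numeric, held-out accuracies recorded at fit time.
#' @exportClass DecoderPipeline
setClass("DecoderPipeline",
  representation(
    flexionCSP = "CSPBank",
    lrCSP = "CSPBank",
    flexionModel = "SequenceClassifier",
    lrModel = "SequenceClassifier",
    bankSpec = "FilterBankSpec",
    windowSpec = "FeatureWindowSpec",
    thresholds = "Thresholds",
    montage = "character",
    referenceChannels = "character",
    samplingRate = "numeric",
    epochLengths = "numeric",
    accuracies = "numeric"
  )
)

setValidity("DecoderPipeline", function(object) {
  msg <- character()
  if (!all(c("flexion", "leftright") %in% names(object@epochLengths))) {
    msg <- c(msg, "epochLengths must name flexion and leftright")
  }
  if (any(object@epochLengths <= 0)) {
    msg <- c(msg, "epoch lengths must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' OnlineBuffer: rolling sample store for online decoding
#'
#' Rolling buffer of the most recent raw samples, appended in 0.5 s update
#' quanta during online operation. The newest `capacity` samples are kept;
#' the decoder extracts the most recent epoch of the required length.
#'
#' @slot data numeric matrix, channels x samples currently buffered.
#' @slot channelNames character, channel order.
#' @slot samplingRate numeric, Hz.
#' @slot capacity integer, maximum samples retained.
#' @slot updateInterval numeric, seconds between online updates (0.5).
#' @slot clock numeric, seconds of signal consumed so far.
#' @exportClass OnlineBuffer
setClass("OnlineBuffer",
  representation(
    data = "matrix",
    channelNames = "character",
    samplingRate = "numeric",
    capacity = "integer",
    updateInterval = "numeric",
    clock = "numeric"
  )
)

setValidity("OnlineBuffer", function(object) {
  msg <- character()
  if (object@capacity < 1L) msg <- c(msg, "capacity must be positive")
  if (object@updateInterval <= 0) {
    msg <- c(msg, "updateInterval must be positive")
  }
  if (ncol(object@data) > object@capacity) {
    msg <- c(msg, "buffer holds more samples than its capacity")
  }
  if (length(msg)) msg else TRUE
})

#' StreetGraph: simulated street network with an agent pose
#'
#' A simulated street network standing in for an online map service: nodes
#' with 2-D positions and junction flags, directed edges, and the agent's
#' pose (current node plus the neighbouring node it faces). Rotation
#' commands move the heading to the next available edge direction
#' counter-clockwise (left) or clockwise (right); walking advances one edge
#' per second.
#'
#' @slot nodes data.frame with columns `id`, `x`, `y`, `junction`.
#' @slot edges data.frame with columns `from`, `to`.
#' @slot agentNode integer, current node id.
#' @slot agentHeading integer, neighbouring node id the agent faces.
#' @exportClass StreetGraph
setClass("StreetGraph",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    agentNode = "integer",
    agentHeading = "integer"
  )
)

setValidity("StreetGraph", function(object) {
  msg <- character()
  need <- c("id", "x", "y", "junction")
  if (!all(need %in% names(object@nodes))) {
    msg <- c(msg, "nodes must have columns id, x, y, junction")
  }
  if (!all(c("from", "to") %in% names(object@edges))) {
    msg <- c(msg, "edges must have columns from, to")
  }
  ids <- object@nodes$id
  if (anyDuplicated(ids)) msg <- c(msg, "node ids must be unique")
  if (nrow(object@edges) &&
      !all(c(object@edges$from, object@edges$to) %in% ids)) {
    msg <- c(msg, "edges reference unknown nodes (dangling edge)")
  }
  if (!object@agentNode %in% ids) {
    msg <- c(msg, "agent must stand on a graph node")
  }
  if (!is.na(object@agentHeading)) {
    nbr <- object@edges$to[object@edges$from == object@agentNode]
    if (!object@agentHeading %in% nbr) {
      msg <- c(msg, "agent heading must point at an outgoing neighbour")
    }
  }
  if (length(msg)) msg else TRUE
})

NAV_STATES <- c("idle", "switch", "walk", "rotation", "correction")
NAV_STRATEGIES <- c("NE", "DC", "EC")

#' NavState: the navigation automaton's state
#'
#' State of the shared-control navigation automaton: the discrete control
#' state, the control level (`low` stops walking on a blink, `middle` stops
#' automatically in front of junctions), the active rotation error-control
#' strategy, a pending direction held mid-strategy, and the simulated clock.
#' The `correction` state is reachable only under the error-correction (EC)
#' strategy.
#'
#' @slot state character, one of idle, switch, walk, rotation, correction.
#' @slot mode character, `low` or `middle`.
#' @slot strategy character, `NE`, `DC` or `EC`.
#' @slot pendingDirection character, `left`/`right` or `NA` outside a
#'   strategy sequence.
#' @slot clock numeric, seconds.
#' @slot stateEntered numeric, clock value when the current state was
#'   entered (drives the 2 s switch dwell and EC correction window).
#' @exportClass NavState
setClass("NavState",
  representation(
    state = "character",
    mode = "character",
    strategy = "character",
    pendingDirection = "character",
    clock = "numeric",
    stateEntered = "numeric"
  ),
  prototype(
    state = "idle", mode = "low", strategy = "NE",
    pendingDirection = NA_character_, clock = 0, stateEntered = 0
  )
)

setValidity("NavState", function(object) {
  msg <- character()
  if (!object@state %in% NAV_STATES) msg <- c(msg, "unknown state")
  if (!object@mode %in% c("low", "middle")) msg <- c(msg, "unknown mode")
  if (!object@strategy %in% NAV_STRATEGIES) msg <- c(msg, "unknown strategy")
  if (object@state == "correction" && object@strategy != "EC") {
    msg <- c(msg, "correction state is reachable only under EC")
  }
  if (!is.na(object@pendingDirection) &&
      !object@pendingDirection %in% c("left", "right")) {
    msg <- c(msg, "pendingDirection must be left or right")
  }
  if (!is.na(object@pendingDirection) &&
      !object@state %in% c("rotation", "correction")) {
    msg <- c(msg, "pendingDirection may only be held mid-strategy")
  }
  if (length(msg)) msg else TRUE
})

#' UserModel: simulated BCI user
#'
#' The simulated user closing the loop. In `abstract` mode the decoder is
#' summarised by a per-trial classification accuracy `p` and a blink
#' detection reliability `q`; in `full` mode every imagination generates a
#' synthetic EEG epoch that is pushed through a fitted [DecoderPipeline].
#' After an unwanted rotation the user issues corrective intents until the
#' heading matches the route.
#'
#' @slot route character vector of intended actions, each `forward`,
#'   `left` or `right`.
#' @slot p numeric in \[0,1\], per-trial classification accuracy.
#' @slot q numeric in \[0,1\], blink detection reliability.
#' @slot mode character, `abstract` or `full`.
#' @slot pipeline a fitted [DecoderPipeline] (full mode only; empty list
#'   slot otherwise).
#' @slot config a [SyntheticConfig] driving epoch generation in full mode.
#' @exportClass UserModel
setClass("UserModel",
  representation(
    route = "character",
    p = "numeric",
    q = "numeric",
    mode = "character",
    pipeline = "list",
    config = "list"
  ),
  prototype(p = 1, q = 1, mode = "abstract", pipeline = list(), config = list())
)

setValidity("UserModel", function(object) {
  msg <- character()
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0,1]")
  if (object@q < 0 || object@q > 1) msg <- c(msg, "q must lie in [0,1]")
  if (!object@mode %in% c("abstract", "full")) {
    msg <- c(msg, "mode must be 'abstract' or 'full'")
  }
  if (length(object@route) &&
      !all(object@route %in% c("forward", "left", "right"))) {
    msg <- c(msg, "route actions must be forward, left or right")
  }
  if (object@mode == "full" &&
      (!length(object@pipeline) || !is(object@pipeline[[1]], "DecoderPipeline"))) {
    msg <- c(msg, "full mode requires a fitted DecoderPipeline")
  }
  if (length(msg)) msg else TRUE
})

#' RotationMetrics: per-rotation error accounting
#'
#' The three rotation metrics, each normalised per executed intended
#' rotation: `noError` counts misclassified imagination trials,
#' `noNavigationError` counts executed unwanted rotations, and
#' `noImagination` counts imagination attempts until the intended rotation
#' was executed. Under the no-error-control strategy every misclassification
#' becomes a wrong rotation, so the first two coincide.
#'
#' @slot noError numeric, misclassified imaginations per intended rotation.
#' @slot noNavigationError numeric, wrong rotations per intended rotation.
#' @slot noImagination numeric, imaginations per intended rotation.
#' @slot nRotations integer, intended rotations the averages are over.
#' @slot counts named numeric, raw totals behind the averages.
#' @exportClass RotationMetrics
setClass("RotationMetrics",
  representation(
    noError = "numeric",
    noNavigationError = "numeric",
    noImagination = "numeric",
    nRotations = "integer",
    counts = "numeric"
  )
)

setValidity("RotationMetrics", function(object) {
  vals <- c(object@noError, object@noNavigationError, object@noImagination)
  if (any(vals < 0)) return("rotation metrics must be nonnegative")
  TRUE
})

#' SimResult: one closed-loop simulation run
#'
#' Complete record of one closed-loop navigation run: the event log, the
#' visited node sequence, the rotation metrics, command issue times, the
#' completion flag, and total simulated time.
#'
#' @slot events data.frame with columns `time`, `kind`, `detail`.
#' @slot trajectory integer vector of visited node ids.
#' @slot metrics a [RotationMetrics].
#' @slot completed logical, whether the route was completed.
#' @slot totalTime numeric, simulated seconds for the whole run.
#' @slot commandTimes named list: `walk` - seconds of decoding epochs per
#'   issued walk command; `rotation` - seconds per executed intended
#'   rotation.
#' @exportClass SimResult
setClass("SimResult",
  representation(
    events = "data.frame",
    trajectory = "integer",
    metrics = "RotationMetrics",
    completed = "logical",
    totalTime = "numeric",
    commandTimes = "list"
  )
)
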
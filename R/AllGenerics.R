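#' @rdname EEGEpoch-class
#' @param object,x an object.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname EEGEpoch-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EEGEpoch-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGEpoch-class
#' @export
setGeneric("epochLabel", function(x) standardGeneric("epochLabel"))

#' @rdname TrialSet-class
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname TrialSet-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Re-reference an epoch to the mean of two reference channels
#'
#' Subtracts the average of the two mastoid reference channels (TP9, TP10 by
#' default) from every other channel and drops the references from the
#' output.
#'
#' @param epoch an [EEGEpoch].
#' @param referenceChannels character of length 2 naming the references.
#' @return an [EEGEpoch] without the reference channels.
#' @export
setGeneric("rereference", function(epoch, referenceChannels = c("TP9", "TP10"))
  standardGeneric("rereference"))

#' Causal Butterworth band-pass filtering
#'
#' Applies a causal (forward-only) Butterworth band-pass of the given order
#' to every channel. The same causal convention is used offline and online,
#' so both paths see identical filter output.
#'
#' @param epoch an [EEGEpoch].
#' @param low,high band edges in Hz, `0 < low < high < samplingRate/2`.
#' @param order filter order (default 5).
#' @return the filtered [EEGEpoch].
#' @export
setGeneric("bandpass", function(epoch, low, high, order = 5L)
  standardGeneric("bandpass"))

#' Amplitude-threshold artifact verdict
#'
#' An epoch is rejected when its absolute amplitude exceeds
#' `artifactMax` (strictly) on any channel. The first 0.2 s are excluded
#' when the epoch has been filtered, to avoid start-up ringing; raw epochs
#' are checked in full.
#'
#' @param epoch an [EEGEpoch].
#' @param thresholds a [Thresholds].
#' @return `TRUE` if the epoch must be rejected.
#' @export
setGeneric("rejectArtifact", function(epoch, thresholds = Thresholds())
  standardGeneric("rejectArtifact"))

#' Threshold blink detector on Fz
#'
#' Band-passes the Fz channel to 4-40 Hz (causal Butterworth) and flags a
#' blink when the absolute filtered amplitude strictly exceeds `blinkMax`.
#' The first 0.2 s of the filtered trace are excluded from the maximum to
#' avoid filter start-up transients.
#'
#' @inheritParams rejectArtifact
#' @return `TRUE` if a blink is detected.
#' @export
setGeneric("detectBlink", function(epoch, thresholds = Thresholds())
  standardGeneric("detectBlink"))

#' Apply the analysis filter bank
#'
#' Band-passes every channel of a 6-channel epoch through each band of the
#' filter bank and stacks the results, yielding 6 x 20 = 120 channels with
#' the sample count preserved. Output channels are grouped by band.
#'
#' @param epoch an [EEGEpoch] with exactly 6 channels.
#' @param spec a [FilterBankSpec].
#' @return an [EEGEpoch] with `nChannels * nBands` channels named
#'   `<channel>@<low>-<high>`.
#' @export
setGeneric("applyFilterBank", function(epoch, spec)
  standardGeneric("applyFilterBank"))

#' Project a multiband signal through a fitted CSP bank
#'
#' Per band, projects the 6 band channels onto the band's two spatial
#' filters, producing 2 x 20 = 40 output channels with the sample count
#' preserved.
#'
#' @param multiband an [EEGEpoch] as returned by [applyFilterBank()].
#' @param bank a fitted [CSPBank].
#' @return an [EEGEpoch] with `2 * nBands` channels.
#' @export
setGeneric("applyCSPBank", function(multiband, bank)
  standardGeneric("applyCSPBank"))

#' Sliding-window statistical features
#'
#' Slides a window of `windowLength` samples with step `hop` over every
#' channel and evaluates the five statistics of [windowFeatures()] in each
#' window, producing a time-step x (5 x nChannels) feature matrix. Only
#' complete windows are evaluated.
#'
#' @param x an [EEGEpoch] (typically the 40-channel CSP output) or a
#'   channels x samples matrix.
#' @param spec a [FeatureWindowSpec].
#' @return numeric matrix, time steps x (5 * nChannels); columns are
#'   ordered (p, v, ZCR, SA, p2p) per channel, channels in input order.
#' @export
setGeneric("slidingFeatures", function(x, spec = FeatureWindowSpec())
  standardGeneric("slidingFeatures"))

#' @rdname CSPBank-class
#' @param x a [CSPBank].
#' @export
setGeneric("cspFilters", function(x) standardGeneric("cspFilters"))

#' @rdname CSPBank-class
#' @export
setGeneric("cspPatterns", function(x) standardGeneric("cspPatterns"))

#' @rdname FilterBankSpec-class
#' @param x a [FilterBankSpec] or [CSPBank].
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname FilterBankSpec-class
#' @export
setGeneric("bandEdges", function(x) standardGeneric("bandEdges"))
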
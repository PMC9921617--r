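#' Construct an EEG epoch
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channelNames character vector of 10-20 channel labels, one per
#'   row of `data`.
#' @param samplingRate sampling rate in Hz.
#' @param label optional task label (`rest`, `flexion`, `left`, `right`).
#' @param markers optional length-2 integer, onset/offset sample indices.
#' @return an [EEGEpoch].
#' @examples
#' e <- EEGEpoch(matrix(rnorm(500), 2), c("C3", "C4"), 250)
#' samplingRate(e)
#' @export
EEGEpoch <- function(data, channelNames = rownames(data), samplingRate = 250,
                     label = NA_character_, markers = c(1L, ncol(data))) {
  data <- as.matrix(data)
  rownames(data) <- channelNames
  new("EEGEpoch",
    data = data, channelNames = as.character(channelNames),
    samplingRate = samplingRate, label = as.character(label),
    markers = as.integer(markers)
  )
}

#' @rdname EEGEpoch-class
#' @export
setMethod("epochData", "EEGEpoch", function(x) x@data)

#' @rdname EEGEpoch-class
#' @export
setMethod("channelNames", "EEGEpoch", function(x) x@channelNames)

#' @rdname EEGEpoch-class
#' @export
setMethod("samplingRate", "EEGEpoch", function(x) x@samplingRate)

#' @rdname EEGEpoch-class
#' @export
setMethod("epochLabel", "EEGEpoch", function(x) x@label)

setMethod("show", "EEGEpoch", function(object) {
  cat(sprintf(
    "EEGEpoch: %d channel(s) x %d samples @ %g Hz (%.2f s)%s\n",
    nrow(object@data), ncol(object@data), object@samplingRate,
    ncol(object@data) / object@samplingRate,
    if (is.na(object@label)) "" else sprintf(", label '%s'", object@label)
  ))
  cat(" channels:", paste(object@channelNames, collapse = ", "), "\n")
})

#' Construct amplitude thresholds
#'
#' @param artifactMax artifact rejection threshold in microvolts; epochs
#'   whose absolute amplitude strictly exceeds it are not classified.
#' @param blinkMax blink threshold on band-passed Fz, microvolts.
#' @param blinkBand blink detection band in Hz.
#' @return a [Thresholds].
#' @export
Thresholds <- function(artifactMax = 200, blinkMax = 100, blinkBand = c(4, 40)) {
  new("Thresholds",
    artifactMax = artifactMax, blinkMax = blinkMax,
    blinkBand = as.numeric(blinkBand)
  )
}

setMethod("show", "Thresholds", function(object) {
  cat(sprintf(
    "Thresholds: artifact > %g uV, blink > %g uV on Fz (%g-%g Hz)\n",
    object@artifactMax, object@blinkMax,
    object@blinkBand[1], object@blinkBand[2]
  ))
})

# samples to drop from threshold checks after causal filtering
filterSettleSamples <- function(samplingRate, settle = 0.2) {
  as.integer(round(settle * samplingRate))
}

#' @rdname rereference
#' @export
setMethod("rereference", "EEGEpoch", function(epoch, referenceChannels) {
  stopIf(length(referenceChannels) != 2L,
         "exactly two reference channels required")
  missing <- setdiff(referenceChannels, epoch@channelNames)
  stopIf(length(missing) > 0,
         "reference channel(s) not in epoch: %s",
         paste(missing, collapse = ", "))
  refMean <- colMeans(epoch@data[referenceChannels, , drop = FALSE])
  keep <- setdiff(epoch@channelNames, referenceChannels)
  out <- sweep(epoch@data[keep, , drop = FALSE], 2, refMean, "-")
  EEGEpoch(out, keep, epoch@samplingRate, epoch@label, epoch@markers)
})

# design a causal Butterworth band-pass for the given epoch rate
butterBand <- function(low, high, samplingRate, order = 5L) {
  nyq <- samplingRate / 2
  stopIf(!(low > 0 && low < high && high < nyq),
         "invalid band (%g, %g) Hz at %g Hz sampling", low, high, samplingRate)
  signal::butter(order, c(low, high) / nyq, type = "pass")
}

applyCausalFilter <- function(data, filt) {
  out <- t(apply(data, 1, function(ch) as.numeric(signal::filter(filt, ch))))
  # apply() drops dims for single-channel input
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

#' @rdname bandpass
#' @export
setMethod("bandpass", "EEGEpoch", function(epoch, low, high, order = 5L) {
  filt <- butterBand(low, high, epoch@samplingRate, order)
  out <- applyCausalFilter(epoch@data, filt)
  EEGEpoch(out, epoch@channelNames, epoch@samplingRate, epoch@label,
           epoch@markers)
})

#' @rdname rejectArtifact
#' @export
setMethod("rejectArtifact", "EEGEpoch", function(epoch, thresholds) {
  stopIf(ncol(epoch@data) == 0L, "empty epoch")
  max(abs(epoch@data)) > thresholds@artifactMax
})

#' @rdname detectBlink
#' @export
setMethod("detectBlink", "EEGEpoch", function(epoch, thresholds) {
  stopIf(!"Fz" %in% epoch@channelNames, "blink detection requires channel Fz")
  fz <- epoch@data["Fz", ]
  filt <- butterBand(thresholds@blinkBand[1], thresholds@blinkBand[2],
                     epoch@samplingRate)
  y <- as.numeric(signal::filter(filt, fz))
  settle <- filterSettleSamples(epoch@samplingRate)
  if (length(y) > settle) y <- y[-seq_len(settle)]
  max(abs(y)) > thresholds@blinkMax
})
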
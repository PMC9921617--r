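#' Design the 20-band analysis filter bank
#'
#' Builds the band list of the FBCSP front end: starting at 4 Hz, each band
#' is 4 Hz wide and overlaps the previous one by 2 Hz, up to the band
#' starting at 40 Hz (i.e. 4-8, 6-10, ..., 40-44), followed by one 4-40 Hz
#' broadband filter — 20 bands in total, realised as 5th-order causal
#' Butterworth band-passes.
#'
#' @param samplingRate sampling rate in Hz; must exceed 88 Hz so the 44 Hz
#'   upper edge stays below Nyquist.
#' @param order Butterworth order.
#' @return a [FilterBankSpec] with 20 bands, broadband last.
#' @examples
#' spec <- designFilterBank(250)
#' nBands(spec)
#' bandEdges(spec)[1, ]
#' @export
designFilterBank <- function(samplingRate, order = 5L) {
  stopIf(samplingRate <= 88,
         "sampling rate %g Hz too low for the 44 Hz band edge", samplingRate)
  starts <- seq(4, 40, by = 2)
  bands <- cbind(low = c(starts, 4), high = c(starts + 4, 40))
  new("FilterBankSpec",
    bands = bands, order = as.integer(order), samplingRate = samplingRate
  )
}

#' @rdname FilterBankSpec-class
#' @export
setMethod("nBands", "FilterBankSpec", function(x) nrow(x@bands))

#' @rdname FilterBankSpec-class
#' @export
setMethod("bandEdges", "FilterBankSpec", function(x) x@bands)

#' @rdname FilterBankSpec-class
#' @export
setMethod("nBands", "CSPBank", function(x) nrow(x@bankSpec@bands))

setMethod("show", "FilterBankSpec", function(object) {
  cat(sprintf(
    "FilterBankSpec: %d bands, order-%d Butterworth @ %g Hz\n",
    nrow(object@bands), object@order, object@samplingRate
  ))
  cat(sprintf(
    " %g-%g, %g-%g, ..., %g-%g Hz + broadband %g-%g Hz\n",
    object@bands[1, 1], object@bands[1, 2],
    object@bands[2, 1], object@bands[2, 2],
    object@bands[nrow(object@bands) - 1, 1],
    object@bands[nrow(object@bands) - 1, 2],
    object@bands[nrow(object@bands), 1], object@bands[nrow(object@bands), 2]
  ))
})

# channel names of the stacked multiband signal, grouped by band
multibandNames <- function(channels, bands) {
  unlist(lapply(seq_len(nrow(bands)), function(b) {
    sprintf("%s@%g-%g", channels, bands[b, 1], bands[b, 2])
  }))
}

#' @rdname applyFilterBank
#' @export
setMethod("applyFilterBank", signature("EEGEpoch", "FilterBankSpec"),
  function(epoch, spec) {
    stopIf(nrow(epoch@data) != 6L,
           "filter bank expects a 6-channel epoch, got %d", nrow(epoch@data))
    stopIf(!isTRUE(all.equal(epoch@samplingRate, spec@samplingRate)),
           "epoch rate %g Hz does not match filter design rate %g Hz",
           epoch@samplingRate, spec@samplingRate)
    nb <- nrow(spec@bands)
    out <- matrix(0, 6L * nb, ncol(epoch@data))
    for (b in seq_len(nb)) {
      filt <- butterBand(spec@bands[b, 1], spec@bands[b, 2],
                         spec@samplingRate, spec@order)
      out[(b - 1L) * 6L + 1:6, ] <- applyCausalFilter(epoch@data, filt)
    }
    EEGEpoch(out, multibandNames(epoch@channelNames, spec@bands),
             epoch@samplingRate, epoch@label, epoch@markers)
  }
)
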
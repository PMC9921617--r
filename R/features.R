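#' Sliding feature-window geometry
#'
#' @param windowLength window length in samples (default 200).
#' @param hop hop size in samples (default 15).
#' @return a [FeatureWindowSpec].
#' @export
FeatureWindowSpec <- function(windowLength = 200L, hop = 15L) {
  new("FeatureWindowSpec",
    windowLength = as.integer(windowLength), hop = as.integer(hop)
  )
}

setMethod("show", "FeatureWindowSpec", function(object) {
  cat(sprintf(
    "FeatureWindowSpec: window %d samples, hop %d samples\n",
    object@windowLength, object@hop
  ))
})

featureNames <- c("p", "v", "ZCR", "SA", "p2p")

#' Five statistical features of one window
#'
#' Evaluates the five window statistics on one channel window `x` of
#' length `WL`:
#' \describe{
#'   \item{p}{logarithmic sum of power, `log(mean(x^2) + 1)`}
#'   \item{v}{logarithmic variance, `log(mean((x - mean(x))^2) + 1)`}
#'   \item{ZCR}{zero crossing rate,
#'     `sum(abs(sgn(x[n]) - sgn(x[n-1]))) / (2 * WL)` with `sgn(x) = 1`
#'     for `x >= 0` and `-1` otherwise}
#'   \item{SA}{sum of absolute values}
#'   \item{p2p}{peak-to-peak value, `max(x) - min(x)`}
#' }
#'
#' @param window numeric vector, samples of one channel.
#' @return named numeric of length 5: `p`, `v`, `ZCR`, `SA`, `p2p`.
#' @examples
#' windowFeatures(rep(1, 10)) # p = log 2, v = 0, ZCR = 0, SA = 10, p2p = 0
#' @export
windowFeatures <- function(window) {
  stopIf(length(window) == 0L, "empty window")
  sgn <- ifelse(window >= 0, 1, -1)
  c(
    p = log(mean(window^2) + 1),
    v = log(mean((window - mean(window))^2) + 1),
    ZCR = sum(abs(diff(sgn))) / (2 * length(window)),
    SA = sum(abs(window)),
    p2p = max(window) - min(window)
  )
}

# vectorised window statistics for one channel: returns 5 x nWindows
channelWindowFeatures <- function(x, idx) {
  w <- matrix(x[idx], nrow = nrow(idx))
  wl <- nrow(w)
  centered <- sweep(w, 2, colMeans(w))
  sgn <- matrix(ifelse(w >= 0, 1, -1), nrow = wl)
  rbind(
    p = log(colMeans(w^2) + 1),
    v = log(colMeans(centered^2) + 1),
    ZCR = colSums(abs(sgn[-1, , drop = FALSE] -
                        sgn[-wl, , drop = FALSE])) / (2 * wl),
    SA = colSums(abs(w)),
    p2p = apply(w, 2, max) - apply(w, 2, min)
  )
}

#' @rdname slidingFeatures
#' @export
setMethod("slidingFeatures", "matrix", function(x, spec) {
  wl <- spec@windowLength
  hop <- spec@hop
  n <- ncol(x)
  stopIf(n < wl,
         "signal of %d samples is shorter than one %d-sample window", n, wl)
  starts <- seq.int(1L, n - wl + 1L, by = hop)
  idx <- outer(0:(wl - 1L), starts, `+`)
  feats <- lapply(seq_len(nrow(x)), function(ch) {
    channelWindowFeatures(x[ch, ], idx)
  })
  out <- t(do.call(rbind, feats)) # time steps x (5 * channels)
  chn <- rownames(x)
  if (is.null(chn)) chn <- sprintf("ch%d", seq_len(nrow(x)))
  colnames(out) <- as.vector(vapply(
    chn, function(ch) paste(featureNames, ch, sep = "."),
    character(5)
  ))
  out
})

#' @rdname slidingFeatures
#' @export
setMethod("slidingFeatures", "EEGEpoch", function(x, spec) {
  slidingFeatures(x@data, spec)
})

#' Number of feature time steps for a given epoch length
#'
#' `floor((samples - windowLength)/hop) + 1` complete windows; incomplete
#' trailing windows are dropped.
#'
#' @param samples epoch length in samples.
#' @param spec a [FeatureWindowSpec].
#' @return integer number of time steps.
#' @export
nTimeSteps <- function(samples, spec = FeatureWindowSpec()) {
  stopIf(samples < spec@windowLength, "signal shorter than one window")
  as.integer((samples - spec@windowLength) %/% spec@hop + 1L)
}
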
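# per-trial covariance, trace-normalised so that amplitude scale cancels
tracedCov <- function(x) {
  c <- tcrossprod(x)
  c / sum(diag(c))
}

# average trace-normalised covariance over a list of channels x samples
# matrices, with diagonal shrinkage to guard against rank deficiency
classCovariance <- function(trials, shrink = 1e-6) {
  cc <- Reduce(`+`, lapply(trials, tracedCov)) / length(trials)
  cc + shrink * sum(diag(cc)) * diag(nrow(cc))
}

#' Fit a two-class common spatial pattern filter pair
#'
#' Solves the two-class CSP problem on averaged, trace-normalised trial
#' covariances: generalized eigenvectors of the class-1 covariance against
#' the composite covariance. The two extreme-eigenvalue filters are
#' retained — the first maximises the class-1 to class-2 variance ratio,
#' the second maximises the reverse — together with the corresponding
#' pattern (mixing) columns used for topographic interpretation.
#'
#' @param trialsA,trialsB lists of channels x samples matrices (or
#'   [EEGEpoch] objects), one per trial, for the two classes.
#' @param shrink diagonal shrinkage factor applied as
#'   `shrink * trace(C) * I` to each class covariance.
#' @return a list with elements `filters` (channels x 2), `patterns`
#'   (channels x 2) and `eigenvalues` (length 2; the share of composite
#'   variance captured from class 1 by each filter).
#' @examples
#' a <- replicate(20, matrix(rnorm(3 * 100), 3), simplify = FALSE)
#' b <- replicate(20, matrix(rnorm(3 * 100), 3), simplify = FALSE)
#' fit <- fitCSP(a, b)
#' dim(fit$filters)
#' @export
fitCSP <- function(trialsA, trialsB, shrink = 1e-6) {
  asMat <- function(t) if (is(t, "EEGEpoch")) t@data else as.matrix(t)
  trialsA <- lapply(trialsA, asMat)
  trialsB <- lapply(trialsB, asMat)
  stopIf(length(trialsA) < 2L || length(trialsB) < 2L,
         "at least two trials per class required")
  ca <- classCovariance(trialsA, shrink)
  cb <- classCovariance(trialsB, shrink)
  cc <- ca + cb
  ec <- eigen(cc, symmetric = TRUE)
  stopIf(min(ec$values) <= .Machine$double.eps * max(ec$values) * 1e3,
         "composite covariance is singular even after regularization")
  # whiten the composite, then diagonalise the class-1 covariance
  whitener <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  s <- whitener %*% ca %*% t(whitener)
  es <- eigen((s + t(s)) / 2, symmetric = TRUE)
  wFull <- t(whitener) %*% es$vectors   # columns: w' cc w = 1, w' ca w = eig
  patternsFull <- cc %*% wFull          # inverse-transpose of the filters
  pick <- c(1L, ncol(wFull))
  list(
    filters = wFull[, pick, drop = FALSE],
    patterns = patternsFull[, pick, drop = FALSE],
    eigenvalues = es$values[pick]
  )
}

#' Fit a CSP bank over all filter-bank bands
#'
#' Fits one [fitCSP()] filter pair per band, independently, from multiband
#' trials (the stacked output of [applyFilterBank()]). Bands are fit on
#' trace-normalised covariances, so the bank is invariant to per-trial
#' global amplitude scaling.
#'
#' @param multibandTrials list of [EEGEpoch] objects with
#'   `nChannels * nBands` channels, as returned by [applyFilterBank()].
#' @param labels character vector of class labels parallel to the trials.
#' @param bankSpec the [FilterBankSpec] the trials were filtered with.
#' @param classes character of length 2 selecting the class pair; trials
#'   with other labels are ignored.
#' @param channelNames names of the underlying (pre-filter-bank) channels.
#' @return a fitted [CSPBank].
#' @export
fitCSPBank <- function(multibandTrials, labels, bankSpec,
                       classes, channelNames = c("Fz", "C3", "Cz", "C4",
                                                 "P3", "P4")) {
  stopIf(length(classes) != 2L, "exactly two classes required")
  stopIf(!all(classes %in% labels),
         "both classes must be present in the labels")
  nc <- length(channelNames)
  nb <- nrow(bankSpec@bands)
  mats <- lapply(multibandTrials, function(t) {
    m <- if (is(t, "EEGEpoch")) t@data else as.matrix(t)
    stopIf(nrow(m) != nc * nb,
           "multiband trial has %d channels, expected %d", nrow(m), nc * nb)
    m
  })
  a <- mats[labels == classes[1]]
  b <- mats[labels == classes[2]]
  fits <- lapply(seq_len(nb), function(band) {
    rows <- (band - 1L) * nc + seq_len(nc)
    fitCSP(lapply(a, function(m) m[rows, , drop = FALSE]),
           lapply(b, function(m) m[rows, , drop = FALSE]))
  })
  new("CSPBank",
    filters = lapply(fits, `[[`, "filters"),
    patterns = lapply(fits, `[[`, "patterns"),
    eigenvalues = lapply(fits, `[[`, "eigenvalues"),
    classes = classes, channelNames = channelNames, bankSpec = bankSpec
  )
}

#' @rdname CSPBank-class
#' @export
setMethod("cspFilters", "CSPBank", function(x) x@filters)

#' @rdname CSPBank-class
#' @export
setMethod("cspPatterns", "CSPBank", function(x) x@patterns)

setMethod("show", "CSPBank", function(object) {
  cat(sprintf(
    "CSPBank: %d band(s), %d -> 2 channels per band (%s vs %s)\n",
    length(object@filters), length(object@channelNames),
    object@classes[1], object@classes[2]
  ))
})

#' @rdname applyCSPBank
#' @export
setMethod("applyCSPBank", signature("EEGEpoch", "CSPBank"),
  function(multiband, bank) {
    nc <- length(bank@channelNames)
    nb <- length(bank@filters)
    stopIf(nrow(multiband@data) != nc * nb,
           "multiband input has %d channels, expected %d",
           nrow(multiband@data), nc * nb)
    out <- matrix(0, 2L * nb, ncol(multiband@data))
    for (band in seq_len(nb)) {
      rows <- (band - 1L) * nc + seq_len(nc)
      out[(band - 1L) * 2L + 1:2, ] <-
        crossprod(bank@filters[[band]], multiband@data[rows, , drop = FALSE])
    }
    edges <- bank@bankSpec@bands
    outNames <- unlist(lapply(seq_len(nb), function(b) {
      sprintf("csp%d@%g-%g", 1:2, edges[b, 1], edges[b, 2])
    }))
    EEGEpoch(out, outNames, multiband@samplingRate, multiband@label,
             multiband@markers)
  }
)
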
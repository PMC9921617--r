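#' Synthetic EEG generator configuration
#'
#' Builds the configuration of the surrogate EEG generator. The defaults
#' reproduce the recording protocol the decoder is designed for: an
#' 8-channel dry-electrode montage sampled at 250 Hz and re-referenced to
#' the mastoids, 70 trials per class, 6 s two-hand flexion epochs and 2 s
#' left/right clenching epochs with 4 s breaks, and motor imagery expressed
#' as a multiplicative event-related desynchronization (ERD) of the mu and
#' beta oscillations at the contralateral central channel.
#'
#' @param samplingRate sampling rate in Hz.
#' @param montage ordered channel names; must contain the references.
#' @param referenceChannels the two mastoid reference channels.
#' @param trialCount trials generated per class.
#' @param durations named seconds per phase; `rest` defaults to the flexion
#'   duration so the flexion-rest decoder sees equal-length epochs.
#' @param erdDepth fractional oscillation amplitude reduction in \[0,1\]
#'   during imagery; 0 means no modulation at all.
#' @param backgroundAmplitude RMS of the 1/f background, microvolts.
#' @param muAmplitude,betaAmplitude RMS of the mu (8-12 Hz) and beta
#'   (14-25 Hz) oscillations at C3/C4, microvolts.
#' @param blinkAmplitude peak blink deflection at Fz, microvolts.
#' @param artifactAmplitude peak amplitude of injected artifacts,
#'   microvolts.
#' @param rngSeed integer seed; fixing it fixes every generated sample.
#' @return a [SyntheticConfig].
#' @examples
#' cfg <- SyntheticConfig(trialCount = 5L)
#' trial <- generateTrial(cfg, "left", seed = 1)
#' trial
#' @export
SyntheticConfig <- function(samplingRate = 250,
                            montage = c("Fz", "C3", "Cz", "C4", "P3", "P4",
                                        "TP9", "TP10"),
                            referenceChannels = c("TP9", "TP10"),
                            trialCount = 70L,
                            durations = c(flexion = 6, left = 2, right = 2,
                                          rest = 6, `break` = 4,
                                          instruction = 2),
                            erdDepth = 0.6,
                            backgroundAmplitude = 10,
                            muAmplitude = 6,
                            betaAmplitude = 3,
                            blinkAmplitude = 150,
                            artifactAmplitude = 250,
                            rngSeed = 1L) {
  new("SyntheticConfig",
    samplingRate = samplingRate, montage = montage,
    referenceChannels = referenceChannels, trialCount = as.integer(trialCount),
    durations = durations, erdDepth = erdDepth,
    backgroundAmplitude = backgroundAmplitude, muAmplitude = muAmplitude,
    betaAmplitude = betaAmplitude, blinkAmplitude = blinkAmplitude,
    artifactAmplitude = artifactAmplitude, rngSeed = as.integer(rngSeed)
  )
}

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d ch @ %g Hz, %d trials/class, ERD depth %.2f\n",
    length(object@montage), object@samplingRate, object@trialCount,
    object@erdDepth
  ))
})

# 1/f-shaped noise (power ~ 1/f) with the requested RMS, via spectral
# shaping of white noise
pinkNoise <- function(n, samplingRate, rms) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- seq(0, samplingRate, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, samplingRate - f) # two-sided frequency axis
  gain <- 1 / sqrt(pmax(f, 1))   # flat below 1 Hz, 1/f power above
  gain[1] <- 0                   # remove DC
  x <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

# narrow-band oscillation as band-limited Gaussian noise at exact RMS
bandOscillation <- function(n, samplingRate, low, high, rms) {
  if (rms <= 0) return(numeric(n))
  filt <- butterBand(low, high, samplingRate, order = 3L)
  x <- as.numeric(signal::filter(filt, stats::rnorm(n)))
  x * rms / sqrt(mean(x^2))
}

# relative oscillation gain per channel; imagery modulates C3/C4 only
oscillationGains <- c(C3 = 1, C4 = 1, Cz = 0.5, P3 = 0.6, P4 = 0.6)

#' Generate one labeled synthetic EEG trial
#'
#' Each channel receives independent 1/f background noise; sensorimotor
#' channels (C3, C4, Cz, P3, P4) additionally carry narrow-band mu and beta
#' oscillations. During `left` imagery the oscillation amplitude at the
#' contralateral C4 is scaled by `(1 - erdDepth)`; `right` scales C3;
#' two-hand `flexion` scales both; `rest` scales none.
#'
#' @param config a [SyntheticConfig].
#' @param label one of `rest`, `flexion`, `left`, `right`.
#' @param seed optional integer; when given, the trial is generated under
#'   this seed without disturbing the caller's RNG state.
#' @return an [EEGEpoch] with the label attached.
#' @export
generateTrial <- function(config, label, seed = NULL) {
  stopIf(!is(config, "SyntheticConfig"), "config must be a SyntheticConfig")
  stopIf(!label %in% MI_CLASSES,
         "unknown label '%s' (expected one of %s)",
         label, paste(MI_CLASSES, collapse = ", "))
  if (!is.null(seed)) {
    return(withSeed(seed, generateTrial(config, label)))
  }
  fs <- config@samplingRate
  n <- as.integer(round(config@durations[[label]] * fs))
  erdScale <- c(C3 = 1, C4 = 1)
  s <- 1 - config@erdDepth
  if (label == "left") erdScale["C4"] <- s
  if (label == "right") erdScale["C3"] <- s
  if (label == "flexion") erdScale[c("C3", "C4")] <- s
  data <- matrix(0, length(config@montage), n,
                 dimnames = list(config@montage, NULL))
  for (ch in config@montage) {
    x <- pinkNoise(n, fs, config@backgroundAmplitude)
    g <- oscillationGains[ch]
    if (!is.na(g)) {
      amp <- if (ch %in% names(erdScale)) erdScale[[ch]] else 1
      x <- x + amp * g * bandOscillation(n, fs, 8, 12, config@muAmplitude) +
        amp * g * bandOscillation(n, fs, 14, 25, config@betaAmplitude)
    }
    data[ch, ] <- x
  }
  EEGEpoch(data, config@montage, fs, label, c(1L, n))
}

# tri-phasic blink transient: an 80 ms half-cosine main lobe flanked by
# 40 ms, 60% undershoots; fast enough that ~90% of the peak survives the
# 4-40 Hz detection filter, keeping a 150 uV blink safely above the
# 100 uV threshold even on top of background noise
blinkWaveform <- function(samplingRate, amplitude) {
  hc <- function(n) sin(pi * seq(0, 1, length.out = n))
  nMain <- max(3L, as.integer(round(0.08 * samplingRate)))
  nUnder <- max(3L, as.integer(round(0.04 * samplingRate)))
  amplitude * c(-0.6 * hc(nUnder), hc(nMain), -0.6 * hc(nUnder))
}

# spatial spread of the blink: largest at Fz, attenuated frontal-adjacent
blinkTopography <- c(Fz = 1, Cz = 0.4, C3 = 0.3, C4 = 0.3)

#' Inject a blink transient into an epoch
#'
#' Adds a biphasic eye-blink deflection peaking at `blinkAmplitude` on Fz,
#' with attenuated copies on adjacent channels (Cz, C3, C4). Returns a new
#' epoch; the input is untouched.
#'
#' @param epoch an [EEGEpoch] containing channel Fz.
#' @param at blink onset in seconds from epoch start.
#' @param config a [SyntheticConfig] supplying `blinkAmplitude`.
#' @return the epoch with the blink added.
#' @export
injectBlink <- function(epoch, at, config = SyntheticConfig()) {
  stopIf(!"Fz" %in% epoch@channelNames, "epoch has no Fz channel")
  fs <- epoch@samplingRate
  w <- blinkWaveform(fs, config@blinkAmplitude)
  start <- as.integer(round(at * fs)) + 1L
  stopIf(at < 0 || start + length(w) - 1L > ncol(epoch@data),
         "blink at %g s does not fit in a %.2f s epoch",
         at, ncol(epoch@data) / fs)
  if (config@blinkAmplitude == 0) return(epoch)
  data <- epoch@data
  idx <- start:(start + length(w) - 1L)
  for (ch in intersect(names(blinkTopography), epoch@channelNames)) {
    data[ch, idx] <- data[ch, idx] + blinkTopography[[ch]] * w
  }
  EEGEpoch(data, epoch@channelNames, fs, epoch@label, epoch@markers)
}

#' Inject a high-amplitude artifact into an epoch
#'
#' Adds a 100 ms half-cosine transient of peak `artifactAmplitude`
#' (default 250 microvolts, above the 200 microvolt rejection threshold) to
#' one channel, emulating the occasional motion/electrode artifact the
#' online gate must discard.
#'
#' @param epoch an [EEGEpoch].
#' @param at artifact onset in seconds from epoch start.
#' @param config a [SyntheticConfig] supplying `artifactAmplitude`.
#' @param channel channel receiving the transient (default the first).
#' @return the epoch with the artifact added.
#' @export
injectArtifact <- function(epoch, at, config = SyntheticConfig(),
                           channel = epoch@channelNames[1]) {
  stopIf(!channel %in% epoch@channelNames, "unknown channel '%s'", channel)
  fs <- epoch@samplingRate
  nW <- max(3L, as.integer(round(0.1 * fs)))
  w <- config@artifactAmplitude * sin(pi * seq(0, 1, length.out = nW))
  start <- as.integer(round(at * fs)) + 1L
  stopIf(at < 0 || start + nW - 1L > ncol(epoch@data),
         "artifact at %g s out of range", at)
  data <- epoch@data
  data[channel, start:(start + nW - 1L)] <-
    data[channel, start:(start + nW - 1L)] + w
  EEGEpoch(data, epoch@channelNames, fs, epoch@label, epoch@markers)
}

#' Generate a full labeled dataset with session structure
#'
#' Generates `trialCount` trials for each of the four classes under the
#' configuration seed: the result is bit-reproducible for a fixed
#' `rngSeed`. Flexion and rest trials are assigned to recording sessions
#' 1-2, left/right trials to sessions 3-4, mirroring the four-session
#' offline protocol.
#'
#' @param config a [SyntheticConfig].
#' @return a [TrialSet].
#' @examples
#' ts <- generateDataset(SyntheticConfig(trialCount = 2L))
#' table(trialLabels(ts))
#' @export
generateDataset <- function(config) {
  stopIf(!is(config, "SyntheticConfig"), "config must be a SyntheticConfig")
  withSeed(config@rngSeed, {
    trials <- list()
    labels <- character()
    session <- integer()
    classSessions <- list(
      rest = 1:2, flexion = 1:2, left = 3:4, right = 3:4
    )
    for (label in MI_CLASSES) {
      k <- config@trialCount
      if (k == 0L) next
      trials <- c(trials, lapply(seq_len(k), function(i) {
        generateTrial(config, label)
      }))
      labels <- c(labels, rep(label, k))
      # first half of the trials in the earlier session, rest in the later
      ses <- classSessions[[label]]
      session <- c(session, rep(ses, c(ceiling(k / 2), floor(k / 2))))
    }
    TrialSet(trials, labels, session)
  })
}

#' Construct a trial set
#'
#' @param trials list of [EEGEpoch] objects.
#' @param labels character vector of class labels, parallel to `trials`.
#' @param session integer vector of recording-session indices.
#' @return a [TrialSet].
#' @export
TrialSet <- function(trials, labels, session = rep(1L, length(trials))) {
  new("TrialSet",
    trials = trials, labels = as.character(labels),
    session = as.integer(session)
  )
}

#' @rdname TrialSet-class
#' @export
setMethod("trialLabels", "TrialSet", function(x) x@labels)

#' @rdname TrialSet-class
#' @export
setMethod("nTrials", "TrialSet", function(x) length(x@trials))

#' @rdname TrialSet-class
#' @param x a [TrialSet].
#' @param i index or logical vector.
#' @export
setMethod("[", "TrialSet", function(x, i) {
  TrialSet(x@trials[i], x@labels[i], x@session[i])
})

#' @rdname TrialSet-class
#' @export
setMethod("[[", "TrialSet", function(x, i) x@trials[[i]])

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d trial(s)\n", length(object@trials)))
  if (length(object@trials)) {
    print(table(label = object@labels, session = object@session))
  }
})
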
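# shared fixtures, all generated in code

# small generator configuration for fast tests
smallConfig <- function(...) {
  SyntheticConfig(trialCount = 4L, rngSeed = 42L, ...)
}

# a flat epoch with known constant channels, handy for re-referencing math
constantEpoch <- function(values, samplingRate = 250, samples = 250L) {
  data <- matrix(rep(values, each = samples), nrow = length(values),
                 byrow = TRUE)
  EEGEpoch(data, names(values), samplingRate)
}

# pure sinusoid epoch on the 6 decoding channels
sineEpoch <- function(freq, seconds = 2, samplingRate = 250, amplitude = 1,
                      channels = c("Fz", "C3", "Cz", "C4", "P3", "P4")) {
  t <- seq(0, seconds, by = 1 / samplingRate)[-1]
  data <- matrix(rep(amplitude * sin(2 * pi * freq * t),
                     length(channels)),
                 nrow = length(channels), byrow = TRUE)
  EEGEpoch(data, channels, samplingRate)
}

# random toy trials (channels x samples) for CSP tests
toyTrials <- function(n, channels = 3L, samples = 150L, mix = NULL,
                      boost = 2) {
  replicate(n, {
    x <- matrix(stats::rnorm(channels * samples), channels)
    if (!is.null(mix)) x <- x + mix %*% t(stats::rnorm(samples) * boost)
    x
  }, simplify = FALSE)
}

# tiny separable labeled sequence set for classifier tests: class means
# differ along every feature
toySequences <- function(n, tSteps = 6L, d = 8L, sep = 1.5, seed = 99L) {
  withr::with_seed(seed, {
    labels <- rep(c("a", "b"), length.out = n)
    seqs <- lapply(labels, function(l) {
      mu <- if (l == "a") sep else -sep
      matrix(stats::rnorm(tSteps * d, mean = mu, sd = 1), tSteps, d)
    })
    list(sequences = seqs, labels = labels)
  })
}
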
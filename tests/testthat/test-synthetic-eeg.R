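# band power of one channel after band-passing, transient excluded
bandPower <- function(epoch, ch, low = 8, high = 12) {
  y <- epochData(bandpass(epoch, low, high))[ch, ]
  mean(y[-seq_len(100)]^2)
}

meanTaskPower <- function(cfg, label, ch, n = 30, seedBase = 0) {
  mean(vapply(seq_len(n), function(i) {
    bandPower(generateTrial(cfg, label, seed = seedBase + i), ch)
  }, numeric(1)))
}

test_that("dataset generation is reproducible and carries session structure", {
  cfg <- SyntheticConfig(trialCount = 3L, rngSeed = 5L)
  ds1 <- generateDataset(cfg)
  ds2 <- generateDataset(cfg)
  expect_equal(nTrials(ds1), 12L)
  expect_equal(as.vector(table(trialLabels(ds1))), rep(3L, 4))
  # bit-identical samples under the same seed
  expect_identical(epochData(ds1[[7]]), epochData(ds2[[7]]))
  # flexion/rest recorded in sessions 1-2, left/right in 3-4
  expect_true(all(ds1@session[trialLabels(ds1) %in% c("rest", "flexion")]
                  %in% 1:2))
  expect_true(all(ds1@session[trialLabels(ds1) %in% c("left", "right")]
                  %in% 3:4))
  expect_equal(nTrials(generateDataset(SyntheticConfig(trialCount = 0L))), 0L)
})

test_that("trial shapes follow the task durations and labels are checked", {
  cfg <- smallConfig()
  flex <- generateTrial(cfg, "flexion", seed = 1)
  lr <- generateTrial(cfg, "left", seed = 1)
  expect_equal(ncol(epochData(flex)), 6L * 250L)
  expect_equal(ncol(epochData(lr)), 2L * 250L)
  expect_equal(epochLabel(flex), "flexion")
  expect_error(generateTrial(cfg, "jump"), "unknown label")
})

test_that("imagery lateralises ERD to the contralateral channel", {
  cfg <- SyntheticConfig(erdDepth = 0.6, trialCount = 1L, rngSeed = 1L)
  restC4 <- meanTaskPower(cfg, "rest", "C4", seedBase = 1000)
  restC3 <- meanTaskPower(cfg, "rest", "C3", seedBase = 1000)
  # left imagery suppresses C4 mu power, leaves C3 untouched
  expect_lt(meanTaskPower(cfg, "left", "C4"), restC4 * 0.7)
  expect_gt(meanTaskPower(cfg, "left", "C3"), restC3 * 0.8)
  # flexion suppresses both
  expect_lt(meanTaskPower(cfg, "flexion", "C4"), restC4 * 0.7)
  expect_lt(meanTaskPower(cfg, "flexion", "C3"), restC3 * 0.7)
})

test_that("zero ERD depth leaves task and rest band power equal", {
  cfg <- SyntheticConfig(erdDepth = 0, trialCount = 1L)
  ratio <- meanTaskPower(cfg, "left", "C4") /
    meanTaskPower(cfg, "rest", "C4", seedBase = 500)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("task/rest power ratio converges to (1 - erdDepth)^2 without background", {
  cfg <- SyntheticConfig(erdDepth = 0.6, backgroundAmplitude = 0,
                         betaAmplitude = 0, trialCount = 1L)
  # only the mu oscillation remains, at exact per-trial RMS, so whole-trial
  # power gives the modulated-component ratio directly
  p <- function(label, i) mean(epochData(
    generateTrial(cfg, label, seed = i)
  )["C4", ]^2)
  ratios <- vapply(1:10, function(i) p("left", i) / p("rest", 100 + i),
                   numeric(1))
  expect_equal(mean(ratios), (1 - 0.6)^2, tolerance = 1e-6)
})

test_that("injected blinks cross the detection threshold", {
  cfg <- smallConfig()
  rest <- generateTrial(cfg, "rest", seed = 3)
  expect_false(detectBlink(rest))
  blinked <- injectBlink(rest, at = 1.5, config = cfg)
  expect_true(detectBlink(blinked))
  # the input epoch is untouched; zero amplitude is the identity
  expect_false(detectBlink(rest))
  zeroCfg <- smallConfig(blinkAmplitude = 0)
  expect_identical(epochData(injectBlink(rest, 1.5, zeroCfg)),
                   epochData(rest))
  expect_error(injectBlink(rest, at = 50, config = cfg), "does not fit")
})

test_that("two blinks give two supra-threshold maxima on filtered Fz", {
  cfg <- smallConfig()
  ep <- generateTrial(cfg, "rest", seed = 4)
  ep <- injectBlink(injectBlink(ep, 1, cfg), 3, cfg)
  fz <- epochData(bandpass(ep, 4, 40))["Fz", ]
  fs <- samplingRate(ep)
  peakNear <- function(sec) max(abs(fz[(sec * fs):((sec + 0.5) * fs)]))
  expect_gt(peakNear(1), 100)
  expect_gt(peakNear(3), 100)
  # between the two blinks the trace returns below threshold
  expect_lt(max(abs(fz[(2 * fs):(2.6 * fs)])), 100)
})

test_that("background stays below the artifact ceiling unless injected", {
  cfg <- SyntheticConfig(trialCount = 2L, rngSeed = 9L)
  ds <- generateDataset(cfg)
  maxima <- vapply(seq_len(nTrials(ds)), function(i) {
    max(abs(epochData(ds[[i]])))
  }, numeric(1))
  expect_true(all(maxima < cfg@artifactAmplitude))
  spiked <- injectArtifact(ds[[1]], at = 2, config = cfg, channel = "C3")
  expect_gt(max(abs(epochData(spiked))), 200)
  expect_true(rejectArtifact(spiked))
})
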
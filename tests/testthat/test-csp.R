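# independent covariance estimate mirroring the trace-normalised average
avgCov <- function(trials) {
  cs <- lapply(trials, function(x) {
    c <- tcrossprod(x)
    c / sum(diag(c))
  })
  Reduce(`+`, cs) / length(cs)
}

test_that("identical class covariances give symmetric, uninformative filters", {
  set.seed(11)
  a <- toyTrials(30)
  b <- toyTrials(30)
  fit <- fitCSP(a, b)
  # both retained generalized eigenvalues sit near 1/2
  expect_equal(fit$eigenvalues, c(0.5, 0.5), tolerance = 0.08)
  # projected variance ratio between classes is near 1
  va <- mean(vapply(a, function(x) stats::var(drop(crossprod(fit$filters[, 1], x))), 1))
  vb <- mean(vapply(b, function(x) stats::var(drop(crossprod(fit$filters[, 1], x))), 1))
  expect_equal(va / vb, 1, tolerance = 0.25)
})

test_that("CSP recovers a planted mixing direction from 100 trials", {
  set.seed(12)
  mix <- rnorm(6)
  mix <- mix / sqrt(sum(mix^2))
  a <- toyTrials(100, channels = 6L, mix = mix, boost = 2)
  b <- toyTrials(100, channels = 6L)
  fit <- fitCSP(a, b)
  pat <- fit$patterns[, 1]
  r <- abs(sum(pat * mix)) / sqrt(sum(pat^2))
  expect_gt(r, 0.9)
  # eigenvalue ordering: filter 1 favours class 1 more than filter 2 does
  expect_gt(fit$eigenvalues[1], fit$eigenvalues[2])
})

test_that("the eigen solution matches a brute-force search over unit vectors", {
  set.seed(13)
  mix <- c(0.8, -0.5, 0.33)
  mix <- mix / sqrt(sum(mix^2))
  a <- toyTrials(60, channels = 3L, mix = mix, boost = 1.5)
  b <- toyTrials(60, channels = 3L)
  ca <- avgCov(a)
  cb <- avgCov(b)
  ratio <- function(w) drop(t(w) %*% ca %*% w / (t(w) %*% (ca + cb) %*% w))
  # exhaustive search over a fine spherical grid
  best <- 0
  for (th in seq(0, pi, length.out = 120)) {
    for (ph in seq(0, pi, length.out = 120)) {
      w <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      best <- max(best, ratio(w))
    }
  }
  fit <- fitCSP(a, b)
  expect_equal(ratio(fit$filters[, 1]), best, tolerance = 1e-2)
  expect_gte(ratio(fit$filters[, 1]), best - 1e-2)
})

test_that("fitted filters ignore per-trial global amplitude scaling", {
  set.seed(14)
  mix <- rnorm(6)
  a <- toyTrials(40, channels = 6L, mix = mix)
  b <- toyTrials(40, channels = 6L)
  scales <- stats::runif(40, 0.1, 10)
  aScaled <- Map(function(x, s) x * s, a, scales)
  f1 <- fitCSP(a, b)
  f2 <- fitCSP(aScaled, b)
  expect_equal(abs(f1$filters), abs(f2$filters), tolerance = 1e-8)
  expect_error(fitCSP(a[1], b), "at least two trials")
})

test_that("a fitted bank compresses 120 filter-bank channels to 40", {
  set.seed(15)
  spec <- designFilterBank(250)
  cfg <- smallConfig(erdDepth = 0.8)
  mk <- function(label, i) {
    applyFilterBank(rereference(generateTrial(cfg, label, seed = i)), spec)
  }
  trials <- c(lapply(1:3, function(i) mk("left", i)),
              lapply(1:3, function(i) mk("right", 100 + i)))
  labels <- rep(c("left", "right"), each = 3)
  bank <- fitCSPBank(trials, labels, spec, c("left", "right"))
  expect_equal(length(cspFilters(bank)), 20L)
  out <- applyCSPBank(trials[[1]], bank)
  expect_equal(nrow(epochData(out)), 40L)
  expect_equal(ncol(epochData(out)), ncol(epochData(trials[[1]])))

  # zero in, zero out; scaling the input scales the output
  zero <- EEGEpoch(matrix(0, 120, 100), channelNames(trials[[1]]), 250)
  expect_true(all(epochData(applyCSPBank(zero, bank)) == 0))
  doubled <- EEGEpoch(2 * epochData(trials[[1]]), channelNames(trials[[1]]),
                      250)
  expect_equal(epochData(applyCSPBank(doubled, bank)),
               2 * epochData(applyCSPBank(trials[[1]], bank)),
               tolerance = 1e-12)

  bad <- EEGEpoch(matrix(0, 60, 100), sprintf("c%d", 1:60), 250)
  expect_error(applyCSPBank(bad, bank), "expected 120")
})
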
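turnWorld <- function() {
  # a straight street into a crossroads: walk to node 2 (in front of the
  # crossing at 3), then turn
  nodes <- data.frame(id = 1:6, x = c(0, 1, 2, 3, 2, 2), y = c(0, 0, 0, 0, 1, -1),
                      junction = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  edges <- data.frame(from = c(1, 2, 3, 3, 3), to = c(2, 3, 4, 5, 6))
  streetGraph(nodes, edges, start = 1, heading = 2)
}

test_that("a perfect decoder yields the ideal command counts and times", {
  w <- turnWorld()
  route <- c("forward", "left")
  for (strategy in c("NE", "DC", "EC")) {
    res <- runClosedLoop(UserModel(route, p = 1, q = 1), strategy,
                         mode = "middle", world = w, seed = 1)
    m <- res@metrics
    expect_equal(m@noError, 0)
    expect_equal(m@noNavigationError, 0)
    # one imagining per rotation, except DC which needs exactly two
    expect_equal(m@noImagination, if (strategy == "DC") 2 else 1)
    # the walk command takes exactly one 6 s flexion epoch
    expect_equal(res@commandTimes$walk, 6)
    # NE rotation takes exactly one 2 s epoch; EC adds its 2 s window
    if (strategy == "NE") expect_equal(res@commandTimes$rotation, 2)
    if (strategy == "DC") expect_equal(res@commandTimes$rotation, 4)
    if (strategy == "EC") expect_equal(res@commandTimes$rotation, 4)
    expect_true(res@completed)
  }
})

test_that("closed-loop runs execute the intended turns on the street graph", {
  w <- turnWorld()
  res <- runClosedLoop(UserModel(c("forward", "left"), p = 1), "NE",
                       mode = "middle", world = w, seed = 2)
  # walked up to node 2 (in front of junction 3), stepped onto 3 to turn
  expect_equal(res@trajectory, c(1L, 2L, 3L))
  expect_true("rotate_left" %in% res@events$detail)
})

test_that("closed forms match hand-derived values and reject divergence", {
  expect_equal(expectedImaginations("NE", 1), 1)
  expect_equal(expectedImaginations("DC", 1), 2)
  expect_equal(expectedImaginations("NE", 0.75), 2)
  expect_equal(expectedImaginations("DC", 0.75), 4)
  expect_equal(expectedImaginations("EC", 0.6, q = 1), 1)
  expect_equal(expectedImaginations("EC", 0.8, q = 0.5),
               1 / (2 * (0.8 + 0.2 * 0.5) - 1))
  expect_error(expectedImaginations("NE", 0.5), "diverge")
  expect_error(expectedImaginations("DC", 0.4), "diverge")
})

test_that("Monte-Carlo strategy walks converge to the closed forms", {
  for (p in c(0.75, 0.9)) {
    ne <- mcImaginations("NE", p, n = 2e4, seed = 3)
    dc <- mcImaginations("DC", p, n = 2e4, seed = 4)
    expect_equal(ne$imaginations, expectedImaginations("NE", p),
                 tolerance = 0.05)
    expect_equal(dc$imaginations, expectedImaginations("DC", p),
                 tolerance = 0.05)
  }
  # EC with reliable blinks: exactly one imagining, never a wrong rotation
  ec <- mcImaginations("EC", 0.8, n = 5000, seed = 5)
  expect_equal(ec$imaginations, 1)
  expect_equal(ec$navErrors, 0)
  expect_equal(ec$errors, 0.2, tolerance = 0.1)
})

test_that("Monte-Carlo error shrinks roughly like 1/sqrt(N)", {
  truth <- expectedImaginations("NE", 0.75)
  errSmall <- mean(vapply(1:10, function(i) {
    abs(mcImaginations("NE", 0.75, n = 1e3, seed = i)$imaginations - truth)
  }, numeric(1)))
  errLarge <- mean(vapply(1:10, function(i) {
    abs(mcImaginations("NE", 0.75, n = 1e5, seed = 100 + i)$imaginations -
          truth)
  }, numeric(1)))
  # a 100x sample increase should cut the error by ~10x; allow slack
  expect_lt(errLarge, errSmall / 3)
})

test_that("under NE every misclassification is a navigation error", {
  for (p in c(0.6, 0.75, 0.9)) {
    mc <- mcImaginations("NE", p, n = 5000, seed = 10 + round(100 * p))
    expect_identical(mc$errors, mc$navErrors)
  }
  # and in a full closed-loop run, counted event by event
  res <- runClosedLoop(UserModel(c("left", "right", "left"), p = 0.7),
                       "NE", mode = "low", world = turnWorld(), seed = 6)
  cts <- res@metrics@counts
  expect_identical(cts[["errors"]], cts[["navErrors"]])
})

test_that("strategies order as expected on an accuracy grid", {
  tab <- compareStrategies(pGrid = c(0.6, 0.7, 0.8, 0.9), n = 4000, seed = 7)
  for (p in unique(tab$p)) {
    at <- function(s) tab[tab$strategy == s & tab$p == p, ]
    expect_lte(at("EC")$noImagination, at("NE")$noImagination)
    expect_lte(at("NE")$noImagination, at("DC")$noImagination)
    # Monte-Carlo agrees with its analytic column
    expect_equal(at("NE")$noImagination, at("NE")$expected, tolerance = 0.1)
  }
  at07 <- tab[tab$p == 0.7, ]
  ne <- at07[at07$strategy == "NE", ]
  expect_lt(at07[at07$strategy == "DC", "noNavigationError"],
            ne$noNavigationError)
  expect_lt(at07[at07$strategy == "EC", "noNavigationError"],
            ne$noNavigationError)
})

test_that("metrics depend on the route topology, not world geometry", {
  w1 <- turnWorld()
  # same crossing topology, wildly different coordinates and extra arm length
  nodes <- data.frame(id = 1:6,
                      x = c(0, 5, 10, 15, 10, 10), y = c(2, 1, 0, 0, 7, -9),
                      junction = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  edges <- data.frame(from = c(1, 2, 3, 3, 3), to = c(2, 3, 4, 5, 6))
  w2 <- streetGraph(nodes, edges, start = 1, heading = 2)
  r1 <- runClosedLoop(UserModel(c("left", "right"), p = 0.8), "DC",
                      mode = "low", world = w1, seed = 8)
  r2 <- runClosedLoop(UserModel(c("left", "right"), p = 0.8), "DC",
                      mode = "low", world = w2, seed = 8)
  expect_equal(r1@metrics@counts, r2@metrics@counts)
})

test_that("infeasible routes and empty routes are rejected", {
  w <- lineWorld(4) # no junction anywhere: a forward segment cannot stop
  u <- UserModel("forward", p = 1)
  expect_error(runClosedLoop(u, "NE", "middle", w, seed = 1,
                             maxStepsPerSegment = 20L), "infeasible")
  expect_error(runClosedLoop(UserModel(character(), p = 1), "NE", "middle",
                             w), "empty")
})

test_that("the full-pipeline user closes the loop through synthetic EEG", {
  cfg <- SyntheticConfig(trialCount = 6L, erdDepth = 0.8, rngSeed = 31L)
  ds <- generateDataset(cfg)
  pipe <- fitOfflineDecoder(ds, TrainingConfig(rngSeed = 31L),
                            trainPerClass = 4L, classifierType = "logistic")
  u <- UserModel("forward", mode = "full", pipeline = pipe, config = cfg)
  res <- runClosedLoop(u, "NE", mode = "middle", world = turnWorld(),
                       seed = 9, maxStepsPerSegment = 60L)
  expect_true(res@completed)
  expect_true(any(res@events$kind == "classification"))
  # every walk command is a whole number of 6 s flexion epochs
  expect_true(all(res@commandTimes$walk %% 6 == 0))
})
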
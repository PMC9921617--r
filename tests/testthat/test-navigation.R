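tickAt <- function(t) controlEvent("tick", t)

# drive a fresh automaton from idle into the rotation state
intoRotation <- function(mode = "low", strategy = "NE", world = lineWorld(3)) {
  s <- NavState(mode = mode, strategy = strategy)
  out <- handleEvent(s, controlEvent("classified_flexion", 1), world)
  out <- handleEvent(out$state, controlEvent("blink", 1.5), out$world)
  out
}

test_that("flexion enters switch; blink selects rotation; silence starts walk", {
  w <- lineWorld(5)
  s <- NavState("low", "NE")
  out <- handleEvent(s, controlEvent("classified_flexion", 1), w)
  expect_equal(out$state@state, "switch")

  # a blink inside the 2 s dwell selects rotation
  rot <- handleEvent(out$state, controlEvent("blink", 1.5), w)
  expect_equal(rot$state@state, "rotation")

  # doing nothing for 2 s starts walking instead
  s2 <- out$state
  early <- handleEvent(s2, tickAt(2.5), w)
  expect_equal(early$state@state, "switch")
  walk <- handleEvent(early$state, tickAt(3), w)
  expect_equal(walk$state@state, "walk")
})

test_that("walking advances one edge per second and stops as its level dictates", {
  w <- lineWorld(6, junctionAt = 5)
  s <- NavState("low", "NE")
  s <- handleEvent(s, controlEvent("classified_flexion", 0), w)$state
  s <- handleEvent(s, tickAt(2), w)$state # walk entered at t = 2
  out <- handleEvent(s, tickAt(2.5), w)
  expect_true(is.na(out$command)) # half-second tick: no move yet
  out <- handleEvent(out$state, tickAt(3), out$world)
  expect_equal(out$command, "forward")
  expect_equal(out$world@agentNode, 2L)

  # low level: a blink stops the walk
  stopped <- handleEvent(out$state, controlEvent("blink", 3.5), out$world)
  expect_equal(stopped$state@state, "idle")
  expect_equal(stopped$command, "stop")

  # middle level: the walk halts in front of the junction on its own
  wm <- lineWorld(6, junctionAt = 4)
  sm <- NavState("middle", "NE")
  sm <- handleEvent(sm, controlEvent("classified_flexion", 0), wm)$state
  sm <- handleEvent(sm, tickAt(2), wm)$state
  world <- wm
  cmds <- character()
  for (t in seq(2.5, 8, by = 0.5)) {
    out <- handleEvent(sm, tickAt(t), world)
    sm <- out$state
    world <- out$world
    if (!is.na(out$command)) cmds <- c(cmds, out$command)
    if (sm@state == "idle") break
  }
  expect_equal(cmds, c("forward", "forward", "stop"))
  expect_equal(world@agentNode, 3L) # halted in front of node 4
  expect_true(junctionOracle(world))

  # middle level ignores blinks during walking
  sm2 <- handleEvent(NavState("middle", "NE"),
                     controlEvent("classified_flexion", 0), wm)$state
  sm2 <- handleEvent(sm2, tickAt(2), wm)$state
  expect_equal(handleEvent(sm2, controlEvent("blink", 2.5), wm)$state@state,
               "walk")

  # a junction_reached event also stops the walk
  expect_equal(handleEvent(sm2, controlEvent("junction_reached", 3),
                           wm)$state@state, "idle")
})

test_that("NE executes every classification immediately", {
  out <- intoRotation(strategy = "NE")
  step <- rotationStrategyStep(out$state, "left")
  expect_equal(step$executed, "left")
  expect_equal(rotationStrategyStep(out$state, "right")$executed, "right")
})

test_that("DC needs two identical classifications and resets on mismatch", {
  out <- intoRotation(strategy = "DC")
  s1 <- rotationStrategyStep(out$state, "left")
  expect_true(is.na(s1$executed)) # arrow displayed, nothing executed
  expect_equal(s1$state@pendingDirection, "left")
  s2 <- rotationStrategyStep(s1$state, "left")
  expect_equal(s2$executed, "left")
  expect_true(is.na(s2$state@pendingDirection))

  # mismatch: reset with no execution, and the next pair starts fresh
  m1 <- rotationStrategyStep(out$state, "left")
  m2 <- rotationStrategyStep(m1$state, "right")
  expect_true(is.na(m2$executed))
  expect_true(is.na(m2$state@pendingDirection))
  m3 <- rotationStrategyStep(m2$state, "right")
  expect_true(is.na(m3$executed)) # first element of a new pair
})

test_that("EC confirms the displayed arrow unless a blink vetoes it", {
  out <- intoRotation(strategy = "EC")
  s1 <- rotationStrategyStep(out$state, "left")
  expect_equal(s1$state@state, "correction")
  expect_true(is.na(s1$executed))
  # blink: the OPPOSITE direction executes
  veto <- rotationStrategyStep(s1$state, blink = TRUE)
  expect_equal(veto$executed, "right")
  # no blink: the displayed direction executes
  confirm <- rotationStrategyStep(s1$state, blink = FALSE)
  expect_equal(confirm$executed, "left")
  expect_equal(confirm$state@state, "rotation")

  expect_error(rotationStrategyStep(NavState("low", "NE"), "left"),
               "outside the rotation state")
})

test_that("the EC correction window expires into the displayed direction", {
  out <- intoRotation(strategy = "EC", world = lineWorld(3))
  s <- handleEvent(out$state, controlEvent("classified_left", 2), out$world)
  expect_equal(s$state@state, "correction")
  expect_equal(s$command, "arrow_left")
  # ticks inside the 2 s window do nothing
  mid <- handleEvent(s$state, tickAt(3), s$world)
  expect_equal(mid$state@state, "correction")
  done <- handleEvent(mid$state, tickAt(4), mid$world)
  expect_equal(done$command, "rotate_left")
  expect_equal(done$state@state, "rotation")

  # blink inside the window executes the opposite
  vet <- handleEvent(s$state, controlEvent("blink", 2.5), s$world)
  expect_equal(vet$command, "rotate_right")
})

test_that("the automaton is total over states, strategies and events", {
  w <- lineWorld(4, junctionAt = 3)
  events <- c("classified_left", "classified_right", "classified_flexion",
              "blink", "tick", "junction_reached")
  for (strategy in c("NE", "DC", "EC")) {
    for (mode in c("low", "middle")) {
      states <- list(
        NavState(mode, strategy),
        handleEvent(NavState(mode, strategy),
                    controlEvent("classified_flexion", 0), w)$state,
        intoRotation(mode, strategy, w)$state
      )
      if (strategy == "EC") {
        states <- c(states, list(
          rotationStrategyStep(intoRotation(mode, "EC", w)$state,
                               "left")$state
        ))
      }
      for (s in states) {
        for (ev in events) {
          out <- handleEvent(s, controlEvent(ev, s@clock + 0.5), w)
          expect_s4_class(out$state, "NavState")
          expect_true(validObject(out$state))
        }
      }
    }
  }
  expect_error(controlEvent("jump"), "malformed")
  expect_error(handleEvent(NavState(), list(kind = "tick"), w), "malformed")
})

test_that("the junction oracle looks one edge ahead", {
  w <- lineWorld(5, junctionAt = 4)
  # agent at node 1 facing 2: nothing ahead
  expect_false(junctionOracle(w))
  expect_false(junctionOracle(w, node = 2, heading = 3))
  expect_true(junctionOracle(w, node = 3, heading = 4))
  # an isolated node has no heading, hence nothing ahead
  iso <- streetGraph(
    nodes = data.frame(id = 1:2, x = 0:1, y = 0, junction = FALSE),
    edges = data.frame(from = integer(), to = integer()),
    start = 1
  )
  expect_false(junctionOracle(iso))
  expect_error(junctionOracle(w, node = 99), "not on the graph")
  expect_error(junctionOracle(w, node = 1, heading = 4), "existing edge")
})

test_that("degree-based junction auto-flagging marks crossings", {
  nodes <- data.frame(id = 1:4, x = c(0, 1, 1, 1), y = c(0, 0, 1, -1),
                      junction = FALSE)
  edges <- data.frame(from = c(1, 2, 2), to = c(2, 3, 4))
  w <- streetGraph(nodes, edges, autoFlagJunctions = TRUE)
  expect_true(w@nodes$junction[w@nodes$id == 2]) # three neighbours
  expect_false(w@nodes$junction[w@nodes$id == 1])
  expect_true(junctionOracle(w)) # agent at 1 faces the crossing
})

test_that("rotation commands move the heading between edge directions", {
  # a crossroads: centre node 5 with four arms
  nodes <- data.frame(id = 1:5, x = c(0, 2, 1, 1, 1), y = c(1, 1, 0, 2, 1),
                      junction = FALSE)
  edges <- data.frame(from = c(5, 5, 5, 5), to = c(1, 2, 3, 4))
  w <- streetGraph(nodes, edges, start = 5, heading = 2)
  left <- rotateAgent(w, "left")
  expect_equal(left@agentHeading, 4L) # east -> north (counter-clockwise)
  right <- rotateAgent(w, "right")
  expect_equal(right@agentHeading, 3L) # east -> south
  expect_equal(rotateAgent(left, "right")@agentHeading, 2L)

  # malformed worlds are rejected by the validity method
  expect_error(streetGraph(nodes, data.frame(from = 5, to = 99)),
               "dangling|unknown")
})
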
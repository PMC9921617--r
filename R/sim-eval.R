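#' Construct a simulated user
#'
#' @param route character vector of intended actions (`forward`, `left`,
#'   `right`).
#' @param p per-trial classification accuracy in \[0,1\] (abstract mode).
#' @param q blink detection reliability in \[0,1\].
#' @param mode `"abstract"` (accuracy-driven oracle) or `"full"` (every
#'   imagination generates synthetic EEG pushed through the decoder).
#' @param pipeline a fitted [DecoderPipeline] (full mode).
#' @param config a [SyntheticConfig] driving EEG generation (full mode).
#' @return a [UserModel].
#' @export
UserModel <- function(route, p = 1, q = 1, mode = c("abstract", "full"),
                      pipeline = NULL, config = NULL) {
  mode <- match.arg(mode)
  new("UserModel",
    route = route, p = p, q = q, mode = mode,
    pipeline = if (is.null(pipeline)) list() else list(pipeline),
    config = if (is.null(config)) list() else list(config)
  )
}

setMethod("show", "UserModel", function(object) {
  cat(sprintf(
    "UserModel (%s): %d route actions, p = %.2f, q = %.2f\n",
    object@mode, length(object@route), object@p, object@q
  ))
})

#' @rdname RotationMetrics-class
#' @param noError,noNavigationError,noImagination per-rotation averages.
#' @param nRotations intended rotations behind the averages.
#' @param counts named raw totals.
#' @export
RotationMetrics <- function(noError, noNavigationError, noImagination,
                            nRotations = 0L, counts = numeric()) {
  new("RotationMetrics",
    noError = noError, noNavigationError = noNavigationError,
    noImagination = noImagination, nRotations = as.integer(nRotations),
    counts = counts
  )
}

setMethod("show", "RotationMetrics", function(object) {
  cat(sprintf(
    "RotationMetrics over %d rotation(s): No_error %.3f, No_navigation_error %.3f, No_imagination %.3f\n",
    object@nRotations, object@noError, object@noNavigationError,
    object@noImagination
  ))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf(
    "SimResult: %s in %.1f s simulated, %d event(s)\n",
    if (object@completed) "route completed" else "route NOT completed",
    object@totalTime, nrow(object@events)
  ))
  show(object@metrics)
})

EPOCH_FLEXION <- 6 # s of EEG per flexion-rest decision
EPOCH_LR <- 2      # s of EEG per left-right decision
QUANTUM <- 0.5     # s, online update interval

# sample an intended-vs-decoded classification; abstract mode flips the
# intended direction with probability 1 - p, full mode decodes a freshly
# generated synthetic epoch
simulateClassification <- function(user, intended) {
  if (user@mode == "abstract") {
    if (stats::runif(1) < user@p) intended else {
      if (intended == "left") "right"
      else if (intended == "right") "left"
      else "rest"
    }
  } else {
    pipe <- user@pipeline[[1]]
    cfg <- user@config[[1]]
    trial <- generateTrial(cfg, intended)
    buf <- OnlineBuffer(cfg@montage, cfg@samplingRate,
                        capacitySeconds = ncol(epochData(trial)) /
                          cfg@samplingRate)
    buf <- pushSamples(buf, epochData(trial))
    which <- if (intended %in% c("flexion", "rest")) "flexion" else "leftright"
    out <- decodeStep(buf, pipe, which)
    if (out$decision %in% MI_CLASSES) out$decision else "rest"
  }
}

# blink detection verdict; full mode injects a blink into a short rest
# epoch and runs the threshold detector
simulateBlink <- function(user) {
  if (user@mode == "abstract") {
    stats::runif(1) < user@q
  } else {
    cfg <- user@config[[1]]
    pipe <- user@pipeline[[1]]
    short <- cfg
    short@durations[["rest"]] <- EPOCH_LR
    ep <- injectBlink(generateTrial(short, "rest"), at = 0.8, config = cfg)
    detectBlink(rereference(ep, pipe@referenceChannels), pipe@thresholds)
  }
}

#' Run one closed-loop navigation simulation
#'
#' Simulates the complete loop — simulated user, decoder (abstract
#' accuracy `p` or the full synthetic-EEG pipeline), navigation automaton,
#' and street world — at 0.5 s resolution. Every classification, blink and
#' command is recorded; rotation metrics and simulated task time are
#' accumulated. Time accounting: 6 s of EEG per flexion decision, 2 s per
#' left/right decision, a 2 s switch dwell, 1 s per forward step, and a
#' 2 s correction window under EC.
#'
#' @param user a [UserModel] carrying the intended route.
#' @param strategy rotation error-control strategy (`NE`, `DC`, `EC`).
#' @param mode control level (`low` or `middle`).
#' @param world a [StreetGraph]; rotations and walking move its agent.
#' @param seed integer seed for all randomness in the run.
#' @param maxStepsPerSegment safety cap on walking steps and imaginations
#'   per route segment; exceeding it marks the route infeasible.
#' @return a [SimResult].
#' @examples
#' w <- lineWorld(6, junctionAt = 4)
#' u <- UserModel(route = c("forward"), p = 1, q = 1)
#' runClosedLoop(u, strategy = "NE", mode = "middle", world = w)
#' @export
runClosedLoop <- function(user, strategy = c("NE", "DC", "EC"),
                          mode = c("low", "middle"), world, seed = 1L,
                          maxStepsPerSegment = 10000L) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  stopIf(!is(world, "StreetGraph"), "world must be a StreetGraph")
  stopIf(!length(user@route), "route is empty")

  withSeed(seed, {
    nav <- NavState(mode = mode, strategy = strategy)
    t <- 0
    events <- list()
    trajectory <- world@agentNode
    log <- function(kind, detail = "") {
      events[[length(events) + 1L]] <<- data.frame(
        time = t, kind = kind, detail = detail
      )
    }
    dispatch <- function(ev) {
      out <- handleEvent(nav, ev, world)
      nav <<- out$state
      world <<- out$world
      if (!is.na(out$command)) {
        log("command", out$command)
        if (out$command == "forward") {
          trajectory <<- c(trajectory, world@agentNode)
        }
      }
      out$command
    }
    tick <- function() {
      t <<- t + QUANTUM
      dispatch(controlEvent("tick", t))
    }

    totErr <- 0; totNavErr <- 0; totImag <- 0
    nRot <- 0L
    walkTimes <- numeric()
    rotTimes <- numeric()
    completed <- TRUE

    startWalking <- function() {
      # flexion imaginations until the start intention is detected
      spent <- 0
      repeat {
        t <<- t + EPOCH_FLEXION
        spent <- spent + EPOCH_FLEXION
        stopIf(spent > maxStepsPerSegment * EPOCH_FLEXION,
               "walk start never detected; route infeasible")
        got <- simulateClassification(user, "flexion")
        log("classification", got)
        if (got == "flexion") break
      }
      walkTimes <<- c(walkTimes, spent)
      dispatch(controlEvent("classified_flexion", t))
      while (nav@state == "switch") tick() # 2 s dwell, then walk
    }

    enterRotation <- function() {
      startSwitch <- function() {
        repeat {
          t <<- t + EPOCH_FLEXION
          got <- simulateClassification(user, "flexion")
          log("classification", got)
          if (got == "flexion") break
        }
        dispatch(controlEvent("classified_flexion", t))
      }
      startSwitch()
      # blink inside the switch dwell to select rotation
      while (nav@state == "switch") {
        t <<- t + QUANTUM
        if (simulateBlink(user)) {
          log("blink", "switch")
          dispatch(controlEvent("blink", t))
        } else {
          dispatch(controlEvent("tick", t))
        }
      }
      if (nav@state == "walk") {
        # every blink in the dwell was missed and walking began; stop
        # (blink in low level, next junction in middle level) and retry
        steps <- 0L
        while (nav@state == "walk") {
          steps <- steps + 1L
          stopIf(steps > maxStepsPerSegment, "cannot stop runaway walk")
          t <<- t + QUANTUM
          if (mode == "low" && simulateBlink(user)) {
            dispatch(controlEvent("blink", t))
          } else {
            dispatch(controlEvent("tick", t))
          }
        }
        enterRotation()
      }
    }

    walkSegment <- function() {
      startWalking()
      steps <- 0L
      while (nav@state == "walk") {
        steps <- steps + 1L
        stopIf(steps > maxStepsPerSegment,
               "no stopping point reached; route infeasible")
        if (mode == "low" && junctionOracle(world)) {
          if (simulateBlink(user)) {
            log("blink", "stop-walk")
            dispatch(controlEvent("blink", t))
            break
          }
        }
        tick()
      }
    }

    turnSegment <- function(intended) {
      nRot <<- nRot + 1L
      # step onto the junction the agent halted in front of
      if (!is.na(world@agentHeading) && junctionOracle(world)) {
        world <<- advanceAgent(world)
        trajectory <<- c(trajectory, world@agentNode)
        t <<- t + 1
      }
      enterRotation()
      offset <- if (intended == "left") 1L else -1L
      imag <- 0L
      spent <- 0
      while (offset != 0L) {
        stopIf(imag > maxStepsPerSegment,
               "rotation never converged (accuracy too low?)")
        needed <- if (offset > 0L) "left" else "right"
        t <<- t + EPOCH_LR
        spent <- spent + EPOCH_LR
        imag <- imag + 1L
        got <- simulateClassification(user, needed)
        log("classification", got)
        if (got != needed) totErr <<- totErr + 1
        cmd <- dispatch(controlEvent(paste0("classified_", got), t))
        if (nav@state == "correction") {
          # EC window: blink to veto a wrong arrow, otherwise let it expire
          tWindow <- t
          if (nav@pendingDirection != needed && simulateBlink(user)) {
            t <<- t + QUANTUM
            log("blink", "veto")
            cmd <- dispatch(controlEvent("blink", t))
          } else {
            while (nav@state == "correction") {
              t <<- t + QUANTUM
              cmd <- dispatch(controlEvent("tick", t))
            }
          }
          spent <- spent + (t - tWindow)
        }
        if (!is.na(cmd) && startsWith(cmd, "rotate_")) {
          executed <- sub("rotate_", "", cmd)
          if (executed != needed) totNavErr <<- totNavErr + 1
          offset <- offset + if (executed == "left") -1L else 1L
        }
      }
      totImag <<- totImag + imag
      rotTimes <<- c(rotTimes, spent)
      # blink out of the rotation state back to idle
      t <<- t + QUANTUM
      log("blink", "exit-rotation")
      dispatch(controlEvent("blink", t))
    }

    for (action in user@route) {
      if (action == "forward") walkSegment() else turnSegment(action)
    }

    eventsDf <- if (length(events)) do.call(rbind, events) else
      data.frame(time = numeric(), kind = character(), detail = character())
    metrics <- RotationMetrics(
      noError = if (nRot) totErr / nRot else 0,
      noNavigationError = if (nRot) totNavErr / nRot else 0,
      noImagination = if (nRot) totImag / nRot else 0,
      nRotations = nRot,
      counts = c(errors = totErr, navErrors = totNavErr,
                 imaginations = totImag)
    )
    new("SimResult",
      events = eventsDf, trajectory = trajectory, metrics = metrics,
      completed = completed, totalTime = t,
      commandTimes = list(walk = walkTimes, rotation = rotTimes)
    )
  })
}

#' Expected imaginations per intended rotation (closed form)
#'
#' Analytic expectation of the number of imagination trials needed to
#' achieve one net intended rotation, as a function of the per-trial
#' accuracy `p`:
#' \describe{
#'   \item{NE}{each trial executes a +1/-1 rotation step, so the count is
#'     a first-passage time of a biased random walk: `1/(2p - 1)`.}
#'   \item{DC}{pairs execute +1 with probability `p^2`, -1 with
#'     `(1-p)^2`, nothing otherwise; drift per pair is `2p - 1`, giving
#'     `2/(2p - 1)`.}
#'   \item{EC}{each trial executes; a blink (reliability `q`) vetoes wrong
#'     arrows, so a step is +1 with probability `p + (1-p) q`, giving
#'     `1/(2(p + (1-p) q) - 1)` — exactly 1 when `q = 1`.}
#' }
#'
#' @param strategy `NE`, `DC` or `EC`.
#' @param p per-trial classification accuracy.
#' @param q blink reliability (EC only).
#' @return expected imaginations per net intended rotation.
#' @examples
#' expectedImaginations("NE", 0.75) # 2
#' expectedImaginations("DC", 1)    # 2
#' expectedImaginations("EC", 0.8)  # 1
#' @export
expectedImaginations <- function(strategy = c("NE", "DC", "EC"), p, q = 1) {
  strategy <- match.arg(strategy)
  stopIf(p < 0 || p > 1, "p must lie in [0,1]")
  if (strategy %in% c("NE", "DC")) {
    stopIf(p <= 0.5,
           "expected imaginations diverge for p <= 0.5 under %s", strategy)
    return(if (strategy == "NE") 1 / (2 * p - 1) else 2 / (2 * p - 1))
  }
  pEff <- p + (1 - p) * q
  stopIf(pEff <= 0.5, "expected imaginations diverge: effective accuracy <= 0.5")
  1 / (2 * pEff - 1)
}

#' Monte-Carlo rotation-strategy simulation
#'
#' Vectorised simulation of `n` independent intended rotations under one
#' strategy: each walk runs the imagination/execution process until the
#' net intended rotation is achieved, counting imaginations,
#' misclassifications and executed wrong rotations.
#'
#' @param strategy `NE`, `DC` or `EC`.
#' @param p per-trial classification accuracy (> 0.5 for NE/DC).
#' @param n number of simulated rotations.
#' @param q blink reliability (EC only).
#' @param seed integer seed.
#' @return a list with means `imaginations`, `errors`, `navErrors` (per
#'   intended rotation) and the full `imaginations` sample in
#'   `imaginationCounts`.
#' @export
mcImaginations <- function(strategy = c("NE", "DC", "EC"), p, n = 1e5,
                           q = 1, seed = 1L) {
  strategy <- match.arg(strategy)
  withSeed(seed, {
    offset <- rep(1L, n)     # net rotations still needed
    imag <- numeric(n)
    errs <- numeric(n)
    navErrs <- numeric(n)
    active <- offset != 0L
    guard <- 0L
    while (any(active)) {
      guard <- guard + 1L
      stopIf(guard > 1e6, "random walk failed to absorb; p too low?")
      k <- sum(active)
      if (strategy == "NE") {
        ok <- stats::runif(k) < p
        imag[active] <- imag[active] + 1
        errs[active] <- errs[active] + !ok
        navErrs[active] <- navErrs[active] + !ok
        offset[active] <- offset[active] - ifelse(ok, 1L, -1L)
      } else if (strategy == "DC") {
        ok1 <- stats::runif(k) < p
        ok2 <- stats::runif(k) < p
        imag[active] <- imag[active] + 2
        errs[active] <- errs[active] + !ok1 + !ok2
        exec <- ok1 == ok2 # both correct or both wrong
        wrong <- exec & !ok1
        navErrs[active] <- navErrs[active] + wrong
        offset[active] <- offset[active] -
          ifelse(exec, ifelse(ok1, 1L, -1L), 0L)
      } else { # EC
        ok <- stats::runif(k) < p
        veto <- stats::runif(k) < q # blink detected when arrow is wrong
        imag[active] <- imag[active] + 1
        errs[active] <- errs[active] + !ok
        plus <- ok | veto
        navErrs[active] <- navErrs[active] + !plus
        offset[active] <- offset[active] - ifelse(plus, 1L, -1L)
      }
      active <- offset != 0L
    }
    list(
      imaginations = mean(imag), errors = mean(errs),
      navErrors = mean(navErrs), imaginationCounts = imag
    )
  })
}

#' Compare rotation error-control strategies on an accuracy grid
#'
#' Monte-Carlo metrics for every strategy at every accuracy in `pGrid`,
#' side by side with the analytic [expectedImaginations()] expectation.
#'
#' @param pGrid accuracies to evaluate (each > 0.5).
#' @param n simulated rotations per cell.
#' @param q blink reliability for EC.
#' @param seed integer seed.
#' @return a data.frame with one row per (strategy, p): `noImagination`,
#'   `noError`, `noNavigationError`, and `expected` (closed form).
#' @export
compareStrategies <- function(pGrid = c(0.6, 0.7, 0.8, 0.9), n = 1e4,
                              q = 1, seed = 1L) {
  rows <- list()
  for (strategy in NAV_STRATEGIES) {
    for (i in seq_along(pGrid)) {
      p <- pGrid[i]
      mc <- mcImaginations(strategy, p, n = n, q = q,
                           seed = subSeed(seed, 100 * i + match(
                             strategy, NAV_STRATEGIES
                           )))
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strategy, p = p,
        noImagination = mc$imaginations,
        noError = mc$errors,
        noNavigationError = mc$navErrors,
        expected = expectedImaginations(strategy, p, q)
      )
    }
  }
  do.call(rbind, rows)
}
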
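#' Construct a street graph
#'
#' @param nodes data.frame with columns `id`, `x`, `y` and optionally
#'   `junction` (logical).
#' @param edges data.frame with columns `from`, `to`; set
#'   `bidirectional = TRUE` to add the reverse of every edge.
#' @param start initial agent node (default the first node).
#' @param heading initial heading, a neighbouring node id (default the
#'   first outgoing neighbour).
#' @param bidirectional add reverse edges (default TRUE).
#' @param autoFlagJunctions additionally flag every node with three or
#'   more distinct neighbours as a junction.
#' @return a [StreetGraph].
#' @examples
#' w <- lineWorld(5, junctionAt = 4)
#' junctionOracle(advanceAgent(w))
#' @export
streetGraph <- function(nodes, edges, start = nodes$id[1], heading = NULL,
                        bidirectional = TRUE, autoFlagJunctions = FALSE) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (is.null(nodes$junction)) nodes$junction <- FALSE
  nodes$id <- as.integer(nodes$id)
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (bidirectional && nrow(edges)) {
    edges <- unique(rbind(edges[c("from", "to")],
                          data.frame(from = edges$to, to = edges$from)))
  }
  if (autoFlagJunctions && nrow(edges)) {
    deg <- table(edges$from)
    busy <- as.integer(names(deg)[deg >= 3])
    nodes$junction <- nodes$junction | nodes$id %in% busy
  }
  if (is.null(heading)) {
    nbr <- edges$to[edges$from == start]
    heading <- if (length(nbr)) nbr[1] else NA_integer_
  }
  new("StreetGraph",
    nodes = nodes, edges = edges,
    agentNode = as.integer(start), agentHeading = as.integer(heading)
  )
}

#' A straight street of `n` nodes
#'
#' Convenience world: nodes 1..n on a line, bidirectional edges, agent at
#' node 1 facing node 2.
#'
#' @param n number of nodes (>= 2).
#' @param junctionAt node ids flagged as junctions.
#' @return a [StreetGraph].
#' @export
lineWorld <- function(n, junctionAt = integer()) {
  stopIf(n < 2, "a street needs at least two nodes")
  streetGraph(
    nodes = data.frame(id = 1:n, x = seq_len(n), y = 0,
                       junction = 1:n %in% junctionAt),
    edges = data.frame(from = 1:(n - 1), to = 2:n)
  )
}

setMethod("show", "StreetGraph", function(object) {
  cat(sprintf(
    "StreetGraph: %d nodes (%d junctions), %d directed edges; agent at %d facing %s\n",
    nrow(object@nodes), sum(object@nodes$junction), nrow(object@edges),
    object@agentNode,
    ifelse(is.na(object@agentHeading), "nowhere", object@agentHeading)
  ))
})

neighborsOf <- function(world, node) {
  sort(unique(world@edges$to[world@edges$from == node]))
}

nodeXY <- function(world, id) {
  i <- match(id, world@nodes$id)
  c(world@nodes$x[i], world@nodes$y[i])
}

# neighbours of `node` ordered counter-clockwise by direction
neighborsByAngle <- function(world, node) {
  nbr <- neighborsOf(world, node)
  if (!length(nbr)) return(integer())
  p0 <- nodeXY(world, node)
  ang <- vapply(nbr, function(id) {
    p <- nodeXY(world, id)
    atan2(p[2] - p0[2], p[1] - p0[1])
  }, numeric(1))
  nbr[order(ang)]
}

#' Rotate the agent's heading
#'
#' Moves the heading to the next available edge direction
#' counter-clockwise (`left`) or clockwise (`right`) — one discrete
#' heading increment per rotation command.
#'
#' @param world a [StreetGraph].
#' @param direction `"left"` or `"right"`.
#' @return the updated [StreetGraph].
#' @export
rotateAgent <- function(world, direction = c("left", "right")) {
  direction <- match.arg(direction)
  nbr <- neighborsByAngle(world, world@agentNode)
  if (length(nbr) < 2L) return(world)
  i <- match(world@agentHeading, nbr)
  step <- if (direction == "left") 1L else -1L
  world@agentHeading <- nbr[((i - 1L + step) %% length(nbr)) + 1L]
  world
}

#' Advance the agent one edge along its heading
#'
#' Moves the agent to the node it faces; the new heading continues as
#' straight ahead as the street allows (the outgoing direction closest to
#' the incoming one, avoiding an immediate U-turn when possible).
#'
#' @param world a [StreetGraph].
#' @return the updated [StreetGraph].
#' @export
advanceAgent <- function(world) {
  stopIf(is.na(world@agentHeading), "agent has no heading to walk along")
  from <- world@agentNode
  world@agentNode <- world@agentHeading
  nbr <- neighborsOf(world, world@agentNode)
  fwdCands <- setdiff(nbr, from)
  if (!length(fwdCands)) fwdCands <- nbr # dead end: only way is back
  if (!length(fwdCands)) {
    world@agentHeading <- NA_integer_
    return(world)
  }
  pIn <- nodeXY(world, world@agentNode) - nodeXY(world, from)
  angIn <- atan2(pIn[2], pIn[1])
  dev <- vapply(fwdCands, function(id) {
    p <- nodeXY(world, id) - nodeXY(world, world@agentNode)
    d <- atan2(p[2], p[1]) - angIn
    abs(atan2(sin(d), cos(d)))
  }, numeric(1))
  world@agentHeading <- fwdCands[which.min(dev)]
  world
}

#' Junction look-ahead oracle
#'
#' `TRUE` iff the node ahead along the agent's heading is flagged as a
#' junction — the middle-level walk stop is evaluated before entering the
#' node, i.e. the agent halts in front of the junction.
#'
#' @param world a [StreetGraph].
#' @param node,heading pose to query (defaults: the agent's).
#' @return logical.
#' @export
junctionOracle <- function(world, node = world@agentNode,
                           heading = world@agentHeading) {
  stopIf(!node %in% world@nodes$id, "pose is not on the graph")
  if (is.na(heading)) return(FALSE)
  stopIf(!heading %in% neighborsOf(world, node),
         "heading does not follow an existing edge")
  isTRUE(world@nodes$junction[match(heading, world@nodes$id)])
}

EVENT_KINDS <- c("classified_left", "classified_right", "classified_flexion",
                 "blink", "tick", "junction_reached")

#' Construct a control event
#'
#' @param kind one of `classified_left`, `classified_right`,
#'   `classified_flexion`, `blink`, `tick`, `junction_reached`.
#' @param timestamp event time in seconds.
#' @return a list with class `ControlEvent`.
#' @export
controlEvent <- function(kind, timestamp = 0) {
  stopIf(!kind %in% EVENT_KINDS, "malformed event kind '%s'", kind)
  structure(list(kind = kind, timestamp = timestamp), class = "ControlEvent")
}

#' Construct a navigation automaton state
#'
#' @param mode control level, `"low"` or `"middle"`.
#' @param strategy rotation error-control strategy: `"NE"` (none),
#'   `"DC"` (double confirmation) or `"EC"` (blink error correction).
#' @param state initial discrete state (default `idle`).
#' @return a [NavState].
#' @export
NavState <- function(mode = c("low", "middle"), strategy = c("NE", "DC", "EC"),
                     state = "idle") {
  new("NavState",
    state = state, mode = match.arg(mode), strategy = match.arg(strategy),
    pendingDirection = NA_character_, clock = 0, stateEntered = 0
  )
}

setMethod("show", "NavState", function(object) {
  cat(sprintf(
    "NavState: %s (%s-level, %s)%s, clock %.1f s\n",
    object@state, object@mode, object@strategy,
    if (is.na(object@pendingDirection)) "" else
      sprintf(", pending %s", object@pendingDirection),
    object@clock
  ))
})

enterState <- function(state, name) {
  state@state <- name
  state@stateEntered <- state@clock
  if (!name %in% c("rotation", "correction")) {
    state@pendingDirection <- NA_character_
  }
  state
}

oppositeDirection <- function(d) c(left = "right", right = "left")[[d]]

SWITCH_DWELL <- 2     # seconds in the switch transition state
CORRECTION_DWELL <- 2 # seconds of the EC correction window

#' One rotation-strategy step
#'
#' Advances the active rotation error-control strategy with one
#' classification (and, in the EC correction state, a blink verdict):
#' \describe{
#'   \item{NE}{every classification executes immediately.}
#'   \item{DC}{the first classification displays an arrow; a second,
#'     identical classification executes; a mismatch resets with no
#'     execution.}
#'   \item{EC}{a classification displays an arrow and opens the correction
#'     window; a blink inside the window executes the OPPOSITE direction,
#'     no blink confirms the displayed one.}
#' }
#'
#' @param state a [NavState] in the `rotation` (or, under EC,
#'   `correction`) state.
#' @param classification `"left"` or `"right"` (ignored in the EC
#'   correction state).
#' @param blink logical; under EC in the correction state, whether a blink
#'   was detected inside the window.
#' @return a list with the updated `state` and `executed` (`"left"`,
#'   `"right"` or `NA` when no rotation was executed).
#' @export
rotationStrategyStep <- function(state, classification = NA_character_,
                                 blink = FALSE) {
  stopIf(!state@state %in% c("rotation", "correction"),
         "rotation strategy stepped outside the rotation state ('%s')",
         state@state)
  executed <- NA_character_
  if (state@strategy == "NE") {
    stopIf(!classification %in% c("left", "right"),
           "NE step needs a left/right classification")
    executed <- classification
  } else if (state@strategy == "DC") {
    stopIf(state@state != "rotation", "DC has no correction state")
    stopIf(!classification %in% c("left", "right"),
           "DC step needs a left/right classification")
    if (is.na(state@pendingDirection)) {
      state@pendingDirection <- classification # arrow displayed
    } else if (state@pendingDirection == classification) {
      executed <- classification
      state@pendingDirection <- NA_character_
    } else {
      state@pendingDirection <- NA_character_ # mismatch: reset, no execution
    }
  } else { # EC
    if (state@state == "rotation") {
      stopIf(!classification %in% c("left", "right"),
             "EC step needs a left/right classification")
      state@pendingDirection <- classification # arrow displayed
      state <- enterState(state, "correction")
    } else {
      executed <- if (blink) oppositeDirection(state@pendingDirection)
                  else state@pendingDirection
      state@pendingDirection <- NA_character_
      state <- enterState(state, "rotation")
    }
  }
  list(state = state, executed = executed)
}

#' Drive the navigation automaton with one event
#'
#' Deterministic transition function of the shared-control automaton. A
#' detected two-hand flexion in `idle` enters the 2 s `switch` state; a
#' blink there selects `rotation`, while doing nothing for 2 s starts
#' `walk`, which moves the agent forward every second. Low-level walking
#' stops on a blink; middle-level walking stops by itself in front of a
#' junction. In the rotation states, left/right classifications are fed to
#' the active error-control strategy and executed rotations turn the
#' agent's heading. The automaton is total: events that are meaningless in
#' the current state leave it unchanged.
#'
#' @param state a [NavState].
#' @param event a [controlEvent()].
#' @param world a [StreetGraph] (moved/rotated as commands execute).
#' @return a list with `state`, `command` (`NA` or one of `forward`,
#'   `stop`, `arrow_left`, `arrow_right`, `rotate_left`, `rotate_right`)
#'   and the updated `world`.
#' @export
handleEvent <- function(state, event, world) {
  stopIf(!inherits(event, "ControlEvent"), "malformed event")
  stopIf(event$timestamp < state@clock,
         "event timestamps must be nondecreasing")
  state@clock <- event$timestamp
  command <- NA_character_
  kind <- event$kind

  if (state@state == "idle") {
    if (kind == "classified_flexion") state <- enterState(state, "switch")

  } else if (state@state == "switch") {
    if (kind == "blink") {
      state <- enterState(state, "rotation")
    } else if (kind == "tick" &&
               state@clock - state@stateEntered >= SWITCH_DWELL) {
      state <- enterState(state, "walk")
    }

  } else if (state@state == "walk") {
    if (kind == "blink" && state@mode == "low") {
      state <- enterState(state, "idle")
      command <- "stop"
    } else if (kind == "junction_reached") {
      state <- enterState(state, "idle")
      command <- "stop"
    } else if (kind == "tick") {
      elapsed <- state@clock - state@stateEntered
      onSecond <- elapsed > 0 &&
        abs(elapsed - round(elapsed)) < 1e-9
      if (onSecond) {
        if (state@mode == "middle" && junctionOracle(world)) {
          state <- enterState(state, "idle")
          command <- "stop" # halt in front of the junction, do not enter
        } else {
          world <- advanceAgent(world)
          command <- "forward"
        }
      }
    }

  } else if (state@state == "rotation") {
    if (kind %in% c("classified_left", "classified_right")) {
      dir <- sub("classified_", "", kind)
      out <- rotationStrategyStep(state, dir)
      state <- out$state
      if (!is.na(out$executed)) {
        world <- rotateAgent(world, out$executed)
        command <- paste0("rotate_", out$executed)
      } else if (!is.na(state@pendingDirection)) {
        command <- paste0("arrow_", state@pendingDirection)
      }
    } else if (kind == "blink") {
      state <- enterState(state, "idle") # stop rotating
      command <- "stop"
    }

  } else if (state@state == "correction") {
    if (kind == "blink") {
      out <- rotationStrategyStep(state, blink = TRUE)
      state <- out$state
      world <- rotateAgent(world, out$executed)
      command <- paste0("rotate_", out$executed)
    } else if (kind == "tick" &&
               state@clock - state@stateEntered >= CORRECTION_DWELL) {
      out <- rotationStrategyStep(state, blink = FALSE)
      state <- out$state
      world <- rotateAgent(world, out$executed)
      command <- paste0("rotate_", out$executed)
    }
  }

  list(state = state, command = command, world = world)
}
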
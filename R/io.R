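#' Save / load a trial set
#'
#' Datasets are stored as a single serialized bundle (epoch matrices,
#' labels, session indices and channel metadata).
#'
#' @param trials a [TrialSet].
#' @param path file path (conventionally `.rds`).
#' @return `saveTrialSet` returns `path` invisibly; `loadTrialSet` the
#'   restored [TrialSet].
#' @export
saveTrialSet <- function(trials, path) {
  stopIf(!is(trials, "TrialSet"), "trials must be a TrialSet")
  saveRDS(trials, path)
  invisible(path)
}

#' @rdname saveTrialSet
#' @export
loadTrialSet <- function(path) {
  obj <- readRDS(path)
  stopIf(!is(obj, "TrialSet"), "'%s' does not contain a TrialSet", path)
  validObject(obj)
  obj
}

#' Save / load a fitted decoder pipeline
#'
#' The bundle holds both CSP banks, both classifiers (weights, feature
#' normalisation, training log), the filter-bank specification and the
#' thresholds. A YAML sidecar with the band list and training settings is
#' written next to the bundle for auditability.
#'
#' @param pipeline a fitted [DecoderPipeline].
#' @param path file path (conventionally `.rds`).
#' @param writeSidecar write `<path>.yaml` with a human-readable summary.
#' @return `savePipeline` returns `path` invisibly; `loadPipeline` the
#'   restored [DecoderPipeline].
#' @export
savePipeline <- function(pipeline, path, writeSidecar = TRUE) {
  stopIf(!is(pipeline, "DecoderPipeline"), "pipeline must be a DecoderPipeline")
  saveRDS(pipeline, path)
  if (writeSidecar) {
    cfg <- pipeline@flexionModel@config
    side <- list(
      samplingRate = pipeline@samplingRate,
      montage = pipeline@montage,
      referenceChannels = pipeline@referenceChannels,
      bands = apply(bandEdges(pipeline@bankSpec), 1,
                    function(b) sprintf("%g-%g Hz", b[1], b[2])),
      window = list(length = pipeline@windowSpec@windowLength,
                    hop = pipeline@windowSpec@hop),
      thresholds = list(artifactMax = pipeline@thresholds@artifactMax,
                        blinkMax = pipeline@thresholds@blinkMax),
      training = list(
        initialLearningRate = cfg@initialLearningRate,
        lrDecayFactor = cfg@lrDecayFactor,
        maxIterations = cfg@maxIterations,
        l2Penalty = cfg@l2Penalty,
        dropoutRate = cfg@dropoutRate,
        hiddenUnits = cfg@hiddenUnits
      ),
      heldOutAccuracy = as.list(pipeline@accuracies)
    )
    yaml::write_yaml(side, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname savePipeline
#' @export
loadPipeline <- function(path) {
  obj <- readRDS(path)
  stopIf(!is(obj, "DecoderPipeline"), "'%s' does not contain a DecoderPipeline",
         path)
  obj
}

#' Load a street graph scenario from YAML or JSON
#'
#' The scenario file holds a `nodes` list (each with `id`, `x`, `y` and
#' optional `junction` flag), an `edges` list (each with `from`, `to`),
#' and optional `start`/`heading` node ids. See the bundled scenarios
#' under `system.file("extdata", package = "BCInav")`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` scenario.
#' @param autoFlagJunctions flag nodes with three or more neighbours.
#' @return a [StreetGraph].
#' @examples
#' p <- system.file("extdata", "museum_path.yaml", package = "BCInav")
#' loadStreetGraph(p)
#' @export
loadStreetGraph <- function(path, autoFlagJunctions = FALSE) {
  stopIf(!file.exists(path), "scenario file '%s' not found", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  stopIf(is.null(raw$nodes) || is.null(raw$edges),
         "scenario must define nodes and edges")
  asDf <- function(x) {
    if (is.data.frame(x)) x else do.call(rbind, lapply(x, as.data.frame))
  }
  nodes <- asDf(raw$nodes)
  # YAML 1.1 parses a bare `y` key as boolean TRUE; map it back
  if (is.null(nodes$y) && any(names(nodes) %in% c("TRUE.", "TRUE"))) {
    names(nodes)[names(nodes) %in% c("TRUE.", "TRUE")] <- "y"
  }
  if (is.null(nodes$junction)) nodes$junction <- FALSE
  nodes$junction[is.na(nodes$junction)] <- FALSE
  streetGraph(
    nodes = nodes, edges = asDf(raw$edges),
    start = if (!is.null(raw$start)) raw$start else nodes$id[1],
    heading = raw$heading,
    autoFlagJunctions = autoFlagJunctions
  )
}

#' Export a simulation result
#'
#' Writes the event log as CSV, the rotation metrics as JSON and returns
#' the trajectory as a node-id vector — the machine-readable mirror of a
#' run's on-screen record.
#'
#' @param result a [SimResult].
#' @param eventsCsv,metricsJson output paths (`NULL` to skip either).
#' @return the trajectory (integer node ids), invisibly.
#' @export
exportSimResult <- function(result, eventsCsv = NULL, metricsJson = NULL) {
  stopIf(!is(result, "SimResult"), "result must be a SimResult")
  if (!is.null(eventsCsv)) {
    utils::write.csv(result@events, eventsCsv, row.names = FALSE)
  }
  if (!is.null(metricsJson)) {
    m <- result@metrics
    jsonlite::write_json(
      list(
        noError = m@noError, noNavigationError = m@noNavigationError,
        noImagination = m@noImagination, nRotations = m@nRotations,
        totalTime = result@totalTime, completed = result@completed
      ),
      metricsJson, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(result@trajectory)
}
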
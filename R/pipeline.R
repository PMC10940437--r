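#' Run the full analysis pipeline
#'
#' Executes the complete chain on one recording: dark/flat correction,
#' phase splitting, within-group drift registration, segmentation on the
#' stretch phase, cross-group transform estimation and ROI mapping, trace
#' extraction, normalisation and peak detection, per-cell classification and
#' the per-sample summary. Inputs are taken from the config's paths, or can
#' be supplied in memory (a rendered scene bundle). Every output carries a
#' provenance block with the configuration hash, all parameter values and
#' the package version; deterministic stages are bit-identical under rerun.
#'
#' @param config an \linkS4class{ExperimentConfig}.
#' @param stack optional in-memory \linkS4class{FrameStack} (overrides
#'   \code{config@paths$stack}).
#' @param corrections optional \linkS4class{CorrectionFrames}.
#' @param outDir optional output directory; when given, the trace table,
#'   record table, label maps, transforms and provenance are written there.
#' @param sampleId sample identifier.
#' @return A list: \code{records} (cell-record data.frame), \code{traces},
#'   \code{labelMaps}, \code{transforms}, \code{summary}, \code{provenance}.
#' @export
runPipeline <- function(config, stack = NULL, corrections = NULL,
                        outDir = NULL, sampleId = "sample") {
  stopifnot(is(config, "ExperimentConfig"))
  schedule <- config@schedule
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(stack) && is.null(config@paths$stack))
    stop("pipeline stage 'input': no stack path in config and none supplied")
  if (config@correction && is.null(corrections) &&
      (is.null(config@paths$dark) || is.null(config@paths$flat)))
    stop("pipeline stage 'input': correction enabled but dark/flat path missing ",
         "(dark: ", if (is.null(config@paths$dark)) "<unset>" else config@paths$dark,
         ", flat: ", if (is.null(config@paths$flat)) "<unset>" else config@paths$flat,
         ")")
  if (config@correction && is.null(corrections))
    corrections <- stage("input",
      readCorrectionTIFF(config@paths$dark, config@paths$flat))
  if (is.null(stack))
    stack <- stage("input",
      readStackTIFF(config@paths$stack, schedule@framePeriod, schedule))

  if (config@correction)
    stack <- stage("correct", correctStack(stack, corrections))
  phaseStacks <- stage("split", splitPhases(stack, schedule))
  regs <- stage("register", lapply(phaseStacks, function(st)
    if (nFrames(st) > 0L) registerDrift(st) else list(stack = st, transforms = list())))
  phaseStacks <- lapply(regs, `[[`, "stack")

  labStretch <- stage("segment", segmentCells(
    phaseStacks$stretch, threshold = config@segmentation$threshold,
    minArea = config@segmentation$min_area,
    smoothSigma = config@segmentation$smooth_sigma,
    tolerance = config@segmentation$tolerance))

  proj <- lapply(phaseStacks, function(st) apply(st@frames, 1:2, max))
  tPre <- stage("map", estimatePhaseTransform(proj$stretch, proj$pre))
  tRel <- stage("map", estimatePhaseTransform(proj$stretch, proj$release))
  labelMaps <- list(
    pre = stage("map", mapRois(labStretch, tPre, coordinateFrame = "pre")),
    stretch = labStretch,
    release = stage("map", mapRois(labStretch, tRel, coordinateFrame = "release")))

  extracted <- stage("extract",
    extractTraces(phaseStacks, labelMaps, schedule, sampleId = sampleId))
  records <- stage("classify",
    classifyCells(extracted$traces, schedule, config@params,
                  incompleteIds = extracted$incomplete))
  summary <- stage("summarize", summarizeSample(records))

  provenance <- list(
    package = "stretchCa",
    version = as.character(packageVersion("stretchCa")),
    config = configToList(config),
    config_hash = rlang::hash(configToList(config)),
    n_cells_segmented = nCells(labStretch),
    dropped_labels = list(pre = attr(labelMaps$pre, "dropped"),
                          release = attr(labelMaps$release, "dropped")))

  out <- list(records = records, traces = extracted$traces,
              labelMaps = labelMaps,
              transforms = list(stretch_to_pre = tPre, stretch_to_release = tRel,
                                drift = lapply(regs, `[[`, "transforms")),
              summary = summary, provenance = provenance)
  if (!is.null(outDir)) writeReport(out, outDir)
  out
}

#' Write a pipeline output bundle to disk
#'
#' @param bundle output of \code{\link{runPipeline}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
writeReport <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "records.csv"),
             traces = file.path(dir, "traces.csv"),
             labels = file.path(dir, "labels_stretch.tif"),
             transforms = file.path(dir, "transforms.json"),
             provenance = file.path(dir, "provenance.json"))
  write.csv(bundle$records, paths[["records"]], row.names = FALSE)
  writeTracesCSV(bundle$traces, paths[["traces"]])
  writeLabelTIFF(bundle$labelMaps$stretch, paths[["labels"]])
  tr2list <- function(tr) list(scale = tr@scale, rotation = tr@rotation,
                               translation = tr@translation, center = tr@center)
  jsonlite::write_json(list(
      stretch_to_pre = tr2list(bundle$transforms$stretch_to_pre),
      stretch_to_release = tr2list(bundle$transforms$stretch_to_release)),
    paths[["transforms"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$provenance, paths[["provenance"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
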
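#' Experiment configuration
#'
#' Bundles the phase schedule, condition flags, analysis and segmentation
#' parameters and input paths for one pipeline run. Configurations are read
#' from and written to YAML; unknown keys are rejected so that typos cannot
#' silently fall back to defaults.
#'
#' @slot schedule a \linkS4class{PhaseSchedule}.
#' @slot params an \linkS4class{AnalysisParams}.
#' @slot segmentation list: \code{threshold} (\code{"otsu"} or number),
#'   \code{min_area}, \code{smooth_sigma}, \code{tolerance}.
#' @slot paths list: \code{stack}, \code{dark}, \code{flat} (may be empty
#'   for in-memory runs).
#' @slot correction logical, apply dark/flat correction.
#' @slot seed integer seed for any stochastic stage.
#' @export
setClass("ExperimentConfig",
  representation(schedule = "PhaseSchedule", params = "AnalysisParams",
                 segmentation = "list", paths = "list",
                 correction = "logical", seed = "integer"))

CONFIG_KEYS <- c("phases", "frame_period_s", "stretch_percent", "condition",
                 "analysis", "segmentation", "paths", "correction", "seed")
ANALYSIS_KEYS <- c("prominence_threshold", "s0_window_s", "spontaneous_min_peaks",
                   "sustained_delta", "retention_fraction",
                   "initial_response_window_s", "baseline_percentile",
                   "elevation_threshold", "spontaneous_includes_pii")
SEGMENTATION_KEYS <- c("threshold", "min_area", "smooth_sigma", "tolerance")

#' Default experiment configuration
#'
#' Four one-minute phases at 10 frames/s, 15 percent stretch, no drugs,
#' default analysis and segmentation parameters.
#'
#' @return An \linkS4class{ExperimentConfig}.
#' @export
defaultConfig <- function() {
  new("ExperimentConfig", schedule = phaseSchedule(), params = analysisParams(),
      segmentation = list(threshold = "otsu", min_area = 30,
                          smooth_sigma = 1, tolerance = 0.05),
      paths = list(), correction = TRUE, seed = 1L)
}

#' Load a configuration from YAML
#'
#' Validates the document against the configuration schema: unknown keys
#' anywhere are rejected, numeric fields must be positive where required,
#' and phase windows must be contiguous. \code{writeConfig} is the inverse;
#' \code{loadConfig(writeConfig(x))} reproduces \code{x}.
#'
#' @param path YAML file path.
#' @return An \linkS4class{ExperimentConfig}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  doc <- yaml::read_yaml(path)
  configFromList(doc)
}

#' @rdname loadConfig
#' @param doc a named list with the YAML document structure.
#' @export
configFromList <- function(doc) {
  bad <- setdiff(names(doc), CONFIG_KEYS)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  need <- function(x, default) if (is.null(x)) default else x
  fp <- need(doc$frame_period_s, 0.1)
  if (!is.numeric(fp) || fp <= 0) stop("frame_period_s must be positive")
  ph <- need(doc$phases, list(starts = 60 * 0:3, ends = 60 * 1:4))
  cond <- need(doc$condition, list(gsmtx4 = FALSE, yoda1 = FALSE))
  badc <- setdiff(names(cond), c("gsmtx4", "yoda1"))
  if (length(badc)) stop("unknown condition keys: ", paste(badc, collapse = ", "))
  schedule <- phaseSchedule(starts = unlist(ph$starts), ends = unlist(ph$ends),
                            framePeriod = fp,
                            stretchPercent = need(doc$stretch_percent, 15),
                            gsmtx4 = isTRUE(cond$gsmtx4),
                            yoda1 = isTRUE(cond$yoda1))
  an <- need(doc$analysis, list())
  bada <- setdiff(names(an), ANALYSIS_KEYS)
  if (length(bada)) stop("unknown analysis keys: ", paste(bada, collapse = ", "))
  params <- analysisParams(
    prominenceThreshold = need(an$prominence_threshold, 0.3),
    s0WindowS = need(an$s0_window_s, 3),
    spontaneousMinPeaks = need(an$spontaneous_min_peaks, 2),
    sustainedDelta = need(an$sustained_delta, 1.5),
    retentionFraction = need(an$retention_fraction, 0.2),
    initialResponseWindowS = need(an$initial_response_window_s, 20),
    baselinePercentile = need(an$baseline_percentile, 10),
    elevationThreshold = need(an$elevation_threshold, 0.1),
    spontaneousIncludesPII = isTRUE(an$spontaneous_includes_pii))
  seg <- need(doc$segmentation, list())
  bads <- setdiff(names(seg), SEGMENTATION_KEYS)
  if (length(bads)) stop("unknown segmentation keys: ", paste(bads, collapse = ", "))
  segmentation <- list(threshold = need(seg$threshold, "otsu"),
                       min_area = need(seg$min_area, 30),
                       smooth_sigma = need(seg$smooth_sigma, 1),
                       tolerance = need(seg$tolerance, 0.05))
  if (segmentation$min_area < 0) stop("segmentation min_area must be >= 0")
  paths <- need(doc$paths, list())
  badp <- setdiff(names(paths), c("stack", "dark", "flat"))
  if (length(badp)) stop("unknown path keys: ", paste(badp, collapse = ", "))
  new("ExperimentConfig", schedule = schedule, params = params,
      segmentation = segmentation, paths = paths,
      correction = isTRUE(need(doc$correction, TRUE)),
      seed = as.integer(need(doc$seed, 1L)))
}

#' @rdname loadConfig
#' @param config an \linkS4class{ExperimentConfig}.
#' @export
configToList <- function(config) {
  s <- config@schedule; p <- config@params
  list(phases = list(starts = as.numeric(s@starts), ends = as.numeric(s@ends)),
       frame_period_s = s@framePeriod,
       stretch_percent = s@stretchPercent,
       condition = list(gsmtx4 = s@gsmtx4, yoda1 = s@yoda1),
       analysis = list(prominence_threshold = p@prominenceThreshold,
                       s0_window_s = p@s0WindowS,
                       spontaneous_min_peaks = p@spontaneousMinPeaks,
                       sustained_delta = p@sustainedDelta,
                       retention_fraction = p@retentionFraction,
                       initial_response_window_s = p@initialResponseWindowS,
                       baseline_percentile = p@baselinePercentile,
                       elevation_threshold = p@elevationThreshold,
                       spontaneous_includes_pii = p@spontaneousIncludesPII),
       segmentation = config@segmentation,
       paths = config@paths,
       correction = config@correction,
       seed = config@seed)
}

#' @rdname loadConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(configToList(config), path, precision = 15L)
  invisible(path)
}

setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig\n")
  show(object@schedule)
  cat(sprintf("  segmentation: threshold %s, min_area %g | correction: %s | seed %d\n",
      format(object@segmentation$threshold), object@segmentation$min_area,
      object@correction, object@seed))
})
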
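#' @import methods
#' @importFrom stats quantile rnorm rpois runif sd median shapiro.test
#'   kruskal.test oneway.test fft setNames qbinom
#' @importFrom utils write.csv read.csv packageVersion
NULL

PHASE_IDS <- c("PI", "PII", "PIII", "PIV")

#' Experimental phase schedule
#'
#' Describes the four one-minute experimental windows of a stretch
#' experiment: \code{PI} (pre-stretch baseline, optionally with a
#' mechanosensitive-channel blocker present), \code{PII} (agonist addition),
#' \code{PIII} (isotropic stretch) and \code{PIV} (release). Windows are
#' half-open \code{[start, end)} and contiguous.
#'
#' @slot starts,ends numeric(4), window boundaries in seconds.
#' @slot framePeriod seconds between consecutive frames (0.1 for 10 Hz).
#' @slot stretchPercent radial stretch applied in \code{PIII} (percent).
#' @slot gsmtx4 logical, blocker present from \code{PI}.
#' @slot yoda1 logical, agonist added at \code{PII}.
#' @export
setClass("PhaseSchedule",
  representation(starts = "numeric", ends = "numeric", framePeriod = "numeric",
                 stretchPercent = "numeric", gsmtx4 = "logical", yoda1 = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@starts) != 4L || length(object@ends) != 4L)
      msg <- c(msg, "schedule must have exactly four phases")
    if (any(object@ends < object@starts))
      msg <- c(msg, "each phase must have end >= start")
    if (length(object@starts) == 4L &&
        any(abs(object@starts[-1] - object@ends[-4]) > 1e-9))
      msg <- c(msg, "phase windows must be contiguous")
    if (length(object@framePeriod) != 1L || !is.finite(object@framePeriod) ||
        object@framePeriod <= 0)
      msg <- c(msg, "framePeriod must be a single positive number")
    if (length(object@stretchPercent) != 1L || object@stretchPercent < 0)
      msg <- c(msg, "stretchPercent must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct a phase schedule
#'
#' @param phaseLength length of each phase in seconds (default 60).
#' @param framePeriod frame period in seconds (default 0.1, i.e. 10 Hz).
#' @param stretchPercent radial stretch magnitude in \code{PIII} (default 15).
#' @param gsmtx4,yoda1 drug condition flags.
#' @param starts,ends explicit window boundaries (override \code{phaseLength}).
#' @return A \linkS4class{PhaseSchedule}.
#' @examples
#' sched <- phaseSchedule()
#' phaseDurations(sched)
#' @export
phaseSchedule <- function(phaseLength = 60, framePeriod = 0.1,
                          stretchPercent = 15, gsmtx4 = FALSE, yoda1 = FALSE,
                          starts = NULL, ends = NULL) {
  if (is.null(starts)) starts <- phaseLength * 0:3
  if (is.null(ends))   ends   <- phaseLength * 1:4
  new("PhaseSchedule", starts = as.numeric(starts), ends = as.numeric(ends),
      framePeriod = as.numeric(framePeriod),
      stretchPercent = as.numeric(stretchPercent),
      gsmtx4 = isTRUE(gsmtx4), yoda1 = isTRUE(yoda1))
}

#' @describeIn phaseSchedule phase window durations in seconds, named by phase.
#' @param schedule a \linkS4class{PhaseSchedule}.
#' @export
phaseDurations <- function(schedule) {
  setNames(schedule@ends - schedule@starts, PHASE_IDS)
}

#' @describeIn phaseSchedule phase index (1..4) of each time point under the
#'   half-open \code{[start, end)} convention; \code{NA} outside the schedule.
#' @param time numeric vector of times in seconds.
#' @export
phaseOfTime <- function(schedule, time) {
  idx <- findInterval(time, c(schedule@starts, schedule@ends[4L]),
                      left.open = FALSE, rightmost.closed = FALSE)
  idx[idx < 1L | idx > 4L | time >= schedule@ends[4L]] <- NA_integer_
  as.integer(idx)
}

setMethod("show", "PhaseSchedule", function(object) {
  cat("PhaseSchedule:", paste(sprintf("%s [%g, %g)", PHASE_IDS,
      object@starts, object@ends), collapse = " "), "\n")
  cat(sprintf("  framePeriod: %g s | stretch: %g%% | GsMTx4: %s | Yoda1: %s\n",
      object@framePeriod, object@stretchPercent, object@gsmtx4, object@yoda1))
})

#' Analysis parameters
#'
#' Numeric thresholds used in trace normalisation, peak detection and
#' response classification. Defaults follow the published analysis protocol:
#' peaks are detected at topographic prominence 0.3 relative units, the
#' normalisation constant is the mean of a 3-s peak-free window, spontaneous
#' activity requires at least two peaks in \code{PI}, and a sustained stretch
#' response requires a baseline elevation of at least 1.5 relative units, 20%
#' of which must be retained through the remainder of the phase.
#'
#' @slot prominenceThreshold minimum topographic prominence of a peak
#'   (relative units, default 0.3).
#' @slot s0WindowS length of the peak-free baseline window for S0 (s, default 3).
#' @slot spontaneousMinPeaks minimum \code{PI} peak count for the
#'   spontaneously-active class (default 2).
#' @slot sustainedDelta minimum baseline elevation over the \code{PII}
#'   baseline for a sustained response (relative units, default 1.5).
#' @slot retentionFraction fraction of the initial elevation that must be
#'   retained in the later two-thirds of the phase (default 0.2).
#' @slot initialResponseWindowS window after stretch/release onset in which
#'   the maximal response peak is sought (s, default 20).
#' @slot baselinePercentile percentile of the relative trace used as the
#'   phase baseline intensity (default 10).
#' @slot elevationThreshold minimum between-phase baseline increase flagged
#'   as an elevation (relative units, default 0.1).
#' @slot spontaneousIncludesPII logical; if \code{TRUE}, peaks in \code{PII}
#'   also count towards spontaneity (default \code{FALSE}).
#' @export
setClass("AnalysisParams",
  representation(prominenceThreshold = "numeric", s0WindowS = "numeric",
                 spontaneousMinPeaks = "numeric", sustainedDelta = "numeric",
                 retentionFraction = "numeric", initialResponseWindowS = "numeric",
                 baselinePercentile = "numeric", elevationThreshold = "numeric",
                 spontaneousIncludesPII = "logical"),
  validity = function(object) {
    msg <- character()
    pos <- c(prominenceThreshold = object@prominenceThreshold,
             s0WindowS = object@s0WindowS,
             spontaneousMinPeaks = object@spontaneousMinPeaks,
             sustainedDelta = object@sustainedDelta,
             initialResponseWindowS = object@initialResponseWindowS,
             baselinePercentile = object@baselinePercentile,
             elevationThreshold = object@elevationThreshold)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad)) msg <- c(msg, paste("must be positive:", paste(bad, collapse = ", ")))
    if (object@retentionFraction <= 0 || object@retentionFraction >= 1)
      msg <- c(msg, "retentionFraction must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Construct analysis parameters
#'
#' @param prominenceThreshold,s0WindowS,spontaneousMinPeaks,sustainedDelta
#'   see \linkS4class{AnalysisParams}.
#' @param retentionFraction,initialResponseWindowS,baselinePercentile see
#'   \linkS4class{AnalysisParams}.
#' @param elevationThreshold,spontaneousIncludesPII see
#'   \linkS4class{AnalysisParams}.
#' @return An \linkS4class{AnalysisParams} object.
#' @export
analysisParams <- function(prominenceThreshold = 0.3, s0WindowS = 3,
                           spontaneousMinPeaks = 2, sustainedDelta = 1.5,
                           retentionFraction = 0.2, initialResponseWindowS = 20,
                           baselinePercentile = 10, elevationThreshold = 0.1,
                           spontaneousIncludesPII = FALSE) {
  new("AnalysisParams",
      prominenceThreshold = prominenceThreshold, s0WindowS = s0WindowS,
      spontaneousMinPeaks = spontaneousMinPeaks, sustainedDelta = sustainedDelta,
      retentionFraction = retentionFraction,
      initialResponseWindowS = initialResponseWindowS,
      baselinePercentile = baselinePercentile,
      elevationThreshold = elevationThreshold,
      spontaneousIncludesPII = isTRUE(spontaneousIncludesPII))
}

setMethod("show", "AnalysisParams", function(object) {
  cat("AnalysisParams\n")
  for (s in slotNames(object))
    cat(sprintf("  %s: %s\n", s, format(slot(object, s))))
})

#' Single-cell fluorescence trace
#'
#' One cell's fluorescence signal sampled at a fixed frame rate, either raw
#' (mean ROI intensity, camera units) or relative (\eqn{S_t/S_0}). Phase tags
#' assign every sample to one of the four experimental windows.
#'
#' @slot cellId,sampleId identifiers.
#' @slot time sample times in seconds, strictly increasing.
#' @slot values signal values, finite.
#' @slot phase integer phase index (1..4) per sample.
#' @slot relative logical; \code{TRUE} once normalised to \eqn{S_t/S_0}.
#' @slot s0 the normalisation constant (NA while raw).
#' @export
setClass("CaTrace",
  representation(cellId = "character", sampleId = "character",
                 time = "numeric", values = "numeric", phase = "integer",
                 relative = "logical", s0 = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@time)
    if (length(object@values) != n || length(object@phase) != n)
      msg <- c(msg, "time, values and phase must have equal length")
    if (n > 1L && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (isTRUE(object@relative) && !(is.finite(object@s0) && object@s0 > 0))
      msg <- c(msg, "relative trace requires s0 > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a single-cell trace
#'
#' @param values signal samples.
#' @param schedule a \linkS4class{PhaseSchedule} supplying the frame period
#'   and phase windows, or \code{NULL} if \code{time} and \code{phase} are
#'   given explicitly.
#' @param time sample times (seconds); derived from the schedule by default.
#' @param phase integer phase tags; derived from the schedule by default.
#' @param cellId,sampleId identifiers.
#' @param relative logical, whether \code{values} are already relative.
#' @param s0 normalisation constant when \code{relative}.
#' @return A \linkS4class{CaTrace}.
#' @export
caTrace <- function(values, schedule = NULL, time = NULL, phase = NULL,
                    cellId = "cell", sampleId = "sample",
                    relative = FALSE, s0 = NA_real_) {
  if (is.null(time)) {
    if (is.null(schedule)) stop("either 'schedule' or 'time' must be given")
    time <- schedule@starts[1L] + (seq_along(values) - 1L) * schedule@framePeriod
  }
  if (is.null(phase)) {
    if (is.null(schedule)) stop("either 'schedule' or 'phase' must be given")
    phase <- phaseOfTime(schedule, time)
  }
  new("CaTrace", cellId = as.character(cellId), sampleId = as.character(sampleId),
      time = as.numeric(time), values = as.numeric(values),
      phase = as.integer(phase), relative = isTRUE(relative), s0 = as.numeric(s0))
}

setMethod("show", "CaTrace", function(object) {
  cat(sprintf("CaTrace '%s' (%s): %d samples, %s, range [%.3g, %.3g]\n",
      object@cellId, object@sampleId, length(object@values),
      if (object@relative) sprintf("relative (s0 = %.3g)", object@s0) else "raw",
      min(object@values), max(object@values)))
})

#' @describeIn caTrace number of samples in the trace.
#' @param x a \linkS4class{CaTrace}.
#' @export
setMethod("length", "CaTrace", function(x) length(x@values))

#' Image stack with phase tags
#'
#' An ordered set of 2-D grayscale frames sharing dimensions, with the frame
#' period and a per-frame phase tag. The pixel array is stored as
#' \code{[y, x, frame]} with the origin at the top-left pixel centre,
#' x to the right and y downwards.
#'
#' @slot frames 3-D numeric array \code{[y, x, frame]}.
#' @slot framePeriod seconds per frame.
#' @slot phaseTags integer phase index per frame, non-decreasing.
#' @export
setClass("FrameStack",
  representation(frames = "array", framePeriod = "numeric", phaseTags = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "frames must be a 3-D array [y, x, frame]")
    else if (dim(object@frames)[3L] != length(object@phaseTags))
      msg <- c(msg, "one phase tag per frame required")
    if (object@framePeriod <= 0) msg <- c(msg, "framePeriod must be positive")
    tags <- object@phaseTags[!is.na(object@phaseTags)]
    if (length(tags) > 1L && any(diff(tags) < 0L))
      msg <- c(msg, "phase tags must be non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' Construct a frame stack
#'
#' @param frames 3-D array \code{[y, x, frame]} or list of matrices.
#' @param framePeriod seconds per frame.
#' @param phaseTags integer phase per frame; derived from \code{schedule} if
#'   omitted.
#' @param schedule optional \linkS4class{PhaseSchedule} used to derive tags.
#' @param startTime acquisition time of the first frame (s).
#' @return A \linkS4class{FrameStack}.
#' @export
frameStack <- function(frames, framePeriod, phaseTags = NULL, schedule = NULL,
                       startTime = 0) {
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(dim(frames[[1L]]), length(frames)))
  nf <- dim(frames)[3L]
  if (is.null(phaseTags)) {
    if (is.null(schedule)) stop("either 'phaseTags' or 'schedule' must be given")
    phaseTags <- phaseOfTime(schedule, startTime + (seq_len(nf) - 1L) * framePeriod)
  }
  new("FrameStack", frames = frames, framePeriod = as.numeric(framePeriod),
      phaseTags = as.integer(phaseTags))
}

#' @describeIn frameStack number of frames.
#' @param x a \linkS4class{FrameStack}.
#' @export
nFrames <- function(x) dim(x@frames)[3L]

#' @describeIn frameStack acquisition time of each frame, relative to the
#'   first frame of the parent recording.
#' @export
frameTimes <- function(x) (seq_len(nFrames(x)) - 1L) * x@framePeriod

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d px, %g s/frame, phases %s\n",
      d[3L], d[1L], d[2L], object@framePeriod,
      paste(unique(object@phaseTags), collapse = ",")))
})

#' Dark and flat-field correction frames
#'
#' @slot dark dark (zero-light) image, same size as the data frames.
#' @slot flat flat-field image; normalised to unit mean before use, and must
#'   be strictly positive after normalisation.
#' @export
setClass("CorrectionFrames",
  representation(dark = "matrix", flat = "matrix"),
  validity = function(object) {
    if (!all(dim(object@dark) == dim(object@flat)))
      "dark and flat frames must share dimensions" else TRUE
  })

#' Construct correction frames
#' @param dark,flat matrices of identical size.
#' @return A \linkS4class{CorrectionFrames}.
#' @export
correctionFrames <- function(dark, flat) new("CorrectionFrames",
                                             dark = dark, flat = flat)

#' Cell label map
#'
#' Integer segmentation mask: 0 is background, label \code{k > 0} marks the
#' pixels of cell \code{k}. The \code{coordinateFrame} records which phase
#' group's pixel grid the map lives in.
#'
#' @slot labels integer matrix.
#' @slot coordinateFrame phase-group id the map is defined in
#'   (\code{"pre"}, \code{"stretch"} or \code{"release"}).
#' @export
setClass("LabelMap",
  representation(labels = "matrix", coordinateFrame = "character"),
  validity = function(object) {
    lv <- object@labels
    if (any(lv < 0)) return("labels must be non-negative")
    TRUE
  })

#' Construct a label map
#' @param labels integer matrix (0 = background).
#' @param coordinateFrame phase group the map is defined in.
#' @return A \linkS4class{LabelMap}.
#' @export
labelMap <- function(labels, coordinateFrame = "stretch") {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, coordinateFrame = coordinateFrame)
}

#' @describeIn labelMap number of labelled cells.
#' @param x a \linkS4class{LabelMap}.
#' @export
nCells <- function(x) max(0L, as.integer(x@labels))

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap (%s frame): %d x %d px, %d cells\n",
      object@coordinateFrame, nrow(object@labels), ncol(object@labels),
      nCells(object)))
})

#' Similarity transform between phase groups
#'
#' Maps source pixel coordinates \eqn{p} to target coordinates
#' \eqn{c + s R(\theta) (p - c) + t} where \eqn{c} is the image centre,
#' \eqn{s} the isotropic scale, \eqn{\theta} the rotation and \eqn{t} the
#' translation. The stretch device produces an isotropic in-plane expansion,
#' so this family absorbs the dominant cross-phase deformation.
#'
#' @slot scale isotropic scale factor (> 0).
#' @slot rotation rotation angle in radians.
#' @slot translation length-2 pixel vector (x, y).
#' @slot center length-2 fixed point of the scaling (x, y).
#' @export
setClass("SimilarityTransform",
  representation(scale = "numeric", rotation = "numeric",
                 translation = "numeric", center = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(is.finite(object@scale) && object@scale > 0))
      msg <- c(msg, "scale must be positive")
    if (length(object@translation) != 2L) msg <- c(msg, "translation must be length 2")
    if (length(object@center) != 2L) msg <- c(msg, "center must be length 2")
    if (length(msg)) msg else TRUE
  })

#' Construct a similarity transform
#' @param scale isotropic scale factor.
#' @param rotation rotation in radians.
#' @param translation length-2 pixel translation (x, y).
#' @param center length-2 fixed point (x, y); defaults to the origin.
#' @return A \linkS4class{SimilarityTransform}.
#' @export
similarityTransform <- function(scale = 1, rotation = 0,
                                translation = c(0, 0), center = c(0, 0)) {
  new("SimilarityTransform", scale = as.numeric(scale),
      rotation = as.numeric(rotation), translation = as.numeric(translation),
      center = as.numeric(center))
}

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf(
    "SimilarityTransform: scale %.4f, rotation %.4f rad, t = (%.2f, %.2f), centre (%.1f, %.1f)\n",
    object@scale, object@rotation, object@translation[1L], object@translation[2L],
    object@center[1L], object@center[2L]))
})
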
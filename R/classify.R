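ACTIVITY_CLASSES <- c("SPONTANEOUS", "STRETCH_ACTIVATED", "RANDOM_PEAKS",
                      "NO_PEAKS", "INCOMPLETE")

#' Classify the activity type of a cell
#'
#' Rule-based activity typing: a cell is \code{SPONTANEOUS} when it shows at
#' least \code{spontaneousMinPeaks} (default two) peaks during the
#' pre-stretch baseline \code{PI}; otherwise \code{STRETCH_ACTIVATED} when it
#' shows at least one peak during the stretch phase \code{PIII} or a
#' sustained baseline elevation there (a strongly sustained response can
#' saturate into a plateau carrying at most one detectable peak);
#' otherwise \code{RANDOM_PEAKS} when any peak exists in any phase; otherwise
#' \code{NO_PEAKS} (dead cells or misplaced ROIs).
#'
#' @param metrics per-phase metrics from \code{\link{computePhaseMetrics}}.
#' @param params an \linkS4class{AnalysisParams}. With
#'   \code{spontaneousIncludesPII = TRUE}, \code{PII} peaks also count
#'   towards spontaneity.
#' @param sustainedPIII logical: a sustained elevation was detected in
#'   \code{PIII} (see \code{\link{testSustainedElevation}}).
#' @return One of \code{"SPONTANEOUS"}, \code{"STRETCH_ACTIVATED"},
#'   \code{"RANDOM_PEAKS"}, \code{"NO_PEAKS"}.
#' @export
classifyActivity <- function(metrics, params = analysisParams(),
                             sustainedPIII = FALSE) {
  n <- metrics$n_peaks
  if (anyNA(n)) stop("metrics incomplete: use INCOMPLETE for such cells")
  nSpont <- n[1L] + if (params@spontaneousIncludesPII) n[2L] else 0L
  if (nSpont >= params@spontaneousMinPeaks) return("SPONTANEOUS")
  if (n[3L] >= 1L || isTRUE(sustainedPIII)) return("STRETCH_ACTIVATED")
  if (sum(n) >= 1L) return("RANDOM_PEAKS")
  "NO_PEAKS"
}

#' Test for a sustained baseline elevation
#'
#' A phase shows a sustained signal increase when the baseline intensity of
#' its first third exceeds the reference baseline (the \code{PII} BI) by at
#' least \code{sustainedDelta} relative units (the initial elevation E), and
#' the BI of each of the two remaining thirds stays at or above the reference
#' plus \code{retentionFraction} of E. All inequalities are inclusive.
#'
#' @param rel a relative \linkS4class{CaTrace}.
#' @param window \code{c(start, end)} of the phase in seconds.
#' @param referenceBI the \code{PII} baseline intensity.
#' @param params an \linkS4class{AnalysisParams}.
#' @return \code{TRUE}/\code{FALSE}; \code{FALSE} with attribute
#'   \code{missing = TRUE} when the window holds no samples or the reference
#'   is unavailable.
#' @export
testSustainedElevation <- function(rel, window, referenceBI,
                                   params = analysisParams()) {
  if (!is.finite(referenceBI))
    return(structure(FALSE, missing = TRUE))
  thirds <- seq(window[1L], window[2L], length.out = 4L)
  bi <- vapply(1:3, function(k)
    phaseBaseline(rel, c(thirds[k], thirds[k + 1L]), params), numeric(1L))
  if (anyNA(bi)) return(structure(FALSE, missing = TRUE))
  eps <- 1e-9       # guard the inclusive boundaries against rounding
  E <- bi[1L] - referenceBI
  if (E < params@sustainedDelta - eps) return(FALSE)
  floorBI <- referenceBI + params@retentionFraction * E
  all(bi[2:3] >= floorBI - eps)
}

#' Categorise the response in a stretch or release phase
#'
#' Each of \code{PIII} (stretch) and \code{PIV} (release) is categorised as
#' \code{"sustained"} (sustained baseline elevation over the \code{PII}
#' reference), \code{"oscillating"} (at least two peaks in the phase without
#' a sustained-scale baseline increase), or \code{"neither"}. The reference
#' baseline is \code{PII} for both phases.
#'
#' @param rel a relative \linkS4class{CaTrace}.
#' @param metrics per-phase metrics from \code{\link{computePhaseMetrics}}.
#' @param phase 3 (stretch) or 4 (release).
#' @param schedule a \linkS4class{PhaseSchedule}.
#' @param params an \linkS4class{AnalysisParams}.
#' @return \code{"sustained"}, \code{"oscillating"} or \code{"neither"}.
#' @export
categorizeStretchResponse <- function(rel, metrics, phase, schedule,
                                      params = analysisParams()) {
  stopifnot(phase %in% c(3L, 4L))
  refBI <- metrics$baseline[2L]
  w <- c(schedule@starts[phase], schedule@ends[phase])
  if (isTRUE(as.logical(testSustainedElevation(rel, w, refBI, params))))
    return("sustained")
  n <- metrics$n_peaks[phase]
  bi <- metrics$baseline[phase]
  if (!is.na(n) && n >= 2L && is.finite(bi) && is.finite(refBI) &&
      (bi - refBI) < params@sustainedDelta)
    return("oscillating")
  "neither"
}

#' Detect a between-phase baseline elevation
#'
#' @param prevBI,curBI baseline intensities of the earlier and later phase.
#' @param params an \linkS4class{AnalysisParams}; the elevation marker fires
#'   when the increase reaches \code{elevationThreshold}.
#' @return \code{TRUE}/\code{FALSE}; \code{NA} when either value is missing.
#' @export
detectBaselineElevation <- function(prevBI, curBI, params = analysisParams()) {
  if (!is.finite(prevBI) || !is.finite(curBI)) return(NA)
  (curBI - prevBI) >= params@elevationThreshold - 1e-9
}

#' Detect an oscillation-rate increase from PI to PII
#'
#' Flags a strict increase in the peak rate after agonist addition, the
#' expected signature of chemical channel sensitisation.
#'
#' @param metricsPI,metricsPII single-phase rows of the metrics table (or
#'   numeric rates in peaks/min).
#' @return \code{TRUE} iff the \code{PII} rate strictly exceeds the
#'   \code{PI} rate.
#' @export
detectOscillationIncrease <- function(metricsPI, metricsPII) {
  r1 <- if (is.data.frame(metricsPI)) metricsPI$peaks_per_min else metricsPI
  r2 <- if (is.data.frame(metricsPII)) metricsPII$peaks_per_min else metricsPII
  if (!is.finite(r1) || !is.finite(r2)) return(NA)
  r2 > r1
}

#' Classify one cell into a full record
#'
#' Assembles the activity class, all response markers and the per-phase
#' metrics of one cell into a single record row. Cells classified as
#' \code{RANDOM_PEAKS} or \code{NO_PEAKS} are flagged as excluded from the
#' response analyses; cells whose trace could not be extracted in every
#' phase are \code{INCOMPLETE} and carry no markers.
#'
#' @param rel a relative \linkS4class{CaTrace}.
#' @param peaks peak table from \code{\link{detectPeaks}}.
#' @param metrics per-phase metrics from \code{\link{computePhaseMetrics}}.
#' @param schedule a \linkS4class{PhaseSchedule}.
#' @param condition list or vector with logical elements \code{gsmtx4} and
#'   \code{yoda1}; defaults to the schedule's annotations.
#' @param params an \linkS4class{AnalysisParams}.
#' @param incomplete logical: trace extraction failed in some phase.
#' @return A one-row data.frame (the cell record): identifiers, condition
#'   flags, \code{class}, \code{first_activity_phase}, marker booleans,
#'   response categories, \code{excluded}, and per-phase metrics in wide
#'   form (\code{n_peaks_PI} ... \code{baseline_PIV}).
#' @export
classifyCell <- function(rel, peaks, metrics, schedule,
                         condition = NULL, params = analysisParams(),
                         incomplete = FALSE) {
  stopifnot(is(rel, "CaTrace"))
  if (is.null(condition))
    condition <- list(gsmtx4 = schedule@gsmtx4, yoda1 = schedule@yoda1)
  wide <- metricsWide(metrics)
  base <- data.frame(cell_id = rel@cellId, sample_id = rel@sampleId,
                     gsmtx4 = isTRUE(condition$gsmtx4),
                     yoda1 = isTRUE(condition$yoda1),
                     stringsAsFactors = FALSE)
  if (incomplete || anyNA(metrics$n_peaks)) {
    rec <- cbind(base, data.frame(class = "INCOMPLETE",
      first_activity_phase = NA_character_,
      baseline_elevated_PII = NA, baseline_elevated_PIII = NA,
      baseline_elevated_PIV = NA, oscillation_increase_PII = NA,
      response_PIII = NA_character_, response_PIV = NA_character_,
      fewer_oscillations_PIV_vs_PII = NA, excluded = TRUE), wide)
    return(rec)
  }
  wPIII <- c(schedule@starts[3L], schedule@ends[3L])
  sustainedPIII <- isTRUE(as.logical(
    testSustainedElevation(rel, wPIII, metrics$baseline[2L], params)))
  cls <- classifyActivity(metrics, params, sustainedPIII = sustainedPIII)

  firstPhase <- NA_character_
  withPeaks <- which(metrics$n_peaks > 0L)
  if (length(withPeaks)) firstPhase <- PHASE_IDS[min(withPeaks)]
  else if (sustainedPIII) firstPhase <- "PIII"

  bi <- metrics$baseline
  resp3 <- categorizeStretchResponse(rel, metrics, 3L, schedule, params)
  resp4 <- categorizeStretchResponse(rel, metrics, 4L, schedule, params)
  cbind(base, data.frame(class = cls,
    first_activity_phase = firstPhase,
    baseline_elevated_PII  = detectBaselineElevation(bi[1L], bi[2L], params),
    baseline_elevated_PIII = detectBaselineElevation(bi[2L], bi[3L], params),
    baseline_elevated_PIV  = detectBaselineElevation(bi[3L], bi[4L], params),
    oscillation_increase_PII = detectOscillationIncrease(
      metrics$peaks_per_min[1L], metrics$peaks_per_min[2L]),
    response_PIII = resp3, response_PIV = resp4,
    fewer_oscillations_PIV_vs_PII =
      metrics$peaks_per_min[4L] < metrics$peaks_per_min[2L],
    excluded = cls %in% c("RANDOM_PEAKS", "NO_PEAKS"),
    stringsAsFactors = FALSE), wide)
}

metricsWide <- function(metrics) {
  out <- list()
  for (p in 1:4) {
    id <- PHASE_IDS[p]
    out[[paste0("n_peaks_", id)]] <- metrics$n_peaks[p]
    out[[paste0("peaks_per_min_", id)]] <- metrics$peaks_per_min[p]
    out[[paste0("mean_peak_height_", id)]] <- metrics$mean_peak_height[p]
    if (p >= 3L)
      out[[paste0("initial_max_peak_height_", id)]] <-
        metrics$initial_max_peak_height[p]
    out[[paste0("baseline_", id)]] <- metrics$baseline[p]
  }
  as.data.frame(out)
}

#' Classify a set of traces
#'
#' Runs the full per-cell chain (S0 estimation, normalisation, peak
#' detection, phase metrics, classification) over a list of raw traces.
#'
#' @param traces list of raw \linkS4class{CaTrace} objects.
#' @param schedule a \linkS4class{PhaseSchedule}.
#' @param params an \linkS4class{AnalysisParams}.
#' @param condition optional condition flags (see \code{\link{classifyCell}}).
#' @param incompleteIds character vector of cell ids whose extraction was
#'   incomplete; these become \code{INCOMPLETE} records.
#' @return A data.frame of cell records, one row per trace.
#' @export
classifyCells <- function(traces, schedule, params = analysisParams(),
                          condition = NULL, incompleteIds = character()) {
  recs <- lapply(traces, function(tr) {
    if (tr@cellId %in% incompleteIds) {
      metrics <- data.frame(phase = PHASE_IDS, n_peaks = NA_integer_,
                            peaks_per_min = NA_real_, mean_peak_height = NA_real_,
                            initial_max_peak_height = NA_real_, baseline = NA_real_)
      rel <- tr; rel@relative <- TRUE; rel@s0 <- 1
      return(classifyCell(rel, emptyPeaks(rel), metrics, schedule, condition,
                          params, incomplete = TRUE))
    }
    a <- analyzeTrace(tr, schedule, params)
    classifyCell(a$rel, a$peaks, a$metrics, schedule, condition, params)
  })
  do.call(rbind, recs)
}
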
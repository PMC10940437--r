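#' Detect peaks by topographic prominence
#'
#' Finds all local maxima of a relative trace whose topographic prominence
#' reaches \code{prominenceThreshold}. Prominence is the vertical distance
#' between a peak and the lowest contour line separating it from higher
#' ground: for each local maximum the trace is scanned left and right until a
#' strictly higher sample (or the trace end) is reached, the minimum of each
#' flank is taken, and the prominence is the peak value minus the larger of
#' the two flank minima. Plateau maxima are reported once, at their leftmost
#' sample.
#'
#' @param rel a relative \linkS4class{CaTrace} (or any \linkS4class{CaTrace};
#'   values are used as given).
#' @param params an \linkS4class{AnalysisParams}; only
#'   \code{prominenceThreshold} is used.
#' @return A data.frame with one row per peak, ordered by time: \code{index}
#'   (1-based sample index of the apex), \code{time_s}, \code{height} (signal
#'   value at the apex), \code{prominence}, \code{left_base} and
#'   \code{right_base} (sample indices of the flank minima that define the
#'   prominence), \code{phase}.
#' @examples
#' sched <- phaseSchedule(phaseLength = 1, framePeriod = 0.1)
#' tr <- caTrace(c(1, 1, 2, 1, 1, 1, 1, 1, 1, 1) + 0, schedule = sched,
#'               relative = TRUE, s0 = 1)
#' detectPeaks(tr, analysisParams())
#' @export
detectPeaks <- function(rel, params = analysisParams()) {
  stopifnot(is(rel, "CaTrace"))
  v <- rel@values
  n <- length(v)
  if (n < 3L) stop("trace must have at least 3 samples")
  apex <- plateauMaxima(v)
  if (!length(apex)) return(emptyPeaks(rel))
  pr <- lapply(apex, function(i) peakProminence(v, i))
  prom <- vapply(pr, `[[`, numeric(1L), "prominence")
  keep <- prom >= params@prominenceThreshold
  apex <- apex[keep]
  data.frame(index = apex, time_s = rel@time[apex], height = v[apex],
             prominence = prom[keep],
             left_base = vapply(pr[keep], `[[`, integer(1L), "leftBase"),
             right_base = vapply(pr[keep], `[[`, integer(1L), "rightBase"),
             phase = rel@phase[apex])
}

emptyPeaks <- function(rel) {
  data.frame(index = integer(), time_s = numeric(), height = numeric(),
             prominence = numeric(), left_base = integer(),
             right_base = integer(), phase = integer())
}

## Indices of local maxima, plateaus collapsed to their leftmost sample.
## A plateau run is a maximum iff both neighbouring samples (where present
## and interior) are strictly lower; runs touching the trace ends are not
## maxima (no higher ground requirement is decidable there).
plateauMaxima <- function(v) {
  n <- length(v)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer()
  for (j in seq_len(k)) {
    if (starts[j] == 1L || ends[j] == n) next
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
      out <- c(out, starts[j])
  }
  out
}

## Topographic prominence of the local maximum at index i: scan each flank to
## the first strictly higher sample (or the end), take the minimum on each
## flank, prominence = v[i] - max(left minimum, right minimum). The base
## indices (first position of each flank minimum, scanning outward) delimit
## the peak's extent and are used to exclude peaks from baseline windows.
peakProminence <- function(v, i) {
  n <- length(v)
  leftMin <- v[i]; leftBase <- i; j <- i - 1L
  while (j >= 1L && v[j] <= v[i]) {
    if (v[j] < leftMin) { leftMin <- v[j]; leftBase <- j }
    j <- j - 1L
  }
  rightMin <- v[i]; rightBase <- i; j <- i + 1L
  while (j <= n && v[j] <= v[i]) {
    if (v[j] < rightMin) { rightMin <- v[j]; rightBase <- j }
    j <- j + 1L
  }
  list(prominence = v[i] - max(leftMin, rightMin),
       leftBase = leftBase, rightBase = rightBase)
}

#' Estimate the normalisation constant S0
#'
#' The relative trace is the ratio of the signal at time t to a baseline
#' level S0 measured at the start of the experiment. Because many cells
#' oscillate spontaneously, transient peaks must not contaminate S0: peaks
#' are pre-detected on a provisionally normalised copy of the trace and S0 is
#' the mean of the earliest \code{s0WindowS}-long window within \code{PI}
#' that contains no peak apex. If every window in \code{PI} contains a peak,
#' S0 falls back to the mean of the lowest \code{baselinePercentile} percent
#' of \code{PI} samples.
#'
#' @param raw a raw \linkS4class{CaTrace} covering at least \code{s0WindowS}
#'   seconds.
#' @param params an \linkS4class{AnalysisParams}.
#' @return The scalar S0 (> 0).
#' @export
estimateS0 <- function(raw, params = analysisParams()) {
  stopifnot(is(raw, "CaTrace"))
  v <- raw@values
  dt <- if (length(raw@time) > 1L) raw@time[2L] - raw@time[1L] else Inf
  win <- max(1L, round(params@s0WindowS / dt))
  if (length(v) < max(win, 3L))
    stop("trace shorter than the S0 window (", params@s0WindowS, " s)")
  if (all(v == 0)) stop("all-zero trace cannot be normalised")

  inPI <- which(raw@phase == 1L)
  if (!length(inPI)) inPI <- seq_len(min(length(v), win))
  ## provisional normalisation by the PI median for peak pre-detection
  prov <- median(v[inPI])
  if (prov <= 0) prov <- mean(v[v > 0])
  provTrace <- raw; provTrace@values <- v / prov
  pk <- detectPeaks(provTrace, params)
  ## samples on a peak's rising or falling limb (the monotone runs around
  ## the apex) are not baseline and disqualify a window
  n <- length(v)
  inPeak <- rep(FALSE, n)
  for (a in pk$index) {
    L <- a; while (L > 1L && v[L - 1L] < v[L]) L <- L - 1L
    R <- a; while (R < n && v[R + 1L] < v[R]) R <- R + 1L
    inPeak[L:R] <- TRUE
  }

  lastStart <- max(inPI) - win + 1L
  s0 <- NA_real_
  if (lastStart >= min(inPI)) {
    for (st in min(inPI):lastStart) {
      idx <- st:(st + win - 1L)
      if (!any(inPeak[idx])) { s0 <- mean(v[idx]); break }
    }
  }
  if (!is.finite(s0)) {                 # no peak-free window in PI
    pv <- sort(v[inPI])
    k <- max(1L, ceiling(length(pv) * params@baselinePercentile / 100))
    s0 <- mean(pv[seq_len(k)])
  }
  if (!(is.finite(s0) && s0 > 0)) stop("estimated S0 is not positive")
  s0
}

#' Normalise a raw trace to relative units
#'
#' Pointwise division of the raw signal by S0, preserving time, phase tags
#' and identifiers. Every downstream metric operates on the relative scale,
#' which removes between-cell differences in indicator loading.
#'
#' @param raw a raw \linkS4class{CaTrace}.
#' @param s0 the normalisation constant (> 0); estimated with
#'   \code{\link{estimateS0}} if missing.
#' @param params an \linkS4class{AnalysisParams} (used only when \code{s0}
#'   is estimated).
#' @return A relative \linkS4class{CaTrace}.
#' @export
normalizeTrace <- function(raw, s0 = NULL, params = analysisParams()) {
  stopifnot(is(raw, "CaTrace"))
  if (is.null(s0)) s0 <- estimateS0(raw, params)
  if (!(is.finite(s0) && s0 > 0)) stop("s0 must be positive")
  rel <- raw
  rel@values <- raw@values / s0
  rel@relative <- TRUE
  rel@s0 <- s0
  validObject(rel)
  rel
}

#' Phase baseline intensity
#'
#' The baseline intensity (BI) of a window is the plateau level of the
#' relative trace with transient peaks excluded; it is estimated as a low
#' percentile (\code{baselinePercentile}, default 10) of the samples in the
#' window, which tracks sustained elevations while ignoring sparse
#' superimposed oscillations.
#'
#' @param rel a relative \linkS4class{CaTrace}.
#' @param window \code{c(start, end)} in seconds, half-open.
#' @param params an \linkS4class{AnalysisParams}.
#' @return The BI, or \code{NA} for an empty window.
#' @export
phaseBaseline <- function(rel, window, params = analysisParams()) {
  stopifnot(is(rel, "CaTrace"))
  idx <- rel@time >= window[1L] & rel@time < window[2L]
  if (!any(idx)) return(NA_real_)
  unname(quantile(rel@values[idx], params@baselinePercentile / 100, type = 7))
}

#' Per-phase trace metrics
#'
#' Assigns detected peaks to phases by apex time (half-open windows) and
#' computes, per phase: the peak count, the rate in peaks per minute, the
#' mean peak height (signal value at the apex; \code{NA} when there are no
#' peaks), the baseline intensity, and — for the stretch (\code{PIII}) and
#' release (\code{PIV}) phases — the maximal peak height among peaks within
#' the first \code{initialResponseWindowS} seconds of the phase.
#'
#' @param rel a relative \linkS4class{CaTrace}.
#' @param peaks peak table from \code{\link{detectPeaks}} on the same trace.
#' @param schedule a \linkS4class{PhaseSchedule}.
#' @param params an \linkS4class{AnalysisParams}.
#' @return A data.frame with four rows (phases) and columns \code{phase},
#'   \code{n_peaks}, \code{peaks_per_min}, \code{mean_peak_height},
#'   \code{initial_max_peak_height}, \code{baseline}.
#' @export
computePhaseMetrics <- function(rel, peaks, schedule, params = analysisParams()) {
  stopifnot(is(rel, "CaTrace"), is(schedule, "PhaseSchedule"))
  out <- data.frame(phase = PHASE_IDS, n_peaks = 0L, peaks_per_min = 0,
                    mean_peak_height = NA_real_,
                    initial_max_peak_height = NA_real_, baseline = NA_real_)
  for (p in 1:4) {
    w <- c(schedule@starts[p], schedule@ends[p])
    hasSamples <- any(rel@time >= w[1L] & rel@time < w[2L])
    if (!hasSamples) {      # empty phase window: metrics absent, not zero
      out$n_peaks[p] <- NA_integer_
      out$peaks_per_min[p] <- NA_real_
      next
    }
    inP <- peaks$time_s >= w[1L] & peaks$time_s < w[2L]
    out$n_peaks[p] <- sum(inP)
    out$peaks_per_min[p] <- sum(inP) / (w[2L] - w[1L]) * 60
    if (any(inP)) out$mean_peak_height[p] <- mean(peaks$height[inP])
    if (p >= 3L) {
      early <- inP & peaks$time_s < w[1L] + params@initialResponseWindowS
      if (any(early)) out$initial_max_peak_height[p] <- max(peaks$height[early])
    }
    out$baseline[p] <- phaseBaseline(rel, w, params)
  }
  out
}

#' Analyse one trace end to end
#'
#' Convenience wrapper: estimate S0, normalise, detect peaks and compute
#' per-phase metrics.
#'
#' @param raw a raw \linkS4class{CaTrace}.
#' @param schedule a \linkS4class{PhaseSchedule}.
#' @param params an \linkS4class{AnalysisParams}.
#' @return A list with \code{rel}, \code{peaks}, \code{metrics}.
#' @export
analyzeTrace <- function(raw, schedule, params = analysisParams()) {
  rel <- normalizeTrace(raw, params = params)
  peaks <- detectPeaks(rel, params)
  metrics <- computePhaseMetrics(rel, peaks, schedule, params)
  list(rel = rel, peaks = peaks, metrics = metrics)
}
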
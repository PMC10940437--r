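#' Cell phenotype for synthetic traces
#'
#' Ground-truth behavioural parameters of one simulated cell. Two activity
#' types are emulated: cells oscillating spontaneously before any stimulus
#' (\code{spontaneousRate > 0}) and cells first activated by stretch
#' (\code{stretchResponse} of \code{"sustained"} or \code{"oscillating"}).
#'
#' @slot spontaneousRate spontaneous Ca2+ peak rate in \code{PI}
#'   (peaks per minute, >= 0).
#' @slot drugRateMultiplier factor applied to the oscillation rate from
#'   \code{PII} onward (agonist sensitisation or blocker suppression; >= 0).
#' @slot stretchResponse one of \code{"sustained"}, \code{"oscillating"},
#'   \code{"none"}.
#' @slot sustainedAmplitude baseline elevation (relative units) during
#'   \code{PIII} for sustained responders; must be 0 otherwise.
#' @slot peakAmplitude typical relative peak height above baseline (> 0).
#' @export
setClass("Phenotype",
  representation(spontaneousRate = "numeric", drugRateMultiplier = "numeric",
                 stretchResponse = "character", sustainedAmplitude = "numeric",
                 peakAmplitude = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@spontaneousRate < 0) msg <- c(msg, "spontaneousRate must be >= 0")
    if (object@drugRateMultiplier < 0) msg <- c(msg, "drugRateMultiplier must be >= 0")
    if (!object@stretchResponse %in% c("sustained", "oscillating", "none"))
      msg <- c(msg, "stretchResponse must be sustained/oscillating/none")
    if (!(is.finite(object@peakAmplitude) && object@peakAmplitude > 0))
      msg <- c(msg, "peakAmplitude must be positive")
    if (object@sustainedAmplitude > 0 && object@stretchResponse != "sustained")
      msg <- c(msg, "sustainedAmplitude > 0 requires stretchResponse 'sustained'")
    if (object@sustainedAmplitude < 0) msg <- c(msg, "sustainedAmplitude must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a phenotype
#'
#' @param spontaneousRate spontaneous peak rate in \code{PI} (peaks/min).
#' @param drugRateMultiplier rate factor from \code{PII} onward.
#' @param stretchResponse \code{"sustained"}, \code{"oscillating"} or
#'   \code{"none"}.
#' @param sustainedAmplitude \code{PIII} baseline elevation (relative units)
#'   for sustained responders.
#' @param peakAmplitude typical relative peak height (> 0).
#' @return A \linkS4class{Phenotype}.
#' @examples
#' phenotype(spontaneousRate = 6, stretchResponse = "oscillating")
#' @export
phenotype <- function(spontaneousRate = 0, drugRateMultiplier = 1,
                      stretchResponse = "none",
                      sustainedAmplitude = if (identical(stretchResponse, "sustained")) 2 else 0,
                      peakAmplitude = 1) {
  new("Phenotype", spontaneousRate = as.numeric(spontaneousRate),
      drugRateMultiplier = as.numeric(drugRateMultiplier),
      stretchResponse = as.character(stretchResponse),
      sustainedAmplitude = as.numeric(sustainedAmplitude),
      peakAmplitude = as.numeric(peakAmplitude))
}

setMethod("show", "Phenotype", function(object) {
  cat(sprintf(
    "Phenotype: %g peaks/min in PI, x%g from PII, stretch response '%s'%s, peak amp %g\n",
    object@spontaneousRate, object@drugRateMultiplier, object@stretchResponse,
    if (object@stretchResponse == "sustained")
      sprintf(" (+%g baseline)", object@sustainedAmplitude) else "",
    object@peakAmplitude))
})

## Fast-rise / exponential-decay transient kernel, normalised to unit peak.
## riseTau ~ 0.3 s, decayTau ~ 1.5 s mimic a fluorescent-indicator transient.
spikeKernel <- function(t, riseTau = 0.3, decayTau = 1.5) {
  tPeak <- riseTau * log((riseTau + decayTau) / riseTau)
  fMax <- (1 - exp(-tPeak / riseTau)) * exp(-tPeak / decayTau)
  v <- ifelse(t < 0, 0, (1 - exp(-t / riseTau)) * exp(-t / decayTau) / fMax)
  v
}

## Thinned homogeneous Poisson event times on [t0, t1): events closer than
## minGap to their predecessor are dropped so transients remain resolvable.
poissonEvents <- function(ratePerMin, t0, t1, minGap = 2) {
  if (ratePerMin <= 0 || t1 <= t0) return(numeric())
  n <- rpois(1L, ratePerMin * (t1 - t0) / 60)
  if (n == 0L) return(numeric())
  times <- sort(runif(n, t0, t1))
  keep <- c(TRUE, diff(times) >= minGap)
  while (!all(keep)) {            # re-thin against the kept predecessor
    times <- times[keep]
    keep <- c(TRUE, diff(times) >= minGap)
  }
  times
}

#' Simulate a single-cell fluorescence trace with ground truth
#'
#' Generates a raw-intensity trace for one cell under the four-phase stretch
#' protocol. Spontaneous oscillations are a thinned homogeneous Poisson
#' process at the phenotype's rate (modulated by \code{drugRateMultiplier}
#' from \code{PII} onward); each event adds a fast-rise/exponential-decay
#' transient with amplitude jittered by +/- 20 percent. Stretch responses are
#' rendered either as extra oscillations during \code{PIII}
#' (\code{"oscillating"}) or as a baseline plateau of
#' \code{sustainedAmplitude} relative units spanning \code{PIII} that decays
#' after release (\code{"sustained"}; an onset transient marks the initial
#' response). Signal-dependent (photon-like) Gaussian noise is added on the
#' raw scale.
#'
#' @param phen a \linkS4class{Phenotype}.
#' @param schedule a \linkS4class{PhaseSchedule}.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param s0True the true baseline raw intensity (camera units).
#' @param noiseSd relative noise level: per-sample Gaussian sd is
#'   \code{noiseSd * s0True * sqrt(relative signal)}.
#' @param stretchOscRate extra oscillation rate (peaks/min) during
#'   \code{PIII} for \code{"oscillating"} responders.
#' @return A list with components \code{trace} (raw \linkS4class{CaTrace}),
#'   \code{events} (data.frame of true event times and phases) and
#'   \code{sustainedInterval} (\code{c(start, end)} of the true sustained
#'   elevation, or \code{NULL}).
#' @examples
#' out <- simulateTrace(phenotype(spontaneousRate = 6), phaseSchedule(), seed = 1)
#' nrow(out$events)
#' @export
simulateTrace <- function(phen, schedule, seed, s0True = 500, noiseSd = 0.02,
                          stretchOscRate = 8) {
  stopifnot(is(phen, "Phenotype"), is(schedule, "PhaseSchedule"))
  validObject(phen)
  dt <- schedule@framePeriod
  time <- seq(schedule@starts[1L], schedule@ends[4L] - dt / 2, by = dt)

  withr::with_seed(as.integer(seed), {
    ## per-phase oscillation rates
    rates <- rep(phen@spontaneousRate, 4L)
    rates[2:4] <- rates[2:4] * phen@drugRateMultiplier
    if (phen@stretchResponse == "oscillating")
      rates[3L] <- rates[3L] + stretchOscRate

    events <- lapply(1:4, function(p)
      poissonEvents(rates[p], schedule@starts[p], schedule@ends[p]))
    if (phen@stretchResponse == "sustained")   # onset transient marks the response
      events[[3L]] <- sort(unique(c(schedule@starts[3L] + 0.5, events[[3L]])))
    eventTimes <- unlist(events)
    amps <- phen@peakAmplitude * runif(length(eventTimes), 0.8, 1.2)

    rel <- rep(1, length(time))
    for (i in seq_along(eventTimes))
      rel <- rel + amps[i] * spikeKernel(time - eventTimes[i])

    sustainedInterval <- NULL
    if (phen@stretchResponse == "sustained") {
      on <- schedule@starts[3L]; off <- schedule@ends[3L]
      plateau <- phen@sustainedAmplitude *
        pmin(1, pmax(0, (time - on) / 1)) *       # 1 s onset ramp
        ifelse(time < off, 1, exp(-(time - off) / 5))  # decay after release
      rel <- rel + plateau
      sustainedInterval <- c(on, off)
    }

    raw <- s0True * rel
    raw <- raw + rnorm(length(raw), 0, noiseSd * s0True * sqrt(pmax(rel, 0)))
    raw <- pmax(raw, 0)

    trace <- caTrace(raw, schedule = schedule)
    ev <- data.frame(time = eventTimes,
                     phase = phaseOfTime(schedule, eventTimes))
    list(trace = trace, events = ev[order(ev$time), , drop = FALSE],
         sustainedInterval = sustainedInterval)
  })
}

#' Simulate a cohort of cells with a known spontaneous fraction
#'
#' Draws \code{n} cells whose phenotype is spontaneously active with
#' probability \code{spontaneousFraction} (oscillating at
#' \code{spontaneousRate} peaks/min) and otherwise silent until stretch,
#' responding in \code{PIII} with a sustained elevation or extra
#' oscillations (equal odds). Used to test phenotype recovery through the
#' full trace-analysis and classification chain.
#'
#' @param n number of cells.
#' @param spontaneousFraction probability a cell is spontaneously active.
#' @param schedule a \linkS4class{PhaseSchedule}.
#' @param seed integer seed.
#' @param spontaneousRate oscillation rate of spontaneous cells (peaks/min).
#' @param ... passed on to \code{\link{simulateTrace}}.
#' @return A list with \code{traces} (list of raw \linkS4class{CaTrace}),
#'   \code{truth} (data.frame: cell_id, spontaneous, stretchResponse) and
#'   \code{events} (list of ground-truth event tables).
#' @export
simulateCohort <- function(n, spontaneousFraction, schedule = phaseSchedule(),
                           seed = 1, spontaneousRate = 6, ...) {
  withr::with_seed(as.integer(seed), {
    spont <- runif(n) < spontaneousFraction
    resp <- ifelse(runif(n) < 0.5, "sustained", "oscillating")
    seeds <- sample.int(.Machine$integer.max, n)
  })
  traces <- vector("list", n); events <- vector("list", n)
  for (i in seq_len(n)) {
    phen <- phenotype(
      spontaneousRate = if (spont[i]) spontaneousRate else 0,
      stretchResponse = resp[i])
    out <- simulateTrace(phen, schedule, seed = seeds[i], ...)
    out$trace@cellId <- as.character(i)
    traces[[i]] <- out$trace
    events[[i]] <- out$events
  }
  list(traces = traces,
       truth = data.frame(cell_id = as.character(seq_len(n)),
                          spontaneous = spont, stretchResponse = resp),
       events = events)
}
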
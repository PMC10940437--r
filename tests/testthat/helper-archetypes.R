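## Constructed relative traces exercising every branch of the response
## decision tree, with the expected classification alongside. Traces are
## built deterministically on a 60-s x 4 schedule at 10 frames/s from a flat
## baseline of 1.0 plus triangular transients and piecewise-constant plateau
## shifts; no noise, so every expectation is exact under default parameters.

archetypeSchedule <- function() phaseSchedule()

## add a symmetric triangular transient of given height and half-width (s)
addBump <- function(v, time, at, height, halfWidth = 1) {
  w <- pmax(0, 1 - abs(time - at) / halfWidth)
  v + height * w
}

## add `delta` to the signal on [from, to)
addPlateau <- function(v, time, from, to, delta) {
  v + delta * (time >= from & time < to)
}

## Each archetype: name, builder(time) -> values, expected record fields.
buildArchetypes <- function() {
  sched <- archetypeSchedule()
  time <- seq(0, 240 - 0.1, by = 0.1)
  base <- rep(1, length(time))
  ## thirds of P III start at 120, 140, 160 s
  list(
    list(name = "silent cell",
         values = base,
         expect = list(class = "NO_PEAKS", excluded = TRUE)),
    list(name = "single random peak in PI",
         values = addBump(base, time, 30, 1),
         expect = list(class = "RANDOM_PEAKS", excluded = TRUE)),
    list(name = "spontaneous, unresponsive",
         values = addBump(addBump(base, time, 20, 1), time, 40, 1),
         expect = list(class = "SPONTANEOUS", response_PIII = "neither",
                       excluded = FALSE)),
    list(name = "stretch-activated by a single PIII peak",
         values = addBump(base, time, 130, 1),
         expect = list(class = "STRETCH_ACTIVATED",
                       first_activity_phase = "PIII")),
    list(name = "stretch-activated by peakless-onset sustained elevation",
         ## plateau over all of PIII decaying in PIV; its plateau maximum is
         ## the one detectable peak of a saturated sustained response
         values = addPlateau(base, time, 120, 180, 2),
         expect = list(class = "STRETCH_ACTIVATED", response_PIII = "sustained")),
    list(name = "spontaneous with sustained stretch response",
         values = addPlateau(addBump(addBump(base, time, 15, 1), time, 35, 1),
                             time, 120, 180, 2),
         expect = list(class = "SPONTANEOUS", response_PIII = "sustained",
                       baseline_elevated_PIII = TRUE)),
    list(name = "spontaneous with oscillating stretch response",
         values = Reduce(function(v, at) addBump(v, time, at, 1),
                         c(125, 135, 145, 155),
                         addBump(addBump(base, time, 10, 1), time, 30, 1)),
         expect = list(class = "SPONTANEOUS", response_PIII = "oscillating")),
    list(name = "sustained at the exact thresholds (E = 1.5, retention = 20%)",
         ## first third +1.5 => E = 1.5; later thirds at exactly ref + 0.3
         values = addPlateau(addPlateau(base, time, 120, 140, 1.5),
                             time, 140, 180, 0.3),
         expect = list(class = "STRETCH_ACTIVATED", response_PIII = "sustained")),
    list(name = "elevation just below the sustained threshold (E = 1.4)",
         values = addPlateau(base, time, 120, 180, 1.4),
         expect = list(class = "STRETCH_ACTIVATED", response_PIII = "neither")),
    list(name = "initial elevation not retained (middle third sags)",
         ## E = 1.6, floor = 1.32; middle third at 1.2 < floor
         values = addPlateau(addPlateau(addPlateau(base, time, 120, 140, 1.6),
                                        time, 140, 160, 0.2),
                             time, 160, 180, 0.25),
         expect = list(class = "STRETCH_ACTIVATED", response_PIII = "neither")),
    list(name = "oscillation increase in PII",
         values = Reduce(function(v, at) addBump(v, time, at, 1),
                         c(70, 85, 100, 110),
                         addBump(addBump(base, time, 10, 1), time, 40, 1)),
         expect = list(class = "SPONTANEOUS", oscillation_increase_PII = TRUE)),
    list(name = "baseline arrow in PII and fewer oscillations in PIV",
         values = addPlateau(Reduce(function(v, at) addBump(v, time, at, 1),
                                    c(10, 25, 40, 70, 90), base),
                             time, 60, 240, 0.5),
         expect = list(class = "SPONTANEOUS", baseline_elevated_PII = TRUE,
                       fewer_oscillations_PIV_vs_PII = TRUE))
  )
}

## classify one archetype's value vector under default parameters
classifyArchetype <- function(values, sched = archetypeSchedule(),
                              params = analysisParams()) {
  raw <- caTrace(500 * values, schedule = sched)
  a <- analyzeTrace(raw, sched, params)
  classifyCell(a$rel, a$peaks, a$metrics, sched, params = params)
}
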
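mkMetrics <- function(n, baselines = c(1, 1, 1, 1)) {
  data.frame(phase = c("PI", "PII", "PIII", "PIV"), n_peaks = as.integer(n),
             peaks_per_min = as.numeric(n),
             mean_peak_height = ifelse(n > 0, 2, NA_real_),
             initial_max_peak_height = NA_real_, baseline = baselines)
}

test_that("activity typing follows the peak-count rules", {
  p <- analysisParams()
  expect_equal(classifyActivity(mkMetrics(c(3, 1, 2, 0)), p), "SPONTANEOUS")
  expect_equal(classifyActivity(mkMetrics(c(0, 0, 1, 0)), p), "STRETCH_ACTIVATED")
  expect_equal(classifyActivity(mkMetrics(c(1, 0, 0, 0)), p), "RANDOM_PEAKS")
  expect_equal(classifyActivity(mkMetrics(c(0, 0, 0, 0)), p), "NO_PEAKS")
  ## exactly at the spontaneity threshold counts (inclusive)
  expect_equal(classifyActivity(mkMetrics(c(2, 0, 0, 0)), p), "SPONTANEOUS")
  ## peakless sustained elevation still counts as stretch-activated
  expect_equal(classifyActivity(mkMetrics(c(0, 0, 0, 0)), p, sustainedPIII = TRUE),
               "STRETCH_ACTIVATED")
  ## optional PII spontaneity switch
  pII <- analysisParams(spontaneousIncludesPII = TRUE)
  expect_equal(classifyActivity(mkMetrics(c(1, 1, 0, 0)), pII), "SPONTANEOUS")
  expect_equal(classifyActivity(mkMetrics(c(1, 1, 0, 0)), p), "RANDOM_PEAKS")
})

## piecewise-constant relative trace over a 60-s phase split into thirds
thirdsTrace <- function(biThirds, sched = phaseSchedule()) {
  time <- seq(0, 240 - 0.1, by = 0.1)
  v <- rep(1, length(time))
  bounds <- seq(sched@starts[3L], sched@ends[3L], length.out = 4L)
  for (k in 1:3)
    v[time >= bounds[k] & time < bounds[k + 1L]] <- biThirds[k]
  caTrace(v, schedule = sched, relative = TRUE, s0 = 1)
}

test_that("sustained elevation requires E >= 1.5 with 20% retention, inclusively", {
  p <- analysisParams()
  sched <- phaseSchedule()
  w <- c(sched@starts[3L], sched@ends[3L])
  ## E = 1.6, floor = 1.32: both later thirds clear it
  expect_true(testSustainedElevation(thirdsTrace(c(2.6, 1.5, 1.4)), w, 1.0, p))
  ## E = 1.4 < 1.5: not sustained even though fully retained
  expect_false(testSustainedElevation(thirdsTrace(c(2.4, 2.4, 2.4)), w, 1.0, p))
  ## second third sags below the retention floor
  expect_false(testSustainedElevation(thirdsTrace(c(2.6, 1.2, 2.0)), w, 1.0, p))
  ## exact thresholds are inclusive: E = 1.5, later thirds at ref + 0.2*E
  expect_true(testSustainedElevation(thirdsTrace(c(2.5, 1.3, 1.3)), w, 1.0, p))
  ## missing reference flags missing data
  res <- testSustainedElevation(thirdsTrace(c(2.6, 2.6, 2.6)), w, NA_real_, p)
  expect_false(as.logical(res))
  expect_true(attr(res, "missing"))
  ## empty window flags missing data
  res2 <- testSustainedElevation(thirdsTrace(c(2.6, 2.6, 2.6)), c(500, 560), 1.0, p)
  expect_false(as.logical(res2))
  expect_true(attr(res2, "missing"))
})

test_that("stretch/release response categories compose the stated rules", {
  p <- analysisParams()
  sched <- phaseSchedule()
  time <- seq(0, 240 - 0.1, by = 0.1)

  ## sustained fixture
  relS <- thirdsTrace(c(2.6, 1.5, 1.4))
  mS <- computePhaseMetrics(relS, detectPeaks(relS, p), sched, p)
  expect_equal(categorizeStretchResponse(relS, mS, 3L, sched, p), "sustained")

  ## four PIII peaks over a flat baseline equal to PII
  v <- rep(1, length(time))
  for (at in c(125, 135, 145, 155)) v <- addBump(v, time, at, 1)
  relO <- caTrace(v, schedule = sched, relative = TRUE, s0 = 1)
  mO <- computePhaseMetrics(relO, detectPeaks(relO, p), sched, p)
  expect_equal(categorizeStretchResponse(relO, mO, 3L, sched, p), "oscillating")

  ## flat, peak-free phase
  relF <- caTrace(rep(1, length(time)), schedule = sched, relative = TRUE, s0 = 1)
  mF <- computePhaseMetrics(relF, detectPeaks(relF, p), sched, p)
  expect_equal(categorizeStretchResponse(relF, mF, 3L, sched, p), "neither")
  expect_equal(categorizeStretchResponse(relF, mF, 4L, sched, p), "neither")
})

test_that("baseline-elevation and oscillation-increase markers apply their thresholds", {
  p <- analysisParams()
  expect_false(detectBaselineElevation(1.0, 1.0, p))
  expect_true(detectBaselineElevation(1.0, 2.5, p))
  expect_false(detectBaselineElevation(2.5, 1.0, p))
  expect_true(detectBaselineElevation(1.0, 1.1, p))    # inclusive at 0.1
  expect_true(is.na(detectBaselineElevation(NA, 1.0, p)))

  expect_true(detectOscillationIncrease(2, 5))
  expect_false(detectOscillationIncrease(3, 3))        # strict inequality
  expect_false(detectOscillationIncrease(5, 2))
})

test_that("classifyCell assembles records and flags excluded or incomplete cells", {
  sched <- phaseSchedule()
  p <- analysisParams()

  ## spontaneous phenotype with a sustained stretch response
  out <- simulateTrace(phenotype(spontaneousRate = 6, stretchResponse = "sustained"),
                       sched, seed = 21)
  a <- analyzeTrace(out$trace, sched, p)
  rec <- classifyCell(a$rel, a$peaks, a$metrics, sched, params = p)
  expect_equal(rec$class, "SPONTANEOUS")
  expect_equal(rec$response_PIII, "sustained")
  expect_equal(rec$first_activity_phase, "PI")
  expect_true(rec$baseline_elevated_PIII)
  expect_false(rec$excluded)

  ## flat trace: silent, excluded
  flat <- caTrace(rep(500, 2400), schedule = sched)
  af <- analyzeTrace(flat, sched, p)
  recF <- classifyCell(af$rel, af$peaks, af$metrics, sched, params = p)
  expect_equal(recF$class, "NO_PEAKS")
  expect_true(recF$excluded)

  ## incomplete extraction
  recI <- classifyCells(list(flat), sched, p, incompleteIds = flat@cellId)
  expect_equal(recI$class, "INCOMPLETE")
  expect_true(is.na(recI$response_PIII))
})

test_that("the archetype suite classifies exactly as enumerated", {
  for (arch in buildArchetypes()) {
    rec <- classifyArchetype(arch$values)
    for (field in names(arch$expect))
      expect_equal(rec[[field]], arch$expect[[field]],
                   info = paste(arch$name, "-", field))
  }
})

test_that("every cell receives exactly one class and counts partition the cohort", {
  sched <- phaseSchedule()
  co <- simulateCohort(30, 0.5, sched, seed = 31)
  recs <- classifyCells(co$traces, sched)
  expect_equal(nrow(recs), 30L)
  expect_true(all(recs$class %in% c("SPONTANEOUS", "STRETCH_ACTIVATED",
                                    "RANDOM_PEAKS", "NO_PEAKS")))
  expect_equal(sum(table(recs$class)), 30L)
})

test_that("classification is invariant to positive rescaling of the raw trace", {
  sched <- phaseSchedule()
  p <- analysisParams()
  out <- simulateTrace(phenotype(spontaneousRate = 5, stretchResponse = "sustained"),
                       sched, seed = 41)
  base <- classifyCells(list(out$trace), sched, p)
  for (c0 in c(0.2, 3.7)) {
    scaled <- out$trace
    scaled@values <- scaled@values * c0
    rec <- classifyCells(list(scaled), sched, p)
    expect_equal(rec$class, base$class)
    expect_equal(rec$response_PIII, base$response_PIII)
    expect_equal(rec$n_peaks_PI, base$n_peaks_PI)
    expect_equal(rec$baseline_PIII, base$baseline_PIII, tolerance = 1e-9)
  }
})
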
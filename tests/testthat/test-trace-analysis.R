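test_that("S0 is the mean of the earliest peak-free window", {
  sched <- shortSchedule(phaseLength = 15)
  ## constant trace: S0 equals the constant
  expect_equal(estimateS0(caTrace(rep(50, 600), schedule = sched)), 50)

  ## a transient at t = 1 s pushes the window past it
  v <- rep(40, 600)
  v[8:14] <- c(60, 90, 120, 90, 70, 55, 45)   # peak apex near t = 1 s
  s0 <- estimateS0(caTrace(v, schedule = sched))
  expect_equal(s0, 40)

  expect_error(estimateS0(caTrace(rep(40, 20), schedule = sched)), "shorter")
  expect_error(estimateS0(caTrace(rep(0, 600), schedule = sched)), "zero")
})

test_that("S0 falls back to the low percentile when PI is never peak-free", {
  sched <- shortSchedule(phaseLength = 4, fps = 10)  # PI = 4 s
  v <- rep(40, 160)
  for (at in c(10, 25, 38)) v[at + (-2:2)] <- c(60, 90, 130, 90, 60)
  s0 <- estimateS0(caTrace(v, schedule = sched))
  expect_equal(s0, 40, tolerance = 1e-9)
})

test_that("normalisation divides pointwise and is scale invariant", {
  sched <- shortSchedule()
  raw <- caTrace(rep(80, 400), schedule = sched)
  rel <- normalizeTrace(raw)
  expect_true(all(rel@values == 1))
  expect_true(rel@relative)
  expect_equal(rel@s0, 80)

  v <- 50 * (1 + c(rep(0, 250), rep(2, 100), rep(0, 50)))
  r1 <- normalizeTrace(caTrace(v, schedule = sched))
  r2 <- normalizeTrace(caTrace(3 * v, schedule = sched))
  expect_equal(r1@values, r2@values, tolerance = 1e-12)
  expect_equal(max(r1@values), 3)
  expect_error(normalizeTrace(raw, s0 = -1), "positive")
})

test_that("peak detection matches analytic prominences on constructed traces", {
  sched <- shortSchedule()
  params <- analysisParams()
  flat <- caTrace(rep(1, 50), schedule = sched, relative = TRUE, s0 = 1)
  expect_equal(nrow(detectPeaks(flat, params)), 0L)

  ## single triangular bump of height 0.5 over baseline 1.0
  v <- rep(1, 60); v[28:32] <- 1 + c(0.25, 0.4, 0.5, 0.4, 0.25)
  pk <- detectPeaks(caTrace(v, schedule = sched, relative = TRUE, s0 = 1), params)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$index, 30L)
  expect_equal(pk$height, 1.5)
  expect_equal(pk$prominence, 0.5)

  ## plateau maxima are reported once, at the leftmost sample
  v2 <- c(1, 1, 2, 2, 2, 1, 1)
  pk2 <- detectPeaks(caTrace(v2, schedule = sched, relative = TRUE, s0 = 1), params)
  expect_equal(pk2$index, 3L)
  expect_equal(pk2$prominence, 1)

  expect_error(detectPeaks(caTrace(c(1, 2), schedule = sched), params), "3 samples")
})

test_that("peak detection agrees with the brute-force prominence oracle", {
  sched <- shortSchedule()
  set.seed(11)
  for (case in 1:200) {
    n <- sample(10:100, 1L)
    v <- randomWalkTrace(n)
    got <- detectPeaks(caTrace(v, time = seq_len(n) * 0.1, phase = rep(1L, n),
                               relative = TRUE, s0 = 1),
                       analysisParams(prominenceThreshold = 0.3))
    want <- oraclePeaks(v, 0.3)
    expect_identical(got$index, want$index)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
  }
})

test_that("raising the prominence threshold never adds peaks", {
  set.seed(12)
  sched <- shortSchedule()
  for (case in 1:30) {
    v <- randomWalkTrace(80)
    tr <- caTrace(v, time = seq_len(80) * 0.1, phase = rep(1L, 80),
                  relative = TRUE, s0 = 1)
    counts <- vapply(c(0.1, 0.3, 0.6, 1, 2), function(p)
      nrow(detectPeaks(tr, analysisParams(prominenceThreshold = p))), integer(1L))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("phase baseline is a low percentile robust to sparse peaks", {
  sched <- shortSchedule(phaseLength = 10)
  params <- analysisParams()
  w <- c(0, 10)
  const <- caTrace(rep(1, 400), schedule = sched, relative = TRUE, s0 = 1)
  expect_equal(phaseBaseline(const, w, params), 1)

  ## sparse transients (< 10% of samples) do not move the baseline
  v <- rep(1, 400); v[c(20, 21, 50, 51, 80, 81)] <- 3
  spiky <- caTrace(v, schedule = sched, relative = TRUE, s0 = 1)
  expect_equal(phaseBaseline(spiky, w, params), 1)

  ## a full-window step is tracked
  step <- caTrace(rep(2.5, 400), schedule = sched, relative = TRUE, s0 = 1)
  expect_equal(phaseBaseline(step, w, params), 2.5)

  expect_true(is.na(phaseBaseline(const, c(500, 600), params)))
})

test_that("phase metrics assign peaks by apex time and honour the 20-s response window", {
  sched <- phaseSchedule()
  params <- analysisParams()
  time <- seq(0, 240 - 0.1, by = 0.1)
  v <- rep(1, length(time))
  tr <- caTrace(v, schedule = sched, relative = TRUE, s0 = 1)

  ## no peaks: zero counts, missing heights
  m0 <- computePhaseMetrics(tr, detectPeaks(tr, params), sched, params)
  expect_equal(m0$n_peaks, rep(0L, 4L))
  expect_true(all(is.na(m0$mean_peak_height)))

  ## two PI peaks with heights 1.5 and 2.5 average to 2.0;
  ## PIII peaks at +5 s (height 3) and +30 s (height 4): only the first
  ## falls in the 20-s initial-response window
  v1 <- addBump(addBump(addBump(addBump(v, time, 10, 0.5), time, 30, 1.5),
                        time, 125, 2), time, 150, 3)
  tr1 <- caTrace(v1, schedule = sched, relative = TRUE, s0 = 1)
  m1 <- computePhaseMetrics(tr1, detectPeaks(tr1, params), sched, params)
  expect_equal(m1$n_peaks, c(2L, 0L, 2L, 0L))
  expect_equal(m1$mean_peak_height[1L], 2.0)
  expect_equal(m1$peaks_per_min[1L], 2)
  expect_equal(m1$initial_max_peak_height[3L], 3)
  expect_equal(m1$mean_peak_height[3L], 3.5)
})

test_that("peak height is at least its prominence above the surrounding minima", {
  set.seed(14)
  for (case in 1:20) {
    v <- randomWalkTrace(100)
    tr <- caTrace(v, time = seq_len(100) * 0.1, phase = rep(1L, 100),
                  relative = TRUE, s0 = 1)
    pk <- detectPeaks(tr, analysisParams())
    if (nrow(pk))
      expect_true(all(pk$height - min(v) >= pk$prominence - 1e-12))
  }
})
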
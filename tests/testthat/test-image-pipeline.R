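## small deterministic stacks keep these tests fast
makeStack <- function(frames, framePeriod = 0.1, phase = NULL) {
  if (is.null(phase)) phase <- rep(1L, length(frames))
  frameStack(frames, framePeriod, phaseTags = phase)
}

test_that("dark/flat correction inverts the camera model", {
  dark <- matrix(100, 16, 16)
  xv <- seq(-1, 1, length.out = 16)
  flat <- 1 - 0.4 * outer(xv^2, xv^2, "+") / 2
  corr <- correctionFrames(dark = dark, flat = flat)

  ## frame equal to the dark image corrects to zero
  st <- makeStack(list(dark))
  expect_true(all(correctStack(st, corr)@frames == 0))

  ## a uniformly illuminated vignetted frame becomes uniform
  obs <- dark + flat * 200
  out <- correctStack(makeStack(list(obs)), corr)@frames[, , 1L]
  expect_lt(diff(range(out)), 1e-9)
  expect_equal(mean(out), 200 * mean(flat), tolerance = 1e-9)

  expect_error(correctStack(makeStack(list(matrix(0, 8, 8))), corr), "dimensions")
  badFlat <- flat; badFlat[1L, 1L] <- -5
  expect_error(correctStack(st, correctionFrames(dark, badFlat)), "non-positive")
})

test_that("flat-field correction reduces background variation on a rendered scene", {
  scene <- renderScene(sceneSpec(nCells = 4, fieldSize = c(96, 96), seed = 2,
                                 vignettingStrength = 0.5),
                       phaseSchedule(phaseLength = 5, framePeriod = 0.5))
  darkSub <- pmax(scene$stack@frames[, , 1L] - scene$corrections@dark, 0)
  cor <- correctStack(scene$stack, scene$corrections)@frames[, , 1L]
  bg <- scene$labels@labels == 0L
  cv <- function(m) sd(m[bg]) / mean(m[bg])
  expect_lt(cv(cor), cv(darkSub))
})

test_that("phase splitting partitions frames by half-open windows", {
  sched <- phaseSchedule()   # four 60-s phases
  nf <- 2400L                # 240 s at 10 frames/s
  frames <- array(runif(4 * 4 * nf), c(4, 4, nf))
  stack <- frameStack(frames, 0.1, schedule = sched)
  groups <- splitPhases(stack, sched)
  expect_equal(vapply(groups, nFrames, integer(1L)),
               c(pre = 1200L, stretch = 600L, release = 600L))
  ## frame exactly at the 120-s boundary goes to the stretch group
  expect_equal(groups$stretch@phaseTags[1L], 3L)
  expect_equal(sum(vapply(groups, nFrames, integer(1L))), nf)

  ## zero-length stretch phase leaves that group empty
  zs <- phaseSchedule(starts = c(0, 60, 120, 120), ends = c(60, 120, 120, 240))
  g0 <- splitPhases(stack, zs)
  expect_equal(nFrames(g0$stretch), 0L)
  expect_equal(nFrames(g0$pre), 1200L)
  expect_equal(nFrames(g0$release), 1200L)

  long <- phaseSchedule(phaseLength = 100)
  expect_error(splitPhases(stack, long), "exceeds")
})

test_that("drift registration recovers injected translations", {
  set.seed(4)
  base <- matrix(0, 64, 64)
  for (k in 1:5) { cx <- sample(15:50, 1L); cy <- sample(15:50, 1L)
    for (y in -4:4) for (x in -4:4)
      if (x^2 + y^2 <= 16) base[cy + y, cx + x] <- base[cy + y, cx + x] + 100 }
  base <- base + matrix(runif(64 * 64, 0, 3), 64)

  aligned <- makeStack(list(base, base, base))
  regA <- registerDrift(aligned)
  for (tr in regA$transforms)
    expect_lt(max(abs(tr@translation)), 0.1)

  shifted <- matrix(0, 64, 64); shifted[4:64, 4:64] <- base[1:61, 1:61]
  st <- makeStack(list(base, base, shifted))
  reg <- registerDrift(st)
  expect_lt(max(abs(reg$transforms[[3L]]@translation - c(-3, -3))), 0.5)

  flat <- makeStack(list(base, matrix(7, 64, 64)))
  expect_error(registerDrift(flat), "frame 2")
})

test_that("segmentation labels separated and touching cells from the projection", {
  ## blank stack: all background, with a warning
  blank <- makeStack(list(matrix(5, 32, 32), matrix(5, 32, 32)))
  expect_warning(lab0 <- segmentCells(blank), "blank|empty")
  expect_equal(nCells(lab0), 0L)

  ## two touching discs with distinct intensity maxima split into two labels
  img <- matrix(0, 64, 64)
  mk <- function(cx, cy, r, amp) {
    for (y in seq(-r, r)) for (x in seq(-r, r))
      if (x^2 + y^2 <= r^2)
        img[cy + y, cx + x] <<- img[cy + y, cx + x] +
          amp * exp(-(x^2 + y^2) / (2 * (r / 1.5)^2))
  }
  mk(25, 32, 8, 200); mk(40, 32, 8, 180)
  st <- makeStack(list(img))
  lab <- segmentCells(st, tolerance = 0.05)
  expect_equal(nCells(lab), 2L)
  ## both maxima carry different labels
  expect_false(lab@labels[32, 25] == lab@labels[32, 40])
  expect_true(all(lab@labels[32, c(25, 40)] > 0L))
})

test_that("segmentation is stable under frame-order permutation", {
  scene <- renderScene(sceneSpec(nCells = 6, fieldSize = c(128, 128), seed = 13),
                       phaseSchedule(phaseLength = 10, framePeriod = 0.5))
  groups <- splitPhases(scene$stack, scene$schedule)
  st <- groups$stretch
  perm <- st
  set.seed(1)
  perm@frames <- st@frames[, , sample(nFrames(st))]
  expect_identical(segmentCells(st)@labels, segmentCells(perm)@labels)
})

test_that("cross-phase transform estimation recovers known similarity transforms", {
  set.seed(6)
  img <- matrix(0, 96, 96)
  for (k in 1:8) { cx <- sample(25:70, 1L); cy <- sample(25:70, 1L)
    for (y in -5:5) for (x in -5:5)
      if (x^2 + y^2 <= 25) img[cy + y, cx + x] <- img[cy + y, cx + x] + 150 }
  img <- img + matrix(runif(96 * 96, 0, 4), 96)
  ctr <- c((96 - 1) / 2, (96 - 1) / 2)

  ident <- estimatePhaseTransform(img, img)
  expect_equal(ident@scale, 1, tolerance = 0.01)
  expect_lt(max(abs(ident@translation)), 0.5)

  scaled <- stretchCa:::warpImage(img, similarityTransform(scale = 1.15, center = ctr),
                                  fill = median(img))
  est <- estimatePhaseTransform(img, scaled)
  expect_equal(est@scale, 1.15, tolerance = 0.01)

  shifted <- stretchCa:::warpImage(img, similarityTransform(translation = c(5, 0)),
                                   fill = median(img))
  est2 <- estimatePhaseTransform(img, shifted)
  expect_equal(est2@scale, 1, tolerance = 0.01)
  expect_equal(est2@translation[1L], 5, tolerance = 0.5)

  expect_error(estimatePhaseTransform(matrix(1, 96, 96), img), "featureless")
})

test_that("trace extraction averages ROI pixels per frame and flags missing cells", {
  sched <- phaseSchedule(phaseLength = 1, framePeriod = 0.5)
  lab <- matrix(0L, 20, 20); lab[5:8, 5:8] <- 1L
  lm <- labelMap(lab, "stretch")
  mkFrame <- function(cellVal) { m <- matrix(10, 20, 20); m[5:8, 5:8] <- cellVal; m }
  mk <- function(n, val, phase) frameStack(rep(list(mkFrame(val)), n), 0.5,
                                           phaseTags = rep(phase, n))
  stacks <- list(pre = frameStack(c(rep(list(mkFrame(100)), 4)), 0.5,
                                  phaseTags = c(1L, 1L, 2L, 2L)),
                 stretch = mk(2L, 250, 3L), release = mk(2L, 100, 4L))
  maps <- list(pre = lm, stretch = lm, release = lm)
  out <- extractTraces(stacks, maps, sched)
  expect_length(out$traces, 1L)
  tr <- out$traces[[1L]]
  expect_equal(length(tr), 8L)
  expect_equal(unique(tr@values[tr@phase %in% 1:2]), 100)
  expect_equal(unique(tr@values[tr@phase == 3L]), 250)
  expect_equal(out$incomplete, character())

  ## PIII transient exceeds PI maximum by construction
  expect_gt(max(tr@values[tr@phase == 3L]), max(tr@values[tr@phase == 1L]))

  ## a cell absent from one group is flagged incomplete
  lab2 <- lab; lab2[lab2 == 1L] <- 0L
  maps2 <- list(pre = lm, stretch = lm, release = labelMap(lab2, "release"))
  out2 <- extractTraces(stacks, maps2, sched)
  expect_equal(out2$incomplete, "1")

  ## no labels anywhere: empty result, no error
  empty <- labelMap(matrix(0L, 20, 20))
  out3 <- extractTraces(stacks, list(pre = empty, stretch = empty,
                                     release = empty), sched)
  expect_length(out3$traces, 0L)
})
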
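## Independent brute-force prominence oracle. For every candidate local
## maximum (plateaus collapsed to their leftmost sample, runs touching the
## trace ends excluded), scan outward on each side to the first strictly
## higher sample (or the end), take the minimum of each flank, and define
## prominence = peak value - max(flank minima). O(n^2); used only as a
## reference for the package's detector.
oraclePeaks <- function(v, prominenceMin) {
  n <- length(v)
  idx <- integer(); prom <- numeric()
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L   # plateau run [i, j]
      if (j < n && v[j + 1L] < v[i]) {
        lo <- Inf
        for (k in (i - 1L):1L) { if (v[k] > v[i]) break; lo <- min(lo, v[k]) }
        hi <- Inf
        for (k in (j + 1L):n) { if (v[k] > v[i]) break; hi <- min(hi, v[k]) }
        p <- v[i] - max(lo, hi)
        if (p >= prominenceMin) { idx <- c(idx, i); prom <- c(prom, p) }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(index = idx, prominence = prom)
}

## Random trace generators for property tests.
randomWalkTrace <- function(n, sd = 0.3) cumsum(rnorm(n, 0, sd)) + 1

## A quick schedule for short constructed traces: four `phaseLength`-second
## phases sampled at `fps` frames/s.
shortSchedule <- function(phaseLength = 10, fps = 10)
  phaseSchedule(phaseLength = phaseLength, framePeriod = 1 / fps)
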
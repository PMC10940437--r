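#' Synthetic scene specification
#'
#' Ground-truth description of a synthetic stretch experiment: cell count
#' and geometry, per-cell phenotypes, the isotropic stretch applied at the
#' \code{PIII} onset, per-phase-group field drift, and the camera noise
#' model (dark offset, vignetting flat-field, signal-dependent noise).
#' Identical specs (same seed) render bit-identical stacks.
#'
#' @slot nCells number of cells (>= 1).
#' @slot fieldSize \code{c(height, width)} in pixels.
#' @slot cellRadiusRange \code{c(min, max)} cell radius in pixels.
#' @slot phenotypes list of \linkS4class{Phenotype}, length \code{nCells}
#'   (recycled if shorter).
#' @slot stretchScale isotropic scale applied at \code{PIII} onset (>= 1).
#' @slot drift 3 x 2 matrix of per-phase-group (pre/stretch/release) field
#'   translations in pixels (x, y).
#' @slot darkOffset camera dark level (counts).
#' @slot background substrate background signal (counts).
#' @slot cellBrightness baseline cell signal (counts); the raw trace scale.
#' @slot vignettingStrength relative intensity falloff at the field corner.
#' @slot noiseSd relative photon-noise level (see
#'   \code{\link{simulateTrace}}).
#' @slot readNoiseSd Gaussian read noise sd (counts).
#' @slot seed integer RNG seed.
#' @export
setClass("SceneSpec",
  representation(nCells = "integer", fieldSize = "integer",
                 cellRadiusRange = "numeric", phenotypes = "list",
                 stretchScale = "numeric", drift = "matrix",
                 darkOffset = "numeric", background = "numeric",
                 cellBrightness = "numeric", vignettingStrength = "numeric",
                 noiseSd = "numeric", readNoiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
    if (object@stretchScale < 1) msg <- c(msg, "stretchScale must be >= 1")
    if (any(object@cellRadiusRange <= 0) ||
        object@cellRadiusRange[1L] > object@cellRadiusRange[2L])
      msg <- c(msg, "cellRadiusRange must be positive and ordered")
    need <- ceiling(2 * (object@cellRadiusRange[2L] * object@stretchScale + 3))
    if (any(object@fieldSize < need))
      msg <- c(msg, "field too small for the requested cell radii")
    if (!all(dim(object@drift) == c(3L, 2L)))
      msg <- c(msg, "drift must be a 3 x 2 matrix")
    if (length(msg)) msg else TRUE
  })

#' Construct a scene specification
#'
#' @param nCells number of cells.
#' @param fieldSize \code{c(height, width)} px (default 256 x 256).
#' @param cellRadiusRange \code{c(min, max)} radius in px (default 5-8).
#' @param phenotypes list of \linkS4class{Phenotype}s (recycled); default is
#'   an equal mix of spontaneous and stretch-responding cells.
#' @param stretchScale isotropic scale at \code{PIII} onset (default 1.15,
#'   i.e. 15 percent radial stretch).
#' @param drift 3 x 2 per-group (x, y) field translation in px; default a
#'   small shift during stretch and release.
#' @param darkOffset,background,cellBrightness intensity model (counts).
#' @param vignettingStrength,noiseSd,readNoiseSd noise model.
#' @param seed integer seed.
#' @return A \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(nCells = 20, fieldSize = c(256, 256),
                      cellRadiusRange = c(5, 8), phenotypes = NULL,
                      stretchScale = 1.15,
                      drift = rbind(pre = c(0, 0), stretch = c(2, -1.5),
                                    release = c(-1, 1)),
                      darkOffset = 100, background = 40, cellBrightness = 500,
                      vignettingStrength = 0.3, noiseSd = 0.02,
                      readNoiseSd = 2, seed = 1) {
  if (is.null(phenotypes))
    phenotypes <- list(phenotype(spontaneousRate = 6, stretchResponse = "oscillating"),
                       phenotype(stretchResponse = "sustained"))
  new("SceneSpec", nCells = as.integer(nCells),
      fieldSize = as.integer(fieldSize),
      cellRadiusRange = as.numeric(cellRadiusRange),
      phenotypes = rep(phenotypes, length.out = nCells),
      stretchScale = as.numeric(stretchScale),
      drift = matrix(as.numeric(drift), 3L, 2L,
                     dimnames = list(c("pre", "stretch", "release"), c("x", "y"))),
      darkOffset = as.numeric(darkOffset), background = as.numeric(background),
      cellBrightness = as.numeric(cellBrightness),
      vignettingStrength = as.numeric(vignettingStrength),
      noiseSd = as.numeric(noiseSd), readNoiseSd = as.numeric(readNoiseSd),
      seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d cells in %d x %d px, stretch x%.2f, seed %d\n",
    object@nCells, object@fieldSize[1L], object@fieldSize[2L],
    object@stretchScale, object@seed))
})

## Non-overlapping circle placement by rejection sampling; cells (and their
## stretched images) must stay clear of the border. 0-based (x, y) centres.
placeCells <- function(spec, maxTries = 1000L * spec@nCells) {
  h <- spec@fieldSize[1L]; w <- spec@fieldSize[2L]
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  centers <- matrix(NA_real_, spec@nCells, 2L)
  radii <- numeric(spec@nCells)
  tries <- 0L
  for (i in seq_len(spec@nCells)) {
    repeat {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not place ", spec@nCells,
             " non-overlapping cells after ", maxTries, " attempts")
      r <- runif(1L, spec@cellRadiusRange[1L], spec@cellRadiusRange[2L])
      margin <- r * spec@stretchScale + 3
      p <- c(runif(1L, margin, w - 1 - margin), runif(1L, margin, h - 1 - margin))
      ps <- applyStretchTransform(p, spec@stretchScale, ctr)
      rs <- r * spec@stretchScale
      if (ps[1L] < rs + 6 || ps[1L] > w - 7 - rs ||
          ps[2L] < rs + 6 || ps[2L] > h - 7 - rs) next
      if (i > 1L) {
        d <- sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE], 2L, p)^2))
        minD <- (radii[seq_len(i - 1L)] + r) * spec@stretchScale + 2
        if (any(d < minD)) next
      }
      centers[i, ] <- p; radii[i] <- r
      break
    }
  }
  list(centers = centers, radii = radii)
}

## Soft-edged disc footprint: pixel indices (into an h x w matrix) and
## weights in [0, 1] for a cell at 0-based centre (x, y) with radius r.
discFootprint <- function(center, r, h, w, edge = 1) {
  x0 <- max(0L, floor(center[1L] - r - edge)); x1 <- min(w - 1L, ceiling(center[1L] + r + edge))
  y0 <- max(0L, floor(center[2L] - r - edge)); y1 <- min(h - 1L, ceiling(center[2L] + r + edge))
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - center[2L])^2, (xs - center[1L])^2, "+"))
  wgt <- pmin(1, pmax(0, (r + edge / 2 - d) / edge))
  sel <- wgt > 0
  idx <- which(sel)
  yy <- ((idx - 1L) %% length(ys)) + y0 + 1L
  xx <- ((idx - 1L) %/% length(ys)) + x0 + 1L
  list(index = (xx - 1L) * h + yy, weight = wgt[sel])
}

#' Render a synthetic stretch experiment
#'
#' Generates a full four-phase image stack with known ground truth. Cells
#' are soft-edged discs at non-overlapping positions; each carries a
#' simulated fluorescence trace (see \code{\link{simulateTrace}}). At the
#' \code{PIII} onset all positions and radii are scaled isotropically about
#' the field centre by \code{stretchScale} (and revert at release), with a
#' per-group field drift emulating chamber shift. The camera model adds a
#' radial vignetting flat-field, a constant dark offset, signal-dependent
#' photon-like noise and Gaussian read noise, quantised to 16-bit counts.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param schedule a \linkS4class{PhaseSchedule}; the default renders at
#'   2 frames/s to keep stacks compact.
#' @return A list: \code{stack} (\linkS4class{FrameStack}), \code{corrections}
#'   (\linkS4class{CorrectionFrames}: true dark and flat),
#'   \code{labels} (ground-truth \linkS4class{LabelMap} in stretch-phase
#'   coordinates), \code{truth} (data.frame of per-cell, per-group centroids,
#'   radii, areas and phenotype fields), \code{events} (list of per-cell true
#'   event tables), \code{schedule}.
#' @export
renderScene <- function(spec, schedule = phaseSchedule(framePeriod = 0.5)) {
  stopifnot(is(spec, "SceneSpec"), is(schedule, "PhaseSchedule"))
  validObject(spec)
  h <- spec@fieldSize[1L]; w <- spec@fieldSize[2L]
  ctr <- c((w - 1) / 2, (h - 1) / 2)

  withr::with_seed(spec@seed, {
    geo <- placeCells(spec)
    traceSeeds <- sample.int(.Machine$integer.max, spec@nCells)

    sims <- lapply(seq_len(spec@nCells), function(i)
      simulateTrace(spec@phenotypes[[i]], schedule, seed = traceSeeds[i],
                    s0True = 1, noiseSd = 0))  # noiseless relative dynamics
    relM <- do.call(rbind, lapply(sims, function(s) s$trace@values))

    ## geometry per phase group
    groupOf <- c(1L, 1L, 2L, 3L)[phaseOfTime(schedule,
      schedule@starts[1L] + (seq_len(ncol(relM)) - 1L) * schedule@framePeriod)]
    centers <- list(pre = geo$centers,
                    stretch = applyStretchTransform(geo$centers, spec@stretchScale, ctr),
                    release = geo$centers)
    radii <- list(pre = geo$radii, stretch = geo$radii * spec@stretchScale,
                  release = geo$radii)
    for (g in 1:3) centers[[g]] <- sweep(centers[[g]], 2L, spec@drift[g, ], "+")

    footprints <- lapply(1:3, function(g)
      lapply(seq_len(spec@nCells), function(i)
        discFootprint(centers[[g]][i, ], radii[[g]][i], h, w)))

    ## camera model
    yv <- (0:(h - 1)) - ctr[2L]; xv <- (0:(w - 1)) - ctr[1L]
    d2 <- outer(yv^2, xv^2, "+")
    flat <- 1 - spec@vignettingStrength * d2 / max(d2)
    dark <- matrix(spec@darkOffset, h, w)

    nf <- ncol(relM)
    frames <- array(0, c(h, w, nf))
    for (t in seq_len(nf)) {
      sig <- matrix(spec@background, h, w)
      fps <- footprints[[groupOf[t]]]
      for (i in seq_len(spec@nCells)) {
        fp <- fps[[i]]
        sig[fp$index] <- sig[fp$index] +
          spec@cellBrightness * relM[i, t] * fp$weight
      }
      obs <- dark + flat * sig
      ## photon-like variance grows linearly with signal; calibrated so the
      ## relative noise at cellBrightness equals noiseSd
      noise <- rnorm(h * w, 0,
                     sd = sqrt(spec@noiseSd^2 * spec@cellBrightness * pmax(sig, 0) +
                               spec@readNoiseSd^2))
      frames[, , t] <- pmin(65535, pmax(0, round(obs + noise)))
    }
    stack <- frameStack(frames, schedule@framePeriod, schedule = schedule)

    ## ground-truth label map in stretch-phase coordinates (hard discs)
    lab <- matrix(0L, h, w)
    for (i in seq_len(spec@nCells)) {
      fp <- discFootprint(centers$stretch[i, ], radii$stretch[i], h, w, edge = 1e-6)
      lab[fp$index] <- i
    }
    truth <- do.call(rbind, lapply(1:3, function(g)
      data.frame(cell_id = as.character(seq_len(spec@nCells)),
                 group = c("pre", "stretch", "release")[g],
                 x = centers[[g]][, 1L], y = centers[[g]][, 2L],
                 radius = radii[[g]],
                 area = pi * radii[[g]]^2,
                 spontaneous_rate = vapply(spec@phenotypes, slot, numeric(1L),
                                           "spontaneousRate"),
                 stretch_response = vapply(spec@phenotypes, slot, character(1L),
                                           "stretchResponse"))))
    list(stack = stack,
         corrections = correctionFrames(dark = dark, flat = flat),
         labels = labelMap(lab, "stretch"),
         truth = truth,
         events = lapply(sims, `[[`, "events"),
         schedule = schedule)
  })
}
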
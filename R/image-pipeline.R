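#' Dark and flat-field correction
#'
#' Standard shading correction for scientific cameras: the dark frame
#' (fixed-pattern offset) is subtracted from every frame and the result is
#' divided by the flat-field image, normalised to unit mean so that the
#' overall intensity scale is preserved. Negative values after subtraction
#' are clipped at zero.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param corr a \linkS4class{CorrectionFrames}.
#' @return The corrected \linkS4class{FrameStack}.
#' @export
correctStack <- function(stack, corr) {
  stopifnot(is(stack, "FrameStack"), is(corr, "CorrectionFrames"))
  d <- dim(stack@frames)
  if (!all(d[1:2] == dim(corr@dark)))
    stop("correction frames do not match stack dimensions (",
         paste(d[1:2], collapse = "x"), " vs ",
         paste(dim(corr@dark), collapse = "x"), ")")
  flatN <- corr@flat / mean(corr@flat)
  if (any(flatN <= 0))
    stop("flat field contains non-positive values after normalisation")
  out <- stack
  out@frames <- array(pmax(sweep(stack@frames, 1:2, corr@dark), 0), d)
  out@frames <- sweep(out@frames, 1:2, flatN, "/")
  out
}

#' Split a recording into phase-group stacks
#'
#' The recording is partitioned into the three stacks used for segmentation
#' and ROI mapping: \code{pre} (\code{PI} + \code{PII}, pre-stretch),
#' \code{stretch} (\code{PIII}) and \code{release} (\code{PIV}). Frames are
#' assigned by their acquisition time under the half-open \code{[start, end)}
#' convention, so a frame exactly at a boundary belongs to the later phase.
#'
#' @param stack a \linkS4class{FrameStack} covering the full recording.
#' @param schedule a \linkS4class{PhaseSchedule}; must fit within the stack.
#' @return A named list of \linkS4class{FrameStack}s (\code{pre},
#'   \code{stretch}, \code{release}); zero-length groups are empty stacks.
#' @export
splitPhases <- function(stack, schedule) {
  stopifnot(is(stack, "FrameStack"), is(schedule, "PhaseSchedule"))
  t <- frameTimes(stack) + schedule@starts[1L]
  dur <- t[length(t)] + stack@framePeriod
  if (schedule@ends[4L] > dur + 1e-9)
    stop("schedule (", schedule@ends[4L], " s) exceeds stack duration (",
         dur, " s)")
  ph <- phaseOfTime(schedule, t)
  groups <- list(pre = which(ph %in% 1:2), stretch = which(ph == 3L),
                 release = which(ph == 4L))
  lapply(groups, function(idx) {
    d <- dim(stack@frames)
    fr <- stack@frames[, , idx, drop = FALSE]
    new("FrameStack", frames = array(fr, c(d[1:2], length(idx))),
        framePeriod = stack@framePeriod,
        phaseTags = as.integer(ph[idx]))
  })
}

## Integer-pixel translation estimate source -> target by FFT cross
## correlation, refined to sub-pixel accuracy with a parabolic fit around
## the correlation maximum. Returns c(dx, dy) such that shifting the source
## by (dx, dy) aligns it with the target.
phaseCorrelate <- function(source, target) {
  a <- source - mean(source); b <- target - mean(target)
  Fa <- fft(a); Fb <- fft(b)
  cc <- Re(fft(Fb * Conj(Fa), inverse = TRUE))
  h <- nrow(cc); w <- ncol(cc)
  k <- which.max(cc)
  iy <- (k - 1L) %% h; ix <- (k - 1L) %/% h
  ## sub-pixel refinement by 1-D parabola in each axis (circular indexing)
  parab <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else 0.5 * (cm - cp) / den
  }
  ym <- cc[(iy - 1L) %% h + 1L, ix + 1L]; y0 <- cc[iy + 1L, ix + 1L]
  yp <- cc[(iy + 1L) %% h + 1L, ix + 1L]
  xm <- cc[iy + 1L, (ix - 1L) %% w + 1L]; xp <- cc[iy + 1L, (ix + 1L) %% w + 1L]
  dy <- iy + parab(ym, y0, yp); dx <- ix + parab(xm, y0, xp)
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dx = dx, dy = dy)
}

#' Correct xy-drift within a stack
#'
#' Estimates a translation for every frame against a reference frame by
#' Fourier cross-correlation with sub-pixel refinement, and resamples each
#' frame into the reference coordinates (bilinear interpolation). Rotation
#' and scale are assumed constant within a phase group; cross-group scale
#' changes are handled by \code{\link{estimatePhaseTransform}}.
#'
#' @param stack a non-empty \linkS4class{FrameStack}.
#' @param referenceIndex index of the reference frame (default 1).
#' @return A list: \code{stack} (registered \linkS4class{FrameStack}) and
#'   \code{transforms} (list of per-frame \linkS4class{SimilarityTransform}
#'   mapping original to reference coordinates).
#' @export
registerDrift <- function(stack, referenceIndex = 1L) {
  stopifnot(is(stack, "FrameStack"))
  nf <- nFrames(stack)
  if (nf == 0L) stop("cannot register an empty stack")
  if (referenceIndex < 1L || referenceIndex > nf)
    stop("reference index out of range")
  ref <- stack@frames[, , referenceIndex]
  if (sd(ref) == 0)
    stop("registration failure: reference frame ", referenceIndex,
         " is featureless (constant)")
  out <- stack
  transforms <- vector("list", nf)
  for (i in seq_len(nf)) {
    fr <- stack@frames[, , i]
    if (sd(fr) == 0)
      stop("registration failure: frame ", i, " is featureless (constant)")
    sh <- phaseCorrelate(fr, ref)
    tr <- similarityTransform(translation = c(sh[["dx"]], sh[["dy"]]))
    transforms[[i]] <- tr
    out@frames[, , i] <- if (all(abs(tr@translation) < 1e-3)) fr
                         else warpImage(fr, tr, fill = median(fr))
  }
  list(stack = out, transforms = transforms)
}

#' Estimate the similarity transform between two phase-group images
#'
#' Recovers the isotropic scale and translation that map the source image
#' onto the target image, absorbing the stretch-induced scale change between
#' phase groups. The scale is found by a coarse grid search (each candidate
#' scale is applied about the image centre and the residual translation
#' estimated by cross-correlation), followed by a local golden-section
#' refinement of the correlation score.
#'
#' @param source,target 2-D intensity arrays of identical size (typically
#'   maximum-intensity projections of registered phase groups).
#' @param scaleRange numeric(2), search interval for the scale.
#' @return A \linkS4class{SimilarityTransform} mapping source to target
#'   coordinates (centre = image centre, rotation fixed at 0).
#' @export
estimatePhaseTransform <- function(source, target, scaleRange = c(0.8, 1.3)) {
  if (!all(dim(source) == dim(target))) stop("images must share dimensions")
  if (sd(source) == 0 || sd(target) == 0)
    stop("transform estimation failed: featureless image")
  ctr <- c((ncol(source) - 1) / 2, (nrow(source) - 1) / 2)
  tgt <- target - mean(target)
  score <- function(s) {
    warped <- warpImage(source, similarityTransform(scale = s, center = ctr),
                        fill = median(source))
    sh <- phaseCorrelate(warped, target)
    shifted <- warpImage(warped,
                         similarityTransform(translation = c(sh[["dx"]], sh[["dy"]])),
                         fill = median(source))
    sc <- shifted - mean(shifted)
    list(cor = sum(sc * tgt) / sqrt(sum(sc^2) * sum(tgt^2)), shift = sh)
  }
  grid <- seq(scaleRange[1L], scaleRange[2L], by = 0.01)
  cors <- vapply(grid, function(s) score(s)$cor, numeric(1L))
  if (!any(is.finite(cors))) stop("transform estimation failed to converge")
  sBest <- grid[which.max(cors)]
  opt <- stats::optimize(function(s) score(s)$cor,
                         interval = c(sBest - 0.01, sBest + 0.01),
                         maximum = TRUE, tol = 1e-4)
  sHat <- opt$maximum
  if (score(sHat)$cor < cors[which.max(cors)]) sHat <- sBest
  sh <- score(sHat)$shift
  similarityTransform(scale = sHat, translation = c(sh[["dx"]], sh[["dy"]]),
                      center = ctr)
}

#' Segment cells from the stretch-phase stack
#'
#' Cell segmentation runs on the temporal maximum-intensity projection of
#' the stretch-phase stack, where active cells are brightest. Foreground is
#' defined by a global threshold (Otsu's method on the projection by
#' default, or a user-supplied absolute value), the projection is smoothed
#' with a 1-px Gaussian, and cells are separated by a watershed seeded at
#' the regional intensity maxima within the foreground (equal-plateau
#' maxima merge into one seed). Regions smaller than \code{minArea} or
#' touching the image border are removed and the remaining labels are
#' renumbered contiguously.
#'
#' @param stack the stretch-phase \linkS4class{FrameStack}.
#' @param threshold \code{"otsu"} (default) or an absolute intensity value.
#' @param minArea minimum region area in px^2 (default 30).
#' @param smoothSigma Gaussian smoothing sigma in px (default 1).
#' @param tolerance minimum intensity drop separating two watershed seeds
#'   (in units of the projection; default 0.05 of the dynamic range).
#' @param coordinateFrame phase-group tag for the returned map.
#' @return A \linkS4class{LabelMap}; all-background (with a warning) when no
#'   foreground survives.
#' @export
segmentCells <- function(stack, threshold = "otsu", minArea = 30,
                         smoothSigma = 1, tolerance = NULL,
                         coordinateFrame = "stretch") {
  stopifnot(is(stack, "FrameStack"))
  if (nFrames(stack) == 0L) stop("cannot segment an empty stack")
  proj <- apply(stack@frames, 1:2, max)
  rng <- range(proj)
  if (diff(rng) == 0) {
    warning("blank projection: returning all-background label map")
    return(labelMap(matrix(0L, nrow(proj), ncol(proj)), coordinateFrame))
  }
  projN <- (proj - rng[1L]) / diff(rng)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(projN), range = c(0, 1))
  } else (as.numeric(threshold) - rng[1L]) / diff(rng)
  mask <- projN > thr
  if (!any(mask)) {
    warning("empty foreground: returning all-background label map")
    return(labelMap(matrix(0L, nrow(proj), ncol(proj)), coordinateFrame))
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(projN), sigma = smoothSigma))
  if (is.null(tolerance)) tolerance <- 0.05
  ws <- EBImage::watershed(EBImage::Image(sm * mask), tolerance = tolerance,
                           ext = 1L)
  lab <- matrix(as.integer(as.matrix(ws)), nrow(proj), ncol(proj))
  lab[!mask] <- 0L
  lab <- pruneLabels(lab, minArea = minArea, dropBorder = TRUE)
  labelMap(lab, coordinateFrame)
}

## Remove small and border-touching regions; renumber labels contiguously.
pruneLabels <- function(lab, minArea = 0, dropBorder = TRUE) {
  if (!any(lab > 0L)) return(lab)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < minArea)
  if (dropBorder) {
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  old <- sort(unique(lab[lab > 0L]))
  if (length(old)) {
    remap <- integer(max(old)); remap[old] <- seq_along(old)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Map a label map into another phase group's coordinates
#'
#' Carries every labelled region into the target coordinate frame through
#' the inverse of the given transform: each target pixel looks up its label
#' at the back-transformed source position (nearest-neighbour, so labels
#' stay integral). Label identity is preserved, which is what ties the same
#' cell together before, during and after stretch. Labels that land
#' entirely outside the field are dropped and reported.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param transform a \linkS4class{SimilarityTransform} mapping the source
#'   frame to the target frame.
#' @param targetDim dimensions of the target field (default: same as
#'   source).
#' @param coordinateFrame tag for the returned map.
#' @return A \linkS4class{LabelMap} in target coordinates, with attribute
#'   \code{dropped} listing labels lost in the mapping.
#' @export
mapRois <- function(labels, transform, targetDim = dim(labels@labels),
                    coordinateFrame = "mapped") {
  stopifnot(is(labels, "LabelMap"), is(transform, "SimilarityTransform"))
  inv <- invertTransform(transform)
  h <- targetDim[1L]; w <- targetDim[2L]
  grid <- cbind(x = rep(0:(w - 1L), each = h), y = rep(0:(h - 1L), times = w))
  src <- transformPoints(inv, grid)
  mapped <- matrix(nearestSample(labels@labels, src[, 1L], src[, 2L], fill = 0L),
                   h, w)
  before <- sort(unique(labels@labels[labels@labels > 0L]))
  after <- unique(mapped[mapped > 0L])
  dropped <- setdiff(before, after)
  out <- new("LabelMap", labels = mapped, coordinateFrame = coordinateFrame)
  attr(out, "dropped") <- as.integer(dropped)
  out
}

#' Extract per-cell intensity traces across phase groups
#'
#' For every cell and frame, the mean pixel intensity over the cell's ROI is
#' computed in the coordinate frame of that frame's phase group, and the
#' per-group traces are concatenated in time order over all four phases.
#' Cells absent from any group's label map are flagged incomplete and are
#' excluded from classification downstream.
#'
#' @param phaseStacks named list of \linkS4class{FrameStack}s (\code{pre},
#'   \code{stretch}, \code{release}) from \code{\link{splitPhases}}.
#' @param labelMaps named list of \linkS4class{LabelMap}s, one per group, in
#'   that group's coordinates, sharing label identities.
#' @param schedule a \linkS4class{PhaseSchedule}.
#' @param sampleId sample identifier stamped on each trace.
#' @return A list: \code{traces} (list of raw \linkS4class{CaTrace}, one per
#'   label present in at least one group) and \code{incomplete} (character
#'   ids of cells missing from some group).
#' @export
extractTraces <- function(phaseStacks, labelMaps, schedule, sampleId = "sample") {
  groups <- c("pre", "stretch", "release")
  stopifnot(all(groups %in% names(phaseStacks)), all(groups %in% names(labelMaps)))
  allLabels <- sort(unique(unlist(lapply(labelMaps, function(lm)
    lm@labels[lm@labels > 0L]))))
  if (!length(allLabels))
    return(list(traces = list(), incomplete = character()))
  nLab <- max(allLabels)
  perGroup <- lapply(groups, function(g) {
    st <- phaseStacks[[g]]; lm <- labelMaps[[g]]@labels
    nf <- nFrames(st)
    m <- matrix(NA_real_, nLab, nf)
    sel <- lm > 0L
    if (any(sel) && nf > 0L) {
      labv <- lm[sel]
      counts <- tabulate(labv, nbins = nLab)
      for (i in seq_len(nf)) {
        fr <- st@frames[, , i]
        sums <- rowsum(fr[sel], labv)
        m[as.integer(rownames(sums)), i] <- sums[, 1L] /
          counts[as.integer(rownames(sums))]
      }
    }
    m
  })
  names(perGroup) <- groups
  tags <- unlist(lapply(groups, function(g) phaseStacks[[g]]@phaseTags))
  full <- do.call(cbind, perGroup)
  dt <- phaseStacks$pre@framePeriod
  time <- schedule@starts[1L] + (seq_len(ncol(full)) - 1L) * dt

  traces <- list(); incomplete <- character()
  for (k in allLabels) {
    v <- full[k, ]
    if (anyNA(v)) {
      incomplete <- c(incomplete, as.character(k))
      if (all(is.na(v))) next
      v[is.na(v)] <- 0
    }
    traces[[as.character(k)]] <- caTrace(v, time = time, phase = tags,
                                         cellId = as.character(k),
                                         sampleId = sampleId)
  }
  if (length(allLabels) && !length(traces) && length(incomplete) == 0L)
    stop("no label present in any phase group")
  list(traces = traces, incomplete = incomplete)
}
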
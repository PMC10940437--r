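## 16-bit grayscale TIFF I/O. The tiff package works on [0, 1] doubles; raw
## camera counts are mapped through the 16-bit range.
TIFF_MAX <- 65535

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file path.
#' @param framePeriod seconds per frame.
#' @param schedule optional \linkS4class{PhaseSchedule} to derive phase tags.
#' @return A \linkS4class{FrameStack} in camera counts.
#' @export
readStackTIFF <- function(path, framePeriod, schedule = NULL) {
  if (!file.exists(path)) stop("stack not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(unlist(pages) * TIFF_MAX, c(dim(pages[[1L]]), length(pages)))
  frameStack(round(frames), framePeriod, schedule = schedule,
             phaseTags = if (is.null(schedule)) rep(1L, length(pages)) else NULL)
}

#' Write a stack as a multi-page 16-bit TIFF
#' @param stack a \linkS4class{FrameStack} in camera counts (0..65535).
#' @param path output path.
#' @export
writeStackTIFF <- function(stack, path) {
  pages <- lapply(seq_len(nFrames(stack)), function(i)
    pmin(pmax(stack@frames[, , i] / TIFF_MAX, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read/write single-page correction frames
#' @param darkPath,flatPath single-page TIFF paths.
#' @return A \linkS4class{CorrectionFrames} in camera counts.
#' @export
readCorrectionTIFF <- function(darkPath, flatPath) {
  for (p in c(darkPath, flatPath))
    if (!file.exists(p)) stop("correction frame not found: ", p)
  dark <- tiff::readTIFF(darkPath) * TIFF_MAX
  flat <- tiff::readTIFF(flatPath) * TIFF_MAX
  correctionFrames(dark = dark, flat = flat)
}

#' @rdname readCorrectionTIFF
#' @param corr a \linkS4class{CorrectionFrames}.
#' @export
writeCorrectionTIFF <- function(corr, darkPath, flatPath) {
  tiff::writeTIFF(pmin(pmax(corr@dark / TIFF_MAX, 0), 1), darkPath,
                  bits.per.sample = 16L, compression = "none")
  ## the flat field is dimensionless (~1); scale into the 16-bit range
  tiff::writeTIFF(pmin(pmax(corr@flat * 1e4 / TIFF_MAX, 0), 1), flatPath,
                  bits.per.sample = 16L, compression = "none")
  invisible(c(darkPath, flatPath))
}

#' Write/read a label map as 16-bit TIFF
#' @param labels a \linkS4class{LabelMap}.
#' @param path TIFF path.
#' @export
writeLabelTIFF <- function(labels, path) {
  tiff::writeTIFF(labels@labels / TIFF_MAX, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabelTIFF
#' @param coordinateFrame tag for the map.
#' @export
readLabelTIFF <- function(path, coordinateFrame = "stretch") {
  if (!file.exists(path)) stop("label map not found: ", path)
  img <- tiff::readTIFF(path)
  labelMap(matrix(as.integer(round(img * TIFF_MAX)), nrow = nrow(img)),
           coordinateFrame)
}

#' Write traces to a tidy CSV table
#'
#' One row per cell and frame with columns \code{cell_id}, \code{frame},
#' \code{time_s}, \code{phase}, \code{raw_intensity} (or
#' \code{relative_intensity} for normalised traces).
#'
#' @param traces list of \linkS4class{CaTrace}.
#' @param path CSV path.
#' @export
writeTracesCSV <- function(traces, path) {
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr@cellId, sample_id = tr@sampleId,
               frame = seq_along(tr@values), time_s = tr@time,
               phase = PHASE_IDS[tr@phase], intensity = tr@values,
               relative = tr@relative)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTracesCSV
#' @return \code{readTracesCSV}: a list of \linkS4class{CaTrace}.
#' @export
readTracesCSV <- function(path) {
  if (!file.exists(path)) stop("trace table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$cell_id), function(d) {
    d <- d[order(d$time_s), ]
    caTrace(d$intensity, time = d$time_s,
            phase = match(d$phase, PHASE_IDS),
            cellId = d$cell_id[1L], sampleId = d$sample_id[1L],
            relative = isTRUE(d$relative[1L]),
            s0 = if (isTRUE(d$relative[1L])) 1 else NA_real_)
  })
}

#' Write a synthetic scene bundle to disk
#'
#' Writes everything a downstream `process` run needs: the image stack, the
#' dark and flat frames, the ground-truth label map and truth table, and the
#' true event times.
#'
#' @param scene output of \code{\link{renderScene}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSceneBundle <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(stack = file.path(dir, "stack.tif"),
             dark = file.path(dir, "dark.tif"),
             flat = file.path(dir, "flat.tif"),
             labels = file.path(dir, "truth_labels.tif"),
             truth = file.path(dir, "truth_cells.csv"),
             events = file.path(dir, "truth_events.csv"))
  writeStackTIFF(scene$stack, paths[["stack"]])
  writeCorrectionTIFF(scene$corrections, paths[["dark"]], paths[["flat"]])
  writeLabelTIFF(scene$labels, paths[["labels"]])
  write.csv(scene$truth, paths[["truth"]], row.names = FALSE)
  ev <- do.call(rbind, lapply(seq_along(scene$events), function(i) {
    e <- scene$events[[i]]
    if (!nrow(e)) return(NULL)
    cbind(cell_id = as.character(i), e)
  }))
  if (is.null(ev)) ev <- data.frame(cell_id = character(), time = numeric(),
                                    phase = integer())
  write.csv(ev, paths[["events"]], row.names = FALSE)
  invisible(paths)
}
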
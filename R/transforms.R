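#' Apply an isotropic stretch to point coordinates
#'
#' Radial expansion of the elastomer substrate moves every adherent cell away
#' from the stretch centre: a point \eqn{p} maps to
#' \eqn{c + s (p - c)} for scale \eqn{s} and centre \eqn{c}.
#'
#' @param points numeric matrix with columns (x, y), or a length-2 vector.
#' @param scale isotropic scale factor (> 0).
#' @param center length-2 stretch centre (x, y).
#' @return Transformed coordinates, same shape as \code{points}.
#' @examples
#' applyStretchTransform(c(10, 10), scale = 1.15, center = c(10, 10))
#' @export
applyStretchTransform <- function(points, scale, center) {
  if (!(is.numeric(scale) && length(scale) == 1L && is.finite(scale) && scale > 0))
    stop("'scale' must be a single positive number")
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, ncol = 2L) else as.matrix(points)
  out <- sweep(sweep(p, 2L, center) * scale, 2L, center, "+")
  if (vec) drop(out) else out
}

## Forward map of a SimilarityTransform: q = c + s R (p - c) + t,
## with p, q as (x, y) row matrices.
transformPoints <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, ncol = 2L) else as.matrix(points)
  s <- transform@scale; th <- transform@rotation
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  q <- sweep(p, 2L, transform@center) %*% t(s * R)
  q <- sweep(q, 2L, transform@center + transform@translation, "+")
  if (vec) drop(q) else q
}

#' Invert a similarity transform
#'
#' @param transform a \linkS4class{SimilarityTransform}.
#' @return The inverse \linkS4class{SimilarityTransform} (same centre).
#' @export
invertTransform <- function(transform) {
  s <- transform@scale; th <- transform@rotation
  ## inverse about the same centre: p = c + (1/s) R(-th) (q - c - t)
  Rinv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
  tinv <- -as.numeric((Rinv / s) %*% transform@translation)
  similarityTransform(scale = 1 / s, rotation = -th, translation = tinv,
                      center = transform@center)
}

## Bilinear sampling of matrix `img` (y rows, x cols) at 0-based pixel-centre
## coordinates (xs, ys); out-of-field samples return `fill`.
bilinearSample <- function(img, xs, ys, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  gather <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1L & yi >= 0 & yi <= h - 1L
    v <- rep(fill, length(xi))
    v[ok] <- img[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    v
  }
  v00 <- gather(x0, y0);     v10 <- gather(x0 + 1L, y0)
  v01 <- gather(x0, y0 + 1L); v11 <- gather(x0 + 1L, y0 + 1L)
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

## Nearest-neighbour sampling (for label maps); 0-based coordinates.
nearestSample <- function(img, xs, ys, fill = 0L) {
  h <- nrow(img); w <- ncol(img)
  xi <- round(xs); yi <- round(ys)
  ok <- xi >= 0 & xi <= w - 1L & yi >= 0 & yi <= h - 1L
  v <- rep(fill, length(xi))
  v[ok] <- img[cbind(yi[ok] + 1L, xi[ok] + 1L)]
  v
}

## Warp an intensity image into the target frame of `transform`
## (target pixel q looks up source pixel T^{-1}(q), bilinear).
warpImage <- function(img, transform, targetDim = dim(img), fill = 0) {
  inv <- invertTransform(transform)
  h <- targetDim[1L]; w <- targetDim[2L]
  grid <- cbind(x = rep(0:(w - 1L), each = h), y = rep(0:(h - 1L), times = w))
  src <- transformPoints(inv, grid)
  matrix(bilinearSample(img, src[, 1L], src[, 2L], fill = fill), h, w)
}
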
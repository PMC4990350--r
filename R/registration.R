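#' Construct a rigid transform
#'
#' @param dxPx,dyPx translation in pixels (x = column, y = row direction)
#' @param thetaDeg rotation in degrees, counter-clockwise about the image
#'   centre
#' @param score registration quality (normalised correlation peak)
#' @param pixelSizeUm pixel side length for um-scale accessors
#' @return a \linkS4class{RigidTransform}
#' @export
RigidTransform <- function(dxPx = 0, dyPx = 0, thetaDeg = 0, score = NA_real_,
                           pixelSizeUm = 1) {
  new("RigidTransform", dxPx = dxPx, dyPx = dyPx, thetaDeg = thetaDeg,
      score = score, pixelSizeUm = pixelSizeUm)
}

# Bilinear rotation about the image centre; out-of-field pixels filled
# with `fill`.
rotateImage <- function(img, thetaDeg, fill = 0) {
  if (thetaDeg == 0) return(img)
  ny <- nrow(img)
  nx <- ncol(img)
  th <- -thetaDeg * pi / 180          # inverse map: output -> input
  cy <- (ny + 1) / 2
  cx <- (nx + 1) / 2
  gy <- rep(seq_len(ny), nx) - cy
  gx <- rep(seq_len(nx), each = ny) - cx
  sx <- cos(th) * gx - sin(th) * gy + cx
  sy <- sin(th) * gx + cos(th) * gy + cy
  x0 <- floor(sx)
  y0 <- floor(sy)
  fx <- sx - x0
  fy <- sy - y0
  ok <- x0 >= 1 & x0 <= nx - 1 & y0 >= 1 & y0 <= ny - 1
  out <- rep(fill, ny * nx)
  i00 <- (x0 - 1L) * ny + y0
  v <- (1 - fx[ok]) * (1 - fy[ok]) * img[i00[ok]] +
    fx[ok] * (1 - fy[ok]) * img[i00[ok] + ny] +
    (1 - fx[ok]) * fy[ok] * img[i00[ok] + 1L] +
    fx[ok] * fy[ok] * img[i00[ok] + ny + 1L]
  out[ok] <- v
  matrix(out, ny, nx)
}

hannWindow <- function(ny, nx) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
  outer(wy, wx)
}

# Phase correlation of two equally sized images; returns the translation
# (dx, dy) that maps `moving` onto `fixed`, with subpixel parabolic
# refinement, and the normalised peak height.
phaseCorrelate <- function(moving, fixed, window = TRUE) {
  ny <- nrow(moving)
  nx <- ncol(moving)
  a <- moving - mean(moving)
  b <- fixed - mean(fixed)
  if (window) {
    w <- hannWindow(ny, nx)
    a <- a * w
    b <- b * w
  }
  Fa <- fft(a)
  Fb <- fft(b)
  R <- Fb * Conj(Fa)
  mag <- Mod(R)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  r <- Re(fft(R / mag, inverse = TRUE)) / (ny * nx)
  pk <- which.max(r)
  py <- (pk - 1) %% ny + 1
  px <- (pk - 1) %/% ny + 1
  # parabolic subpixel refinement with wrap-around neighbours
  wrap <- function(i, n) ((i - 1) %% n) + 1
  sub <- function(c0, cm, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (cm - cp) / den
  }
  dy <- sub(r[py, px], r[wrap(py - 1, ny), px], r[wrap(py + 1, ny), px])
  dx <- sub(r[py, px], r[py, wrap(px - 1, nx)], r[py, wrap(px + 1, nx)])
  sy <- py - 1 + dy
  sx <- px - 1 + dx
  if (sy > ny / 2) sy <- sy - ny
  if (sx > nx / 2) sx <- sx - nx
  list(dx = sx, dy = sy, score = max(r))
}

#' Rigid registration of a moving field onto a fixed field
#'
#' Estimates the rotation (coarse grid search over \code{thetaRangeDeg},
#' then golden-section refinement of the phase-correlation peak height)
#' and the translation (phase correlation with parabolic subpixel
#' refinement) that superimpose the moving nuclear field on the fixed one.
#' Hann windowing suppresses wrap-around edge response.
#'
#' @param moving,fixed equally sized intensity matrices (nuclear channels)
#' @param thetaRangeDeg rotation search half-range, degrees; 0 restricts
#'   the fit to pure translation
#' @param thetaStepDeg coarse grid step
#' @param pixelSizeUm pixel size recorded on the transform
#' @return a \linkS4class{RigidTransform} mapping \code{moving} onto
#'   \code{fixed}
#' @export
registerRigid <- function(moving, fixed, thetaRangeDeg = 5,
                          thetaStepDeg = 0.5, pixelSizeUm = 1) {
  stopifnot(is.matrix(moving), is.matrix(fixed),
            all(dim(moving) == dim(fixed)))
  if (sd(moving) == 0 || sd(fixed) == 0)
    stop("no registration signal: flat image")
  scoreAt <- function(th) {
    m <- if (th == 0) moving else rotateImage(moving, th, fill = mean(moving))
    phaseCorrelate(m, fixed)$score
  }
  bestTheta <- 0
  if (thetaRangeDeg > 0) {
    grid <- seq(-thetaRangeDeg, thetaRangeDeg, by = thetaStepDeg)
    sc <- vapply(grid, scoreAt, numeric(1))
    bestTheta <- grid[which.max(sc)]
    lo <- max(bestTheta - thetaStepDeg, -thetaRangeDeg)
    hi <- min(bestTheta + thetaStepDeg, thetaRangeDeg)
    opt <- stats::optimize(scoreAt, c(lo, hi), maximum = TRUE,
                           tol = 0.01)
    if (opt$objective >= max(sc)) bestTheta <- opt$maximum
  }
  m <- if (bestTheta == 0) moving
       else rotateImage(moving, bestTheta, fill = mean(moving))
  pc <- phaseCorrelate(m, fixed)
  RigidTransform(dxPx = pc$dx, dyPx = pc$dy, thetaDeg = bestTheta,
                 score = pc$score, pixelSizeUm = pixelSizeUm)
}

#' Apply a rigid transform to an image
#'
#' Rotates about the image centre then translates, with bilinear
#' interpolation; pixels mapped from outside the field are filled with the
#' image mean.
#'
#' @param img intensity matrix
#' @param transform a \linkS4class{RigidTransform}
#' @return transformed matrix
#' @export
applyTransform <- function(img, transform) {
  out <- rotateImage(img, transform@thetaDeg, fill = mean(img))
  dx <- transform@dxPx
  dy <- transform@dyPx
  if (dx == 0 && dy == 0) return(out)
  ny <- nrow(out)
  nx <- ncol(out)
  # integer + fractional shift via bilinear resample of the inverse map
  gy <- rep(seq_len(ny), nx) - dy
  gx <- rep(seq_len(nx), each = ny) - dx
  x0 <- floor(gx)
  y0 <- floor(gy)
  fx <- gx - x0
  fy <- gy - y0
  ok <- x0 >= 1 & x0 <= nx - 1 & y0 >= 1 & y0 <= ny - 1
  res <- rep(mean(img), ny * nx)
  i00 <- (x0 - 1L) * ny + y0
  v <- (1 - fx[ok]) * (1 - fy[ok]) * out[i00[ok]] +
    fx[ok] * (1 - fy[ok]) * out[i00[ok] + ny] +
    (1 - fx[ok]) * fy[ok] * out[i00[ok] + 1L] +
    fx[ok] * fy[ok] * out[i00[ok] + ny + 1L]
  res[ok] <- v
  matrix(res, ny, nx)
}
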
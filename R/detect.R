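# Object detection: nuclei counting (total-cell denominator) and
# baseline-referenced flux-object detection with physical-unit size and
# edge filters.

# Summarise a label image into an object table with physical units.
objectTable <- function(labels, pxUm) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(data.frame(label = integer(), x_um = numeric(), y_um = numeric(),
                      area_px = integer(), area_um2 = numeric(),
                      equiv_diameter_um = numeric(), touches_edge = logical()))
  ny <- nrow(labels)
  nx <- ncol(labels)
  pos <- which(labels > 0)
  lab <- labels[pos]
  iy <- (pos - 1L) %% ny + 1L
  ix <- (pos - 1L) %/% ny + 1L
  areaPx <- as.integer(table(factor(lab, levels = ids)))
  cx <- tapply(ix, lab, mean)[as.character(ids)]
  cy <- tapply(iy, lab, mean)[as.character(ids)]
  edge <- tapply(iy == 1L | iy == ny | ix == 1L | ix == nx, lab, any)[
    as.character(ids)]
  areaUm2 <- areaPx * pxUm^2
  data.frame(label = as.integer(ids),
             x_um = as.numeric((cx - 0.5) * pxUm),
             y_um = as.numeric((cy - 0.5) * pxUm),
             area_px = areaPx,
             area_um2 = areaUm2,
             equiv_diameter_um = 2 * sqrt(areaUm2 / pi),
             touches_edge = as.logical(edge))
}

#' Count nuclei in a nuclear-stain frame
#'
#' Laplacian-of-Gaussian blob detection with non-maximum suppression:
#' the frame is smoothed at the blob scale (sigma = expected radius /
#' sqrt(2)), the scale-normalised LoG response computed, local maxima above
#' a robust threshold retained, and maxima closer than the expected radius
#' merged keeping the stronger response. The count is the total-cell
#' denominator for the responder-proportion statistic.
#'
#' @param nuclearFrame 2-d intensity matrix
#' @param pxUm pixel side length, um
#' @param expectedRadiusUm expected nuclear blob radius, um
#' @param thresholdK robust threshold: response must exceed
#'   median + thresholdK * mad of the response image
#' @return object table (data.frame: label, x_um, y_um, area_um2, ...)
#'   with one disk-mask row per detected nucleus; zero rows for an empty
#'   image
#' @export
countNuclei <- function(nuclearFrame, pxUm, expectedRadiusUm = 3.3,
                        thresholdK = 10) {
  stopifnot(is.matrix(nuclearFrame))
  ny <- nrow(nuclearFrame)
  nx <- ncol(nuclearFrame)
  sigma <- max(0.8, expectedRadiusUm / pxUm / sqrt(2))
  sm <- EBImage::gblur(matrix(as.numeric(nuclearFrame), ny, nx),
                       sigma = sigma)
  # scale-normalised negative Laplacian (bright blobs -> positive response)
  resp <- -sigma^2 * laplacian4(sm)
  thr <- median(resp) + thresholdK * mad(resp)
  if (!is.finite(thr) || mad(resp) == 0)
    thr <- median(resp) + thresholdK * (sd(resp) + .Machine$double.eps)
  peaks <- localMaxima(resp, thr)
  if (!nrow(peaks))
    return(objectTable(matrix(0L, ny, nx), pxUm))
  # non-maximum suppression at the blob scale: keep stronger response
  minDistPx <- max(2, expectedRadiusUm / pxUm)
  keep <- nmsPoints(peaks$x, peaks$y, peaks$value, minDistPx)
  peaks <- peaks[keep, , drop = FALSE]
  labels <- matrix(0L, ny, nx)
  rPx <- expectedRadiusUm / pxUm
  for (i in seq_len(nrow(peaks))) {
    f <- diskIdx(peaks$x[i], peaks$y[i], rPx, ny, nx)
    labels[f[labels[f] == 0L]] <- i
  }
  objectTable(labels, pxUm)
}

laplacian4 <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  up <- m[c(1, seq_len(ny - 1)), ]
  dn <- m[c(seq_len(ny - 1) + 1, ny), ]
  lf <- m[, c(1, seq_len(nx - 1))]
  rt <- m[, c(seq_len(nx - 1) + 1, nx)]
  up + dn + lf + rt - 4 * m
}

localMaxima <- function(resp, thr) {
  ny <- nrow(resp)
  nx <- ncol(resp)
  if (ny < 3 || nx < 3)
    return(data.frame(x = integer(), y = integer(), value = numeric()))
  core <- resp[2:(ny - 1), 2:(nx - 1)]
  isMax <- core >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & core >= resp[2:(ny - 1) + dy, 2:(nx - 1) + dx]
  }
  w <- which(isMax, arr.ind = TRUE)
  data.frame(x = w[, 2] + 1L, y = w[, 1] + 1L,
             value = core[isMax])
}

nmsPoints <- function(x, y, value, minDist) {
  ord <- order(value, decreasing = TRUE)
  keep <- logical(length(x))
  kx <- ky <- numeric(0)
  for (i in ord) {
    if (!length(kx) || all((kx - x[i])^2 + (ky - y[i])^2 >= minDist^2)) {
      keep[i] <- TRUE
      kx <- c(kx, x[i])
      ky <- c(ky, y[i])
    }
  }
  keep
}

diskIdx <- function(cx, cy, r, ny, nx) {
  x0 <- max(1L, floor(cx - r))
  x1 <- min(nx, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r))
  y1 <- min(ny, ceiling(cy + r))
  xs <- x0:x1
  ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  keep <- d2 <= r^2
  iy <- row(d2)[keep] + y0 - 1L
  ix <- col(d2)[keep] + x0 - 1L
  (ix - 1L) * ny + iy
}

#' Detect flux-responsive objects against the pre-stimulation baseline
#'
#' Computes a per-pixel baseline mean and SD over the pre-stimulation
#' frames; pixels exceeding mean + k * SD in at least \code{minFrames}
#' post-stimulus frames are candidate foreground. Connected components with
#' equivalent diameter below \code{minDiameterUm} (the 5-um minimal size
#' filter) are removed, and components touching the frame border are
#' removed when \code{excludeEdges}. Per-pixel SDs are floored at the field
#' median SD so that six-frame SD underestimates do not create speckle.
#'
#' @param movie a \linkS4class{FluxMovie}
#' @param minDiameterUm minimal equivalent diameter, um (default 5)
#' @param excludeEdges drop border-touching objects (default TRUE)
#' @param k baseline threshold multiplier (default 3)
#' @param minFrames minimum number of exceeding post-stimulus frames
#' @param endFrame last frame of the detection window (default: end of the
#'   record, so the ionomycin challenge recruits every viable cell)
#' @return list(objects = object table, labels = label image)
#' @export
detectFluxObjects <- function(movie, minDiameterUm = 5, excludeEdges = TRUE,
                              k = 3, minFrames = 3L,
                              endFrame = movie@meta@nFrames) {
  stopifnot(is(movie, "FluxMovie"))
  meta <- movie@meta
  nb <- meta@nBaselineFrames
  if (dim(movie@flux)[3] < nb + 1)
    stop("movie shorter than the baseline window (", nb, " frames)")
  pxUm <- pixelSizeUm(meta)
  ny <- dim(movie@flux)[1]
  nx <- dim(movie@flux)[2]
  base <- movie@flux[, , seq_len(nb), drop = FALSE]
  mu <- rowMeans(base, dims = 2)
  s2 <- rowSums((base - as.vector(mu))^2, dims = 2) / (nb - 1)
  sdPx <- sqrt(s2)
  sdPx <- pmax(sdPx, median(sdPx))
  thr <- mu + k * sdPx
  postFrames <- seq(meta@stimulusFrame, min(endFrame, meta@nFrames))
  exceed <- matrix(0L, ny, nx)
  for (t in postFrames)
    exceed <- exceed + (movie@flux[, , t] > thr)
  fg <- exceed >= minFrames
  labels <- EBImage::bwlabel(fg)
  storage.mode(labels) <- "integer"
  objects <- objectTable(labels, pxUm)
  drop <- objects$equiv_diameter_um < minDiameterUm
  if (excludeEdges) drop <- drop | objects$touches_edge
  dropped <- objects$label[drop]
  if (length(dropped)) labels[labels %in% dropped] <- 0L
  objects <- objects[!drop, , drop = FALSE]
  # relabel compactly so labels match table rows
  if (nrow(objects)) {
    map <- integer(max(objects$label))
    map[objects$label] <- seq_len(nrow(objects))
    pos <- labels > 0L
    labels[pos] <- map[labels[pos]]
    objects$label <- seq_len(nrow(objects))
  }
  rownames(objects) <- NULL
  list(objects = objects, labels = labels)
}

#' Write an object table as CSV
#'
#' @param objects an object table from \code{countNuclei} or
#'   \code{detectFluxObjects}
#' @param path output CSV path
#' @export
writeObjects <- function(objects, path) {
  write.csv(objects, path, row.names = FALSE)
  invisible(path)
}
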
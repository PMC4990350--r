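#' Corrected total cell fluorescence
#'
#' CTCF = IntDen - area_px * mean field background intensity. Negative
#' values are preserved, not clipped.
#'
#' @param intden integrated density (sum of pixel intensities in the mask)
#' @param areaPx mask size in pixels (>= 0)
#' @param meanBackground mean field background intensity
#' @return corrected intensity (vectorised over frames)
#' @examples
#' ctcf(1000, 10, 5)   # 950
#' @export
ctcf <- function(intden, areaPx, meanBackground) {
  if (any(areaPx < 0)) stop("areaPx must be >= 0")
  intden - areaPx * meanBackground
}

#' Extract background-corrected traces for detected objects
#'
#' For every labelled object, sums the flux channel over the object's mask
#' per frame (IntDen), computes the mean field background per frame over
#' all pixels outside the union of the object masks, applies the CTCF
#' correction, and sets F0 to the mean CTCF over the pre-stimulation
#' frames. Traces whose F0 is non-positive, or any of whose mask pixels hit
#' the bit-depth ceiling, are flagged invalid with a reason rather than
#' silently used.
#'
#' @param movie a \linkS4class{FluxMovie}
#' @param labels integer label image (0 = background), e.g. from
#'   \code{detectFluxObjects} or \code{sceneMasks}
#' @param backgroundMask optional logical matrix naming the background
#'   region explicitly (overrides the non-object default)
#' @return named list of \linkS4class{FluxTrace}, one per label
#' @export
extractTraces <- function(movie, labels, backgroundMask = NULL) {
  stopifnot(is(movie, "FluxMovie"), is.matrix(labels))
  meta <- movie@meta
  d <- dim(movie@flux)
  if (!all(dim(labels) == d[1:2]))
    stop("label image shape differs from the movie frames")
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(list())
  pos <- which(labels > 0L)
  lab <- factor(labels[pos], levels = ids)
  areaPx <- as.integer(table(lab))
  names(areaPx) <- as.character(ids)
  if (is.null(backgroundMask)) {
    bgIdx <- which(labels == 0L)
  } else {
    if (!all(dim(backgroundMask) == d[1:2]))
      stop("backgroundMask shape differs from the movie frames")
    bgIdx <- which(backgroundMask)
  }
  if (!length(bgIdx)) stop("no background pixels available")
  nT <- d[3]
  intden <- matrix(0, nT, length(ids))
  background <- numeric(nT)
  satMax <- 2^meta@bitDepth - 1
  saturated <- setNames(rep(FALSE, length(ids)), as.character(ids))
  for (t in seq_len(nT)) {
    frame <- movie@flux[, , t]
    vals <- frame[pos]
    intden[t, ] <- rowsum(as.numeric(vals), lab)[, 1]
    background[t] <- mean(frame[bgIdx])
    hit <- rowsum(as.numeric(vals == satMax), lab)[, 1] > 0
    saturated <- saturated | hit
  }
  pxUm <- pixelSizeUm(meta)
  baseIdx <- seq_len(meta@nBaselineFrames)
  out <- lapply(seq_along(ids), function(j) {
    cc <- ctcf(intden[, j], areaPx[j], background)
    f0 <- mean(cc[baseIdx])
    valid <- TRUE
    reason <- ""
    if (saturated[j]) {
      valid <- FALSE
      reason <- "saturated"
    } else if (f0 <= 0) {
      valid <- FALSE
      reason <- "non-positive baseline"
    }
    new("FluxTrace", label = as.integer(ids[j]), intden = intden[, j],
        areaPx = areaPx[j], areaUm2 = areaPx[j] * pxUm^2,
        background = background, ctcf = cc, f0 = f0,
        saturated = unname(saturated[j]), valid = valid, reason = reason)
  })
  names(out) <- as.character(ids)
  out
}

#' Extract a single cell's trace
#'
#' Convenience wrapper over \code{\link{extractTraces}} for one object.
#' The background region is all pixels outside \code{allLabels} (or outside
#' the cell's own mask when no full label image is given).
#'
#' @param movie a \linkS4class{FluxMovie}
#' @param cellLabel the object's label in \code{allLabels}
#' @param allLabels label image containing all objects
#' @return a \linkS4class{FluxTrace}
#' @export
extractTrace <- function(movie, cellLabel, allLabels) {
  if (!any(allLabels == cellLabel)) stop("empty mask for label ", cellLabel)
  traces <- extractTraces(movie, allLabels)
  traces[[as.character(cellLabel)]]
}

#' Fold-over-baseline series of a trace
#'
#' ctcf(t) / F0; errors on invalid traces (F0 <= 0 or saturated).
#'
#' @param trace a \linkS4class{FluxTrace}
#' @export
foldSeries <- function(trace) {
  stopifnot(is(trace, "FluxTrace"))
  if (!trace@valid) stop("trace is invalid: ", trace@reason)
  trace@ctcf / trace@f0
}

#' Write traces as long-format CSV
#'
#' Columns: label, frame, time_s, intden, background, ctcf.
#'
#' @param traces list of \linkS4class{FluxTrace}
#' @param meta the movie's \linkS4class{AcquisitionMeta}
#' @param path output CSV path
#' @export
writeTraces <- function(traces, meta, path) {
  tS <- frameTimesS(meta)
  rows <- lapply(traces, function(tr)
    data.frame(label = tr@label, frame = seq_along(tr@ctcf), time_s = tS,
               intden = tr@intden, background = tr@background,
               ctcf = tr@ctcf))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
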
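#' Pearson correlation of two channels
#'
#' Standard product-moment correlation over the (optionally masked) pixel
#' pairs. Returns NA with a warning when either channel has zero variance.
#'
#' @param imgA,imgB equally shaped intensity matrices
#' @param mask optional logical matrix selecting the pixels to correlate
#' @return correlation in [-1, 1], or NA when undefined
#' @examples
#' a <- matrix(1:9, 3)
#' pearsonR(a, 2 * a)   # 1
#' @export
pearsonR <- function(imgA, imgB, mask = NULL) {
  if (!all(dim(imgA) == dim(imgB))) stop("channel shapes differ")
  a <- as.numeric(imgA)
  b <- as.numeric(imgB)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(imgA))) stop("mask shape differs")
    a <- a[mask]
    b <- b[mask]
  }
  if (length(a) < 2) stop("need >= 2 pixels to correlate")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a channel: correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Costes automatic thresholds for two channels
#'
#' Fits the orthogonal (total least squares) regression line of channel B
#' on channel A, then lowers a candidate threshold along that line
#' stepwise (default 1 intensity level) until the correlation of the
#' pixels below both thresholds reaches <= 0. Pixels above both thresholds
#' define the colocalized set. Undefined (flagged) when the channels are
#' not positively correlated overall.
#'
#' @param imgA,imgB equally shaped intensity matrices
#' @param step threshold search step in intensity units
#' @return list(thresholdA, thresholdB, slope, intercept, defined,
#'   colocMask)
#' @export
costesThreshold <- function(imgA, imgB, step = 1) {
  if (!all(dim(imgA) == dim(imgB))) stop("channel shapes differ")
  a <- as.numeric(imgA)
  b <- as.numeric(imgB)
  undefined <- list(thresholdA = NA_real_, thresholdB = NA_real_,
                    slope = NA_real_, intercept = NA_real_,
                    defined = FALSE, colocMask = NULL)
  overall <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  if (!is.finite(overall) || overall <= 0) return(undefined)
  # orthogonal regression: principal axis of the (a, b) scatter
  cv <- stats::cov(cbind(a, b))
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[1] == 0) return(undefined)
  slope <- v[2] / v[1]
  intercept <- mean(b) - slope * mean(a)
  if (slope <= 0) return(undefined)

  tA <- max(a)
  lastBelow <- NA_real_
  while (tA >= min(a)) {
    tB <- slope * tA + intercept
    below <- a < tA & b < tB
    nb <- sum(below)
    if (nb >= 2 && sd(a[below]) > 0 && sd(b[below]) > 0) {
      rBelow <- cor(a[below], b[below])
      if (rBelow <= 0) break
    } else if (nb < 2) {
      # ran out of sub-threshold pixels: criterion met at the minimum
      break
    }
    lastBelow <- tA
    tA <- tA - step
  }
  if (tA < min(a)) tA <- min(a)
  tB <- slope * tA + intercept
  colocMask <- matrix(a >= tA & b >= tB, nrow(imgA), ncol(imgA))
  # no meaningful colocalized component: the below-threshold correlation
  # criterion was already met in the extreme upper tail (uncorrelated
  # channels decorrelate immediately), leaving no set worth reporting
  trivial <- sum(colocMask) < max(10, 0.001 * length(a))
  list(thresholdA = if (trivial) NA_real_ else tA,
       thresholdB = if (trivial) NA_real_ else tB, slope = slope,
       intercept = intercept, defined = !trivial,
       colocMask = if (trivial) NULL else colocMask)
}

# Block-scramble an image: partition into blockPx x blockPx tiles and
# permute the tiles (no rotation).
blockScramble <- function(img, blockPx) {
  ny <- nrow(img)
  nx <- ncol(img)
  by <- ceiling(ny / blockPx)
  bx <- ceiling(nx / blockPx)
  # pad to full blocks with the image mean, scramble, crop back
  pady <- by * blockPx
  padx <- bx * blockPx
  pad <- matrix(mean(img), pady, padx)
  pad[seq_len(ny), seq_len(nx)] <- img
  nBlocks <- by * bx
  perm <- sample.int(nBlocks)
  out <- matrix(0, pady, padx)
  for (k in seq_len(nBlocks)) {
    src <- perm[k]
    sy <- ((src - 1) %% by) * blockPx
    sx <- ((src - 1) %/% by) * blockPx
    ty <- ((k - 1) %% by) * blockPx
    tx <- ((k - 1) %/% by) * blockPx
    out[ty + seq_len(blockPx), tx + seq_len(blockPx)] <-
      pad[sy + seq_len(blockPx), sx + seq_len(blockPx)]
  }
  out[seq_len(ny), seq_len(nx)]
}

#' Costes randomization significance of colocalization
#'
#' Compares the observed Pearson correlation with correlations from
#' block-scrambled versions of channel A (blocks at the cell scale,
#' permuted without rotation);
#' p = (1 + #\{R_rand >= R_obs\}) / (1 + n). With the default 10
#' randomizations a correlation exceeding every scramble gives p = 1/11.
#'
#' @param imgA,imgB equally shaped intensity matrices
#' @param nRandomizations randomization count (default 10)
#' @param blockSizeUm scramble block side in um (default: mean cell
#'   diameter, 12 um)
#' @param pxUm pixel size, um
#' @param seed integer seed
#' @return a \linkS4class{ColocResult}
#' @export
costesSignificance <- function(imgA, imgB, nRandomizations = 10L,
                               blockSizeUm = 12, pxUm = 1, seed = 1L) {
  blockPx <- max(2L, as.integer(round(blockSizeUm / pxUm)))
  rObs <- pearsonR(imgA, imgB)
  if (is.na(rObs)) stop("observed correlation undefined")
  thr <- costesThreshold(imgA, imgB)
  withSeed(seed, {
    rRand <- vapply(seq_len(nRandomizations), function(i)
      pearsonR(blockScramble(imgA, blockPx), imgB), numeric(1))
    p <- (1 + sum(rRand >= rObs, na.rm = TRUE)) / (1 + nRandomizations)
    new("ColocResult", pearsonR = rObs,
        thresholds = c(thr$thresholdA, thr$thresholdB),
        pValue = p, nRandomizations = as.integer(nRandomizations),
        blockSizePx = blockPx, randomR = rRand,
        thresholdsDefined = thr$defined)
  })
}

#' Flux-positive frame for colocalization
#'
#' The single flux frame nearest \code{atSPostStimulus} seconds after the
#' calcium stimulus, background-subtracted: the per-pixel mean over the
#' pre-stimulation baseline frames is removed and negative values clipped
#' to zero, so only stimulus-induced signal remains.
#'
#' @param movie a \linkS4class{FluxMovie}
#' @param atSPostStimulus seconds after the stimulus (default 120, the
#'   2-minute post-stimulation frame)
#' @return intensity matrix
#' @export
fluxPositiveFrame <- function(movie, atSPostStimulus = 120) {
  meta <- movie@meta
  frame <- meta@stimulusFrame +
    as.integer(round(atSPostStimulus / meta@frameIntervalS))
  frame <- min(max(frame, meta@stimulusFrame), meta@nFrames)
  base <- rowMeans(movie@flux[, , seq_len(meta@nBaselineFrames),
                              drop = FALSE], dims = 2)
  pmax(movie@flux[, , frame] - base, 0)
}
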
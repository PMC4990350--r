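#' Construct acquisition metadata
#'
#' Defaults reproduce the reference live-cell acquisition: 132 frames at 5-s
#' intervals (11 min), a 30-s six-frame baseline, the calcium stimulus added
#' at the end of the baseline window, ionomycin for the final minute, a
#' 606.1-um field imaged at 512 x 512 and 8-bit depth. The pixel side
#' length is derived as fieldSizeUm / imageSizePx.
#'
#' @param frameIntervalS seconds between frames
#' @param nFrames total number of frames
#' @param nBaselineFrames pre-stimulation frames
#' @param fieldSizeUm field side length in micrometres
#' @param imageSizePx pixels per side
#' @param bitDepth intensity bit depth (8, 12 or 16)
#' @param stimulusFrame first post-stimulus frame (1-based); default
#'   \code{nBaselineFrames + 1}
#' @param ionomycinFrame first ionomycin-challenge frame, or NA for none;
#'   the default leaves the final minute of the record for the challenge
#' @return an \linkS4class{AcquisitionMeta}
#' @examples
#' meta <- AcquisitionMeta()
#' pixelSizeUm(meta)
#' @export
AcquisitionMeta <- function(frameIntervalS = 5, nFrames = 132L,
                            nBaselineFrames = 6L, fieldSizeUm = 606.1,
                            imageSizePx = 512L, bitDepth = 8L,
                            stimulusFrame = nBaselineFrames + 1L,
                            ionomycinFrame = NULL) {
  nFrames <- as.integer(nFrames)
  if (is.null(ionomycinFrame)) {
    post <- nFrames - round(60 / frameIntervalS)
    ionomycinFrame <- if (post > stimulusFrame) as.integer(post + 1L) else NA_integer_
  }
  new("AcquisitionMeta",
      frameIntervalS = as.numeric(frameIntervalS),
      nFrames = nFrames,
      nBaselineFrames = as.integer(nBaselineFrames),
      fieldSizeUm = as.numeric(fieldSizeUm),
      imageSizePx = as.integer(imageSizePx),
      bitDepth = as.integer(bitDepth),
      stimulusFrame = as.integer(stimulusFrame),
      ionomycinFrame = as.integer(ionomycinFrame))
}

#' @rdname AcquisitionMeta
#' @param object,x an \code{AcquisitionMeta}
#' @export
pixelSizeUm <- function(object) object@fieldSizeUm / object@imageSizePx

#' Frame times in seconds
#'
#' Time of each frame relative to the start of the record (frame 1 at 0 s).
#' @param meta an \linkS4class{AcquisitionMeta}
#' @return numeric vector of length \code{nFrames}
#' @export
frameTimesS <- function(meta) (seq_len(meta@nFrames) - 1) * meta@frameIntervalS

#' Stimulus time in seconds
#' @param meta an \linkS4class{AcquisitionMeta}
#' @export
stimulusTimeS <- function(meta) (meta@stimulusFrame - 1) * meta@frameIntervalS

#' Ionomycin-challenge time in seconds (NA when absent)
#' @param meta an \linkS4class{AcquisitionMeta}
#' @export
ionomycinTimeS <- function(meta) {
  if (is.na(meta@ionomycinFrame)) NA_real_
  else (meta@ionomycinFrame - 1) * meta@frameIntervalS
}

setMethod("show", "AcquisitionMeta", function(object) {
  cat("AcquisitionMeta:", object@nFrames, "frames @",
      object@frameIntervalS, "s |", object@imageSizePx, "px /",
      object@fieldSizeUm, "um field |", object@bitDepth, "bit\n")
  cat("  baseline frames:", object@nBaselineFrames,
      "| stimulus frame:", object@stimulusFrame,
      "| ionomycin frame:", object@ionomycinFrame, "\n")
})

setMethod("show", "FluxMovie", function(object) {
  d <- dim(object@flux)
  cat("FluxMovie:", d[1], "x", d[2], "px,", d[3], "frames; nuclear channel",
      if (is.null(object@viability)) "(no viability channel)"
      else "+ viability channel", "\n")
  if (object@clipped) cat("  note: intensities clipped at bit-depth ceiling\n")
})

setMethod("show", "Scene", function(object) {
  cat("Scene:", nrow(object@cells), "cells at", object@doseMm, "mM Ca\n")
  if (nrow(object@cells))
    print(table(object@cells$class))
})

setMethod("show", "FluxTrace", function(object) {
  cat("FluxTrace [cell", object@label, "]:", length(object@ctcf),
      "frames; area", round(object@areaUm2, 1), "um^2; f0",
      round(object@f0, 1), if (!object@valid) paste0("(INVALID: ", object@reason, ")") else "", "\n")
})

setMethod("show", "FourPLFit", function(object) {
  cat("Four-parameter logistic fit",
      if (!object@identifiable) "(NOT identifiable)" else "", "\n")
  cat(sprintf("  bottom %.4f  top %.4f  hill %.3f  EC50 %.3f mM\n",
              object@bottom, object@top, object@hill, object@ec50Mm))
  cat(sprintf("  rss %.5g  converged %s  weighting %s\n",
              object@rss, object@converged, object@weighting))
})

setMethod("show", "DecayFit", function(object) {
  cat("One-phase exponential decay fit\n")
  cat(sprintf("  p0 %.2f  plateau %.2f  k %.4f /min  half-life %.3f min\n",
              object@p0, object@plateau, object@k, object@halfLifeMin))
  if (!object@converged) cat("  NOT converged:", object@message, "\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: dx %.3f px, dy %.3f px, theta %.3f deg (score %.3f)\n",
              object@dxPx, object@dyPx, object@thetaDeg, object@score))
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult: Pearson R %.3f, p %.4g (%d randomizations, block %d px)\n",
              object@pearsonR, object@pValue, object@nRandomizations,
              object@blockSizePx))
  if (object@thresholdsDefined)
    cat(sprintf("  Costes thresholds: %.1f / %.1f\n",
                object@thresholds[1], object@thresholds[2]))
  else cat("  Costes thresholds undefined\n")
})

#' Accessors for fit and transform objects
#'
#' \code{ec50} returns the fitted EC50 in mM; \code{halfLife} the fitted
#' half-life in minutes; \code{translationPx} / \code{rotationDeg} the rigid
#' transform components; \code{pearson} the observed correlation of a
#' colocalization result.
#' @param object a fitted object
#' @name accessors
NULL

#' @rdname accessors
#' @export
ec50 <- function(object) {
  stopifnot(is(object, "FourPLFit"))
  object@ec50Mm
}

#' @rdname accessors
#' @export
halfLife <- function(object) {
  stopifnot(is(object, "DecayFit"))
  object@halfLifeMin
}

#' @rdname accessors
#' @export
translationPx <- function(object) {
  stopifnot(is(object, "RigidTransform"))
  c(dx = object@dxPx, dy = object@dyPx)
}

#' @rdname accessors
#' @export
rotationDeg <- function(object) {
  stopifnot(is(object, "RigidTransform"))
  object@thetaDeg
}

#' @rdname accessors
#' @export
pearson <- function(object) {
  stopifnot(is(object, "ColocResult"))
  object@pearsonR
}

#' @rdname accessors
#' @export
sceneCells <- function(object) {
  stopifnot(is(object, "Scene"))
  object@cells
}

#' @rdname accessors
#' @export
movieMeta <- function(object) {
  stopifnot(is(object, "FluxMovie") || is(object, "Scene"))
  object@meta
}

#' @rdname accessors
#' @export
fluxChannel <- function(object) {
  stopifnot(is(object, "FluxMovie"))
  object@flux
}

#' @rdname accessors
#' @export
nuclearChannel <- function(object) {
  stopifnot(is(object, "FluxMovie"))
  object@nuclear
}

#' @rdname accessors
#' @export
viabilityChannel <- function(object) {
  stopifnot(is(object, "FluxMovie"))
  object@viability
}
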
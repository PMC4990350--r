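#' Construct classifier parameters
#'
#' Defaults follow the operational maximal-responder definition: a sharp
#' (> 4-fold over baseline) rise within the first 60 s of the calcium
#' stimulus, followed by a sustained plateau with relative deviation within
#' 10\%. The fold threshold is exposed as a parameter because reported
#' conventions for this assay vary between 3x and 4x; 4 is the default.
#'
#' @param maximalFoldThreshold fold threshold (default 4)
#' @param onsetWindowS onset window, s (default 60; 12 frames at 5 s)
#' @param plateauDeviationMax maximum relative plateau deviation
#' @param ionomycinFoldMin viability control threshold
#' @param transientDecayFraction decay fraction defining transient
#' @param settleS settle time before the plateau window opens, s
#' @param plateauStat "maxdev" or "cv"
#' @return a \linkS4class{ClassifierParams}
#' @export
ClassifierParams <- function(maximalFoldThreshold = 4, onsetWindowS = 60,
                             plateauDeviationMax = 0.10,
                             ionomycinFoldMin = 2,
                             transientDecayFraction = 0.5,
                             settleS = 15, plateauStat = "maxdev") {
  new("ClassifierParams",
      maximalFoldThreshold = maximalFoldThreshold,
      onsetWindowS = onsetWindowS,
      plateauDeviationMax = plateauDeviationMax,
      ionomycinFoldMin = ionomycinFoldMin,
      transientDecayFraction = transientDecayFraction,
      settleS = settleS, plateauStat = plateauStat)
}

#' Classify one cell's kinetic waveform
#'
#' Assigns one of \code{maximal}, \code{transient}, \code{gradual} or
#' \code{nonresponder} from the fold-over-baseline trace:
#' \itemize{
#'   \item \strong{maximal}: fold reaches the threshold within the onset
#'     window of the stimulus AND the post-onset plateau (from
#'     \code{settleS} after the crossing to one frame before ionomycin)
#'     deviates by at most \code{plateauDeviationMax} from its median;
#'   \item \strong{transient}: threshold reached within the window but the
#'     signal later falls below
#'     (1 - \code{transientDecayFraction}) x peak;
#'   \item \strong{gradual}: threshold reached only after the window;
#'   \item \strong{nonresponder}: otherwise.
#' }
#' Viability (the \code{nonviable} call) is decided separately by
#' \code{\link{viabilityFilter}} from the ionomycin window and the
#' viability channel. Invalid traces (non-positive baseline, saturation)
#' yield class \code{NA} with a reason.
#'
#' @param trace a \linkS4class{FluxTrace}
#' @param meta the movie's \linkS4class{AcquisitionMeta}
#' @param params a \linkS4class{ClassifierParams}
#' @return one-row data.frame: label, class, fold_peak,
#'   time_to_threshold_s, plateau_deviation, ionomycin_fold, valid, reason
#' @export
classifyWaveform <- function(trace, meta, params = ClassifierParams()) {
  stopifnot(is(trace, "FluxTrace"), is(meta, "AcquisitionMeta"),
            is(params, "ClassifierParams"))
  as.data.frame(classifyOne(trace, meta, params), stringsAsFactors = FALSE)
}

classifyOne <- function(trace, meta, params) {
  out <- list(label = trace@label, class = NA_character_,
              fold_peak = NA_real_, time_to_threshold_s = NA_real_,
              plateau_deviation = NA_real_, ionomycin_fold = NA_real_,
              valid = trace@valid, reason = trace@reason)
  if (!trace@valid) return(out)
  fold <- trace@ctcf / trace@f0
  tS <- frameTimesS(meta)
  tStim <- stimulusTimeS(meta)
  ionoFrame <- meta@ionomycinFrame
  lastPre <- if (is.na(ionoFrame)) meta@nFrames else ionoFrame - 1L
  postIdx <- seq(meta@stimulusFrame, lastPre)

  out$fold_peak <- max(fold[postIdx])
  if (!is.na(ionoFrame)) {
    ionoIdx <- seq(ionoFrame, meta@nFrames)
    out$ionomycin_fold <- max(fold[ionoIdx])
  }

  thr <- params@maximalFoldThreshold
  crossed <- postIdx[fold[postIdx] >= thr]
  if (length(crossed)) {
    tCross <- tS[crossed[1]]
    out$time_to_threshold_s <- tCross - tStim
    inWindow <- (tCross - tStim) <= params@onsetWindowS
    # plateau window opens settleS after the crossing (the rising edge is
    # not scored against the plateau) and closes one frame before ionomycin
    platIdx <- postIdx[tS[postIdx] >= tCross + params@settleS]
    if (length(platIdx) >= 2) {
      p <- fold[platIdx]
      med <- median(p)
      dev <- if (params@plateauStat == "cv") sd(p) / med
             else max(abs(p - med)) / med
    } else dev <- NA_real_
    out$plateau_deviation <- dev
    peakIdx <- postIdx[which.max(fold[postIdx])]
    fellBelow <- any(fold[postIdx[postIdx >= peakIdx]] <
                       (1 - params@transientDecayFraction) * out$fold_peak)
    if (inWindow && !is.na(dev) && dev <= params@plateauDeviationMax) {
      out$class <- "maximal"
    } else if (inWindow && fellBelow) {
      out$class <- "transient"
    } else if (!inWindow) {
      out$class <- "gradual"
    } else {
      out$class <- "nonresponder"
    }
  } else {
    out$class <- "nonresponder"
  }
  out
}

#' Classify a list of traces
#'
#' @param traces list of \linkS4class{FluxTrace}
#' @param meta the movie's \linkS4class{AcquisitionMeta}
#' @param params a \linkS4class{ClassifierParams}
#' @return data.frame of waveform calls, one row per trace
#' @export
classifyWaveforms <- function(traces, meta, params = ClassifierParams()) {
  rows <- lapply(traces, classifyOne, meta = meta, params = params)
  out <- data.frame(
    label = vapply(rows, `[[`, integer(1), "label"),
    class = vapply(rows, `[[`, character(1), "class"),
    fold_peak = vapply(rows, `[[`, numeric(1), "fold_peak"),
    time_to_threshold_s = vapply(rows, `[[`, numeric(1),
                                 "time_to_threshold_s"),
    plateau_deviation = vapply(rows, `[[`, numeric(1), "plateau_deviation"),
    ionomycin_fold = vapply(rows, `[[`, numeric(1), "ionomycin_fold"),
    valid = vapply(rows, `[[`, logical(1), "valid"),
    reason = vapply(rows, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply the ionomycin / viability-stain exclusion
#'
#' Cells whose ionomycin-window peak fold falls below
#' \code{ionomycinFoldMin}, or that are positive in the viability channel,
#' are reclassified \code{nonviable}; nonviable cells are excluded from all
#' downstream denominators. When the acquisition has no ionomycin frame the
#' filter is a no-op with a warning (the stain criterion still applies if a
#' viability frame is supplied).
#'
#' @param calls waveform-call data.frame from \code{classifyWaveforms}
#' @param meta the movie's \linkS4class{AcquisitionMeta}
#' @param params a \linkS4class{ClassifierParams}
#' @param viabilityPositive optional logical vector (per call row) from the
#'   viability stain, e.g. \code{\link{viabilityPositive}}
#' @return the calls with nonviable rows reclassified
#' @export
viabilityFilter <- function(calls, meta, params = ClassifierParams(),
                            viabilityPositive = NULL) {
  hasIono <- !is.na(meta@ionomycinFrame)
  if (!hasIono && is.null(viabilityPositive)) {
    warning("no ionomycin frame and no viability stain: filter is a no-op")
    return(calls)
  }
  nv <- rep(FALSE, nrow(calls))
  if (hasIono)
    nv <- nv | (calls$valid & !is.na(calls$ionomycin_fold) &
                  calls$ionomycin_fold < params@ionomycinFoldMin)
  if (!is.null(viabilityPositive)) nv <- nv | viabilityPositive
  calls$class[nv] <- "nonviable"
  calls
}

#' Score objects against a viability-stain frame
#'
#' An object is viability-positive when the mean stain intensity over its
#' mask exceeds the field background by \code{k} robust SDs.
#'
#' @param viabilityFrame viability-channel matrix
#' @param labels label image of the objects
#' @param k threshold multiplier
#' @return named logical vector, one entry per label
#' @export
viabilityPositive <- function(viabilityFrame, labels, k = 5) {
  ids <- sort(unique(labels[labels > 0]))
  bg <- viabilityFrame[labels == 0L]
  thr <- median(bg) + k * max(mad(bg), 1e-6)
  pos <- which(labels > 0L)
  lab <- factor(labels[pos], levels = ids)
  mfi <- rowsum(as.numeric(viabilityFrame[pos]), lab)[, 1] /
    as.integer(table(lab))
  setNames(mfi > thr, as.character(ids))
}

#' Write waveform calls as CSV
#'
#' @param calls waveform-call data.frame
#' @param path output CSV path
#' @export
writeCalls <- function(calls, path) {
  write.csv(calls[, c("label", "class", "fold_peak", "time_to_threshold_s",
                      "plateau_deviation", "ionomycin_fold")],
            path, row.names = FALSE)
  invisible(path)
}
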
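#' @import methods
#' @importFrom stats median sd mad rnorm runif rbinom quantile approx coef cor setNames
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

#' Acquisition metadata for a flux movie
#'
#' Describes the confocal time-series acquisition: frame timing, baseline
#' window, stimulus and ionomycin-challenge frames, field geometry and bit
#' depth. Defaults reproduce the reference acquisition: 132 frames of
#' 512 x 512 pixels at 5-s intervals over a 606.1 x 606.1 um field at 8-bit
#' depth, with a 30-s (six-frame) pre-stimulation baseline, the calcium
#' stimulus added after the baseline window, and a terminal ionomycin
#' challenge over the final minute.
#'
#' @slot frameIntervalS seconds between frames
#' @slot nFrames total frame count
#' @slot nBaselineFrames number of pre-stimulation frames
#' @slot fieldSizeUm physical field side length, micrometres
#' @slot imageSizePx pixels per image side
#' @slot bitDepth intensity bit depth
#' @slot stimulusFrame 1-based index of the first post-stimulus frame
#' @slot ionomycinFrame 1-based index of the first ionomycin frame
#'   (\code{NA} when no ionomycin challenge was acquired)
#' @export
setClass("AcquisitionMeta", representation(
  frameIntervalS  = "numeric",
  nFrames         = "integer",
  nBaselineFrames = "integer",
  fieldSizeUm     = "numeric",
  imageSizePx     = "integer",
  bitDepth        = "integer",
  stimulusFrame   = "integer",
  ionomycinFrame  = "integer"
))

setValidity("AcquisitionMeta", function(object) {
  msg <- character()
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (object@nFrames < 1) msg <- c(msg, "nFrames must be >= 1")
  if (object@nBaselineFrames < 1 || object@nBaselineFrames >= object@nFrames)
    msg <- c(msg, "nBaselineFrames must be in [1, nFrames)")
  if (object@stimulusFrame <= object@nBaselineFrames ||
      object@stimulusFrame > object@nFrames)
    msg <- c(msg, "stimulusFrame must follow the baseline window and lie within the record")
  if (!is.na(object@ionomycinFrame) &&
      (object@ionomycinFrame <= object@stimulusFrame ||
       object@ionomycinFrame > object@nFrames))
    msg <- c(msg, "ionomycinFrame must follow stimulusFrame and lie within the record")
  if (object@fieldSizeUm <= 0) msg <- c(msg, "fieldSizeUm must be > 0")
  if (object@imageSizePx < 8) msg <- c(msg, "imageSizePx must be >= 8")
  if (!object@bitDepth %in% c(8L, 12L, 16L))
    msg <- c(msg, "bitDepth must be 8, 12 or 16")
  if (length(msg)) msg else TRUE
})

#' Scene configuration for the synthetic generator
#'
#' Holds the cell-population and imaging-noise parameters from which
#' synthetic tissue-slice scenes are drawn: cell count and size, the
#' nonviable fraction, the four-parameter-logistic responder model giving
#' P(maximal | calcium dose), the mixture over non-maximal kinetic classes,
#' per-class kinetic parameters, and rendering/noise levels.
#'
#' @slot nCells number of cells per scene
#' @slot cellRadiusUm length-2 numeric, mean and sd of the cell radius (um)
#' @slot deadFraction probability a cell is nonviable
#' @slot responderModel list(bottom, top, ec50Mm, hill): 4PL for
#'   P(maximal | dose) among viable cells
#' @slot nonMaximalWeights named numeric over
#'   c("transient","gradual","nonresponder"); mixture of the residual mass
#' @slot kinetics per-class kinetic parameter lists (see
#'   \code{\link{defaultKinetics}})
#' @slot noise list(readSd, signalScale): additive Gaussian sd plus
#'   signal-proportional (Poisson-like) variance scale
#' @slot backgroundLevel flux-channel background intensity
#' @slot baselineIntensity length-2 numeric, mean and sd of per-cell
#'   baseline fluorescence amplitude above background
#' @slot nuclearIntensity nuclear-blob peak amplitude
#' @slot viabilityIntensity viability-channel amplitude for dead cells
#' @export
setClass("SceneConfig", representation(
  nCells            = "integer",
  cellRadiusUm      = "numeric",
  deadFraction      = "numeric",
  responderModel    = "list",
  nonMaximalWeights = "numeric",
  kinetics          = "list",
  noise             = "list",
  backgroundLevel   = "numeric",
  baselineIntensity = "numeric",
  nuclearIntensity  = "numeric",
  viabilityIntensity = "numeric"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  rm_ <- object@responderModel
  if (object@nCells < 0) msg <- c(msg, "nCells must be >= 0")
  if (length(object@cellRadiusUm) != 2 || object@cellRadiusUm[1] <= 0)
    msg <- c(msg, "cellRadiusUm must be c(mean, sd) with mean > 0")
  if (object@deadFraction < 0 || object@deadFraction > 1)
    msg <- c(msg, "deadFraction must lie in [0, 1]")
  need <- c("bottom", "top", "ec50Mm", "hill")
  if (!all(need %in% names(rm_))) {
    msg <- c(msg, "responderModel needs bottom, top, ec50Mm, hill")
  } else {
    if (rm_$bottom < 0 || rm_$top > 1 || rm_$bottom > rm_$top)
      msg <- c(msg, "responderModel must satisfy 0 <= bottom <= top <= 1")
    if (rm_$ec50Mm <= 0) msg <- c(msg, "responderModel ec50Mm must be > 0")
  }
  w <- object@nonMaximalWeights
  if (!all(c("transient", "gradual", "nonresponder") %in% names(w)) ||
      any(w < 0) || sum(w) <= 0)
    msg <- c(msg, "nonMaximalWeights must be non-negative over transient/gradual/nonresponder")
  if (!all(c("readSd", "signalScale") %in% names(object@noise)))
    msg <- c(msg, "noise needs readSd and signalScale")
  if (length(msg)) msg else TRUE
})

#' A sampled synthetic scene
#'
#' One realisation of the generator: cell positions, sizes, latent kinetic
#' class labels and per-cell kinetic parameters at a given extracellular
#' calcium dose, plus the acquisition metadata and the configuration the
#' scene was drawn from.
#'
#' @slot cells data.frame with one row per cell: id, x_um, y_um, radius_um,
#'   class, f0 (baseline amplitude), viable
#' @slot doseMm extracellular calcium concentration, mM
#' @slot meta an \code{AcquisitionMeta}
#' @slot config the \code{SceneConfig} the scene was sampled from
#' @export
setClass("Scene", representation(
  cells  = "data.frame",
  doseMm = "numeric",
  meta   = "AcquisitionMeta",
  config = "SceneConfig"
))

setValidity("Scene", function(object) {
  msg <- character()
  cells <- object@cells
  need <- c("id", "x_um", "y_um", "radius_um", "class", "f0", "viable")
  if (!all(need %in% names(cells)))
    msg <- c(msg, paste("cells must have columns:", paste(need, collapse = ", ")))
  if (nrow(cells)) {
    fs <- object@meta@fieldSizeUm
    if (any(cells$x_um < 0 | cells$x_um > fs | cells$y_um < 0 | cells$y_um > fs))
      msg <- c(msg, "cell centres must lie within the field")
    if (!all(cells$class %in% c("maximal", "transient", "gradual",
                                "nonresponder", "nonviable")))
      msg <- c(msg, "unknown kinetic class label")
  }
  if (object@doseMm < 0) msg <- c(msg, "doseMm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Multi-channel fluorescence flux movie
#'
#' The pipeline's central image container: a calcium-indicator channel as a
#' Y x X x T integer array, a single-frame nuclear channel, an optional
#' single-frame viability channel, and acquisition metadata.
#'
#' @slot flux integer array, dim c(ny, nx, nFrames)
#' @slot nuclear integer matrix ny x nx
#' @slot viability integer matrix ny x nx, or NULL when not acquired
#' @slot meta an \code{AcquisitionMeta}
#' @slot clipped TRUE if any rendered/stored intensity hit the bit-depth
#'   ceiling
#' @export
setClass("FluxMovie", representation(
  flux      = "array",
  nuclear   = "matrix",
  viability = "ANY",
  meta      = "AcquisitionMeta",
  clipped   = "logical"
))

setValidity("FluxMovie", function(object) {
  msg <- character()
  d <- dim(object@flux)
  if (length(d) != 3) msg <- c(msg, "flux must be a 3-d array (ny, nx, T)")
  else {
    if (d[3] != object@meta@nFrames)
      msg <- c(msg, sprintf("flux has %d frames but metadata declares %d",
                            d[3], object@meta@nFrames))
    if (!all(dim(object@nuclear) == d[1:2]))
      msg <- c(msg, "nuclear channel shape differs from flux frames")
    if (!is.null(object@viability) && !all(dim(object@viability) == d[1:2]))
      msg <- c(msg, "viability channel shape differs from flux frames")
    mx <- 2^object@meta@bitDepth - 1
    rng <- range(object@flux)
    if (rng[1] < 0 || rng[2] > mx)
      msg <- c(msg, "flux intensities outside bit depth")
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell background-corrected fluorescence trace
#'
#' One cell's integrated density over time with the corrected total cell
#' fluorescence, CTCF = IntDen - area_px * mean field background, the
#' baseline value F0 (mean CTCF over the pre-stimulation frames) and QC
#' flags.
#'
#' @slot label cell/object id
#' @slot intden per-frame integrated density (sum over the mask)
#' @slot areaPx mask size in pixels
#' @slot areaUm2 mask area in um^2
#' @slot background per-frame mean field background intensity
#' @slot ctcf per-frame corrected intensity (may be negative)
#' @slot f0 mean CTCF over the baseline frames
#' @slot saturated TRUE if any mask pixel reached the bit-depth maximum
#' @slot valid FALSE when the trace cannot be used (f0 <= 0 or saturation)
#' @slot reason why an invalid trace was flagged
#' @export
setClass("FluxTrace", representation(
  label      = "integer",
  intden     = "numeric",
  areaPx     = "integer",
  areaUm2    = "numeric",
  background = "numeric",
  ctcf       = "numeric",
  f0         = "numeric",
  saturated  = "logical",
  valid      = "logical",
  reason     = "character"
))

setValidity("FluxTrace", function(object) {
  if (length(object@intden) != length(object@ctcf) ||
      length(object@intden) != length(object@background))
    return("intden, background and ctcf must have equal length")
  TRUE
})

#' Waveform classifier parameters
#'
#' Thresholds for the kinetic waveform classifier. The maximal-responder
#' definition: fold over baseline exceeding \code{maximalFoldThreshold}
#' (default 4) within \code{onsetWindowS} (default 60 s) of the stimulus,
#' followed by a sustained plateau whose relative deviation stays within
#' \code{plateauDeviationMax} (default 0.10). The plateau window opens
#' \code{settleS} seconds after the threshold crossing so the rising edge
#' itself is not scored against the plateau. Cells whose ionomycin-window
#' peak fold falls below \code{ionomycinFoldMin} are treated as nonviable.
#'
#' @slot maximalFoldThreshold fold over F0 defining a response (default 4)
#' @slot onsetWindowS onset window after the stimulus, seconds (default 60)
#' @slot plateauDeviationMax maximum relative plateau deviation (default 0.10)
#' @slot ionomycinFoldMin minimum ionomycin-window fold for viability
#'   (default 2)
#' @slot transientDecayFraction a responder whose signal later falls below
#'   (1 - this) x peak is transient (default 0.5)
#' @slot settleS settle time between threshold crossing and the start of the
#'   plateau window, seconds (default 15)
#' @slot plateauStat "maxdev" (max |x - median|/median) or "cv"
#' @export
setClass("ClassifierParams", representation(
  maximalFoldThreshold   = "numeric",
  onsetWindowS           = "numeric",
  plateauDeviationMax    = "numeric",
  ionomycinFoldMin       = "numeric",
  transientDecayFraction = "numeric",
  settleS                = "numeric",
  plateauStat            = "character"
))

setValidity("ClassifierParams", function(object) {
  msg <- character()
  for (s in c("maximalFoldThreshold", "onsetWindowS", "plateauDeviationMax",
              "ionomycinFoldMin", "transientDecayFraction"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
  if (object@settleS < 0) msg <- c(msg, "settleS must be >= 0")
  if (!object@plateauStat %in% c("maxdev", "cv"))
    msg <- c(msg, "plateauStat must be 'maxdev' or 'cv'")
  if (length(msg)) msg else TRUE
})

#' Four-parameter logistic dose-response fit
#'
#' Result of fitting p = bottom + (top - bottom) /
#' (1 + 10^((logEc50 - log10(dose)) * hill)) to per-dose maximal-responder
#' proportions, with bounds 0 <= bottom <= top <= 1 and hill > 0.
#'
#' @slot bottom lower asymptote (proportion)
#' @slot top upper asymptote (proportion)
#' @slot logEc50 log10 EC50 (mM)
#' @slot hill Hill slope
#' @slot ec50Mm EC50 in mM (= 10^logEc50)
#' @slot rss weighted residual sum of squares
#' @slot converged optimiser convergence flag
#' @slot identifiable FALSE when the data cannot pin down the curve (too few
#'   distinct doses or flat proportions); ec50Mm is NA then
#' @slot points the dose table the fit used
#' @slot weighting "binomial" (n_total weights) or "none"
#' @export
setClass("FourPLFit", representation(
  bottom       = "numeric",
  top          = "numeric",
  logEc50      = "numeric",
  hill         = "numeric",
  ec50Mm       = "numeric",
  rss          = "numeric",
  converged    = "logical",
  identifiable = "logical",
  points       = "data.frame",
  weighting    = "character"
))

#' One-phase exponential decay fit
#'
#' Least-squares fit of P(t) = plateau + (p0 - plateau) * exp(-k t) to a
#' timed hormone concentration series; half-life = ln(2)/k.
#'
#' @slot p0 concentration at t = 0, pg/ml
#' @slot plateau asymptotic concentration, pg/ml
#' @slot k decay rate, per minute
#' @slot halfLifeMin ln(2)/k, minutes
#' @slot rss residual sum of squares
#' @slot converged FALSE for degenerate inputs (constant or rising series)
#' @slot message diagnostic for non-converged fits
#' @export
setClass("DecayFit", representation(
  p0          = "numeric",
  plateau     = "numeric",
  k           = "numeric",
  halfLifeMin = "numeric",
  rss         = "numeric",
  converged   = "logical",
  message     = "character"
))

#' Rigid 2-d transform between a moving and a fixed field
#'
#' Rotation by theta about the image centre followed by a translation,
#' estimated from the nuclear channels of a live and a fixed acquisition.
#'
#' @slot dxPx x translation, pixels
#' @slot dyPx y translation, pixels
#' @slot thetaDeg rotation, degrees (counter-clockwise about image centre)
#' @slot score registration quality (normalised correlation peak)
#' @slot pixelSizeUm pixel side length, for um-scale accessors
#' @export
setClass("RigidTransform", representation(
  dxPx        = "numeric",
  dyPx        = "numeric",
  thetaDeg    = "numeric",
  score       = "numeric",
  pixelSizeUm = "numeric"
))

#' Colocalization result
#'
#' Pearson correlation of two channels with Costes auto-thresholds and a
#' block-scramble randomization p-value,
#' p = (1 + #\{R_rand >= R_obs\}) / (1 + n).
#'
#' @slot pearsonR observed correlation
#' @slot thresholds per-channel Costes thresholds (NA when undefined)
#' @slot pValue randomization probability
#' @slot nRandomizations randomization count (default 10)
#' @slot blockSizePx scramble block side, pixels
#' @slot randomR the randomized correlations
#' @slot thresholdsDefined FALSE when the Costes criterion had no solution
#' @export
setClass("ColocResult", representation(
  pearsonR          = "numeric",
  thresholds        = "numeric",
  pValue            = "numeric",
  nRandomizations   = "integer",
  blockSizePx       = "integer",
  randomR           = "numeric",
  thresholdsDefined = "logical"
))
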
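# Small acquisition used throughout the unit tests: 40 frames at 5 s,
# six-frame baseline, ionomycin over the last ~1 min, 128 px field.
quickMeta <- function(imageSizePx = 128L, nFrames = 40L,
                      ionomycinFrame = 33L, ...) {
  AcquisitionMeta(imageSizePx = imageSizePx, nFrames = nFrames,
                  ionomycinFrame = ionomycinFrame, ...)
}

quickConfig <- function(nCells = 30L, ...) SceneConfig(nCells = nCells, ...)

# A hand-built scene with one cell per requested class, well separated.
classScene <- function(classes, meta = quickMeta(), radiusUm = 6,
                       doseMm = 3, config = quickConfig()) {
  n <- length(classes)
  fs <- meta@fieldSizeUm
  gx <- ceiling(sqrt(n))
  pos <- expand.grid(ix = seq_len(gx), iy = seq_len(gx))[seq_len(n), ]
  step <- fs / (gx + 1)
  cells <- data.frame(id = seq_len(n),
                      x_um = pos$ix * step, y_um = pos$iy * step,
                      radius_um = radiusUm, class = classes,
                      f0 = 25, viable = classes != "nonviable",
                      stringsAsFactors = FALSE)
  Scene(cells, doseMm = doseMm, meta = meta, config = config)
}

# Synthetic trace straight from a fold curve (f0 = 10 by construction).
foldTrace <- function(fold, label = 1L) {
  f0 <- 10
  new("FluxTrace", label = as.integer(label), intden = fold * f0,
      areaPx = 1L, areaUm2 = 1, background = rep(0, length(fold)),
      ctcf = fold * f0, f0 = f0, saturated = FALSE, valid = TRUE,
      reason = "")
}

# Independent evaluation of the documented piecewise kinetic model, used to
# check the rendering path end to end.
kineticFoldOracle <- function(tS, class, kin, tStimS, tIonoS) {
  f <- rep(1, length(tS))
  k <- kin[[class]]
  for (i in seq_along(tS)) {
    u <- tS[i] - tStimS - (if (is.null(k$onsetDelayS)) 0 else k$onsetDelayS)
    if (class %in% c("maximal", "gradual") && u > 0)
      f[i] <- 1 + (k$peakFold - 1) * (1 - exp(-u / k$riseTauS))
    if (class == "transient" && u > 0) {
      tPk <- 5 * k$riseTauS
      if (u <= tPk) f[i] <- 1 + (k$peakFold - 1) * (1 - exp(-u / k$riseTauS))
      else {
        fPk <- 1 + (k$peakFold - 1) * (1 - exp(-5))
        f[i] <- 1 + (fPk - 1) * exp(-(u - tPk) / k$decayTauS)
      }
    }
    if (class != "nonviable" && !is.na(tIonoS) && tS[i] >= tIonoS) {
      v <- tS[i] - tIonoS
      f[i] <- max(f[i], 1 + (kin$ionomycin$foldPeak - 1) *
                    (1 - exp(-v / kin$ionomycin$riseTauS)))
    }
  }
  f
}
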
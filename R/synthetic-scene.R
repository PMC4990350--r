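#' Default per-class kinetic parameters
#'
#' Piecewise kinetic models for the waveform classes observed in live
#' parathyroid tissue: \emph{maximal} (fast saturating rise to a sustained
#' plateau), \emph{transient} (fast rise, then exponential decay back
#' towards baseline), \emph{gradual} (delayed slow ramp), and
#' \emph{nonresponder} (flat). Every viable cell additionally mounts a fast
#' ionomycin spike after the terminal challenge; nonviable cells stay flat
#' throughout. Times in seconds, amplitudes as fold over the cell's
#' baseline.
#'
#' @return named list of per-class parameter lists with elements
#'   \code{riseTauS}, \code{peakFold}, \code{onsetDelayS},
#'   \code{decayTauS} (transient only), plus the shared
#'   \code{ionomycin = list(foldPeak, riseTauS)}
#' @export
defaultKinetics <- function() {
  list(
    maximal      = list(riseTauS = 5,   peakFold = 6, onsetDelayS = 0),
    transient    = list(riseTauS = 5,   peakFold = 6, onsetDelayS = 0,
                        decayTauS = 60),
    gradual      = list(riseTauS = 120, peakFold = 5, onsetDelayS = 90),
    nonresponder = list(peakFold = 1),
    ionomycin    = list(foldPeak = 6, riseTauS = 3)
  )
}

#' Construct a scene configuration
#'
#' Study-condition defaults: cells of radius 5.5 +/- 0.5 um (about 11-um
#' tumor cells), 5\% nonviable, a responder model with bottom 0, top 0.8,
#' EC50 3.2 mM and Hill slope 4, non-maximal mass split 25/25/50 between
#' transient, gradual and nonresponder, read noise sd 1.5 intensity units
#' with a signal-proportional variance scale of 0.02, background level 10
#' and per-cell baseline amplitude 25 +/- 2.5.
#'
#' @param nCells cells per scene
#' @param cellRadiusUm c(mean, sd) cell radius in um
#' @param deadFraction nonviable fraction
#' @param responderModel list(bottom, top, ec50Mm, hill)
#' @param nonMaximalWeights named weights over transient/gradual/nonresponder
#' @param kinetics see \code{\link{defaultKinetics}}
#' @param noise list(readSd, signalScale)
#' @param backgroundLevel flux background intensity
#' @param baselineIntensity c(mean, sd) of per-cell baseline amplitude
#' @param nuclearIntensity nuclear blob amplitude
#' @param viabilityIntensity viability-channel amplitude for dead cells
#' @return a \linkS4class{SceneConfig}
#' @examples
#' cfg <- SceneConfig(nCells = 50)
#' @export
SceneConfig <- function(nCells = 150L,
                        cellRadiusUm = c(5.5, 0.5),
                        deadFraction = 0.05,
                        responderModel = list(bottom = 0, top = 0.8,
                                              ec50Mm = 3.2, hill = 4),
                        nonMaximalWeights = c(transient = 0.25,
                                              gradual = 0.25,
                                              nonresponder = 0.5),
                        kinetics = defaultKinetics(),
                        noise = list(readSd = 1.5, signalScale = 0.02),
                        backgroundLevel = 10,
                        baselineIntensity = c(25, 2.5),
                        nuclearIntensity = 120,
                        viabilityIntensity = 150) {
  new("SceneConfig",
      nCells = as.integer(nCells),
      cellRadiusUm = as.numeric(cellRadiusUm),
      deadFraction = as.numeric(deadFraction),
      responderModel = responderModel,
      nonMaximalWeights = nonMaximalWeights,
      kinetics = kinetics,
      noise = noise,
      backgroundLevel = as.numeric(backgroundLevel),
      baselineIntensity = as.numeric(baselineIntensity),
      nuclearIntensity = as.numeric(nuclearIntensity),
      viabilityIntensity = as.numeric(viabilityIntensity))
}

# Draw latent class labels for n viable cells at a dose.
sampleClasses <- function(config, doseMm, n) {
  rm_ <- config@responderModel
  pMax <- fourPL(doseMm, rm_$bottom, rm_$top, log10(rm_$ec50Mm), rm_$hill)
  w <- config@nonMaximalWeights / sum(config@nonMaximalWeights)
  probs <- c(maximal = pMax, (1 - pMax) * w)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Sample a synthetic tissue-slice scene
#'
#' Draws cell positions (non-overlapping disks, rejection sampling), radii,
#' viability, per-cell baseline amplitudes, and latent kinetic class
#' labels. Each viable cell is \code{maximal} with the probability given by
#' the configured four-parameter logistic at \code{doseMm}; the remaining
#' mass is split among the non-maximal classes by the configured weights.
#' Nonviable cells are drawn independently with probability
#' \code{deadFraction} and labelled \code{nonviable}.
#'
#' @param config a \linkS4class{SceneConfig}
#' @param doseMm extracellular calcium concentration, mM (> 0)
#' @param seed integer seed; the scene is fully reproducible from it
#' @param meta an \linkS4class{AcquisitionMeta} (geometry + timing)
#' @return a \linkS4class{Scene}
#' @examples
#' sc <- sampleScene(SceneConfig(nCells = 40), doseMm = 3, seed = 1,
#'                   meta = AcquisitionMeta(imageSizePx = 256L))
#' table(sceneCells(sc)$class)
#' @export
sampleScene <- function(config, doseMm, seed, meta = AcquisitionMeta()) {
  stopifnot(is(config, "SceneConfig"), is(meta, "AcquisitionMeta"))
  validObject(config)
  if (doseMm <= 0) stop("doseMm must be > 0")
  withSeed(seed, {
    n <- config@nCells
    fs <- meta@fieldSizeUm
    radii <- pmax(1, rnorm(n, config@cellRadiusUm[1], config@cellRadiusUm[2]))
    xs <- ys <- numeric(n)
    gapUm <- 6
    if (n > 0) {
      maxTries <- 2000L * n
      placed <- 0L
      tries <- 0L
      while (placed < n && tries < maxTries) {
        tries <- tries + 1L
        r <- radii[placed + 1L]
        x <- runif(1, r + 1, fs - r - 1)
        y <- runif(1, r + 1, fs - r - 1)
        if (placed == 0L ||
            all((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2 >
                (radii[seq_len(placed)] + r + gapUm)^2)) {
          placed <- placed + 1L
          xs[placed] <- x
          ys[placed] <- y
        }
      }
      if (placed < n)
        stop("could not place ", n, " non-overlapping cells in a ",
             fs, " um field; reduce nCells or cell radius")
    }
    dead <- runif(n) < config@deadFraction
    cls <- rep("nonviable", n)
    nViable <- sum(!dead)
    if (nViable > 0) cls[!dead] <- sampleClasses(config, doseMm, nViable)
    f0 <- pmax(5, rnorm(n, config@baselineIntensity[1],
                        config@baselineIntensity[2]))
    cells <- data.frame(id = seq_len(n), x_um = xs, y_um = ys,
                        radius_um = radii, class = cls, f0 = f0,
                        viable = !dead, stringsAsFactors = FALSE)
    new("Scene", cells = cells, doseMm = doseMm, meta = meta, config = config)
  })
}

# Fold-over-baseline kinetic model for one cell, evaluated at frame times.
# tS: frame times (s); tStimS stimulus addition; tIonoS ionomycin addition
# (NA for none).
kineticFold <- function(tS, class, kin, tStimS, tIonoS) {
  fold <- rep(1, length(tS))
  k <- kin[[class]]
  if (class %in% c("maximal", "gradual")) {
    u <- tS - tStimS - k$onsetDelayS
    on <- u > 0
    fold[on] <- 1 + (k$peakFold - 1) * (1 - exp(-u[on] / k$riseTauS))
  } else if (class == "transient") {
    u <- tS - tStimS - k$onsetDelayS
    tPeak <- 5 * k$riseTauS               # rise considered complete at 5 tau
    rising <- u > 0 & u <= tPeak
    fold[rising] <- 1 + (k$peakFold - 1) * (1 - exp(-u[rising] / k$riseTauS))
    fPk <- 1 + (k$peakFold - 1) * (1 - exp(-5))
    dec <- u > tPeak
    fold[dec] <- 1 + (fPk - 1) * exp(-(u[dec] - tPeak) / k$decayTauS)
  }
  if (!is.na(tIonoS) && class != "nonviable") {
    io <- kin$ionomycin
    v <- tS - tIonoS
    post <- v >= 0
    spike <- 1 + (io$foldPeak - 1) * (1 - exp(-v[post] / io$riseTauS))
    fold[post] <- pmax(fold[post], spike)
  }
  fold
}

# Soft-edged disk footprint of one cell on the pixel grid. Returns linear
# pixel indices, weights, and the hard mask (d <= r) used as ground truth.
# Edge softness is physical (um) so footprint support is grid-independent:
# with the sampler's placement gap, footprints of distinct cells can never
# own adjacent pixels, keeping connected-component ground truth unambiguous.
cellFootprint <- function(xUm, yUm, rUm, pxUm, ny, nx, edgeSoftUm = 0.35,
                          scale = 1) {
  edgeSoftPx <- max(edgeSoftUm / pxUm * scale, 1e-3)
  r <- rUm / pxUm * scale
  cx <- xUm / pxUm * scale + 0.5    # pixel-centre convention, 1-based grids
  cy <- yUm / pxUm * scale + 0.5
  x0 <- max(1L, floor(cx - r - 3))
  x1 <- min(nx, ceiling(cx + r + 3))
  y0 <- max(1L, floor(cy - r - 3))
  y1 <- min(ny, ceiling(cy + r + 3))
  if (x0 > x1 || y0 > y1)
    return(list(idx = integer(), w = numeric(), hard = logical()))
  xs <- x0:x1
  ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  w <- 1 / (1 + exp((d - r) / edgeSoftPx))
  keep <- w > 0.1
  iy <- row(d)[keep] + y0 - 1L
  ix <- col(d)[keep] + x0 - 1L
  list(idx = (ix - 1L) * ny + iy, w = w[keep], hard = d[keep] <= r)
}

#' Render a scene into a flux movie
#'
#' Renders each cell as a soft-edged disk. The flux channel follows each
#' cell's latent kinetic model (baseline before the stimulus frame,
#' class-specific response after, ionomycin spike for all viable cells);
#' the nuclear channel carries one blob per cell; the viability channel is
#' bright only over nonviable cells. Noise is additive Gaussian with a
#' signal-proportional variance component; intensities are rounded and
#' clipped to the bit depth last, with clipping flagged on the movie.
#'
#' @param scene a \linkS4class{Scene}
#' @param seed integer seed for the noise
#' @param noiseless render without noise (exact latent model)
#' @return a \linkS4class{FluxMovie}
#' @examples
#' sc <- sampleScene(SceneConfig(nCells = 20), 3, seed = 1,
#'                   meta = AcquisitionMeta(imageSizePx = 128L, nFrames = 30L,
#'                                          ionomycinFrame = 25L))
#' mv <- renderMovie(sc, seed = 2)
#' @export
renderMovie <- function(scene, seed = 1L, noiseless = FALSE) {
  stopifnot(is(scene, "Scene"))
  validObject(scene)
  meta <- scene@meta
  cfg <- scene@config
  npx <- meta@imageSizePx
  ny <- nx <- as.integer(npx)
  pxUm <- pixelSizeUm(meta)
  cells <- scene@cells
  tS <- frameTimesS(meta)
  tStim <- stimulusTimeS(meta)
  tIono <- ionomycinTimeS(meta)

  foot <- lapply(seq_len(nrow(cells)), function(i)
    cellFootprint(cells$x_um[i], cells$y_um[i], cells$radius_um[i],
                  pxUm, ny, nx))
  nucFoot <- lapply(seq_len(nrow(cells)), function(i)
    cellFootprint(cells$x_um[i], cells$y_um[i], 0.55 * cells$radius_um[i],
                  pxUm, ny, nx))
  folds <- vapply(seq_len(nrow(cells)), function(i)
    kineticFold(tS, cells$class[i], cfg@kinetics, tStim, tIono),
    numeric(meta@nFrames))
  if (nrow(cells) == 0) folds <- matrix(0, meta@nFrames, 0)

  idxAll <- unlist(lapply(foot, `[[`, "idx"))
  wAll <- unlist(lapply(foot, `[[`, "w"))
  cellOf <- rep.int(seq_len(nrow(cells)), vapply(foot, function(f)
    length(f$idx), integer(1)))
  ampAll <- cells$f0[cellOf] * wAll

  withSeed(seed, {
    flux <- array(0L, dim = c(ny, nx, meta@nFrames))
    clippedAny <- FALSE
    readSd <- cfg@noise$readSd
    sScale <- cfg@noise$signalScale
    for (t in seq_len(meta@nFrames)) {
      frame <- rep(cfg@backgroundLevel, ny * nx)
      if (length(idxAll))
        frame[idxAll] <- frame[idxAll] + ampAll * folds[t, cellOf]
      if (!noiseless) {
        sdPx <- sqrt(readSd^2 + sScale * frame)
        frame <- frame + rnorm(ny * nx) * sdPx
      }
      cl <- clipToBitDepth(round(frame), meta@bitDepth)
      clippedAny <- clippedAny || cl$clipped
      flux[, , t] <- as.integer(cl$values)
    }

    nuclear <- rep(0.8 * cfg@backgroundLevel, ny * nx)
    for (i in seq_along(nucFoot)) {
      f <- nucFoot[[i]]
      if (length(f$idx))
        nuclear[f$idx] <- nuclear[f$idx] + cfg@nuclearIntensity * f$w
    }
    if (!noiseless)
      nuclear <- nuclear + rnorm(ny * nx) *
        sqrt(readSd^2 + sScale * nuclear)
    cln <- clipToBitDepth(round(nuclear), meta@bitDepth)
    clippedAny <- clippedAny || cln$clipped
    nuclear <- matrix(as.integer(cln$values), ny, nx)

    viability <- rep(0.5 * cfg@backgroundLevel, ny * nx)
    deadIdx <- which(!cells$viable)
    for (i in deadIdx) {
      f <- foot[[i]]
      if (length(f$idx))
        viability[f$idx] <- viability[f$idx] + cfg@viabilityIntensity * f$w
    }
    if (!noiseless)
      viability <- viability + rnorm(ny * nx) *
        sqrt(readSd^2 + sScale * viability)
    clv <- clipToBitDepth(round(viability), meta@bitDepth)
    viability <- matrix(as.integer(clv$values), ny, nx)

    new("FluxMovie", flux = flux, nuclear = nuclear, viability = viability,
        meta = meta, clipped = clippedAny)
  })
}

#' Ground-truth pixel masks for a scene's cells
#'
#' Hard disk masks (distance <= radius) on the rendering grid, for oracle
#' tests and truth-mask trace extraction.
#'
#' @param scene a \linkS4class{Scene}
#' @return list of \code{CellObject}-style data: a data.frame
#'   (label, x_um, y_um, area_um2, equiv_diameter_um, touches_edge) and a
#'   label image (ny x nx integer matrix, 0 = background)
#' @export
sceneMasks <- function(scene) {
  meta <- scene@meta
  ny <- nx <- as.integer(meta@imageSizePx)
  pxUm <- pixelSizeUm(meta)
  labels <- matrix(0L, ny, nx)
  cells <- scene@cells
  for (i in seq_len(nrow(cells))) {
    f <- cellFootprint(cells$x_um[i], cells$y_um[i], cells$radius_um[i],
                       pxUm, ny, nx)
    labels[f$idx[f$hard]] <- cells$id[i]
  }
  objects <- objectTable(labels, pxUm)
  objects <- merge(objects, cells[, c("id", "class", "viable")],
                   by.x = "label", by.y = "id", sort = TRUE)
  list(objects = objects, labels = labels)
}

#' Simulate a full dose series
#'
#' One independent scene and movie per calcium dose, with ground-truth
#' labels retained. Per-dose seeds are derived deterministically from the
#' master seed. Default doses are the eight assayed extracellular calcium
#' concentrations 0.5, 0.75, 1.0, 1.25, 2.0, 3.0, 5.0 and 10.0 mM.
#'
#' @param config a \linkS4class{SceneConfig}
#' @param doses calcium concentrations, mM (>= 2 distinct values)
#' @param seed master seed
#' @param meta an \linkS4class{AcquisitionMeta}
#' @param render also render movies (set FALSE for label-only studies)
#' @return list with one element per dose: list(doseMm, scene, movie)
#' @export
simulateDoseSeries <- function(config, doses = c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10),
                               seed = 1L, meta = AcquisitionMeta(),
                               render = TRUE) {
  if (length(doses) == 0) stop("empty dose list")
  if (length(unique(doses)) < 2) stop("need >= 2 distinct doses")
  lapply(seq_along(doses), function(k) {
    sSeed <- childSeed(seed, 2L * k)
    scene <- sampleScene(config, doses[k], seed = sSeed, meta = meta)
    movie <- if (render) renderMovie(scene, seed = childSeed(seed, 2L * k + 1L))
             else NULL
    list(doseMm = doses[k], scene = scene, movie = movie)
  })
}

#' Simulate a fixed-field immunofluorescence image pair
#'
#' Emulates post-fixation imaging of the same field: the nuclear blobs are
#' reproduced under a rigid transform (rotation about the field centre then
#' translation), and a PTH channel is painted per cell according to a
#' per-class positivity probability and intensity, enabling known-truth
#' registration and colocalization tests.
#'
#' @param scene the live-cell \linkS4class{Scene}
#' @param pthModel list(prob = named per-class positivity probabilities,
#'   intensityMean, intensitySd). Classes absent from \code{prob} default
#'   to probability 0.
#' @param transform a \linkS4class{RigidTransform} (defaults to identity)
#' @param seed integer seed
#' @param noiseless disable noise
#' @return list(pth, nuclear) integer matrices plus \code{truth}
#'   (data.frame: id, class, pth_positive, x_px, y_px of transformed
#'   centres) and the applied \code{transform}
#' @export
simulateFixedField <- function(scene, pthModel = list(
                                 prob = c(maximal = 0, transient = 0.3,
                                          gradual = 0.3, nonresponder = 0.6,
                                          nonviable = 0),
                                 intensityMean = 110, intensitySd = 15),
                               transform = RigidTransform(0, 0, 0),
                               seed = 1L, noiseless = FALSE) {
  stopifnot(is(scene, "Scene"), is(transform, "RigidTransform"))
  meta <- scene@meta
  cfg <- scene@config
  ny <- nx <- as.integer(meta@imageSizePx)
  pxUm <- pixelSizeUm(meta)
  cells <- scene@cells
  # transform cell centres: rotate about field centre, then translate
  th <- transform@thetaDeg * pi / 180
  cUm <- meta@fieldSizeUm / 2
  xr <- cUm + cos(th) * (cells$x_um - cUm) - sin(th) * (cells$y_um - cUm) +
    transform@dxPx * pxUm
  yr <- cUm + sin(th) * (cells$x_um - cUm) + cos(th) * (cells$y_um - cUm) +
    transform@dyPx * pxUm

  withSeed(seed, {
    prob <- pthModel$prob
    p <- vapply(cells$class, function(cl)
      if (cl %in% names(prob)) prob[[cl]] else 0, numeric(1))
    pthPos <- runif(nrow(cells)) < p
    pthAmp <- pmax(0, rnorm(nrow(cells), pthModel$intensityMean,
                            pthModel$intensitySd))

    nuclear <- rep(0.8 * cfg@backgroundLevel, ny * nx)
    pth <- rep(0.6 * cfg@backgroundLevel, ny * nx)
    for (i in seq_len(nrow(cells))) {
      fN <- cellFootprint(xr[i], yr[i], 0.55 * cells$radius_um[i],
                          pxUm, ny, nx)
      if (length(fN$idx))
        nuclear[fN$idx] <- nuclear[fN$idx] + cfg@nuclearIntensity * fN$w
      if (pthPos[i]) {
        fP <- cellFootprint(xr[i], yr[i], cells$radius_um[i], pxUm, ny, nx)
        if (length(fP$idx))
          pth[fP$idx] <- pth[fP$idx] + pthAmp[i] * fP$w
      }
    }
    if (!noiseless) {
      rSd <- cfg@noise$readSd
      sSc <- cfg@noise$signalScale
      nuclear <- nuclear + rnorm(ny * nx) * sqrt(rSd^2 + sSc * nuclear)
      pth <- pth + rnorm(ny * nx) * sqrt(rSd^2 + sSc * pth)
    }
    nuclear <- matrix(as.integer(clipToBitDepth(round(nuclear),
                                                meta@bitDepth)$values), ny, nx)
    pth <- matrix(as.integer(clipToBitDepth(round(pth),
                                            meta@bitDepth)$values), ny, nx)
    truth <- data.frame(id = cells$id, class = cells$class,
                        pth_positive = pthPos,
                        x_px = xr / pxUm + 0.5, y_px = yr / pxUm + 0.5)
    list(pth = pth, nuclear = nuclear, truth = truth, transform = transform)
  })
}

#' Simulate a post-resection circulating hormone decay series
#'
#' Values follow plateau + (p0 - plateau) * 2^(-t / halfLifeMin) with
#' additive Gaussian noise.
#'
#' @param p0 concentration at time 0, pg/ml
#' @param plateau asymptote, pg/ml (p0 > plateau >= 0)
#' @param halfLifeMin half-life, minutes (> 0)
#' @param timesMin strictly increasing sampling times, minutes
#' @param noiseSd additive noise sd, pg/ml
#' @param seed integer seed
#' @return data.frame(time_min, pth_pg_ml)
#' @examples
#' simulatePTHDecay(100, 0, 4, c(0, 10, 15, 20), noiseSd = 0, seed = 1)
#' @export
simulatePTHDecay <- function(p0, plateau, halfLifeMin, timesMin,
                             noiseSd = 0, seed = 1L) {
  if (p0 <= plateau || plateau < 0) stop("need p0 > plateau >= 0")
  if (halfLifeMin <= 0) stop("halfLifeMin must be > 0")
  if (any(diff(timesMin) <= 0)) stop("times must be strictly increasing")
  withSeed(seed, {
    v <- plateau + (p0 - plateau) * 2^(-timesMin / halfLifeMin)
    if (noiseSd > 0) v <- v + rnorm(length(timesMin), 0, noiseSd)
    data.frame(time_min = timesMin, pth_pg_ml = v)
  })
}

#' Construct a scene from an explicit cell table
#'
#' Bypasses sampling; used to build edge cases (e.g. a cell centred on the
#' field border, or a single-class field) with exact ground truth.
#'
#' @param cells data.frame(id, x_um, y_um, radius_um, class, f0, viable)
#' @param doseMm calcium dose, mM
#' @param meta an \linkS4class{AcquisitionMeta}
#' @param config a \linkS4class{SceneConfig} (rendering/noise parameters)
#' @return a \linkS4class{Scene}
#' @export
Scene <- function(cells, doseMm, meta = AcquisitionMeta(),
                  config = SceneConfig()) {
  new("Scene", cells = cells, doseMm = doseMm, meta = meta, config = config)
}
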
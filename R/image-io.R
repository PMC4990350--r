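#' Write a flux movie as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered: all flux frames, then the nuclear frame, then the
#' viability frame when present. The sidecar (same stem, \code{.json})
#' carries the acquisition metadata, a schema version and the page layout;
#' \code{groundTruth} (e.g. \code{sceneCells()}) may be embedded for
#' round-trip tests of simulated data.
#'
#' @param movie a \linkS4class{FluxMovie}
#' @param path output TIFF path (the sidecar replaces the extension with
#'   \code{.json})
#' @param groundTruth optional data.frame stored under \code{ground_truth}
#' @return \code{path}, invisibly
#' @export
writeMovie <- function(movie, path, groundTruth = NULL) {
  stopifnot(is(movie, "FluxMovie"))
  validObject(movie)
  mx <- 2^movie@meta@bitDepth - 1
  bits <- if (movie@meta@bitDepth <= 8) 8L else 16L
  pages <- lapply(seq_len(dim(movie@flux)[3]), function(t)
    movie@flux[, , t] / mx)
  pages <- c(pages, list(movie@nuclear / mx))
  hasViability <- !is.null(movie@viability)
  if (hasViability) pages <- c(pages, list(movie@viability / mx))
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  meta <- movie@meta
  sidecar <- list(
    schema = "calsens-movie/1",
    meta = list(frame_interval_s = meta@frameIntervalS,
                n_frames = meta@nFrames,
                n_baseline_frames = meta@nBaselineFrames,
                field_size_um = meta@fieldSizeUm,
                image_size_px = meta@imageSizePx,
                bit_depth = meta@bitDepth,
                stimulus_frame = meta@stimulusFrame,
                ionomycin_frame = if (is.na(meta@ionomycinFrame)) NULL
                                  else meta@ionomycinFrame),
    layout = list(flux_pages = c(1L, meta@nFrames),
                  nuclear_page = meta@nFrames + 1L,
                  viability_page = if (hasViability) meta@nFrames + 2L else NULL),
    clipped = movie@clipped)
  if (!is.null(groundTruth)) sidecar$ground_truth <- groundTruth
  jsonlite::write_json(sidecar, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecarPath <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a flux movie written by \code{writeMovie}
#'
#' Validates the frame count against the sidecar metadata and restores the
#' integer pixel data losslessly.
#'
#' @param path TIFF path with an adjacent JSON sidecar
#' @return a \linkS4class{FluxMovie}; the sidecar's \code{ground_truth}
#'   table, if present, is attached as attribute \code{"groundTruth"}
#' @export
readMovie <- function(path) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  sp <- sidecarPath(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar for movie: ", sp)
  sidecar <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(sidecar$meta) || !identical(sidecar$schema, "calsens-movie/1"))
    stop("sidecar does not carry calsens-movie/1 metadata: ", sp)
  m <- sidecar$meta
  meta <- AcquisitionMeta(frameIntervalS = m$frame_interval_s,
                          nFrames = m$n_frames,
                          nBaselineFrames = m$n_baseline_frames,
                          fieldSizeUm = m$field_size_um,
                          imageSizePx = m$image_size_px,
                          bitDepth = m$bit_depth,
                          stimulusFrame = m$stimulus_frame,
                          ionomycinFrame = if (is.null(m$ionomycin_frame) ||
                                               !is.numeric(m$ionomycin_frame))
                            NA_integer_ else m$ionomycin_frame)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("failed to read TIFF '", path, "': ",
                           conditionMessage(e)))
  hasViability <- !is.null(sidecar$layout$viability_page)
  expected <- meta@nFrames + 1L + as.integer(hasViability)
  if (length(pages) != expected)
    stop("frame-count mismatch in '", path, "': expected ", expected,
         " pages (", meta@nFrames, " flux + nuclear",
         if (hasViability) " + viability" else "", "), found ", length(pages))
  mx <- 2^meta@bitDepth - 1
  toInt <- function(p) {
    m_ <- round(p * mx)
    storage.mode(m_) <- "integer"
    m_
  }
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  flux <- array(0L, dim = c(ny, nx, meta@nFrames))
  for (t in seq_len(meta@nFrames)) flux[, , t] <- toInt(pages[[t]])
  nuclear <- toInt(pages[[meta@nFrames + 1L]])
  viability <- if (hasViability) toInt(pages[[meta@nFrames + 2L]]) else NULL
  movie <- new("FluxMovie", flux = flux, nuclear = nuclear,
               viability = viability, meta = meta,
               clipped = isTRUE(sidecar$clipped))
  if (!is.null(sidecar$ground_truth))
    attr(movie, "groundTruth") <- as.data.frame(sidecar$ground_truth)
  movie
}

#' Maximum-intensity z-projection
#'
#' Per-pixel maximum over a small stack of co-registered optical sections.
#'
#' @param sections a list of equally shaped matrices, or a 3-d array
#'   (ny, nx, k)
#' @return a single matrix
#' @examples
#' zProject(list(matrix(0, 2, 2), matrix(1:4, 2, 2)))
#' @export
zProject <- function(sections) {
  if (is.array(sections) && length(dim(sections)) == 3)
    sections <- lapply(seq_len(dim(sections)[3]), function(k)
      sections[, , k])
  if (!is.list(sections) || length(sections) < 1)
    stop("need at least one optical section")
  d <- dim(sections[[1]])
  for (s in sections)
    if (!identical(dim(s), d)) stop("optical sections differ in shape")
  Reduce(pmax, sections)
}

#' Read a timed hormone concentration series from CSV
#'
#' Expects columns \code{time_min} and \code{pth_pg_ml}; validates
#' monotone time and non-negative values.
#'
#' @param path CSV path
#' @return data.frame(time_min, pth_pg_ml)
#' @export
readPTHSeries <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_min", "pth_pg_ml") %in% names(d)))
    stop("PTH series CSV needs columns time_min, pth_pg_ml")
  if (any(diff(d$time_min) <= 0)) stop("time_min must be strictly increasing")
  if (any(d$pth_pg_ml < 0)) stop("pth_pg_ml must be >= 0")
  d[, c("time_min", "pth_pg_ml")]
}
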
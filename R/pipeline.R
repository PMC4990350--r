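#' Analyze one movie: detect, trace, classify, QC
#'
#' Runs the per-field stages in order: nuclei counting (total-cell
#' denominator), viability-stain scoring of nuclei (nonviable cells leave
#' the denominator), baseline-referenced flux-object detection, CTCF trace
#' extraction, waveform classification, and the ionomycin viability
#' filter.
#'
#' @param movie a \linkS4class{FluxMovie}
#' @param params a \linkS4class{ClassifierParams}
#' @param nucleiRadiusUm expected nuclear blob radius for detection
#' @param detectArgs extra arguments passed to
#'   \code{\link{detectFluxObjects}}
#' @return list(nuclei, nNuclei, nDead, nTotal, objects, labels, traces,
#'   calls)
#' @export
analyzeMovie <- function(movie, params = ClassifierParams(),
                         nucleiRadiusUm = 3.3, detectArgs = list()) {
  meta <- movie@meta
  pxUm <- pixelSizeUm(meta)
  nuclei <- countNuclei(movie@nuclear, pxUm,
                        expectedRadiusUm = nucleiRadiusUm)
  nDead <- 0L
  if (!is.null(movie@viability) && nrow(nuclei) > 0) {
    deadBlobs <- countNuclei(movie@viability, pxUm,
                             expectedRadiusUm = 1.8 * nucleiRadiusUm)
    nDead <- nrow(deadBlobs)
  }
  nNuclei <- nrow(nuclei)
  nTotal <- max(nNuclei - nDead, 0L)
  det <- do.call(detectFluxObjects, c(list(movie), detectArgs))
  traces <- extractTraces(movie, det$labels)
  calls <- if (length(traces)) {
    cl <- classifyWaveforms(traces, meta, params)
    viabilityFilter(cl, meta, params)
  } else data.frame()
  list(nuclei = nuclei, nNuclei = nNuclei, nDead = nDead, nTotal = nTotal,
       objects = det$objects, labels = det$labels, traces = traces,
       calls = calls)
}

#' Default demo pipeline configuration
#'
#' A small end-to-end configuration: eight-dose series, 120 cells per
#' field, 128 x 128 frames, fitted with binomial weighting.
#'
#' @param outDir output directory
#' @param seed master seed
#' @return config list accepted by \code{\link{runPipeline}}
#' @export
demoPipelineConfig <- function(outDir = tempfile("calsens_run_"), seed = 1L) {
  list(
    out_dir = outDir,
    seed = seed,
    doses_mM = c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10),
    scene = list(n_cells = 120L),
    meta = list(image_size_px = 128L),
    classifier = list(),
    fit = list(weighting = "binomial")
  )
}

#' Run the pipeline end-to-end
#'
#' Simulates (or loads) one movie per calcium dose, runs detection,
#' tracing, classification and viability QC, assembles the per-dose
#' maximal-responder table, fits the four-parameter logistic setpoint
#' curve, and writes all stage outputs (dose table and waveform calls as
#' CSV, fit and run report as JSON) under \code{config$out_dir}. The run
#' is idempotent for a fixed config and seed.
#'
#' Config keys: \code{out_dir}, \code{seed}, either \code{doses_mM} (+
#' optional \code{scene} / \code{meta} overrides, snake_case field names)
#' for simulation or \code{movie_paths} (named by dose) for stored movies;
#' \code{classifier} overrides for \code{\link{ClassifierParams}};
#' \code{fit$weighting}. A YAML file path may be given instead of a list
#' (requires the yaml package).
#'
#' @param config configuration list or YAML path
#' @return run report list (invisibly also written as JSON)
#' @export
runPipeline <- function(config = demoPipelineConfig()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- do.call(ClassifierParams, camelise(config$classifier))
  weighting <- if (is.null(config$fit$weighting)) "binomial"
               else config$fit$weighting

  if (!is.null(config$movie_paths)) {
    for (p in config$movie_paths)
      if (!file.exists(p)) stop("movie path does not exist: ", p)
    movies <- lapply(config$movie_paths, readMovie)
    doses <- as.numeric(names(config$movie_paths))
    if (any(is.na(doses)))
      stop("movie_paths must be named by calcium dose (mM)")
  } else {
    if (is.null(config$doses_mM)) stop("config needs doses_mM or movie_paths")
    doses <- as.numeric(config$doses_mM)
    metaArgs <- camelise(config$meta)
    meta <- do.call(AcquisitionMeta, metaArgs)
    sceneCfg <- do.call(SceneConfig, camelise(config$scene))
    series <- simulateDoseSeries(sceneCfg, doses, seed = seed, meta = meta)
    movies <- lapply(series, `[[`, "movie")
  }

  points <- NULL
  perDose <- list()
  for (k in seq_along(doses)) {
    res <- tryCatch(analyzeMovie(movies[[k]], params = params),
                    error = function(e)
                      stop("stage 'analyze' failed at dose ", doses[k],
                           " mM: ", conditionMessage(e)))
    nMax <- if (nrow(res$calls)) sum(res$calls$class == "maximal",
                                     na.rm = TRUE) else 0L
    nTotal <- max(res$nTotal, 1L)
    points <- rbind(points, dosePoint(NULL, nTotal, doses[k],
                                      nMaximal = min(nMax, nTotal)))
    if (nrow(res$calls))
      writeCalls(res$calls, file.path(config$out_dir,
                                      sprintf("calls_dose_%g.csv", doses[k])))
    perDose[[k]] <- list(dose_mM = doses[k], n_nuclei = res$nNuclei,
                         n_dead = res$nDead, n_total = nTotal,
                         n_maximal = nMax)
  }
  write.csv(points, file.path(config$out_dir, "dose_table.csv"),
            row.names = FALSE)
  fit <- fit4PL(points, weighting = weighting)
  writeFitReport(fit, file.path(config$out_dir, "setpoint_fit.json"))
  report <- list(package_version = as.character(utils::packageVersion("calsens")),
                 seed = seed, doses_mM = doses, per_dose = perDose,
                 ec50_mM = fit@ec50Mm, hill = fit@hill,
                 converged = fit@converged, identifiable = fit@identifiable)
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

# snake_case config keys -> camelCase constructor arguments
camelise <- function(x) {
  if (is.null(x) || !length(x)) return(list())
  names(x) <- vapply(names(x), function(n)
    gsub("_(.)", "\\U\\1", n, perl = TRUE), character(1))
  x
}
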
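#' Per-dose maximal-responder proportion
#'
#' The proportion of cells exhibiting a rapid and sustained flux profile,
#' over the total (viable) cell count of the field. Nonviable cells must
#' already have been excluded from \code{nTotal}.
#'
#' @param calls waveform-call data.frame (or NULL with \code{nMaximal})
#' @param nTotal total viable cell count of the field (>= 1)
#' @param caMm calcium concentration, mM
#' @param nMaximal override the maximal count directly
#' @return one-row data.frame: ca_mM, n_total, n_maximal, proportion
#' @examples
#' dosePoint(NULL, nTotal = 600, caMm = 2, nMaximal = 150)  # proportion 0.25
#' @export
dosePoint <- function(calls, nTotal, caMm, nMaximal = NULL) {
  if (nTotal < 1) stop("nTotal must be >= 1")
  if (is.null(nMaximal))
    nMaximal <- sum(calls$class == "maximal", na.rm = TRUE)
  if (nMaximal > nTotal)
    stop("nTotal (", nTotal, ") below the maximal-responder count (",
         nMaximal, ")")
  data.frame(ca_mM = caMm, n_total = as.integer(nTotal),
             n_maximal = as.integer(nMaximal),
             proportion = nMaximal / nTotal)
}

#' @rdname dosePoint
#' @export
proportionMaximal <- dosePoint

fourPLResiduals <- function(par, x, p, w) {
  sqrt(w) * (p - fourPL(x, par[1], par[2], par[3], par[4]))
}

#' Fit the four-parameter logistic setpoint curve
#'
#' Weighted least squares of
#' p = bottom + (top - bottom) / (1 + 10^((logEC50 - log10(ca)) * hill))
#' with bounds 0 <= bottom <= top <= 1 and hill > 0, multi-start
#' initialisation, and honest convergence / identifiability flags. The
#' default weighting is binomial (weights n_total); \code{weighting =
#' "none"} gives the unweighted fit. With fewer than 3 distinct doses or
#' flat proportions the fit is flagged unidentifiable and EC50 is NA.
#'
#' @param points dose table (columns ca_mM, proportion; n_total for
#'   binomial weights), e.g. rbind of \code{\link{dosePoint}} rows
#' @param weighting "binomial" or "none"
#' @return a \linkS4class{FourPLFit}
#' @examples
#' doses <- c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10)
#' p <- 0.8 / (1 + 10^((log10(3.2) - log10(doses)) * 4))
#' pts <- data.frame(ca_mM = doses, n_total = 600, proportion = p)
#' ec50(fit4PL(pts))   # 3.2
#' @export
fit4PL <- function(points, weighting = c("binomial", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("ca_mM", "proportion") %in% names(points)))
  x <- points$ca_mM
  p <- points$proportion
  w <- if (weighting == "binomial") {
    if (!"n_total" %in% names(points))
      stop("binomial weighting needs an n_total column")
    points$n_total / mean(points$n_total)
  } else rep(1, length(p))

  bad <- new("FourPLFit", bottom = NA_real_, top = NA_real_,
             logEc50 = NA_real_, hill = NA_real_, ec50Mm = NA_real_,
             rss = NA_real_, converged = FALSE, identifiable = FALSE,
             points = as.data.frame(points), weighting = weighting)
  if (length(unique(x)) < 3 || diff(range(p)) < 1e-9) return(bad)

  lx <- log10(x)
  # with fewer points than free parameters, constrain bottom to 0; the
  # result is reported but flagged not identifiable
  constrained <- length(p) < 4
  lower <- c(0, 0, min(lx) - 2, 1e-3)
  upper <- c(1, 1, max(lx) + 2, 50)
  resFn <- if (constrained) {
    function(par, x, p, w) fourPLResiduals(c(0, par), x, p, w)
  } else fourPLResiduals
  dropBottom <- function(v) if (constrained) v[-1] else v
  addBottom <- function(v) if (constrained) c(0, v) else v
  halfRange <- min(p) + diff(range(p)) / 2
  ord <- order(lx)
  l0 <- tryCatch(approx(p[ord], lx[ord], xout = halfRange, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(l0)) l0 <- median(lx)
  starts <- list(
    c(min(p), max(p), l0, 1),
    c(min(p), max(p), l0, 0.5),
    c(min(p), max(p), l0, 2),
    c(min(p), max(p), l0, 4),
    c(min(p), max(p), median(lx), 8),
    c(0, max(p), median(lx), 1))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = dropBottom(s), lower = dropBottom(lower),
                           upper = dropBottom(upper),
                           fn = resFn, x = x, p = p, w = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(bad)
  par <- addBottom(best$fit$par)
  if (par[1] > par[2]) par[1:2] <- par[2:1]
  identifiable <- !constrained &&
    par[3] > min(lx) - 1.5 && par[3] < max(lx) + 1.5 &&
    (par[2] - par[1]) > 1e-6
  new("FourPLFit", bottom = par[1], top = par[2], logEc50 = par[3],
      hill = par[4], ec50Mm = if (identifiable) 10^par[3] else NA_real_,
      rss = best$rss,
      converged = best$fit$info %in% 1:4,
      identifiable = identifiable,
      points = as.data.frame(points), weighting = weighting)
}

#' Bootstrap confidence interval for the EC50
#'
#' Binomial resampling of each dose point (n_maximal* ~ Binomial(n_total,
#' p_hat)) with refitting; percentile interval over the replicate EC50s.
#' Reproducible from the seed.
#'
#' @param fit a converged \linkS4class{FourPLFit}
#' @param nBoot bootstrap replicates
#' @param seed integer seed
#' @param level confidence level
#' @return list(lower, upper, level, ec50Boot)
#' @export
ec50Confint <- function(fit, nBoot = 200L, seed = 1L, level = 0.95) {
  stopifnot(is(fit, "FourPLFit"))
  if (!fit@converged) stop("fit did not converge; no interval")
  pts <- fit@points
  if (!all(c("n_total", "n_maximal") %in% names(pts)))
    stop("bootstrap needs n_total and n_maximal in the dose table")
  withSeed(seed, {
    boots <- vapply(seq_len(nBoot), function(b) {
      nm <- rbinom(nrow(pts), pts$n_total, pts$proportion)
      bp <- pts
      bp$n_maximal <- nm
      bp$proportion <- nm / bp$n_total
      bf <- fit4PL(bp, weighting = fit@weighting)
      if (bf@identifiable) bf@ec50Mm else NA_real_
    }, numeric(1))
    boots <- boots[is.finite(boots)]
    if (length(boots) < max(10, nBoot / 4))
      stop("too few identifiable bootstrap refits (", length(boots), ")")
    a <- (1 - level) / 2
    qs <- quantile(boots, c(a, 1 - a), names = FALSE)
    list(lower = qs[1], upper = qs[2], level = level, ec50Boot = boots)
  })
}

#' Write a fit report as JSON
#'
#' @param fit a \linkS4class{FourPLFit}
#' @param path output path
#' @export
writeFitReport <- function(fit, path) {
  jsonlite::write_json(list(bottom = fit@bottom, top = fit@top,
                            log_ec50 = fit@logEc50, hill = fit@hill,
                            ec50_mM = fit@ec50Mm, rss = fit@rss,
                            converged = fit@converged,
                            identifiable = fit@identifiable,
                            weighting = fit@weighting,
                            points = fit@points),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
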
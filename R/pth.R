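#' Quantify a fixed-field PTH immunofluorescence image
#'
#' Computes both customary metrics after subtracting the supplied
#' background threshold (established from isotype-control images; negative
#' pixels clipped to 0 for this step): the Hoechst-normalized mean
#' fluorescence intensity (PTH MFI / nuclear MFI) and the field-median
#' per-object integrated density.
#'
#' @param pthImg PTH-channel matrix
#' @param nuclearImg nuclear-channel matrix (same shape)
#' @param backgroundThreshold intensity threshold from isotype controls
#' @param labels optional object label image; when absent, objects are the
#'   connected components of the thresholded PTH channel
#' @return data.frame(pth_mfi, nuclear_mfi, normalized, median_intden,
#'   n_objects); \code{normalized} is NA when the nuclear MFI is 0
#' @export
quantifyPTHField <- function(pthImg, nuclearImg, backgroundThreshold = 0,
                             labels = NULL) {
  if (!all(dim(pthImg) == dim(nuclearImg))) stop("channel shapes differ")
  pth <- pmax(pthImg - backgroundThreshold, 0)
  pthMfi <- mean(pth)
  nucMfi <- mean(nuclearImg)
  normalized <- if (nucMfi > 0) pthMfi / nucMfi else NA_real_
  if (is.null(labels)) {
    fg <- pth > 0
    labels <- EBImage::bwlabel(fg)
    storage.mode(labels) <- "integer"
  }
  ids <- sort(unique(labels[labels > 0]))
  medianIntden <- if (length(ids)) {
    pos <- which(labels > 0L)
    lab <- factor(labels[pos], levels = ids)
    median(rowsum(as.numeric(pth[pos]), lab)[, 1])
  } else NA_real_
  data.frame(pth_mfi = pthMfi, nuclear_mfi = nucMfi,
             normalized = normalized, median_intden = medianIntden,
             n_objects = length(ids))
}

#' Fold suppression of PTH between matched fields
#'
#' reference.normalized / challenged.normalized; fold > 1 means the
#' challenge suppressed PTH. A zero challenged signal yields Inf (flagged
#' by the caller), not an exception.
#'
#' @param reference quantification of the normocalcemic field
#'   (\code{\link{quantifyPTHField}} row)
#' @param challenged quantification of the high-calcium field
#' @return numeric fold
#' @export
foldSuppression <- function(reference, challenged) {
  rn <- reference$normalized
  cn <- challenged$normalized
  if (is.na(rn) || is.na(cn)) stop("undefined normalized MFI")
  if (cn == 0) return(Inf)
  rn / cn
}

decayResiduals <- function(par, t, y) {
  y - (par[2] + (par[1] - par[2]) * exp(-par[3] * t))
}

#' Fit a one-phase exponential decay
#'
#' Least squares of P(t) = plateau + (p0 - plateau) * exp(-k t) with
#' multi-start on k; half-life = ln(2)/k. The plateau is free with lower
#' bound 0 by default, or fixed at 0 with \code{plateauFixed}. Degenerate
#' series (constant, or not decreasing overall) return converged = FALSE
#' with a diagnostic.
#'
#' @param series data.frame(time_min, pth_pg_ml), e.g. from
#'   \code{\link{simulatePTHDecay}} or \code{\link{readPTHSeries}}
#' @param plateauFixed fix the plateau at 0 (2-parameter mode)
#' @return a \linkS4class{DecayFit}
#' @examples
#' s <- simulatePTHDecay(100, 0, 4, c(0, 10, 15, 20), noiseSd = 0)
#' halfLife(fitDecay(s))    # 4
#' @export
fitDecay <- function(series, plateauFixed = FALSE) {
  stopifnot(all(c("time_min", "pth_pg_ml") %in% names(series)))
  t <- series$time_min
  y <- series$pth_pg_ml
  minPts <- if (plateauFixed) 2L else 3L
  if (length(t) < minPts)
    stop("need >= ", minPts, " points for this decay model")
  bad <- function(msg) new("DecayFit", p0 = NA_real_, plateau = NA_real_,
                           k = NA_real_, halfLifeMin = NA_real_,
                           rss = NA_real_, converged = FALSE, message = msg)
  if (diff(range(y)) < 1e-12 * max(abs(y), 1))
    return(bad("constant series: decay rate not identifiable (k -> 0)"))
  if (y[length(y)] >= y[1])
    return(bad("series does not decrease overall: no decay signal"))

  span <- max(t) - min(t)
  kStarts <- log(2) / (span * c(0.05, 0.15, 0.4, 1, 3))
  best <- NULL
  for (k0 in kStarts) {
    par0 <- c(max(y), if (plateauFixed) 0 else max(0, min(y) * 0.5), k0)
    lower <- c(0, 0, 1e-8)
    upper <- c(Inf, if (plateauFixed) 0 else Inf, Inf)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = decayResiduals, t = t, y = y,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(bad("optimiser failed from every start"))
  par <- best$fit$par
  if (par[3] < 1e-7)
    return(bad("fitted rate ~ 0: no decay identifiable"))
  new("DecayFit", p0 = par[1], plateau = par[2], k = par[3],
      halfLifeMin = log(2) / par[3], rss = best$rss,
      converged = best$fit$info %in% 1:4, message = "")
}

#' Percent decrement of a hormone series at a given time
#'
#' \code{drop} mode: 100 * (1 - P(t)/P(0)); \code{residual} mode:
#' 100 * P(t)/P(0). P(t) is linearly interpolated between bracketing
#' samples. A 50-percent drop within 10 minutes is the intraoperative
#' decision boundary this quantity is usually compared against.
#'
#' @param series data.frame(time_min, pth_pg_ml)
#' @param tEvalMin evaluation time, minutes (must be bracketed by the
#'   series)
#' @param mode "drop" or "residual"
#' @return percent
#' @examples
#' s <- data.frame(time_min = c(0, 10), pth_pg_ml = c(100, 40))
#' percentDecrement(s, 10, "drop")       # 60
#' percentDecrement(s, 10, "residual")   # 40
#' @export
percentDecrement <- function(series, tEvalMin, mode = c("drop", "residual")) {
  mode <- match.arg(mode)
  t <- series$time_min
  y <- series$pth_pg_ml
  if (tEvalMin < min(t) || tEvalMin > max(t))
    stop("tEvalMin outside the sampled range")
  p0 <- y[which.min(t)]
  if (p0 == 0) stop("P(0) is zero: decrement undefined")
  pt <- approx(t, y, xout = tEvalMin, ties = mean)$y
  if (mode == "drop") 100 * (1 - pt / p0) else 100 * pt / p0
}
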
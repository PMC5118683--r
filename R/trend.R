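#' Trend detection on cover-fraction time series
#'
#' The core of the hotspot method: per big grid cell and class, ordinary
#' least squares of the annual cover fraction on the year index, a
#' two-sided t test of the slope, and the net change over the record
#' (significant slope x interval x cell area) with its one standard
#' deviation (slope SE x interval x cell area). An endpoint-differencing
#' baseline (last year minus first year) is provided for comparison; it
#' carries no significance concept and is sensitive to anomalous start or
#' end years.
#'
#' @name trend
NULL

# Vectorised closed-form OLS on the year index t = 0..n-1.
# Y: m x n matrix of series (rows = series). Returns a list of length-m
# vectors. Rows with any non-finite value yield NA throughout.
.olsMatrix <- function(Y, n = ncol(Y)) {
  t <- seq_len(n) - 1
  tBar <- mean(t)
  Sxx <- sum((t - tBar)^2)
  ok <- rowSums(!is.finite(Y)) == 0L
  yBar <- rowMeans(Y)
  slope <- as.vector(Y %*% (t - tBar)) / Sxx
  intercept <- yBar - slope * tBar
  fitted <- outer(slope, t) + intercept
  rss <- rowSums((Y - fitted)^2)
  rss[rss < 0] <- 0
  df <- n - 2L
  sigma2 <- rss / df
  se <- sqrt(sigma2 / Sxx)
  tStat <- slope / se
  p <- 2 * stats::pt(-abs(tStat), df)
  # degenerate series: a constant input has slope exactly 0 and an
  # undefined test; any other zero-residual fit is unambiguous (p = 0)
  scale <- pmax(rowSums(Y^2), 1)
  constant <- rowSums((Y - yBar)^2) <= 1e-18 * scale
  slope[constant] <- 0
  se[constant] <- 0
  p[constant] <- NA_real_
  perfect <- !constant & rss <= 1e-18 * scale
  p[perfect] <- 0
  slope[!ok] <- intercept[!ok] <- se[!ok] <- p[!ok] <- NA_real_
  list(slope = slope, intercept = intercept, se = se, p = p)
}

#' Fit a linear trend to one fraction series
#'
#' Ordinary least squares of the values on the year index `t = 0..n-1`:
#' slope, intercept, the slope's standard error from the residual variance
#' with `n - 2` degrees of freedom, and the two-sided p-value of the t test
#' of slope = 0. A perfect noiseless fit with nonzero slope has p = 0; a
#' constant series has slope 0 and an undefined p-value (NA), reported
#' downstream as non-significant.
#'
#' @param values Numeric fraction series, one per year; all finite, >= 3.
#' @param years Strictly increasing integer years (only their count enters
#'   the design; the slope is invariant to regressing on calendar years).
#' @return A [TrendFit-class].
#' @examples
#' fit <- olsTrend(0.10 + 0.02 * (0:12), 2001:2013)
#' fit
#' @export
olsTrend <- function(values, years = seq_along(values)) {
  n <- length(values)
  if (n < 3L) stop("at least 3 points are required for a trend fit")
  if (length(years) != n) stop("values and years lengths differ")
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  f <- .olsMatrix(matrix(values, nrow = 1L), n)
  new("TrendFit", slope = f$slope, intercept = f$intercept,
      seSlope = f$se, pValue = f$p, nYears = as.integer(n))
}

#' Net change and uncertainty from a trend fit
#'
#' Net fraction = slope x interval; net area = net fraction x cell area;
#' its one standard deviation = slope SE x interval x cell area. The fit is
#' significant when its p-value is defined and below `alpha`.
#'
#' @param fit A [TrendFit-class].
#' @param interval Year multiplier (default 13, the length of a 2001-2013
#'   record).
#' @param alpha Significance level (default 0.1).
#' @param cellArea Cell area in km^2 (default 6.25, a 2.5 x 2.5 km cell).
#' @return A [NetChange-class].
#' @examples
#' fit <- olsTrend(0.10 + 0.02 * (0:12))
#' netChange(fit)
#' @export
netChange <- function(fit, interval = 13, alpha = 0.1, cellArea = 6.25) {
  if (interval <= 0 || cellArea <= 0)
    stop("interval and cellArea must be positive")
  sig <- isTRUE(!is.na(fit@pValue) && fit@pValue < alpha)
  new("NetChange",
      netFraction = fit@slope * interval,
      netArea = fit@slope * interval * cellArea,
      sdArea = fit@seSlope * interval * cellArea,
      significant = sig, alpha = alpha, interval = interval)
}

#' Per-cell, per-class trend surface
#'
#' Applies [olsTrend()] and [netChange()] to every (cell, class) fraction
#' series of a cube. Cells with fewer than 3 years of data or any missing
#' year are nodata. The `netArea` layer is the hotspot product: zero where
#' the slope is not significant, slope x interval x cell area elsewhere;
#' the raw (unmasked) fit stays available via [slopeLayer()] and
#' [rawNetArea()].
#'
#' @param cube A [FractionCube-class].
#' @param interval Year multiplier (default: the number of years).
#' @param alpha Significance level (default 0.1). No multiple-testing
#'   correction is applied across classes or cells; see `fdr`.
#' @param classes Classes to fit (default: all classes in the cube).
#' @param fdr Apply a Benjamini-Hochberg correction across all (cell,
#'   class) p-values before thresholding (default FALSE).
#' @return A [TrendRaster-class].
#' @export
trendSurface <- function(cube, interval = length(cube@years), alpha = 0.1,
                         classes = cube@classes, fdr = FALSE) {
  miss <- setdiff(classes, cube@classes)
  if (length(miss))
    stop("classes not present in cube: ", paste(miss, collapse = ", "))
  ci <- match(classes, cube@classes)
  d <- dim(cube@fractions)
  cr <- d[1L]; cc <- d[2L]; ny <- d[3L]
  nCls <- length(classes)
  Y <- matrix(aperm(cube@fractions[, , , ci, drop = FALSE], c(1L, 2L, 4L, 3L)),
              nrow = cr * cc * nCls, ncol = ny)
  f <- .olsMatrix(Y, ny)
  shape <- c(cr, cc, nCls)
  dn <- list(NULL, NULL, classes)
  slope <- array(f$slope, shape, dimnames = dn)
  se <- array(f$se, shape, dimnames = dn)
  p <- array(f$p, shape, dimnames = dn)
  pThresh <- p
  if (fdr) pThresh[] <- stats::p.adjust(as.vector(p), method = "BH")
  significant <- !is.na(pThresh) & pThresh < alpha
  significant[is.na(slope)] <- NA
  netArea <- ifelse(significant %in% TRUE, slope * interval * cube@cellArea, 0)
  netArea[is.na(slope)] <- NA_real_
  dim(netArea) <- shape; dimnames(netArea) <- dn
  sdArea <- se * interval * cube@cellArea
  new("TrendRaster", slope = slope, pValue = p, netArea = netArea,
      sdArea = sdArea, significant = significant, classes = as.character(classes),
      provenance = list(blockSize = cube@blockSize, interval = interval,
                        alpha = alpha, years = cube@years,
                        cellArea = cube@cellArea, fdr = fdr),
      transform = cube@transform)
}

#' Endpoint-differencing baseline
#'
#' Net fraction change estimated as last-year minus first-year cover, per
#' cell and class. This is the naive alternative the trend regression
#' improves on: it offers no significance test and inherits any anomaly in
#' the first or last map in full.
#'
#' @param cube A [FractionCube-class].
#' @return Numeric array `cellRows x cellCols x classes` of net fractions.
#' @export
endpointChange <- function(cube) {
  ny <- length(cube@years)
  if (ny < 2L) stop("endpoint differencing needs at least two years")
  cube@fractions[, , ny, , drop = TRUE] - cube@fractions[, , 1L, , drop = TRUE]
}

#' Minimum detectable change area
#'
#' The change-detection floor of a map stack: the footprint of a single
#' pixel, in hectares, truncated to one decimal. For the 231.656 m edge of
#' a "250 m" sinusoidal-grid pixel this is 5.3 ha.
#'
#' @param pixelEdge Pixel edge length in metres (default 231.656).
#' @return Hectares, truncated to one decimal place.
#' @examples
#' detectionFloor()
#' @export
detectionFloor <- function(pixelEdge = 231.656) {
  floor(pixelEdge^2 / 1e4 * 10) / 10
}
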
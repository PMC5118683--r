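#' Years covered by an object
#'
#' @param x A [LandCoverSeries-class] or [FractionCube-class].
#' @return Integer vector of years.
#' @rdname seriesYears
#' @export
setMethod("seriesYears", "LandCoverSeries", function(x) x@years)

#' @rdname seriesYears
#' @export
setMethod("seriesYears", "FractionCube", function(x) x@years)

#' Legend attached to an object
#' @param x A [LandCoverSeries-class] or [ClassifierOutput-class].
#' @rdname legendOf
#' @export
setMethod("legendOf", "LandCoverSeries", function(x) x@legend)

#' Legend codes / class names
#' @param x A [ClassLegend-class].
#' @rdname legendCodes
#' @export
setMethod("legendCodes", "ClassLegend", function(x) {
  structure(x@codes, names = x@classNames)
})

#' @rdname legendClasses
#' @param x A [ClassLegend-class].
#' @export
setMethod("legendClasses", "ClassLegend", function(x) x@classNames)

#' Names of the classes analysed for hotspots
#' @param x A [ClassLegend-class].
#' @rdname analysisClasses
#' @export
setMethod("analysisClasses", "ClassLegend", function(x) x@analysisSet)

#' Label array of a series
#' @param x A [LandCoverSeries-class].
#' @return Integer `rows x cols x years` array.
#' @rdname seriesLabels
#' @export
setMethod("seriesLabels", "LandCoverSeries", function(x) x@labels)

#' Fraction array of a cube
#' @param x A [FractionCube-class].
#' @rdname fractionsOf
#' @export
setMethod("fractionsOf", "FractionCube", function(x) x@fractions)

#' Valid-pixel counts of a cube
#' @param x A [FractionCube-class].
#' @rdname validCounts
#' @export
setMethod("validCounts", "FractionCube", function(x) x@validCount)

.trendLayer <- function(x, slot, class) {
  arr <- slot(x, slot)
  if (missing(class) || is.null(class)) return(arr)
  i <- match(class, x@classes)
  if (is.na(i)) stop("class '", class, "' not present in trend raster")
  arr[, , i, drop = TRUE]
}

#' Trend-layer accessors
#'
#' Extract one class's cell grid (or the full array when `class` is
#' missing) from a [TrendRaster-class]. `netAreaLayer` is the
#' significance-masked hotspot layer (0 where not significant);
#' `rawNetArea` is the unmasked slope x interval x cell-area surface.
#'
#' @param x A [TrendRaster-class].
#' @param class Optional class name.
#' @rdname slopeLayer
#' @export
setMethod("slopeLayer", "TrendRaster", function(x, class) .trendLayer(x, "slope", class))

#' @rdname pValueLayer
#' @inheritParams slopeLayer
#' @export
setMethod("pValueLayer", "TrendRaster", function(x, class) .trendLayer(x, "pValue", class))

#' @rdname netAreaLayer
#' @inheritParams slopeLayer
#' @export
setMethod("netAreaLayer", "TrendRaster", function(x, class) .trendLayer(x, "netArea", class))

#' @rdname sdAreaLayer
#' @inheritParams slopeLayer
#' @export
setMethod("sdAreaLayer", "TrendRaster", function(x, class) .trendLayer(x, "sdArea", class))

#' @rdname significanceLayer
#' @inheritParams slopeLayer
#' @export
setMethod("significanceLayer", "TrendRaster", function(x, class) .trendLayer(x, "significant", class))

#' @rdname rawNetArea
#' @inheritParams slopeLayer
#' @export
setMethod("rawNetArea", "TrendRaster", function(x, class) {
  raw <- x@slope * x@provenance$interval * x@provenance$cellArea
  if (missing(class) || is.null(class)) return(raw)
  i <- match(class, x@classes)
  if (is.na(i)) stop("class '", class, "' not present in trend raster")
  raw[, , i, drop = TRUE]
})

#' Designed per-cell slopes of a synthetic scenario
#' @param x A [GroundTruth-class].
#' @rdname designedSlopes
#' @export
setMethod("designedSlopes", "GroundTruth", function(x) x@designedSlope)

#' Designed per-cell net fractions (slope x interval)
#' @param x A [GroundTruth-class].
#' @rdname designedNetFraction
#' @export
setMethod("designedNetFraction", "GroundTruth", function(x) {
  x@designedSlope * x@interval
})

setMethod("show", "ClassLegend", function(object) {
  cat("ClassLegend with", length(object@codes), "classes\n")
  cat("  codes:", paste0(object@classNames, "=", object@codes, collapse = " "), "\n")
  cat("  analysis set:", paste(object@analysisSet, collapse = ", "), "\n")
  cat("  forest merge:", paste(object@forestCodes, collapse = ", "),
      "->", object@forestTarget, "\n")
})

setMethod("show", "LandCoverSeries", function(object) {
  d <- dim(object@labels)
  cat("LandCoverSeries:", d[1L], "x", d[2L], "pixels,",
      length(object@years), "years (", object@years[1L], "-",
      object@years[length(object@years)], ")\n")
  cat("  pixel size:", object@transform[["cellsize"]], "m; nodata code:",
      object@nodata, "\n")
})

setMethod("show", "FractionCube", function(object) {
  d <- dim(object@fractions)
  cat("FractionCube:", d[1L], "x", d[2L], "cells x", d[3L], "years x",
      d[4L], "classes (block size", object@blockSize, ", cell area",
      object@cellArea, "km^2)\n")
  if (any(object@dropped > 0L))
    cat("  dropped trailing pixels:", object@dropped[1L], "rows,",
        object@dropped[2L], "cols\n")
})

setMethod("show", "TrendRaster", function(object) {
  d <- dim(object@slope)
  nsig <- sum(object@significant, na.rm = TRUE)
  cat("TrendRaster:", d[1L], "x", d[2L], "cells,", d[3L], "classes;",
      nsig, "significant (cell, class) entries at alpha =",
      object@provenance$alpha, "\n")
  cat("  interval:", object@provenance$interval, "years; cell area:",
      object@provenance$cellArea, "km^2\n")
})

setMethod("show", "TrendFit", function(object) {
  cat(sprintf("TrendFit: slope %.6g / yr (se %.3g), p = %s, n = %d\n",
              object@slope, object@seSlope,
              ifelse(is.na(object@pValue), "NA", format(object@pValue, digits = 4)),
              object@nYears))
})

setMethod("show", "NetChange", function(object) {
  cat(sprintf("NetChange: %+.4f fraction (%+.4f km^2 +/- %.4f), %s at alpha = %g\n",
              object@netFraction, object@netArea, object@sdArea,
              if (isTRUE(object@significant)) "significant" else "not significant",
              object@alpha))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig:", object@gridShape[1L], "x", object@gridShape[2L],
      "pixels,", length(object@years), "years,", nrow(object@transitions),
      "transitions,", length(object@regions), "regions\n")
  cat("  noise rate:", object@noiseRate,
      if (length(object@anomalyYears))
        paste0("(anomaly years ", paste(object@anomalyYears, collapse = ","),
               " at ", object@anomalyNoiseRate, ")") else "", "\n")
})

setMethod("show", "GroundTruth", function(object) {
  d <- dim(object@designedSlope)
  cat("GroundTruth:", d[1L], "x", d[2L], "cells,", d[3L],
      "classes; interval", object@interval, "years\n")
})

setMethod("show", "FusionResult", function(object) {
  n <- length(object@labels)
  cat("FusionResult:", nrow(object@labels), "x", ncol(object@labels),
      "pixels;", round(100 * mean(object@method == 1L), 2),
      "% consensus,", object@ties, "ties\n")
})
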
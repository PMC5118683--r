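#' @import methods
NULL

#' Class legend for categorical land-cover maps
#'
#' Maps integer raster codes to class names, marks the subset of classes
#' analysed for change hotspots, and records which codes collapse into the
#' merged forest super-class (FORE).
#'
#' @slot codes Integer raster codes, unique.
#' @slot classNames Character class names parallel to `codes`.
#' @slot analysisSet Character, names of the classes whose trends are analysed.
#' @slot forestCodes Character, names of the forest types merged into FORE.
#' @slot forestTarget Character scalar, name of the merge target (FORE).
#' @export
setClass("ClassLegend",
  representation(
    codes = "integer",
    classNames = "character",
    analysisSet = "character",
    forestCodes = "character",
    forestTarget = "character"
  )
)

setValidity("ClassLegend", function(object) {
  msg <- character()
  if (length(object@codes) != length(object@classNames))
    msg <- c(msg, "codes and classNames must have equal length")
  if (anyDuplicated(object@codes))
    msg <- c(msg, "class codes must be unique")
  if (anyDuplicated(object@classNames))
    msg <- c(msg, "class names must be unique")
  if (!all(object@analysisSet %in% object@classNames))
    msg <- c(msg, "analysisSet must be a subset of classNames")
  if (length(object@forestTarget) != 1L ||
      !object@forestTarget %in% object@classNames)
    msg <- c(msg, "forestTarget must name exactly one legend class")
  if (!all(object@forestCodes %in% object@classNames))
    msg <- c(msg, "forestCodes must be legend classes")
  if (length(msg)) msg else TRUE
})

#' Co-registered annual land-cover label stack
#'
#' One integer label grid per year, sharing shape, legend and georeference.
#' The georeference is a north-up affine: lower-left corner plus square
#' pixel size, in the convention of plain-text raster grids.
#'
#' @slot years Strictly increasing integer years.
#' @slot labels Integer array `rows x cols x years` of legend codes.
#' @slot legend A [ClassLegend-class].
#' @slot nodata Integer code marking invalid pixels.
#' @slot transform Named numeric `c(xll, yll, cellsize)`.
#' @slot crs Character CRS identifier (may be empty for synthetic data).
#' @export
setClass("LandCoverSeries",
  representation(
    years = "integer",
    labels = "array",
    legend = "ClassLegend",
    nodata = "integer",
    transform = "numeric",
    crs = "character"
  )
)

setValidity("LandCoverSeries", function(object) {
  msg <- character()
  d <- dim(object@labels)
  if (length(d) != 3L)
    msg <- c(msg, "labels must be a rows x cols x years array")
  else if (d[3L] != length(object@years))
    msg <- c(msg, "third dimension of labels must match length(years)")
  if (length(object@years) && any(diff(object@years) <= 0L))
    msg <- c(msg, "years must be strictly increasing")
  codes <- unique(as.vector(object@labels))
  codes <- codes[!is.na(codes) & codes != object@nodata]
  unknown <- setdiff(codes, object@legend@codes)
  if (length(unknown))
    msg <- c(msg, paste0("labels contain codes absent from the legend: {",
                         paste(sort(unknown), collapse = ", "), "}"))
  if (!all(c("xll", "yll", "cellsize") %in% names(object@transform)))
    msg <- c(msg, "transform must carry xll, yll and cellsize")
  if (length(msg)) msg else TRUE
})

#' Synthetic landscape scenario configuration
#'
#' Fully parameterises a synthetic annual land-cover experiment: initial
#' mosaic, named regions, linear class-conversion transitions, per-pixel
#' classification noise and anomaly years, plus the seed. The designed
#' trends implied by `transitions` are recoverable analytically, which is
#' what makes the scenario usable as a validation oracle.
#'
#' @slot gridShape Integer `c(rows, cols)` in pixels.
#' @slot pixelSize Pixel edge length in metres.
#' @slot years Strictly increasing integer years.
#' @slot legend A [ClassLegend-class].
#' @slot initial Integer matrix of legend codes, the year-one mosaic.
#' @slot regions Named list of logical masks, each `rows x cols`.
#' @slot transitions data.frame with columns region, from, to, annualRate
#'   (fraction of region area converted per year) and spatialMode
#'   ("clustered" or "random").
#' @slot noiseRate Per-pixel per-year misclassification probability.
#' @slot confusion Row-stochastic class-confusion matrix used when a pixel
#'   is misclassified (dimnames = class names).
#' @slot anomalyYears Integer years with elevated noise.
#' @slot anomalyNoiseRate Noise rate used in anomaly years.
#' @slot seed Integer RNG seed.
#' @export
setClass("ScenarioConfig",
  representation(
    gridShape = "integer",
    pixelSize = "numeric",
    years = "integer",
    legend = "ClassLegend",
    initial = "matrix",
    regions = "list",
    transitions = "data.frame",
    noiseRate = "numeric",
    confusion = "matrix",
    anomalyYears = "integer",
    anomalyNoiseRate = "numeric",
    seed = "integer"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  gs <- object@gridShape
  if (length(gs) != 2L || any(gs <= 0L))
    msg <- c(msg, "gridShape must be two positive integers")
  if (!identical(dim(object@initial), as.integer(gs)))
    msg <- c(msg, "initial mosaic must match gridShape")
  if (any(diff(object@years) <= 0L))
    msg <- c(msg, "years must be strictly increasing")
  for (nm in names(object@regions)) {
    m <- object@regions[[nm]]
    if (!is.logical(m) || !identical(dim(m), as.integer(gs)))
      msg <- c(msg, sprintf("region '%s' mask must be a logical %d x %d matrix",
                            nm, gs[1L], gs[2L]))
  }
  tr <- object@transitions
  need <- c("region", "from", "to", "annualRate", "spatialMode")
  if (nrow(tr) && !all(need %in% names(tr))) {
    msg <- c(msg, paste("transitions must have columns",
                        paste(need, collapse = ", ")))
  } else if (nrow(tr)) {
    if (any(tr$annualRate < 0))
      msg <- c(msg, "annualRate must be >= 0")
    if (!all(tr$spatialMode %in% c("clustered", "random")))
      msg <- c(msg, "spatialMode must be 'clustered' or 'random'")
    if (!all(tr$region %in% names(object@regions)))
      msg <- c(msg, "transition regions must be named region masks")
    cls <- object@legend@classNames
    if (!all(c(tr$from, tr$to) %in% cls))
      msg <- c(msg, "transition classes must be legend classes")
    # total outflow demand per (region, from) must fit the initial stock
    nSteps <- length(object@years) - 1L
    for (key in unique(paste(tr$region, tr$from))) {
      sub <- tr[paste(tr$region, tr$from) == key, , drop = FALSE]
      reg <- object@regions[[sub$region[1L]]]
      fromCode <- object@legend@codes[match(sub$from[1L], cls)]
      stock <- sum(object@initial[reg] == fromCode) / max(1L, sum(reg))
      if (sum(sub$annualRate) * nSteps > stock + 1e-9)
        msg <- c(msg, sprintf(
          "transitions out of %s in region '%s' demand %.4f of region area but only %.4f is available",
          sub$from[1L], sub$region[1L], sum(sub$annualRate) * nSteps, stock))
    }
  }
  if (object@noiseRate < 0 || object@noiseRate > 1)
    msg <- c(msg, "noiseRate must lie in [0, 1]")
  if (object@anomalyNoiseRate < 0 || object@anomalyNoiseRate > 1)
    msg <- c(msg, "anomalyNoiseRate must lie in [0, 1]")
  cm <- object@confusion
  if (!is.null(dim(cm)) && nrow(cm)) {
    if (any(abs(rowSums(cm) - 1) > 1e-9))
      msg <- c(msg, "confusion rows must sum to 1")
    if (any(cm < 0))
      msg <- c(msg, "confusion entries must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Analytic ground truth of a synthetic scenario
#'
#' Designed per-cell, per-class fraction slopes (derived from the scenario
#' configuration, not from any realization) together with region-level
#' designed net areas. Per-cell slopes are exact in expectation for
#' transitions in "random" mode; in "clustered" mode conversions concentrate
#' spatially and only the region totals are designed exactly.
#'
#' @slot designedSlope Numeric array `cellRows x cellCols x classes`
#'   (fraction of cell area per year), classes at the merged (FORE) level.
#' @slot regionNet data.frame with columns region, class, net_km2.
#' @slot blockSize Pixels per big-grid-cell edge.
#' @slot interval Year multiplier used for designed net change.
#' @export
setClass("GroundTruth",
  representation(
    designedSlope = "array",
    regionNet = "data.frame",
    blockSize = "integer",
    interval = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  s <- apply(object@designedSlope, c(1L, 2L), sum)
  if (any(abs(s) > 1e-9))
    "designed slopes must sum to 0 over classes in every cell"
  else TRUE
})

#' Per-cell class-fraction time series cube
#'
#' Big-grid-cell aggregation of a label series: per cell, year and class,
#' the fraction of valid pixels carrying that class, plus the valid-pixel
#' count. Cells with partial validity keep a reduced denominator.
#'
#' @slot fractions Numeric array `cellRows x cellCols x years x classes`.
#' @slot validCount Integer array `cellRows x cellCols x years`.
#' @slot blockSize Pixels per cell edge.
#' @slot cellArea Area of a fully valid cell, km^2.
#' @slot years Integer years.
#' @slot classes Character class names (4th dimension).
#' @slot transform Named numeric georeference at cell resolution.
#' @slot dropped Integer `c(rows, cols)` of trailing pixels not covered by
#'   a complete block and therefore excluded.
#' @export
setClass("FractionCube",
  representation(
    fractions = "array",
    validCount = "array",
    blockSize = "integer",
    cellArea = "numeric",
    years = "integer",
    classes = "character",
    transform = "numeric",
    dropped = "integer"
  )
)

setValidity("FractionCube", function(object) {
  d <- dim(object@fractions)
  msg <- character()
  if (length(d) != 4L)
    msg <- c(msg, "fractions must be a 4-d array")
  else {
    if (d[3L] != length(object@years))
      msg <- c(msg, "year dimension mismatch")
    if (d[4L] != length(object@classes))
      msg <- c(msg, "class dimension mismatch")
    if (!identical(dim(object@validCount), d[1:3]))
      msg <- c(msg, "validCount must match the first three dimensions")
  }
  if (length(msg)) msg else TRUE
})

#' Single least-squares trend fit
#'
#' Ordinary least squares of a cover-fraction series on the year index
#' 0..n-1: slope, intercept, slope standard error (n-2 df) and the
#' two-sided p-value of slope = 0. A constant series has slope 0 and an
#' undefined (NA) p-value and is treated as non-significant.
#'
#' @slot slope Fraction per year.
#' @slot intercept Fraction at year index 0.
#' @slot seSlope Standard error of the slope.
#' @slot pValue Two-sided p-value (NA when undefined).
#' @slot nYears Number of points fitted.
#' @export
setClass("TrendFit",
  representation(
    slope = "numeric", intercept = "numeric",
    seSlope = "numeric", pValue = "numeric", nYears = "integer"
  )
)

#' Net change of one class in one cell
#'
#' @slot netFraction slope x interval.
#' @slot netArea netFraction x cell area, km^2.
#' @slot sdArea one standard deviation of the net change
#'   (slope SE x interval x cell area), km^2.
#' @slot significant TRUE when the slope p-value is defined and below alpha.
#' @slot alpha Significance level.
#' @slot interval Year multiplier.
#' @export
setClass("NetChange",
  representation(
    netFraction = "numeric", netArea = "numeric", sdArea = "numeric",
    significant = "logical", alpha = "numeric", interval = "numeric"
  )
)

#' Big-grid trend layers for a set of classes
#'
#' Per analysis class, cell grids of slope, p-value, significance-masked
#' net area, net-change standard deviation and the significance flag, plus
#' the provenance needed to interpret them (block size, interval, alpha,
#' years, cell area).
#'
#' @slot slope,pValue,netArea,sdArea Numeric arrays
#'   `cellRows x cellCols x classes`; netArea is 0 where non-significant
#'   (the raw fit stays available through `slope`).
#' @slot significant Logical array of the same shape.
#' @slot classes Character class names.
#' @slot provenance List: blockSize, interval, alpha, years, cellArea.
#' @slot transform Named numeric georeference at cell resolution.
#' @export
setClass("TrendRaster",
  representation(
    slope = "array", pValue = "array", netArea = "array",
    sdArea = "array", significant = "array",
    classes = "character", provenance = "list", transform = "numeric"
  )
)

setValidity("TrendRaster", function(object) {
  d <- dim(object@slope)
  ok <- identical(dim(object@pValue), d) &&
    identical(dim(object@netArea), d) &&
    identical(dim(object@sdArea), d) &&
    identical(dim(object@significant), d) &&
    length(object@classes) == d[3L]
  if (ok) TRUE else "all trend layers must share cellRows x cellCols x classes shape"
})

#' One classifier's map and class-membership probabilities
#'
#' @slot labels Integer matrix of legend codes, the per-pixel argmax of
#'   `probabilities`.
#' @slot probabilities Numeric array `rows x cols x classes`, rows of the
#'   per-pixel probability simplex.
#' @slot classes Integer legend codes for the 3rd dimension.
#' @slot modelId Character identifier.
#' @slot accuracy Optional overall-accuracy weight (NA when unknown).
#' @export
setClass("ClassifierOutput",
  representation(
    labels = "matrix", probabilities = "array",
    classes = "integer", modelId = "character", accuracy = "numeric"
  )
)

setValidity("ClassifierOutput", function(object) {
  d <- dim(object@probabilities)
  msg <- character()
  if (length(d) != 3L || !identical(dim(object@labels), d[1:2]))
    msg <- c(msg, "probabilities must be rows x cols x classes matching labels")
  else {
    if (d[3L] != length(object@classes))
      msg <- c(msg, "class dimension mismatch")
    s <- rowSums(matrix(object@probabilities, ncol = d[3L]))
    if (any(abs(s - 1) > 1e-6))
      msg <- c(msg, "per-pixel probabilities must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Result of fusing several classifier outputs
#'
#' @slot labels Integer matrix of fused legend codes.
#' @slot probabilities Fused per-class probability array.
#' @slot method Integer matrix: 1 = unanimous consensus, 2 = averaged.
#' @slot classes Integer legend codes.
#' @slot ties Number of pixels whose fused probabilities tied exactly.
#' @slot weights Normalised model weights actually used.
#' @export
setClass("FusionResult",
  representation(
    labels = "matrix", probabilities = "array", method = "matrix",
    classes = "integer", ties = "integer", weights = "numeric"
  )
)
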
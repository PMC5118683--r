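#' Merge all forest types into the forest super-class
#'
#' Relabels every forest-type pixel (by default DBLE, DNLE, EBLE, ENLE and
#' MIXED) to the merged forest class FORE; all other codes pass through
#' unchanged. Run before [blockFractions()] so that forest dynamics are
#' analysed as a single class.
#'
#' @param series A [LandCoverSeries-class].
#' @param legend Legend defining the merge (defaults to the series legend).
#' @return A [LandCoverSeries-class] with forest types collapsed.
#' @examples
#' cfg <- demoScenario(seed = 1)
#' sim <- generateSeries(cfg)
#' merged <- mergeClasses(sim$series)
#' @export
mergeClasses <- function(series, legend = legendOf(series)) {
  if (!legend@forestTarget %in% legend@classNames)
    stop("merge target '", legend@forestTarget, "' missing from legend")
  fromCodes <- codeFor(legend, legend@forestCodes)
  toCode <- codeFor(legend, legend@forestTarget)
  labels <- series@labels
  labels[labels %in% fromCodes] <- toCode
  landCoverSeries(labels, series@years, legend = legend,
                  nodata = series@nodata, transform = series@transform,
                  crs = series@crs)
}

#' Aggregate a label series into per-cell class fractions
#'
#' Partitions the pixel grid into `blockSize x blockSize` big grid cells
#' (default 10 x 10, i.e. 2.5 x 2.5 km at 250 m pixels) and computes, per
#' cell, year and class, the fraction of valid (non-nodata) pixels carrying
#' that class. Cells with some nodata pixels keep the reduced denominator;
#' trailing rows/columns that do not fill a complete block are dropped and
#' reported in the cube's `dropped` slot. Fractions over the full legend
#' sum to 1 in fully valid cells, so the per-cell fractions of any subset
#' of classes (e.g. the eight analysis classes) may sum to less than 1.
#'
#' @param series A [LandCoverSeries-class] (typically after
#'   [mergeClasses()]).
#' @param blockSize Pixels per cell edge (> 0).
#' @param classes Character class names to tabulate; default the full
#'   legend.
#' @param minValid Minimum valid-pixel count for a cell-year to keep a
#'   defined fraction (smaller counts become NA); default 1.
#' @return A [FractionCube-class].
#' @export
blockFractions <- function(series, blockSize = 10L,
                           classes = legendClasses(legendOf(series)),
                           minValid = 1L) {
  if (blockSize <= 0L) stop("blockSize must be positive")
  if (!length(classes)) stop("classes must not be empty")
  legend <- series@legend
  codes <- codeFor(legend, classes)
  B <- as.integer(blockSize)
  d <- dim(series@labels)
  cr <- d[1L] %/% B; cc <- d[2L] %/% B
  if (cr == 0L || cc == 0L)
    stop("grid smaller than one ", B, " x ", B, " block")
  ny <- length(series@years)
  fractions <- array(NA_real_, c(cr, cc, ny, length(classes)),
                     dimnames = list(NULL, NULL, series@years, classes))
  validCount <- array(0L, c(cr, cc, ny))
  for (y in seq_len(ny)) {
    lay <- series@labels[, , y]
    valid <- .blockSum((lay != series@nodata) * 1L, B)
    validCount[, , y] <- as.integer(valid)
    denom <- ifelse(valid >= minValid & valid > 0L, valid, NA_real_)
    for (ci in seq_along(codes)) {
      cnt <- .blockSum((lay == codes[ci] & lay != series@nodata) * 1L, B)
      fractions[, , y, ci] <- cnt / denom
    }
  }
  cellsize <- series@transform[["cellsize"]] * B
  # blocks anchor at the top-left (row-major, half-open intervals), so any
  # dropped trailing rows lift the lower-left corner of the cell grid
  yll <- series@transform[["yll"]] +
    (d[1L] - cr * B) * series@transform[["cellsize"]]
  new("FractionCube", fractions = fractions, validCount = validCount,
      blockSize = B,
      cellArea = (cellsize / 1000)^2,
      years = series@years, classes = as.character(classes),
      transform = c(xll = series@transform[["xll"]],
                    yll = yll, cellsize = cellsize),
      dropped = as.integer(c(d[1L] - cr * B, d[2L] - cc * B)))
}
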
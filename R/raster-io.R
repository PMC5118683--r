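#' Plain-text raster input/output
#'
#' All on-disk rasters use the ESRI ASCII grid format (.asc): a six-line
#' header (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value)
#' followed by one line of values per row, top row first. The format is
#' plain text, carries the north-up georeference the pipeline needs, and is
#' read natively by GDAL, QGIS and ArcGIS. Values are written with 17
#' significant digits so numeric layers round-trip bit-exactly. CRS,
#' legend and provenance travel in JSON sidecar files.
#'
#' @name raster_io
NULL

#' Write a matrix as an ESRI ASCII grid
#'
#' @param m Numeric or integer matrix; row 1 is the northernmost row.
#' @param path Output path (conventionally `.asc`).
#' @param transform Named numeric `c(xll, yll, cellsize)`.
#' @param nodata Value written for NA entries.
#' @export
writeAsciiGrid <- function(m, path,
                           transform = c(xll = 0, yll = 0, cellsize = 250),
                           nodata = -9999) {
  isInt <- is.integer(m)
  fmt <- function(v) {
    v[is.na(v)] <- nodata
    if (isInt) sprintf("%d", as.integer(v)) else sprintf("%.17g", v)
  }
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.17g", transform[["xll"]]),
    sprintf("yllcorner %.17g", transform[["yll"]]),
    sprintf("cellsize %.17g", transform[["cellsize"]]),
    sprintf("NODATA_value %.17g", as.numeric(nodata)))
  body <- apply(m, 1L, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @param integer Coerce values to integer.
#' @return List with `values` (matrix, NA where nodata), `transform` and
#'   `nodata`.
#' @export
readAsciiGrid <- function(path, integer = FALSE) {
  if (!file.exists(path)) stop("cannot read raster file: ", path)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  nodata <- vals[["nodata_value"]]
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc)
    stop("raster body of ", path, " has ", length(body),
         " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  if (integer) storage.mode(m) <- "integer"
  list(values = m,
       transform = c(xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
                     cellsize = vals[["cellsize"]]),
       nodata = nodata)
}

#' Write / read a class legend as JSON
#'
#' @param legend A [ClassLegend-class].
#' @param path JSON file path.
#' @rdname legendIO
#' @export
writeLegend <- function(legend, path) {
  jsonlite::write_json(list(
    entries = data.frame(code = legend@codes, name = legend@classNames),
    analysis_set = legend@analysisSet,
    forest_merge = legend@forestCodes,
    forest_target = legend@forestTarget
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname legendIO
#' @export
readLegend <- function(path) {
  if (!file.exists(path)) stop("cannot read legend file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  classLegend(codes = x$entries$code, classNames = x$entries$name,
              analysisSet = x$analysis_set, forestCodes = x$forest_merge,
              forestTarget = x$forest_target)
}

#' Write a land-cover series to a directory
#'
#' One `lc_<year>.asc` label grid per year, `legend.json`, and a
#' `series.json` sidecar with years, nodata code and CRS.
#'
#' @param series A [LandCoverSeries-class].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
writeSeries <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(series@years))
    writeAsciiGrid(series@labels[, , i],
                   file.path(dir, sprintf("lc_%d.asc", series@years[i])),
                   transform = series@transform, nodata = series@nodata)
  writeLegend(series@legend, file.path(dir, "legend.json"))
  jsonlite::write_json(list(years = series@years, nodata = series@nodata,
                            crs = series@crs),
                       file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a land-cover series
#'
#' Accepts either a directory written by [writeSeries()] or an explicit
#' vector of per-year raster paths plus a legend file. All grids must share
#' shape and georeference; labels absent from the legend are an error.
#'
#' @param paths Directory or character vector of `.asc` paths (year order).
#' @param legendPath Legend JSON (defaults to `legend.json` next to the
#'   rasters).
#' @param years Integer years; parsed from `series.json` or file names when
#'   omitted.
#' @return A validated [LandCoverSeries-class].
#' @export
readSeries <- function(paths, legendPath = NULL, years = NULL) {
  nodata <- -1L
  crs <- ""
  if (length(paths) == 1L && dir.exists(paths)) {
    dir <- paths
    meta <- file.path(dir, "series.json")
    if (file.exists(meta)) {
      info <- jsonlite::read_json(meta, simplifyVector = TRUE)
      if (is.null(years)) years <- info$years
      nodata <- as.integer(info$nodata)
      crs <- if (is.null(info$crs)) "" else info$crs
    }
    paths <- file.path(dir, sprintf("lc_%d.asc", years))
    if (is.null(legendPath)) legendPath <- file.path(dir, "legend.json")
  }
  if (is.null(legendPath))
    stop("legendPath is required when reading from explicit raster paths")
  legend <- readLegend(legendPath)
  if (is.null(years))
    years <- as.integer(gsub("\\D", "", basename(paths)))
  grids <- lapply(paths, readAsciiGrid, integer = TRUE)
  ref <- grids[[1L]]
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    if (!identical(dim(g$values), dim(ref$values)))
      stop("raster ", paths[i], " has dimensions ",
           paste(dim(g$values), collapse = "x"), ", expected ",
           paste(dim(ref$values), collapse = "x"))
    if (any(abs(g$transform - ref$transform) > 1e-9))
      stop("raster ", paths[i], " is not co-registered with ", paths[1L])
  }
  labels <- array(NA_integer_,
                  dim = c(dim(ref$values), length(grids)))
  for (i in seq_along(grids)) {
    v <- grids[[i]]$values
    v[is.na(v)] <- nodata
    labels[, , i] <- v
  }
  found <- setdiff(unique(as.vector(labels)), c(legend@codes, nodata))
  if (length(found))
    stop("labels contain codes absent from the legend: {",
         paste(sort(found), collapse = ", "), "}")
  landCoverSeries(labels, years, legend = legend, nodata = nodata,
                  transform = ref$transform, crs = crs)
}

#' Write big-grid trend layers
#'
#' Per analysis class, five ASCII grids at big-grid resolution
#' (`<class>_slope.asc`, `_p_value.asc`, `_net_area.asc`, `_sd_area.asc`,
#' `_significant.asc`; the significance layer is 0/1) plus a `trend.json`
#' sidecar recording interval, alpha, block size, cell area, years and
#' classes. Cells without a defined fit carry the nodata value in every
#' band.
#'
#' @param trend A [TrendRaster-class].
#' @param outDir Output directory (created if absent).
#' @return `outDir`, invisibly.
#' @export
writeTrendRaster <- function(trend, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  bands <- c(slope = "slope", p_value = "pValue", net_area = "netArea",
             sd_area = "sdArea", significant = "significant")
  for (ci in seq_along(trend@classes)) {
    cls <- trend@classes[ci]
    for (b in names(bands)) {
      m <- slot(trend, bands[[b]])[, , ci]
      if (b == "significant") m <- ifelse(is.na(m), NA_real_, as.numeric(m))
      writeAsciiGrid(m, file.path(outDir, sprintf("%s_%s.asc", cls, b)),
                     transform = trend@transform)
    }
  }
  jsonlite::write_json(
    c(trend@provenance, list(classes = trend@classes)),
    file.path(outDir, "trend.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outDir)
}

#' Read big-grid trend layers written by [writeTrendRaster()]
#'
#' @param dir Directory containing the `.asc` layers and `trend.json`.
#' @return A [TrendRaster-class].
#' @export
readTrendRaster <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "trend.json"),
                              simplifyVector = TRUE)
  classes <- meta$classes
  meta$classes <- NULL
  first <- readAsciiGrid(file.path(dir, sprintf("%s_slope.asc", classes[1L])))
  d <- c(dim(first$values), length(classes))
  mk <- function() array(NA_real_, d)
  slope <- mk(); pValue <- mk(); netArea <- mk(); sdArea <- mk()
  signif <- array(NA, d)
  for (ci in seq_along(classes)) {
    rd <- function(b) readAsciiGrid(
      file.path(dir, sprintf("%s_%s.asc", classes[ci], b)))$values
    slope[, , ci] <- rd("slope")
    pValue[, , ci] <- rd("p_value")
    netArea[, , ci] <- rd("net_area")
    sdArea[, , ci] <- rd("sd_area")
    signif[, , ci] <- rd("significant") > 0
  }
  dimnames(slope) <- dimnames(pValue) <- dimnames(netArea) <-
    dimnames(sdArea) <- dimnames(signif) <- list(NULL, NULL, classes)
  new("TrendRaster", slope = slope, pValue = pValue, netArea = netArea,
      sdArea = sdArea, significant = signif, classes = classes,
      provenance = lapply(meta, function(x) if (is.list(x)) unlist(x) else x),
      transform = first$transform)
}

#' Write / read a fraction cube as CSV
#'
#' Long format with header
#' `cell_row,cell_col,year,class,fraction,valid_count`.
#'
#' @param cube A [FractionCube-class].
#' @param path CSV path.
#' @rdname fractionCubeIO
#' @export
writeFractionCube <- function(cube, path) {
  d <- dim(cube@fractions)
  grid <- expand.grid(cell_row = seq_len(d[1L]), cell_col = seq_len(d[2L]),
                      year = cube@years, class = cube@classes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$fraction <- as.vector(cube@fractions)
  grid$valid_count <- as.vector(cube@validCount)[
    (match(grid$year, cube@years) - 1L) * d[1L] * d[2L] +
      (grid$cell_col - 1L) * d[1L] + grid$cell_row]
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param blockSize,cellArea,transform Cube metadata to attach on read.
#' @rdname fractionCubeIO
#' @export
readFractionCube <- function(path, blockSize = 10L, cellArea = 6.25,
                             transform = c(xll = 0, yll = 0, cellsize = 2500)) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  years <- sort(unique(x$year))
  classes <- unique(x$class)
  cr <- max(x$cell_row); cc <- max(x$cell_col)
  fr <- array(NA_real_, c(cr, cc, length(years), length(classes)),
              dimnames = list(NULL, NULL, years, classes))
  vc <- array(NA_integer_, c(cr, cc, length(years)))
  idx <- cbind(x$cell_row, x$cell_col, match(x$year, years),
               match(x$class, classes))
  fr[idx] <- x$fraction
  vc[idx[, 1:3]] <- x$valid_count
  new("FractionCube", fractions = fr, validCount = vc,
      blockSize = as.integer(blockSize), cellArea = cellArea,
      years = as.integer(years), classes = classes,
      transform = transform, dropped = c(0L, 0L))
}

#' Export scenario ground truth as CSV
#'
#' Header `cell_row,cell_col,class,designed_slope,designed_net_fraction`.
#'
#' @param truth A [GroundTruth-class].
#' @param path CSV path.
#' @export
writeGroundTruth <- function(truth, path) {
  d <- dim(truth@designedSlope)
  classes <- dimnames(truth@designedSlope)[[3L]]
  grid <- expand.grid(cell_row = seq_len(d[1L]), cell_col = seq_len(d[2L]),
                      class = classes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$designed_slope <- as.vector(truth@designedSlope)
  grid$designed_net_fraction <- grid$designed_slope * truth@interval
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
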
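#' Construct a land-cover series
#'
#' @param labels Integer `rows x cols x years` array (or a list of matrices)
#'   of legend codes.
#' @param years Strictly increasing integer years.
#' @param legend A [ClassLegend-class].
#' @param nodata Integer nodata code.
#' @param transform Named numeric `c(xll, yll, cellsize)`; `cellsize` is the
#'   pixel edge in metres.
#' @param crs CRS identifier string (may be empty).
#' @return A validated [LandCoverSeries-class].
#' @export
landCoverSeries <- function(labels, years, legend = defaultLegend(),
                            nodata = -1L,
                            transform = c(xll = 0, yll = 0, cellsize = 250),
                            crs = "") {
  if (is.list(labels)) {
    d <- dim(labels[[1L]])
    labels <- array(unlist(labels, use.names = FALSE),
                    dim = c(d, length(labels)))
  }
  storage.mode(labels) <- "integer"
  new("LandCoverSeries", years = as.integer(years), labels = labels,
      legend = legend, nodata = as.integer(nodata),
      transform = transform, crs = crs)
}

#' Construct a classifier output
#'
#' @param probabilities Numeric `rows x cols x classes` array; each pixel's
#'   vector must lie on the probability simplex.
#' @param classes Integer legend codes for the class dimension.
#' @param labels Optional integer label matrix; computed as the per-pixel
#'   argmax when omitted (ties to the lowest code).
#' @param modelId Identifier string.
#' @param accuracy Optional overall-accuracy weight.
#' @return A validated [ClassifierOutput-class].
#' @export
classifierOutput <- function(probabilities, classes, labels = NULL,
                             modelId = "model", accuracy = NA_real_) {
  d <- dim(probabilities)
  if (is.null(labels)) {
    flat <- matrix(probabilities, ncol = d[3L])
    labels <- matrix(as.integer(classes[max.col(flat, ties.method = "first")]),
                     d[1L], d[2L])
  }
  storage.mode(labels) <- "integer"
  new("ClassifierOutput", labels = labels, probabilities = probabilities,
      classes = as.integer(classes), modelId = modelId,
      accuracy = as.numeric(accuracy))
}
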
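#' Construct a class legend
#'
#' @param codes Integer raster codes.
#' @param classNames Class names parallel to `codes`.
#' @param analysisSet Classes whose trends are analysed for hotspots.
#' @param forestCodes Forest-type classes merged into `forestTarget`.
#' @param forestTarget Name of the merged forest super-class.
#' @return A [ClassLegend-class].
#' @export
classLegend <- function(codes, classNames, analysisSet = classNames,
                        forestCodes = character(), forestTarget = "FORE") {
  new("ClassLegend",
      codes = as.integer(codes), classNames = as.character(classNames),
      analysisSet = as.character(analysisSet),
      forestCodes = as.character(forestCodes),
      forestTarget = as.character(forestTarget))
}

#' The default land-cover legend
#'
#' Fifteen classes: agriculture (AGRI), bare ground (BARE), closed and open
#' shrubland (CLSH, OPSH), the five forest types (DBLE, DNLE, EBLE, ENLE,
#' MIXED), grassland (GRAS), permanent snow (SNOW), sparse vegetation
#' (SPAS), urban (URBN), water (WATR), and the merged forest super-class
#' FORE. Hotspot analysis covers the eight conversion-prone classes AGRI,
#' BARE, CLSH, FORE, GRAS, OPSH, SPAS and URBN; the five forest types merge
#' into FORE before aggregation.
#'
#' @return A [ClassLegend-class].
#' @examples
#' defaultLegend()
#' @export
defaultLegend <- function() {
  nms <- c("AGRI", "BARE", "CLSH", "DBLE", "DNLE", "EBLE", "ENLE", "MIXED",
           "GRAS", "OPSH", "SNOW", "SPAS", "URBN", "WATR", "FORE")
  classLegend(
    codes = seq_along(nms), classNames = nms,
    analysisSet = c("AGRI", "BARE", "CLSH", "FORE", "GRAS", "OPSH",
                    "SPAS", "URBN"),
    forestCodes = c("DBLE", "DNLE", "EBLE", "ENLE", "MIXED"),
    forestTarget = "FORE")
}

#' Look up legend codes by class name
#'
#' @param legend A [ClassLegend-class].
#' @param classNames Character class names.
#' @return Integer codes.
#' @export
codeFor <- function(legend, classNames) {
  i <- match(classNames, legend@classNames)
  if (anyNA(i))
    stop("unknown legend class(es): ",
         paste(classNames[is.na(i)], collapse = ", "))
  legend@codes[i]
}

#' Look up class names by legend code
#'
#' @param legend A [ClassLegend-class].
#' @param codes Integer codes.
#' @return Character class names.
#' @export
nameFor <- function(legend, codes) {
  i <- match(codes, legend@codes)
  if (anyNA(i))
    stop("unknown legend code(s): ", paste(codes[is.na(i)], collapse = ", "))
  legend@classNames[i]
}
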
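# Small fixtures shared across the suite; everything is built in code.

# Three-class legend used where the full 15-class scheme would be noise.
tinyLegend <- function() {
  classLegend(codes = c(1L, 2L, 3L), classNames = c("A", "B", "C"),
              analysisSet = c("A", "B", "C"), forestCodes = character(),
              forestTarget = "C")
}

# A series from a list of label matrices at 250 m pixels.
seriesFromMatrices <- function(mats, years = seq(2001, by = 1,
                                                 length.out = length(mats)),
                               legend = defaultLegend(), nodata = -1L) {
  landCoverSeries(mats, years, legend = legend, nodata = nodata)
}

# Single-transition scenario: GRAS -> AGRI inside one square region.
oneTransitionScenario <- function(gridShape = c(100L, 100L),
                                  regionRows = 1:100, regionCols = 1:100,
                                  rate = 0.01, mode = "random", seed = 1L,
                                  noiseRate = 0, years = 2001:2013) {
  legend <- defaultLegend()
  init <- matrix(codeFor(legend, "GRAS"), gridShape[1L], gridShape[2L])
  scenarioConfig(
    gridShape = gridShape, years = years, legend = legend, initial = init,
    regions = list(box = rectRegion(gridShape, regionRows, regionCols)),
    transitions = data.frame(region = "box", from = "GRAS", to = "AGRI",
                             annualRate = rate, spatialMode = mode,
                             stringsAsFactors = FALSE),
    noiseRate = noiseRate, seed = seed)
}

# Hand-built TrendRaster with explicit per-cell values (one class).
manualTrendRaster <- function(netArea, sdArea, significant,
                              classes = "AGRI", interval = 13,
                              cellArea = 6.25, alpha = 0.1) {
  d <- c(dim(netArea), length(classes))
  wrap <- function(m) array(m, d, dimnames = list(NULL, NULL, classes))
  slope <- netArea / (interval * cellArea)
  p <- ifelse(significant, 0.01, 0.5)
  masked <- ifelse(significant, netArea, 0)
  new("TrendRaster", slope = wrap(slope), pValue = wrap(p),
      netArea = wrap(masked), sdArea = wrap(sdArea),
      significant = wrap(significant), classes = classes,
      provenance = list(blockSize = 10L, interval = interval, alpha = alpha,
                        years = 2001:2013, cellArea = cellArea, fdr = FALSE),
      transform = c(xll = 0, yll = 0, cellsize = 2500))
}

# Independent OLS oracle: QR-based lm fit on the year index.
lmOracle <- function(values) {
  t <- seq_along(values) - 1
  fit <- summary(stats::lm(values ~ t))
  co <- stats::coef(fit)
  list(slope = co["t", "Estimate"], intercept = co["(Intercept)", "Estimate"],
       se = co["t", "Std. Error"], p = co["t", "Pr(>|t|)"])
}
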
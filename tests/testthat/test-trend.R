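test_that("flat and noiseless-linear series give the textbook fits", {
  flat <- olsTrend(rep(0.3, 13))
  expect_equal(flat@slope, 0)
  expect_true(is.na(flat@pValue))
  ncFlat <- netChange(flat)
  expect_equal(ncFlat@netFraction, 0)
  expect_false(ncFlat@significant)

  line <- olsTrend(0.10 + 0.02 * (0:12))
  expect_equal(line@slope, 0.02, tolerance = 1e-12)
  expect_equal(line@intercept, 0.10, tolerance = 1e-12)
  expect_equal(line@seSlope, 0, tolerance = 1e-12)
  expect_identical(line@pValue, 0)
  expect_true(netChange(line)@significant)

  expect_error(olsTrend(c(0.1, 0.2)), "3 points")
  expect_error(olsTrend(c(0.1, NA, 0.2, 0.3)), "finite")
})

test_that("slope, SE and p-value match the independent lm oracle to 1e-10", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(c(5, 9, 13), 1)
    y <- 0.3 + runif(1, -0.02, 0.02) * (0:(n - 1)) + rnorm(n, sd = 0.05)
    fit <- olsTrend(y)
    oracle <- lmOracle(y)
    expect_equal(fit@slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit@intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit@seSlope, oracle$se, tolerance = 1e-10)
    expect_equal(fit@pValue, oracle$p, tolerance = 1e-10)
  }
})

test_that("net change, area and SD follow the interval and cell-area arithmetic", {
  fit <- new("TrendFit", slope = 0.02, intercept = 0.1, seSlope = 0.005,
             pValue = 0.01, nYears = 13L)
  nc <- netChange(fit, interval = 13, alpha = 0.1, cellArea = 6.25)
  expect_equal(nc@netFraction, 0.26)
  expect_equal(nc@netArea, 1.625)
  expect_equal(nc@sdArea, 0.40625)
  expect_true(nc@significant)

  fit@pValue <- 0.2
  nc2 <- netChange(fit)
  expect_false(nc2@significant)
  expect_error(netChange(fit, interval = 0), "positive")
})

test_that("a non-significant cell is masked in the hotspot layer but keeps its fit", {
  Y <- simulateFractionSeries(100, slope = 0, noiseSd = 0.05, seed = 3)
  cube <- new("FractionCube",
              fractions = array(Y, c(10, 10, 13, 1),
                                dimnames = list(NULL, NULL, 2001:2013, "AGRI")),
              validCount = array(100L, c(10, 10, 13)), blockSize = 10L,
              cellArea = 6.25, years = 2001:2013, classes = "AGRI",
              transform = c(xll = 0, yll = 0, cellsize = 2500),
              dropped = c(0L, 0L))
  trend <- trendSurface(cube)
  notSig <- !(significanceLayer(trend, "AGRI") %in% TRUE)
  expect_true(any(notSig))
  expect_true(all(netAreaLayer(trend, "AGRI")[notSig] == 0))
  expect_true(all(abs(slopeLayer(trend, "AGRI")[notSig]) > 0))
  expect_equal(rawNetArea(trend, "AGRI"),
               slopeLayer(trend, "AGRI") * 13 * 6.25)
})

test_that("trend surfaces recover designed slopes and cancel across classes", {
  # a zero-trend, zero-noise scenario yields no significant cell anywhere
  legend <- defaultLegend()
  init <- matrix(codeFor(legend, c("GRAS", "AGRI")), 40, 40)
  cfg <- scenarioConfig(gridShape = c(40L, 40L), initial = init, seed = 2L)
  cube0 <- blockFractions(generateSeries(cfg)$series)
  tr0 <- trendSurface(cube0, classes = analysisClasses(legend))
  expect_false(any(tr0@significant, na.rm = TRUE))

  # designed +0.01/yr AGRI: mean estimated slope within 2 MC SE (50 seeds)
  cellSlopes <- vapply(1:50, function(s) {
    cfg <- oneTransitionScenario(rate = 0.01, mode = "random", seed = s)
    sim <- generateSeries(cfg)
    cube <- blockFractions(sim$series)
    tr <- trendSurface(cube, classes = c("AGRI", "GRAS"))
    mean(slopeLayer(tr, "AGRI"))
  }, numeric(1))
  mcSE <- sd(cellSlopes) / sqrt(length(cellSlopes))
  expect_lt(abs(mean(cellSlopes) - 0.01), 2 * mcSE + 1e-6)

  # with noisy labels, per-cell slopes over ALL legend classes sum to zero
  cfgN <- demoScenario(seed = 8, noiseRate = 0.1)
  sim <- generateSeries(cfgN)
  obs <- applyNoise(sim$series, 0.1, seed = 9)
  cube <- blockFractions(mergeClasses(obs))
  tr <- trendSurface(cube)  # all legend classes
  sums <- apply(tr@slope, c(1, 2), sum)
  expect_lt(max(abs(sums)), 1e-9)
})

test_that("endpoint differencing is exact arithmetic but has no safeguards", {
  # noiseless slope 0.02 over 13 maps: endpoint change spans 12 intervals
  Y <- matrix(0.10 + 0.02 * (0:12), 1, 13)
  cube <- new("FractionCube",
              fractions = array(rep(Y, each = 4), c(2, 2, 13, 1),
                                dimnames = list(NULL, NULL, 2001:2013, "AGRI")),
              validCount = array(100L, c(2, 2, 13)), blockSize = 10L,
              cellArea = 6.25, years = 2001:2013, classes = "AGRI",
              transform = c(xll = 0, yll = 0, cellsize = 2500),
              dropped = c(0L, 0L))
  ep <- endpointChange(cube)
  expect_equal(max(abs(ep - 0.24)), 0, tolerance = 1e-12)
  # versus the regression convention slope x 13 = 0.26
  tr <- trendSurface(cube)
  expect_equal(netAreaLayer(tr, "AGRI") / 6.25,
               matrix(0.26, 2, 2), tolerance = 1e-9)
  # identical first and last maps difference to zero
  cube@fractions[, , 13, ] <- cube@fractions[, , 1, ]
  expect_equal(max(abs(endpointChange(cube))), 0)
})

test_that("regression beats endpoint differencing under a final-year shock", {
  n <- 1000
  Y <- simulateFractionSeries(n, slope = 0, noiseSd = 0.03, seed = 11,
                              shock = 0.10, shockYears = 13L)
  fits <- lcluc:::.olsMatrix(Y)
  regErr <- abs(fits$slope * 13)        # designed net change is 0
  epErr <- abs(Y[, 13] - Y[, 1])
  expect_lt(mean(regErr), mean(epErr))
})

test_that("the optional FDR correction only removes significant calls", {
  Y <- simulateFractionSeries(500, slope = 0, noiseSd = 0.03, seed = 13)
  cube <- new("FractionCube",
              fractions = array(Y, c(25, 20, 13, 1),
                                dimnames = list(NULL, NULL, 2001:2013, "AGRI")),
              validCount = array(100L, c(25, 20, 13)), blockSize = 10L,
              cellArea = 6.25, years = 2001:2013, classes = "AGRI",
              transform = c(xll = 0, yll = 0, cellsize = 2500),
              dropped = c(0L, 0L))
  plain <- trendSurface(cube)
  fdr <- trendSurface(cube, fdr = TRUE)
  expect_lte(sum(fdr@significant), sum(plain@significant))
})

test_that("the detection floor is one pixel footprint in hectares", {
  expect_equal(detectionFloor(231.656), 5.3)
  expect_equal(detectionFloor(250), 6.2)
})
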
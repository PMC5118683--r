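test_that("a transition-free, noise-free scenario is static and partitions the grid", {
  legend <- defaultLegend()
  init <- matrix(codeFor(legend, c("GRAS", "AGRI", "URBN", "CLSH")),
                 20, 20)
  cfg <- scenarioConfig(gridShape = c(20L, 20L), initial = init, seed = 3L)
  sim <- generateSeries(cfg, blockSize = 10L)
  labels <- seriesLabels(sim$series)
  for (y in seq_along(seriesYears(sim$series)))
    expect_identical(labels[, , y], init)
  # every pixel carries exactly one legend code, so fractions sum to 1
  expect_true(all(labels %in% legendCodes(legend)))
  cube <- blockFractions(sim$series)
  sums <- apply(fractionsOf(cube), c(1, 2, 3), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(designedSlopes(sim$truth))), 0)
})

test_that("identical configuration and seed reproduce the series bit for bit", {
  cfg <- oneTransitionScenario(rate = 0.008, mode = "clustered", seed = 11L)
  a <- generateSeries(cfg)$series
  b <- generateSeries(cfg)$series
  expect_identical(seriesLabels(a), seriesLabels(b))
})

test_that("realized conversion trajectories carry the designed slope", {
  # rate * |region| = 100 pixels/yr exactly, so the region-level fraction
  # is affine in the year index and OLS recovers the designed slope; the
  # per-seed check is a brute-force pixel count
  for (mode in c("random", "clustered")) {
    slopes <- vapply(1:10, function(s) {
      cfg <- oneTransitionScenario(rate = 0.01, mode = mode, seed = s)
      series <- generateSeries(cfg)$series
      agri <- codeFor(legendOf(series), "AGRI")
      frac <- vapply(1:13, function(y)
        mean(seriesLabels(series)[, , y] == agri), numeric(1))
      expect_equal(frac, 0.01 * (0:12), tolerance = 1e-12)
      olsTrend(frac)@slope
    }, numeric(1))
    expect_equal(mean(slopes), 0.01, tolerance = 1e-10)
  }
})

test_that("clustered conversions accrete around existing target patches", {
  legend <- defaultLegend()
  gs <- c(40L, 40L)
  init <- matrix(codeFor(legend, "AGRI"), gs[1], gs[2])
  init[20:21, 20:21] <- codeFor(legend, "URBN")
  cfg <- scenarioConfig(
    gridShape = gs, initial = init,
    regions = list(all = rectRegion(gs, 1:40, 1:40)),
    transitions = data.frame(region = "all", from = "AGRI", to = "URBN",
                             annualRate = 0.01, spatialMode = "clustered",
                             stringsAsFactors = FALSE),
    seed = 5L)
  series <- generateSeries(cfg)$series
  lab <- seriesLabels(series)
  urbn <- codeFor(legend, "URBN")
  # the urban patch stays a single 4-connected component as it grows
  final <- lab[, , 13] == urbn
  comp <- lcluc:::.gridDistance(which(final)[1], nrow(final), ncol(final))
  expect_true(all(is.finite(comp[final])))
  # growth is monotone: urban pixels never revert
  for (y in 2:13)
    expect_true(all(lab[, , y][lab[, , y - 1] == urbn] == urbn))
})

test_that("infeasible transition demand fails naming region, classes and year", {
  # validity already rejects a demand exceeding the initial stock
  expect_error(
    oneTransitionScenario(gridShape = c(30L, 30L), regionRows = 1:10,
                          regionCols = 1:10, rate = 0.2, mode = "random"),
    "demand")
  # eligible pixels can also be eroded by a competing transition
  legend <- defaultLegend()
  gs <- c(20L, 20L)
  init <- matrix(codeFor(legend, "GRAS"), gs[1], gs[2])
  init[1:10, ] <- codeFor(legend, "AGRI")
  cfg2 <- scenarioConfig(
    gridShape = gs, initial = init,
    regions = list(top = rectRegion(gs, 1:10, 1:20),
                   all = rectRegion(gs, 1:20, 1:20)),
    transitions = data.frame(
      region = c("top", "all"), from = c("AGRI", "AGRI"),
      to = c("URBN", "BARE"), annualRate = c(0.06, 0.04),
      spatialMode = "random", stringsAsFactors = FALSE),
    seed = 1L)
  expect_error(generateSeries(cfg2), "infeasible transition.*region")
})

test_that("noise at rate 0, and rate 1 with identity confusion, are identities", {
  cfg <- oneTransitionScenario(gridShape = c(30L, 30L), regionRows = 1:30,
                               regionCols = 1:30, rate = 0.005)
  series <- generateSeries(cfg)$series
  expect_identical(seriesLabels(applyNoise(series, 0, seed = 1)),
                   seriesLabels(series))
  k <- length(legendCodes(legendOf(series)))
  eye <- diag(k)
  dimnames(eye) <- list(legendClasses(legendOf(series)),
                        legendClasses(legendOf(series)))
  expect_identical(seriesLabels(applyNoise(series, 1, confusion = eye,
                                           seed = 1)),
                   seriesLabels(series))
  expect_error(applyNoise(series, 1.2), "noiseRate")
})

test_that("realized relabelling counts are binomial at the configured rate", {
  legend <- defaultLegend()
  init <- matrix(codeFor(legend, "GRAS"), 1000, 1000)
  series <- landCoverSeries(array(init, c(1000, 1000, 1)), 2001L,
                            legend = legend)
  noisy <- applyNoise(series, 0.1, seed = 99)  # zero-diagonal confusion
  flips <- sum(seriesLabels(noisy) != seriesLabels(series))
  n <- 1e6
  expect_lt(abs(flips - n * 0.1), 3 * sqrt(n * 0.1 * 0.9))
})

test_that("anomaly years use the elevated noise rate, other years do not", {
  cfg <- oneTransitionScenario(gridShape = c(60L, 60L), regionRows = 1:60,
                               regionCols = 1:60, rate = 0)
  series <- generateSeries(cfg)$series
  noisy <- applyNoise(series, 0.02, anomalyYears = 2013L,
                      anomalyNoiseRate = 0.5, seed = 7)
  diffRate <- vapply(1:13, function(y)
    mean(seriesLabels(noisy)[, , y] != seriesLabels(series)[, , y]),
    numeric(1))
  expect_true(all(diffRate[1:12] < 0.05))
  expect_gt(diffRate[13], 0.4)
})

test_that("simulated classifier ensembles honour reliability and the simplex", {
  legend <- defaultLegend()
  truth <- matrix(codeFor(legend, sample(legendClasses(legend), 317 * 317,
                                         replace = TRUE)), 317, 317)
  # reliability 1: every model reproduces the input labels
  perfect <- generateClassifierOutputs(truth, nModels = 2, reliability = 1,
                                       seed = 1, legend = legend)
  for (o in perfect) expect_identical(o@labels, truth)
  # reliability 0.8: per-model accuracy within 3 sigma at ~1e5 pixels
  n <- length(truth)
  models <- generateClassifierOutputs(truth, nModels = 3, reliability = 0.8,
                                      seed = 2, legend = legend)
  for (o in models) {
    acc <- mean(o@labels == truth)
    expect_lt(abs(acc - 0.8), 3 * sqrt(0.8 * 0.2 / n))
    s <- apply(o@probabilities, c(1, 2), sum)
    expect_equal(max(abs(s - 1)), 0, tolerance = 1e-9)
    # labels are the argmax of their own probability stack
    flat <- matrix(o@probabilities, ncol = length(o@classes))
    expect_identical(as.vector(o@labels),
                     o@classes[max.col(flat, ties.method = "first")])
  }
  expect_error(generateClassifierOutputs(truth, nModels = 1, legend = legend),
               "at least 2")
})
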
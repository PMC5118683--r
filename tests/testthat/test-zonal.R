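test_that("zonal gains, losses and nets follow the masking arithmetic", {
  netArea <- matrix(c(1.625, -0.5, 2.0, 0), 2, 2)
  sdArea <- matrix(0.1, 2, 2)
  significant <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  trend <- manualTrendRaster(netArea, sdArea, significant)
  zones <- matrix("z1", 2, 2)
  zt <- zonalNetChange(trend, zones)
  expect_equal(zt$gain_km2, 1.625)
  expect_equal(zt$loss_km2, -0.5)
  expect_equal(zt$net_km2, 1.125)
  expect_equal(zt$net_km2, zt$gain_km2 + zt$loss_km2)
  expect_equal(zt$sd_km2, sqrt(2 * 0.1^2))
  expect_identical(zt$n_cells_significant, 2L)

  # a zone with no significant cells is an all-zero row
  zones2 <- matrix(c("hot", "hot", "cold", "cold"), 2, 2)
  zt2 <- zonalNetChange(trend, zones2)
  cold <- zt2[zt2$zone == "cold", ]
  expect_equal(cold$gain_km2, 0)
  expect_equal(cold$loss_km2, 0)
  expect_identical(cold$n_cells_significant, 0L)
  # NA-zoned cells are excluded
  zones3 <- matrix(c("z", NA, NA, NA), 2, 2)
  zt3 <- zonalNetChange(trend, zones3)
  expect_equal(zt3$net_km2, 1.625)
  expect_error(zonalNetChange(trend, matrix("z", 3, 3)), "shape")
})

test_that("zone tables add over a partition of the domain", {
  cfg <- demoScenario(seed = 14, noiseRate = 0.05)
  res <- generateSeries(cfg)
  obs <- applyNoise(res$series, 0.05, seed = 15)
  trend <- trendSurface(blockFractions(mergeClasses(obs)),
                        classes = analysisClasses(cfg@legend))
  whole <- zonalNetChange(trend, matrix("all", 20, 20))
  left <- matrix(rep(c("a", "b"), each = 200), 20, 20)
  parts <- zonalNetChange(trend, left)
  added <- aggregate(cbind(gain_km2, loss_km2, net_km2, n_cells_significant)
                     ~ class, parts, sum)
  added <- added[match(whole$class, added$class), ]
  expect_equal(added$gain_km2, whole$gain_km2, tolerance = 1e-12)
  expect_equal(added$loss_km2, whole$loss_km2, tolerance = 1e-12)
  expect_equal(added$net_km2, whole$net_km2, tolerance = 1e-12)
  expect_equal(added$n_cells_significant, whole$n_cells_significant)
})

test_that("unmasked nets conserve to zero per zone in a closed scenario", {
  cfg <- demoScenario(seed = 16, noiseRate = 0.05)
  res <- generateSeries(cfg)
  obs <- applyNoise(res$series, 0.05, seed = 17)
  trend <- trendSurface(blockFractions(mergeClasses(obs)))  # full legend
  zones <- zonesFromRegions(cfg@regions)
  zt <- zonalNetChange(trend, zones, maskNonSignificant = FALSE)
  perZone <- tapply(zt$net_km2, zt$zone, sum)
  expect_lt(max(abs(perZone)), 1e-6)
  # significance masking breaks the balance
  ztM <- zonalNetChange(trend, zones)
  perZoneM <- tapply(ztM$net_km2, ztM$zone, sum)
  expect_gt(max(abs(perZoneM)), 1e-6)
})

test_that("designed regional net change is recovered within the table's uncertainty", {
  # designed AGRI net: 0.009231/yr x 1600 px x 13 yr x 0.0625 km2 = +12 km2
  rate <- 12 / (13 * 0.0625 * 1600)
  nets <- numeric(50); sds <- numeric(50)
  for (s in 1:50) {
    cfg <- oneTransitionScenario(gridShape = c(60L, 60L), regionRows = 11:50,
                                 regionCols = 11:50, rate = rate, seed = s,
                                 mode = if (s %% 2) "random" else "clustered")
    sim <- generateSeries(cfg)
    obs <- applyNoise(sim$series, 0.02, seed = s + 1000)
    trend <- trendSurface(blockFractions(mergeClasses(obs)),
                          classes = c("AGRI", "GRAS"))
    zt <- zonalNetChange(trend, zonesFromRegions(cfg@regions))
    row <- zt[zt$zone == "box" & zt$class == "AGRI", ]
    nets[s] <- row$net_km2; sds[s] <- row$sd_km2
  }
  expect_lt(abs(mean(nets) - 12), 2 * mean(sds))
})

test_that("a closed two-class exchange balances and correlates", {
  cfg <- oneTransitionScenario(gridShape = c(80L, 80L), regionRows = 1:80,
                               regionCols = 1:80, rate = 0.01, seed = 30L)
  sim <- generateSeries(cfg)
  obs <- applyNoise(sim$series, 0.02, seed = 31)
  trend <- trendSurface(blockFractions(mergeClasses(obs)),
                        classes = c("AGRI", "GRAS"))
  assoc <- conversionAssociation(trend, "AGRI", "GRAS")
  zt <- zonalNetChange(trend, matrix("all", 8, 8))
  sdAB <- sqrt(sum(zt$sd_km2[zt$class %in% c("AGRI", "GRAS")]^2))
  expect_lt(abs(assoc$net_a + assoc$net_b), 2 * sdAB)
  expect_lt(assoc$correlation, 0)  # gains in one mirror losses in the other

  # class paired with itself correlates perfectly
  self <- conversionAssociation(trend, "AGRI", "AGRI")
  expect_equal(self$correlation, 1)

  # zone without significant cells reports missing correlation
  empty <- manualTrendRaster(matrix(1, 2, 2), matrix(0.1, 2, 2),
                             matrix(FALSE, 2, 2))
  e <- conversionAssociation(empty, "AGRI", "AGRI")
  expect_equal(e$net_a, 0)
  expect_true(is.na(e$correlation))
  expect_error(conversionAssociation(trend, "AGRI", "SNOW"), "missing")
})
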
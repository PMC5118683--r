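#' Synthetic land-cover scenario tools
#'
#' A scenario plants regionally localised, constant-rate class conversions
#' (urban rings eating agriculture, grassland reclamation, shrubland
#' succeeding to forest) on a pixel grid, realises one label map per year,
#' and keeps the designed trends as analytic ground truth so that slope and
#' net-change recovery can be scored exactly.
#'
#' @name synthetic
NULL

#' Build a rectangular region mask
#'
#' @param gridShape Integer `c(rows, cols)`.
#' @param rows,cols Integer index ranges (1-based, inclusive).
#' @return Logical `rows x cols` matrix.
#' @export
rectRegion <- function(gridShape, rows, cols) {
  m <- matrix(FALSE, gridShape[1L], gridShape[2L])
  m[rows, cols] <- TRUE
  m
}

#' Uniform off-diagonal confusion matrix
#'
#' When a pixel is misclassified, the replacement label is drawn uniformly
#' from the other legend classes.
#'
#' @param legend A [ClassLegend-class].
#' @return Row-stochastic matrix with zero diagonal, dimnames = class names.
#' @export
uniformConfusion <- function(legend = defaultLegend()) {
  k <- length(legend@codes)
  cm <- matrix(1 / (k - 1), k, k,
               dimnames = list(legend@classNames, legend@classNames))
  diag(cm) <- 0
  cm
}

#' Construct a scenario configuration
#'
#' @param gridShape Integer `c(rows, cols)` in pixels.
#' @param pixelSize Pixel edge length, metres.
#' @param years Strictly increasing integer years.
#' @param legend A [ClassLegend-class].
#' @param initial Integer matrix of legend codes (year-one mosaic).
#' @param regions Named list of logical masks.
#' @param transitions data.frame(region, from, to, annualRate, spatialMode).
#'   `annualRate` is the fraction of region area converted per year;
#'   `spatialMode` is "clustered" (accretion around existing target-class
#'   patches) or "random" (uniform over eligible pixels).
#' @param noiseRate Per-pixel per-year misclassification probability.
#' @param confusion Row-stochastic confusion matrix (default: uniform over
#'   the other classes).
#' @param anomalyYears Years with elevated noise.
#' @param anomalyNoiseRate Noise rate applied in anomaly years.
#' @param seed Integer RNG seed.
#' @return A validated [ScenarioConfig-class].
#' @export
scenarioConfig <- function(gridShape, pixelSize = 250, years = 2001:2013,
                           legend = defaultLegend(), initial, regions = list(),
                           transitions = data.frame(), noiseRate = 0,
                           confusion = uniformConfusion(legend),
                           anomalyYears = integer(),
                           anomalyNoiseRate = noiseRate, seed = 1L) {
  storage.mode(initial) <- "integer"
  if (nrow(transitions)) {
    transitions$region <- as.character(transitions$region)
    transitions$from <- as.character(transitions$from)
    transitions$to <- as.character(transitions$to)
    transitions$spatialMode <- as.character(transitions$spatialMode)
  }
  new("ScenarioConfig",
      gridShape = as.integer(gridShape), pixelSize = as.numeric(pixelSize),
      years = as.integer(years), legend = legend, initial = initial,
      regions = regions, transitions = transitions,
      noiseRate = as.numeric(noiseRate), confusion = confusion,
      anomalyYears = as.integer(anomalyYears),
      anomalyNoiseRate = as.numeric(anomalyNoiseRate),
      seed = as.integer(seed))
}

#' The built-in demonstration scenario
#'
#' A 200 x 200 pixel landscape (250 m pixels, 20 x 20 big grid cells) over
#' 2001-2013 with three localised change processes on a grassland
#' background: clustered urban expansion into agriculture around a seeded
#' urban core, random agricultural reclamation of grassland, and clustered
#' succession of closed shrubland to deciduous needleleaf forest around a
#' forest remnant. Per-pixel classification noise defaults to 0.05 with a
#' uniform confusion model.
#'
#' @param seed Integer RNG seed.
#' @param noiseRate Per-pixel per-year misclassification probability.
#' @param anomalyYears,anomalyNoiseRate Optional anomaly-year perturbation.
#' @return A [ScenarioConfig-class].
#' @examples
#' cfg <- demoScenario(seed = 1)
#' sim <- generateSeries(cfg)
#' @export
demoScenario <- function(seed = 42L, noiseRate = 0.05,
                         anomalyYears = integer(),
                         anomalyNoiseRate = noiseRate) {
  legend <- defaultLegend()
  gs <- c(200L, 200L)
  init <- matrix(codeFor(legend, "GRAS"), gs[1L], gs[2L])
  regions <- list(
    urban_fringe = rectRegion(gs, 21:60, 21:60),
    reclamation  = rectRegion(gs, 121:180, 21:80),
    succession   = rectRegion(gs, 121:180, 121:180)
  )
  init[regions$urban_fringe] <- codeFor(legend, "AGRI")
  init[36:44, 36:44] <- codeFor(legend, "URBN")
  init[regions$succession] <- codeFor(legend, "CLSH")
  init[146:154, 146:154] <- codeFor(legend, "DNLE")
  transitions <- data.frame(
    region = c("urban_fringe", "reclamation", "succession"),
    from = c("AGRI", "GRAS", "CLSH"),
    to = c("URBN", "AGRI", "DNLE"),
    annualRate = c(0.010, 0.012, 0.015),
    spatialMode = c("clustered", "random", "clustered"),
    stringsAsFactors = FALSE)
  scenarioConfig(gridShape = gs, pixelSize = 250, years = 2001:2013,
                 legend = legend, initial = init, regions = regions,
                 transitions = transitions, noiseRate = noiseRate,
                 anomalyYears = anomalyYears,
                 anomalyNoiseRate = anomalyNoiseRate, seed = seed)
}

# Breadth-first 4-neighbour distance from a seed set; Inf where unreachable.
.gridDistance <- function(seedIdx, nr, nc) {
  dist <- rep.int(Inf, nr * nc)
  if (!length(seedIdx)) return(matrix(dist, nr, nc))
  dist[seedIdx] <- 0
  frontier <- seedIdx
  level <- 0
  while (length(frontier)) {
    level <- level + 1
    r <- (frontier - 1L) %% nr + 1L
    up <- frontier[r > 1L] - 1L
    down <- frontier[r < nr] + 1L
    left <- frontier[frontier > nr] - nr
    right <- frontier[frontier <= nr * (nc - 1L)] + nr
    nb <- c(up, down, left, right)
    nb <- nb[dist[nb] == Inf]
    if (!length(nb)) break
    nb <- unique(nb)
    dist[nb] <- level
    frontier <- nb
  }
  matrix(dist, nr, nc)
}

# Integer pixel demand per year under largest-remainder rounding with the
# running remainder carried across years, so cumulative conversions track
# rate * |region| * yearIndex to within half a pixel.
.carryDemand <- function(ratePixels, nSteps) {
  cumTarget <- ratePixels * seq_len(nSteps)
  k <- diff(c(0, floor(cumTarget + 0.5)))
  as.integer(k)
}

#' Realise a synthetic scenario
#'
#' Produces one label grid per year. Year one is the configured initial
#' mosaic; each later year converts pixels from -> to inside each
#' transition's region at the configured annual rate (fraction of region
#' area), so region-level class-fraction trajectories are linear with the
#' designed slopes. No classification noise is applied here; see
#' [applyNoise()].
#'
#' @param config A valid [ScenarioConfig-class].
#' @param blockSize Pixels per big-grid-cell edge used when deriving the
#'   per-cell ground truth (default 10).
#' @return A list with elements `series` (a [LandCoverSeries-class]) and
#'   `truth` (a [GroundTruth-class] derived analytically from the
#'   configuration, at the merged-forest class level).
#' @export
generateSeries <- function(config, blockSize = 10L) {
  validObject(config)
  legend <- config@legend
  nr <- config@gridShape[1L]; nc <- config@gridShape[2L]
  years <- config@years
  ny <- length(years)
  set.seed(config@seed)

  labels <- array(NA_integer_, dim = c(nr, nc, ny))
  labels[, , 1L] <- config@initial
  tr <- config@transitions
  nTr <- nrow(tr)
  demands <- vector("list", nTr)
  regSize <- integer(nTr)
  if (nTr) for (j in seq_len(nTr)) {
    regSize[j] <- sum(config@regions[[tr$region[j]]])
    demands[[j]] <- .carryDemand(tr$annualRate[j] * regSize[j], ny - 1L)
  }
  # row-major key used for deterministic tie-breaks
  rowMajor <- matrix(seq_len(nr * nc), nr, nc)
  rowMajor[] <- (row(rowMajor) - 1L) * nc + col(rowMajor)

  cur <- config@initial
  for (y in seq_len(ny - 1L)) {
    if (nTr) for (j in seq_len(nTr)) {
      k <- demands[[j]][y]
      if (k == 0L) next
      reg <- config@regions[[tr$region[j]]]
      fromCode <- codeFor(legend, tr$from[j])
      toCode <- codeFor(legend, tr$to[j])
      elig <- which(reg & cur == fromCode)
      if (length(elig) < k)
        stop(sprintf(
          "infeasible transition %s->%s in region '%s', year %d: %d pixels demanded, %d eligible",
          tr$from[j], tr$to[j], tr$region[j], years[y + 1L], k, length(elig)))
      if (tr$spatialMode[j] == "random") {
        take <- elig[sample.int(length(elig), k)]
      } else {
        seeds <- which(reg & cur == toCode)
        if (!length(seeds)) seeds <- elig[which.min(rowMajor[elig])]
        dist <- .gridDistance(seeds, nr, nc)
        take <- elig[order(dist[elig], rowMajor[elig])[seq_len(k)]]
      }
      cur[take] <- toCode
    }
    labels[, , y + 1L] <- cur
  }

  series <- landCoverSeries(
    labels, years, legend = legend,
    transform = c(xll = 0, yll = 0, cellsize = config@pixelSize))
  truth <- .groundTruthFromConfig(config, blockSize)
  list(series = series, truth = truth)
}

# Designed per-cell slopes at the merged-forest class level, from the
# configuration alone (uniform spread of conversions over each region).
.groundTruthFromConfig <- function(config, blockSize) {
  legend <- config@legend
  merged <- setdiff(legend@classNames, legend@forestCodes)
  mergeName <- function(cls) ifelse(cls %in% legend@forestCodes,
                                    legend@forestTarget, cls)
  nr <- config@gridShape[1L]; nc <- config@gridShape[2L]
  B <- as.integer(blockSize)
  cr <- nr %/% B; cc <- nc %/% B
  slopes <- array(0, dim = c(cr, cc, length(merged)),
                  dimnames = list(NULL, NULL, merged))
  tr <- config@transitions
  interval <- length(config@years)
  pixKm2 <- (config@pixelSize / 1000)^2
  regionNet <- data.frame(region = character(), class = character(),
                          net_km2 = numeric(), stringsAsFactors = FALSE)
  if (nrow(tr)) for (j in seq_len(nrow(tr))) {
    reg <- config@regions[[tr$region[j]]]
    cellCount <- .blockSum(reg * 1L, B)[seq_len(cr), seq_len(cc), drop = FALSE]
    perCell <- tr$annualRate[j] * cellCount / B^2
    fromM <- mergeName(tr$from[j]); toM <- mergeName(tr$to[j])
    slopes[, , toM] <- slopes[, , toM] + perCell
    slopes[, , fromM] <- slopes[, , fromM] - perCell
    net <- tr$annualRate[j] * sum(reg) * interval * pixKm2
    regionNet <- rbind(regionNet, data.frame(
      region = tr$region[j], class = c(toM, fromM),
      net_km2 = c(net, -net), stringsAsFactors = FALSE))
  }
  new("GroundTruth", designedSlope = slopes, regionNet = regionNet,
      blockSize = B, interval = as.numeric(interval))
}

# Sum a matrix over blockSize x blockSize blocks (trailing partials dropped).
.blockSum <- function(m, B) {
  nr <- nrow(m); nc <- ncol(m)
  cr <- nr %/% B; cc <- nc %/% B
  m <- m[seq_len(cr * B), seq_len(cc * B), drop = FALSE]
  dim(m) <- c(B, cr, B * cc)
  s <- colSums(m)                      # cr x (B*cc)
  dim(s) <- c(cr, B, cc)
  colSums(aperm(s, c(2L, 1L, 3L)))     # cr x cc
}

#' Apply per-pixel classification noise to a label series
#'
#' Each pixel-year is independently relabelled with probability
#' `noiseRate`; the replacement is drawn from the pixel's row of the
#' confusion matrix. Years listed in `anomalyYears` use
#' `anomalyNoiseRate` instead, emulating map degradation from an extreme
#' year at either end of the record. Nodata pixels are untouched.
#'
#' @param series A [LandCoverSeries-class].
#' @param noiseRate Relabelling probability in `[0, 1]`.
#' @param confusion Row-stochastic confusion matrix over the legend classes
#'   (dimnames = class names); default uniform over the other classes.
#' @param anomalyYears Integer years with elevated noise.
#' @param anomalyNoiseRate Noise rate for anomaly years.
#' @param seed Integer RNG seed.
#' @return A [LandCoverSeries-class] with noisy labels.
#' @export
applyNoise <- function(series, noiseRate, confusion = NULL,
                       anomalyYears = integer(),
                       anomalyNoiseRate = noiseRate, seed = 1L) {
  if (noiseRate < 0 || noiseRate > 1)
    stop("noiseRate must lie in [0, 1]")
  if (anomalyNoiseRate < 0 || anomalyNoiseRate > 1)
    stop("anomalyNoiseRate must lie in [0, 1]")
  legend <- series@legend
  if (is.null(confusion)) confusion <- uniformConfusion(legend)
  if (any(abs(rowSums(confusion) - 1) > 1e-9))
    stop("confusion rows must sum to 1")
  codes <- legend@codes
  set.seed(seed)
  labels <- series@labels
  ny <- dim(labels)[3L]
  for (y in seq_len(ny)) {
    rate <- if (series@years[y] %in% anomalyYears) anomalyNoiseRate else noiseRate
    if (rate == 0) next
    lay <- labels[, , y]
    valid <- which(lay != series@nodata & !is.na(lay))
    hit <- valid[stats::runif(length(valid)) < rate]
    if (!length(hit)) next
    cls <- lay[hit]
    for (code in unique(cls)) {
      i <- hit[cls == code]
      row <- confusion[match(code, codes), ]
      lay[i] <- codes[sample.int(length(codes), length(i), replace = TRUE,
                                 prob = row)]
    }
    labels[, , y] <- lay
  }
  landCoverSeries(labels, series@years, legend = legend,
                  nodata = series@nodata, transform = series@transform,
                  crs = series@crs)
}

#' Simulate ensemble classifier outputs for one map
#'
#' Emulates an ensemble of classifiers applied to the same scene. For each
#' model, the predicted class of a pixel equals the true class with
#' probability `reliability` and is otherwise uniform over the remaining
#' classes; the predicted class receives a membership probability drawn
#' from `winnerMass`, and the remaining mass is split over the other
#' classes by a symmetric Dirichlet, so the label is always the argmax of
#' its own probability vector.
#'
#' @param x A [LandCoverSeries-class] (one year is taken) or an integer
#'   label matrix.
#' @param nModels Number of models (>= 2).
#' @param reliability Per-model probability of a correct label, recycled
#'   to `nModels`; each value in (0, 1].
#' @param seed Integer RNG seed.
#' @param year Year to classify when `x` is a series (default: last).
#' @param legend Legend when `x` is a matrix.
#' @param winnerMass Range of the predicted class's membership probability.
#' @return List of [ClassifierOutput-class], length `nModels`.
#' @export
generateClassifierOutputs <- function(x, nModels = 3L, reliability = 0.85,
                                      seed = 1L, year = NULL,
                                      legend = defaultLegend(),
                                      winnerMass = c(0.55, 0.95)) {
  if (nModels < 2L) stop("nModels must be at least 2")
  reliability <- rep_len(reliability, nModels)
  if (any(reliability <= 0 | reliability > 1))
    stop("reliability must lie in (0, 1]")
  if (is(x, "LandCoverSeries")) {
    legend <- x@legend
    yi <- if (is.null(year)) length(x@years) else match(year, x@years)
    if (is.na(yi)) stop("year ", year, " not in series")
    truth <- x@labels[, , yi]
  } else truth <- x
  codes <- legend@codes
  K <- length(codes)
  nr <- nrow(truth); nc <- ncol(truth); n <- nr * nc
  trueIdx <- match(as.vector(truth), codes)
  set.seed(seed)
  out <- vector("list", nModels)
  for (m in seq_len(nModels)) {
    winIdx <- trueIdx
    wrong <- which(stats::runif(n) >= reliability[m])
    if (length(wrong)) {
      off <- sample.int(K - 1L, length(wrong), replace = TRUE)
      winIdx[wrong] <- ifelse(off >= trueIdx[wrong], off + 1L, off)
    }
    W <- stats::runif(n, winnerMass[1L], winnerMass[2L])
    g <- matrix(stats::rgamma(n * (K - 1L), shape = 1), n, K - 1L)
    g <- g / rowSums(g) * (1 - W)
    probs <- matrix(0, n, K)
    for (k in seq_len(K)) {
      # losers fill the columns left of/right of the winner in order
      sel <- winIdx == k
      if (!any(sel)) next
      probs[sel, -k] <- g[sel, , drop = FALSE]
      probs[sel, k] <- W[sel]
    }
    out[[m]] <- classifierOutput(
      probabilities = array(probs, dim = c(nr, nc, K)),
      classes = codes,
      labels = matrix(codes[winIdx], nr, nc),
      modelId = paste0("model", m))
  }
  out
}

#' Simulate Gaussian cover-fraction series
#'
#' Fraction-scale emulation of big-grid-cell cover trajectories:
#' `intercept + slope * t + e`, `t = 0..n-1`, `e ~ N(0, noiseSd)`. Used to
#' calibrate the trend stage (false-positive rate, net-change recovery,
#' coverage of the one-sigma band) under a noise model where the t test is
#' exact.
#'
#' @param nSeries Number of independent cell series.
#' @param years Integer years (only their count matters for the design).
#' @param slope Designed slope, fraction per year (recycled).
#' @param intercept Fraction at `t = 0` (recycled).
#' @param noiseSd Standard deviation of the iid Gaussian noise.
#' @param seed Integer RNG seed.
#' @param shock Additive fraction shock applied to `shockYears` (e.g. a
#'   final-year anomaly), default none.
#' @param shockYears Indices (1-based) of the years receiving `shock`.
#' @return Numeric matrix `nSeries x length(years)`.
#' @export
simulateFractionSeries <- function(nSeries, years = 2001:2013, slope = 0,
                                   intercept = 0.3, noiseSd = 0.03,
                                   seed = 1L, shock = 0,
                                   shockYears = integer()) {
  n <- length(years)
  t <- seq_len(n) - 1
  set.seed(seed)
  mu <- outer(rep_len(slope, nSeries), t) + rep_len(intercept, nSeries)
  if (length(shockYears)) mu[, shockYears] <- mu[, shockYears] + shock
  mu + matrix(stats::rnorm(nSeries * n, sd = noiseSd), nSeries, n)
}
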
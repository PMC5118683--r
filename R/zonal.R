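#' Zonal gain/loss accounting of significant net changes
#'
#' Aggregates a trend raster over a zone overlay (biomes, urban
#' agglomerations, mountain ranges) into per-zone, per-class gains, losses
#' and net areas. Gains and losses are accumulated separately before
#' netting, matching the dual-bar presentation of regional change budgets;
#' zone standard deviations assume independent cells, i.e.
#' `sd = sqrt(sum(sd_area^2))` over the contributing cells.
#'
#' @name zonal
NULL

#' Reduce a pixel-resolution zone raster to the big grid
#'
#' A cell is assigned the zone covering its centre pixel (for even block
#' sizes, the upper-left of the two central pixels).
#'
#' @param zones Matrix of zone labels at pixel resolution (NA = no zone).
#' @param blockSize Pixels per cell edge.
#' @return Zone matrix at cell resolution.
#' @export
zonesToCells <- function(zones, blockSize = 10L) {
  B <- as.integer(blockSize)
  cr <- nrow(zones) %/% B; cc <- ncol(zones) %/% B
  centre <- (B + 1L) %/% 2L
  rows <- (seq_len(cr) - 1L) * B + centre
  cols <- (seq_len(cc) - 1L) * B + centre
  zones[rows, cols, drop = FALSE]
}

#' Cell-level zone labels from named region masks
#'
#' Convenience overlay for synthetic scenarios: each cell takes the name of
#' the first region containing its centre pixel, or `background` when none
#' does.
#'
#' @param regions Named list of logical pixel masks.
#' @param blockSize Pixels per cell edge.
#' @param background Label for cells outside every region (NA to exclude
#'   them).
#' @return Character matrix at cell resolution.
#' @export
zonesFromRegions <- function(regions, blockSize = 10L,
                             background = "background") {
  stopifnot(length(regions) >= 1L)
  z <- matrix(NA_character_, nrow(regions[[1L]]), ncol(regions[[1L]]))
  for (nm in rev(names(regions))) z[regions[[nm]]] <- nm
  z[is.na(z)] <- background
  zonesToCells(z, blockSize)
}

#' Per-zone, per-class change budget
#'
#' For every zone and class: the summed positive significant net areas
#' (gain), summed negative significant net areas (loss), their net, the
#' square-root-of-summed-squares standard deviation over the significant
#' cells, and the significant-cell count. Cells outside any zone (NA) are
#' excluded. With `maskNonSignificant = FALSE` the raw
#' slope-times-interval net areas of all fitted cells enter the sums
#' instead, which restores exact cross-class conservation in closed
#' scenarios (significance masking breaks it).
#'
#' @param trend A [TrendRaster-class].
#' @param zones Zone label matrix at cell resolution (same shape as the
#'   trend grids), or at pixel resolution (reduced via [zonesToCells()]).
#' @param maskNonSignificant Use only significant cells (default TRUE).
#' @return data.frame with columns
#'   `zone,class,gain_km2,loss_km2,net_km2,sd_km2,n_cells_significant`.
#' @export
zonalNetChange <- function(trend, zones, maskNonSignificant = TRUE) {
  d <- dim(trend@slope)
  if (!identical(dim(zones), d[1:2])) {
    B <- trend@provenance$blockSize
    if (!is.null(B) && identical(dim(zonesToCells(zones, B)), d[1:2]))
      zones <- zonesToCells(zones, B)
    else
      stop("zone raster shape ", paste(dim(zones), collapse = "x"),
           " does not match trend grid ", paste(d[1:2], collapse = "x"))
  }
  zoneLevels <- sort(unique(as.vector(zones[!is.na(zones)])))
  out <- expand.grid(zone = zoneLevels, class = trend@classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$gain_km2 <- 0; out$loss_km2 <- 0; out$net_km2 <- 0; out$sd_km2 <- 0
  out$n_cells_significant <- 0L
  rawNet <- trend@slope * trend@provenance$interval * trend@provenance$cellArea
  for (i in seq_len(nrow(out))) {
    ci <- match(out$class[i], trend@classes)
    inZone <- !is.na(zones) & zones == out$zone[i]
    sig <- trend@significant[, , ci] %in% TRUE & inZone
    use <- if (maskNonSignificant) sig else
      (inZone & !is.na(trend@slope[, , ci]))
    net <- (if (maskNonSignificant) trend@netArea else rawNet)[, , ci][use]
    sd2 <- trend@sdArea[, , ci][use]^2
    out$gain_km2[i] <- sum(net[net > 0])
    out$loss_km2[i] <- sum(net[net < 0])
    out$net_km2[i] <- sum(net)
    out$sd_km2[i] <- sqrt(sum(sd2))
    out$n_cells_significant[i] <- sum(sig)
  }
  out
}

#' Paired-change summary for two classes in a zone
#'
#' Quantifies how far one class's gains are matched by another's losses
#' (urban vs agriculture, agriculture vs grassland): the two zonal net
#' areas plus the cellwise Pearson correlation of significant net areas
#' over cells where both classes are significant. The correlation is NA
#' when fewer than two such cells exist or either side is constant.
#'
#' @param trend A [TrendRaster-class].
#' @param classA,classB Class names present in the trend raster.
#' @param zones Optional zone matrix; `zone` selects one zone label. When
#'   omitted the whole domain is used.
#' @param zone Zone label to restrict to.
#' @return List with `net_a`, `net_b`, `correlation`, `n_cells`.
#' @export
conversionAssociation <- function(trend, classA, classB, zones = NULL,
                                  zone = NULL) {
  ia <- match(classA, trend@classes); ib <- match(classB, trend@classes)
  if (is.na(ia) || is.na(ib))
    stop("class missing from trend raster: ",
         paste(c(classA, classB)[is.na(c(ia, ib))], collapse = ", "))
  d <- dim(trend@slope)
  inZone <- matrix(TRUE, d[1L], d[2L])
  if (!is.null(zones)) {
    if (!identical(dim(zones), d[1:2]))
      zones <- zonesToCells(zones, trend@provenance$blockSize)
    inZone <- !is.na(zones) & zones == zone
  }
  sigA <- trend@significant[, , ia] %in% TRUE & inZone
  sigB <- trend@significant[, , ib] %in% TRUE & inZone
  netA <- sum(trend@netArea[, , ia][sigA])
  netB <- sum(trend@netArea[, , ib][sigB])
  both <- sigA & sigB
  corr <- NA_real_
  if (sum(both) >= 2L) {
    a <- trend@netArea[, , ia][both]
    b <- trend@netArea[, , ib][both]
    if (stats::sd(a) > 0 && stats::sd(b) > 0)
      corr <- stats::cor(a, b)
    else if (identical(ia, ib))
      corr <- 1
  }
  list(net_a = netA, net_b = netB, correlation = corr, n_cells = sum(both))
}
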
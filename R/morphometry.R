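#' DensityMap: per-microtile tissue density over the section
#'
#' For each microtile, density is the stained-tissue pixel count divided by
#' the section pixel count inside the tile, a value in [0, 1]: 0 where the
#' tile is pure airspace/lumen, 1 where it is solid tissue. Stained tissue
#' means collagen plus parenchyma in PSR_AB mode (counterstain plus
#' immunopositive in IHC mode); mucus and background count as unstained
#' airspace. A tile is included iff its section coverage (section pixels /
#' tile pixels) reaches \code{minTileCoverage}.
#'
#' @slot density numeric \code{nRows x nCols} matrix; \code{NA} for
#'   excluded tiles.
#' @slot coverage per-tile section-coverage fraction in [0, 1].
#' @slot sectionPx per-tile section pixel counts.
#' @slot included logical matrix of included tiles.
#' @slot tau fibrosis-density threshold (default 0.75).
#' @slot minTileCoverage inclusion cutoff (default 0.5).
#' @slot grid the \code{\linkS4class{TileGrid}} used.
#' @export
setClass("DensityMap",
  representation(density = "matrix", coverage = "matrix",
                 sectionPx = "matrix", included = "matrix",
                 tau = "numeric", minTileCoverage = "numeric",
                 grid = "TileGrid")
)

setValidity("DensityMap", function(object) {
  d <- object@density[object@included]
  if (length(d) && (any(!is.finite(d)) || any(d < 0) || any(d > 1)))
    return("included-tile densities must lie in [0, 1]")
  TRUE
})

setMethod("show", "DensityMap", function(object) {
  n <- sum(object@included)
  cat(sprintf(
    "DensityMap: %d x %d tiles (%d included); tau = %.2f\n",
    nrow(object@density), ncol(object@density), n, object@tau))
  if (n) cat(sprintf("  mean density %.3f, %.1f%% of tiles > tau\n",
                     mean(object@density[object@included]),
                     100 * mean(object@density[object@included] > object@tau)))
})

#' @rdname DensityMap
#' @param x a \code{DensityMap}.
#' @export
setGeneric("tileDensities", function(x) standardGeneric("tileDensities"))

#' @rdname DensityMap
#' @export
setMethod("tileDensities", "DensityMap", function(x) x@density)

#' @rdname DensityMap
#' @export
setGeneric("includedTiles", function(x) standardGeneric("includedTiles"))

#' @rdname DensityMap
#' @export
setMethod("includedTiles", "DensityMap", function(x) x@included)

.tissueClasses <- function(stainMode) {
  if (stainMode == "PSR_AB") c("collagen_red", "parenchyma_yellow")
  else c("counterstain_blue", "immunopositive_brown")
}

#' Compute the microtile density map
#'
#' @param masks a \code{\linkS4class{StainMasks}}.
#' @param section a \code{\linkS4class{SectionMask}} derived from the same
#'   slide.
#' @param grid a \code{\linkS4class{TileGrid}} matching the slide geometry.
#' @param minTileCoverage minimum section coverage for a tile to be
#'   included (default 0.5); avoids background-dominated boundary tiles.
#' @param tau fibrosis-density threshold stored with the map (default 0.75).
#' @return A \code{\linkS4class{DensityMap}}.
#' @export
densityMap <- function(masks, section, grid, minTileCoverage = 0.5,
                       tau = 0.75) {
  stopifnot(is(masks, "StainMasks"), is(section, "SectionMask"),
            is(grid, "TileGrid"))
  d <- dim(masks@labels)
  if (!identical(d, dim(section@section)) ||
      grid@heightPx != d[1] || grid@widthPx != d[2])
    .stopValidation("masks, section and grid geometries differ")
  tid <- tileIndexMatrix(grid)
  nT <- grid@nRows * grid@nCols
  stained <- masks@labels %in%
    match(.tissueClasses(masks@stainMode), masks@classNames)
  stained <- matrix(stained, d[1], d[2])
  tileArea <- tabulate(tid, nT)
  secPx <- tabulate(tid[section@section], nT)
  stPx <- tabulate(tid[stained & section@section], nT)
  coverage <- secPx / tileArea
  included <- coverage >= minTileCoverage & secPx > 0L
  dens <- ifelse(included, stPx / pmax(secPx, 1L), NA_real_)
  if (!any(included))
    .stopEmptyMap("no tile reaches the minimum section coverage")
  shape <- function(v) matrix(v, grid@nRows, grid@nCols, byrow = TRUE)
  new("DensityMap",
      density = shape(dens), coverage = shape(coverage),
      sectionPx = shape(secPx), included = shape(included),
      tau = tau, minTileCoverage = minTileCoverage, grid = grid)
}

#' Mean pulmonary tissue density
#'
#' The mean of per-microtile density values over the section: the paper's
#' first morphometric parameter. By default tiles are averaged unweighted;
#' \code{weighted = TRUE} weights each tile by its section pixel count
#' (equivalent to a per-pixel mean over the section).
#'
#' @param dmap a \code{\linkS4class{DensityMap}}.
#' @param weighted weight tiles by section pixels (default \code{FALSE}).
#' @return A fraction in [0, 1].
#' @export
meanTissueDensity <- function(dmap, weighted = FALSE) {
  stopifnot(is(dmap, "DensityMap"))
  inc <- dmap@included
  if (!any(inc)) .stopEmptyMap("density map has no included tiles")
  if (weighted) {
    w <- dmap@sectionPx[inc]
    sum(dmap@density[inc] * w) / sum(w)
  } else {
    mean(dmap@density[inc])
  }
}

#' Fibrosis score
#'
#' The percentage of included microtiles whose density strictly exceeds
#' \code{tau} (default the map's stored threshold, 0.75): high densities
#' are specifically expressed in fibrotic areas, so this percentage is a
#' continuous section-level severity score. With
#' \code{denominator = "all"} the percentage is taken over all grid tiles
#' instead of section-covered ones.
#'
#' @param dmap a \code{\linkS4class{DensityMap}}.
#' @param tau density threshold; strict \code{>} comparison.
#' @param denominator \code{"included"} (default) or \code{"all"}.
#' @return A percentage in [0, 100].
#' @export
fibrosisScore <- function(dmap, tau = NULL,
                          denominator = c("included", "all")) {
  stopifnot(is(dmap, "DensityMap"))
  denominator <- match.arg(denominator)
  if (is.null(tau)) tau <- dmap@tau
  inc <- dmap@included
  if (!any(inc)) .stopEmptyMap("density map has no included tiles")
  nHigh <- sum(dmap@density[inc] > tau)
  nDen <- if (denominator == "included") sum(inc) else length(inc)
  100 * nHigh / nDen
}

#' Stain-class area fraction of the section
#'
#' The ratio of class pixels inside the analyzable section to the section
#' area, as a percentage — e.g. picrosirius-red collagen content, alcian
#' blue mucus percentage, or CD68 immunopositive percentage. Mucus pixels
#' lie inside the section outline (they occupy airspace within the
#' section), so the mucus fraction is computed against the same section
#' denominator as collagen.
#'
#' @param masks a \code{\linkS4class{StainMasks}}.
#' @param cls a class name valid for the stain mode.
#' @param section a \code{\linkS4class{SectionMask}}.
#' @return A percentage in [0, 100].
#' @export
areaFraction <- function(masks, cls, section) {
  stopifnot(is(masks, "StainMasks"), is(section, "SectionMask"))
  if (section@sectionAreaPx == 0L) .stopEmptySection("section is empty")
  m <- classMask(masks, cls)   # validates cls
  100 * sum(m & section@section) / section@sectionAreaPx
}
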
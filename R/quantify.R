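#' MorphometryResult: all per-section metrics from one quantification run
#'
#' @slot slideId slide identifier.
#' @slot stainMode \code{"PSR_AB"} or \code{"IHC_CD68"}.
#' @slot meanTissueDensity fraction in [0, 1].
#' @slot fibrosisScorePct percentage of microtiles with density > tau.
#' @slot collagenPct,mucusPct,cd68Pct area fractions in percent
#'   (\code{NA} where not applicable to the stain mode).
#' @slot sectionAreaPx,sectionAreaMm2 analyzable section area.
#' @slot excludedLuminaAreaPx excluded lumen + wall pixels.
#' @slot tileEdgePx microtile edge used.
#' @slot nTilesIncluded number of section-covered microtiles.
#' @slot tau fibrosis-density threshold used.
#' @export
setClass("MorphometryResult",
  representation(
    slideId = "character", stainMode = "character",
    meanTissueDensity = "numeric", fibrosisScorePct = "numeric",
    collagenPct = "numeric", mucusPct = "numeric", cd68Pct = "numeric",
    sectionAreaPx = "integer", sectionAreaMm2 = "numeric",
    excludedLuminaAreaPx = "integer",
    tileEdgePx = "integer", nTilesIncluded = "integer", tau = "numeric"
  )
)

setValidity("MorphometryResult", function(object) {
  msgs <- character(0)
  inRange <- function(v, lo, hi) is.na(v) || (v >= lo && v <= hi)
  if (!inRange(object@meanTissueDensity, 0, 1))
    msgs <- c(msgs, "meanTissueDensity must lie in [0, 1]")
  for (nm in c("fibrosisScorePct", "collagenPct", "mucusPct", "cd68Pct"))
    if (!inRange(slot(object, nm), 0, 100))
      msgs <- c(msgs, sprintf("%s must lie in [0, 100]", nm))
  if (!is.na(object@collagenPct) && !is.na(object@mucusPct) &&
      object@collagenPct + object@mucusPct > 100)
    msgs <- c(msgs, "collagenPct + mucusPct cannot exceed 100")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MorphometryResult", function(object) {
  cat(sprintf("MorphometryResult '%s' (%s)\n", object@slideId,
              object@stainMode))
  cat(sprintf("  mean tissue density : %.4f\n", object@meanTissueDensity))
  cat(sprintf("  fibrosis score      : %.2f %% (tau = %.2f)\n",
              object@fibrosisScorePct, object@tau))
  if (!is.na(object@collagenPct))
    cat(sprintf("  collagen content    : %.2f %%\n", object@collagenPct))
  if (!is.na(object@mucusPct))
    cat(sprintf("  mucus               : %.2f %%\n", object@mucusPct))
  if (!is.na(object@cd68Pct))
    cat(sprintf("  CD68 positive area  : %.2f %%\n", object@cd68Pct))
  cat(sprintf("  section area        : %d px (%.3f mm^2), %d px excluded lumina\n",
              object@sectionAreaPx, object@sectionAreaMm2,
              object@excludedLuminaAreaPx))
  cat(sprintf("  microtiles          : %d included, edge %d px\n",
              object@nTilesIncluded, object@tileEdgePx))
})

#' Coerce a MorphometryResult to a one-row data.frame
#'
#' @param x a \code{\linkS4class{MorphometryResult}}.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return A one-row \code{data.frame} with snake_case metric columns.
#' @export
as.data.frame.MorphometryResult <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(
    slide_id = x@slideId, stain_mode = x@stainMode,
    mean_tissue_density = x@meanTissueDensity,
    fibrosis_score_pct = x@fibrosisScorePct,
    collagen_pct = x@collagenPct, mucus_pct = x@mucusPct,
    cd68_pct = x@cd68Pct,
    section_area_px = x@sectionAreaPx,
    section_area_mm2 = x@sectionAreaMm2,
    excluded_lumina_area_px = x@excludedLuminaAreaPx,
    tile_edge_px = x@tileEdgePx, n_tiles_included = x@nTilesIncluded,
    tau = x@tau, stringsAsFactors = FALSE)
}

#' Quantification configuration
#'
#' Bundles every tunable parameter of \code{\link{quantifySection}} with
#' the package defaults. \code{tileEdgeUm = 50} gives the default microtile
#' (about 111 px at 0.452 um/px); pass \code{tileEdgePx} to fix the edge in
#' pixels instead.
#'
#' @param profile a \code{\linkS4class{StainProfile}} or \code{NULL} for
#'   the stain mode's default.
#' @param tileEdgeUm microtile edge in microns (default 50).
#' @param tileEdgePx microtile edge in pixels; overrides \code{tileEdgeUm}.
#' @param tau fibrosis-density threshold, strict \code{>} (default 0.75).
#' @param minTileCoverage tile inclusion cutoff (default 0.5).
#' @param minObjectAreaPx smallest tissue fragment kept (default 500).
#' @param closingRadiusPx section closing radius (default 2).
#' @param minLumenAreaMm2 lumen exclusion cutoff in mm^2 (default 0.05).
#' @param wallDilationUm excluded wall band width in microns (default 20).
#' @param mucusAsSection keep mucus pixels inside the section denominator
#'   (default \code{TRUE}: mucus occupies airspace within the section);
#'   \code{FALSE} removes them from the denominator as well.
#' @param weightedMean weight tiles by section pixels in the mean density
#'   (default \code{FALSE}).
#' @param fibrosisDenominator \code{"included"} (default) or \code{"all"}.
#' @return A named list of class \code{"fqQuantConfig"}.
#' @export
quantConfig <- function(profile = NULL, tileEdgeUm = 50, tileEdgePx = NULL,
                        tau = 0.75, minTileCoverage = 0.5,
                        minObjectAreaPx = 500, closingRadiusPx = 2,
                        minLumenAreaMm2 = 0.05, wallDilationUm = 20,
                        mucusAsSection = TRUE, weightedMean = FALSE,
                        fibrosisDenominator = c("included", "all")) {
  structure(list(
    profile = profile, tileEdgeUm = tileEdgeUm, tileEdgePx = tileEdgePx,
    tau = tau, minTileCoverage = minTileCoverage,
    minObjectAreaPx = minObjectAreaPx, closingRadiusPx = closingRadiusPx,
    minLumenAreaMm2 = minLumenAreaMm2, wallDilationUm = wallDilationUm,
    mucusAsSection = mucusAsSection, weightedMean = weightedMean,
    fibrosisDenominator = match.arg(fibrosisDenominator)),
    class = "fqQuantConfig")
}

#' Quantify one stained section end to end
#'
#' Runs the full pipeline on a single slide — pixel classification, section
#' segmentation, large-lumen exclusion, microtile density mapping — and
#' returns every per-section metric from the same section in one call:
#' mean tissue density, fibrosis score, and the collagen/mucus (PSR_AB) or
#' CD68 (IHC_CD68) area fractions. Every step is a deterministic function
#' of the pixel data and the configuration, so repeated runs are
#' bit-identical.
#'
#' @param slide a \code{\linkS4class{SlideImage}}.
#' @param config a \code{\link{quantConfig}} list.
#' @param keepIntermediates also return the masks, section and density map.
#' @return A \code{\linkS4class{MorphometryResult}}, or (with
#'   \code{keepIntermediates = TRUE}) a list with elements \code{result},
#'   \code{masks}, \code{section}, \code{dmap}.
#' @examples
#' gt <- generateSection(syntheticSpec(width = 220, height = 220,
#'                                     micronsPerPixel = 1.8, seed = 7))
#' quantifySection(gt$slide, quantConfig(tileEdgePx = 20))
#' @export
quantifySection <- function(slide, config = quantConfig(),
                            keepIntermediates = FALSE) {
  stopifnot(is(slide, "SlideImage"), inherits(config, "fqQuantConfig"))
  tryCatch({
    masks <- classifyPixels(slide, config$profile)
    section <- sectionMask(masks, config$minObjectAreaPx,
                           config$closingRadiusPx)
    section <- excludeLargeLumina(section, config$minLumenAreaMm2,
                                  config$wallDilationUm,
                                  slide@micronsPerPixel)
    if (slide@stainMode == "PSR_AB" && !config$mucusAsSection) {
      sec <- section@section & !classMask(masks, "mucus_blue")
      section <- new("SectionMask", section = sec,
                     excludedLumina = section@excludedLumina,
                     tissue = section@tissue,
                     sectionAreaPx = as.integer(sum(sec)))
    }
    edge <- if (!is.null(config$tileEdgePx)) config$tileEdgePx
            else max(1L, round(config$tileEdgeUm / slide@micronsPerPixel))
    grid <- buildTileGrid(nrow(masks@labels), ncol(masks@labels), edge)
    dmap <- densityMap(masks, section, grid, config$minTileCoverage,
                       config$tau)
    psr <- slide@stainMode == "PSR_AB"
    res <- new("MorphometryResult",
      slideId = slide@slideId, stainMode = slide@stainMode,
      meanTissueDensity = meanTissueDensity(dmap, config$weightedMean),
      fibrosisScorePct = fibrosisScore(dmap, config$tau,
                                       config$fibrosisDenominator),
      collagenPct = if (psr) areaFraction(masks, "collagen_red", section)
                    else NA_real_,
      mucusPct = if (psr) areaFraction(masks, "mucus_blue", section)
                 else NA_real_,
      cd68Pct = if (!psr)
                  areaFraction(masks, "immunopositive_brown", section)
                else NA_real_,
      sectionAreaPx = section@sectionAreaPx,
      sectionAreaMm2 = section@sectionAreaPx *
        slide@micronsPerPixel^2 / 1e6,
      excludedLuminaAreaPx = as.integer(sum(section@excludedLumina)),
      tileEdgePx = as.integer(edge),
      nTilesIncluded = as.integer(sum(dmap@included)),
      tau = config$tau)
    if (keepIntermediates)
      list(result = res, masks = masks, section = section, dmap = dmap)
    else res
  }, fqError = function(e) {
    # re-raise with slide context, keeping the condition class
    stop(errorCondition(
      sprintf("slide '%s': %s", slide@slideId, conditionMessage(e)),
      class = class(e)))
  })
}
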
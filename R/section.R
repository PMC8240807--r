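#' SectionMask: the analyzable section area of a slide
#'
#' The section footprint is the outline of the tissue section including its
#' enclosed airspaces (alveoli, small lumina): density is defined as stained
#' tissue over section area, so open airspace inside the section must count
#' in the denominator. \code{\link{excludeLargeLumina}} subsequently removes
#' large airway/vessel lumina (and a surrounding wall band) from the
#' analyzable area.
#'
#' @slot section logical \code{H x W} raster of analyzable section area.
#' @slot excludedLumina logical raster of excluded lumen + wall pixels
#'   (disjoint from \code{section}).
#' @slot tissue logical raster of stained (non-background) pixels after
#'   cleaning; used to locate interior airspace holes.
#' @slot sectionAreaPx integer, \code{sum(section)}.
#' @export
setClass("SectionMask",
  representation(section = "matrix", excludedLumina = "matrix",
                 tissue = "matrix", sectionAreaPx = "integer")
)

setValidity("SectionMask", function(object) {
  msgs <- character(0)
  if (!is.logical(object@section) || !is.logical(object@excludedLumina))
    msgs <- c(msgs, "section and excludedLumina must be logical matrices")
  else {
    if (any(object@section & object@excludedLumina))
      msgs <- c(msgs, "section and excludedLumina must be disjoint")
    if (object@sectionAreaPx != sum(object@section))
      msgs <- c(msgs, "sectionAreaPx inconsistent with section raster")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SectionMask", function(object) {
  d <- dim(object@section)
  cat(sprintf(
    "SectionMask: %d x %d px; section %d px (%.1f%%), excluded lumina %d px\n",
    d[1], d[2], object@sectionAreaPx,
    100 * object@sectionAreaPx / prod(d), sum(object@excludedLumina)))
})

#' @rdname SectionMask
#' @param x a \code{SectionMask}.
#' @export
setGeneric("sectionArea", function(x) standardGeneric("sectionArea"))

#' @rdname SectionMask
#' @export
setMethod("sectionArea", "SectionMask", function(x) x@sectionAreaPx)

#' Segment the analyzable section area
#'
#' Takes the union of all non-background stain classes, applies a
#' morphological closing to bridge staining gaps, removes connected
#' components smaller than \code{minObjectAreaPx} (debris, specks), and
#' fills interior holes so that enclosed airspaces belong to the section
#' footprint. Large lumina are removed afterwards by
#' \code{\link{excludeLargeLumina}}.
#'
#' @param masks a \code{\linkS4class{StainMasks}}.
#' @param minObjectAreaPx smallest tissue fragment kept, in pixels
#'   (default 500).
#' @param closingRadiusPx closing radius in pixels (default 2).
#' @return A \code{\linkS4class{SectionMask}} with an empty
#'   \code{excludedLumina} raster.
#' @export
sectionMask <- function(masks, minObjectAreaPx = 500, closingRadiusPx = 2) {
  stopifnot(is(masks, "StainMasks"))
  bg <- match("background_white", masks@classNames)
  tissue <- masks@labels != bg
  if (!any(tissue))
    .stopEmptySection("no stained tissue found: section is empty")
  tissue <- .binClose(tissue, closingRadiusPx)
  if (minObjectAreaPx > 1) {
    lab <- .labelComponents(tissue)
    sizes <- tabulate(lab)
    if (length(sizes)) {
      drop <- which(sizes < minObjectAreaPx)
      if (length(drop)) tissue[lab %in% drop] <- FALSE
    }
  }
  if (!any(tissue))
    .stopEmptySection(
      "all tissue fragments fell below minObjectAreaPx: section is empty")
  footprint <- .fillHoles(tissue)
  new("SectionMask", section = footprint,
      excludedLumina = matrix(FALSE, nrow(footprint), ncol(footprint)),
      tissue = tissue, sectionAreaPx = as.integer(sum(footprint)))
}

#' Exclude large airway and vessel lumina from the section
#'
#' Interior background holes of the section whose physical area is at least
#' \code{minLumenAreaMm2} are marked excluded, together with a surrounding
#' wall band of width \code{wallDilationUm}; alveolar-scale holes are left
#' untouched. Excluded pixels leave the analyzable section area.
#'
#' @param section a \code{\linkS4class{SectionMask}}.
#' @param minLumenAreaMm2 lumen area cutoff in mm^2 (default 0.05; the
#'   comparison is \code{>=}).
#' @param wallDilationUm wall band width in microns (default 20).
#' @param micronsPerPixel physical pixel edge in microns.
#' @return An updated \code{\linkS4class{SectionMask}}.
#' @export
excludeLargeLumina <- function(section, minLumenAreaMm2 = 0.05,
                               wallDilationUm = 20, micronsPerPixel = 0.452) {
  stopifnot(is(section, "SectionMask"))
  .assertScalarNum(micronsPerPixel, "micronsPerPixel")
  if (section@sectionAreaPx == 0L)
    .stopEmptySection("section is empty")
  holes <- section@section & !section@tissue
  if (!any(holes)) return(section)
  pxPerMm2 <- 1e6 / micronsPerPixel^2
  minPx <- minLumenAreaMm2 * pxPerMm2
  lab <- .labelComponents(holes)
  sizes <- tabulate(lab)
  big <- which(sizes >= minPx)
  if (!length(big)) return(section)
  lumen <- matrix(lab %in% big, nrow(lab), ncol(lab))
  wallPx <- round(wallDilationUm / micronsPerPixel)
  excluded <- .binDilate(lumen, wallPx) & section@section
  newSection <- section@section & !excluded
  new("SectionMask", section = newSection,
      excludedLumina = section@excludedLumina | excluded,
      tissue = section@tissue,
      sectionAreaPx = as.integer(sum(newSection)))
}
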
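#' Write a pseudocolor QC overlay
#'
#' Renders a PNG the same size as the slide for visual quality control:
#' \describe{
#'   \item{fibrosis}{the original image with microtiles of density > tau
#'     painted orange (the quantified fibrotic area) and mucus painted
#'     green (excluded from quantification).}
#'   \item{collagen}{collagen red, other parenchymal tissue gray, mucus in
#'     its stain color, airspace/background white — the collagen-content
#'     view.}
#'   \item{density}{a per-tile heat map of density from white (0) through
#'     orange to dark red (1).}
#' }
#'
#' @param slide a \code{\linkS4class{SlideImage}}.
#' @param masks \code{\linkS4class{StainMasks}} derived from the slide.
#' @param dmap \code{\linkS4class{DensityMap}} derived from the slide.
#' @param mode \code{"fibrosis"}, \code{"collagen"} or \code{"density"}.
#' @param path output PNG path.
#' @return Invisibly, \code{path}.
#' @export
writeOverlay <- function(slide, masks, dmap,
                         mode = c("fibrosis", "collagen", "density"),
                         path) {
  mode <- match.arg(mode)
  stopifnot(is(slide, "SlideImage"), is(masks, "StainMasks"),
            is(dmap, "DensityMap"))
  d <- dim(slide@pixels)[1:2]
  if (!identical(d, dim(masks@labels)) ||
      dmap@grid@heightPx != d[1] || dmap@grid@widthPx != d[2])
    .stopValidation("slide, masks and density map geometries differ")

  out <- array(slide@pixels / 255, dim = c(d, 3L))
  paintPx <- function(mask, rgb) {
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[mask] <- rgb[ch] / 255
      out[, , ch] <<- plane
    }
  }
  tid <- tileIndexMatrix(dmap@grid)

  if (mode == "fibrosis") {
    high <- dmap@included & !is.na(dmap@density) & dmap@density > dmap@tau
    highIds <- which(t(high))          # row-major tile ids
    paintPx(matrix(tid %in% highIds, d[1], d[2]), c(255, 140, 0))
    if (masks@stainMode == "PSR_AB")
      paintPx(classMask(masks, "mucus_blue"), c(0, 160, 60))
  } else if (mode == "collagen") {
    out[] <- 1
    if (masks@stainMode == "PSR_AB") {
      paintPx(classMask(masks, "parenchyma_yellow"), c(150, 150, 150))
      paintPx(classMask(masks, "mucus_blue"), .stainPalette["mucus_blue", ])
      paintPx(classMask(masks, "collagen_red"), c(200, 30, 40))
    } else {
      paintPx(classMask(masks, "counterstain_blue"), c(150, 150, 150))
      paintPx(classMask(masks, "immunopositive_brown"), c(200, 30, 40))
    }
  } else {
    out[] <- 1
    ramp <- colorRamp(c("white", "orange", "darkred"))
    dens <- dmap@density
    inc <- dmap@included & !is.na(dens)
    for (id in which(t(inc))) {
      tr <- (id - 1L) %/% dmap@grid@nCols + 1L
      tc <- (id - 1L) %% dmap@grid@nCols + 1L
      ext <- tileExtent(dmap@grid, tr, tc)
      col <- ramp(dens[tr, tc]) / 255
      for (ch in 1:3) out[ext$rows, ext$cols, ch] <- col[ch]
    }
  }

  ok <- tryCatch({ png::writePNG(out, target = path); TRUE },
                 error = function(e) FALSE)
  if (!ok) .stopIO(sprintf("cannot write overlay to %s", path))
  invisible(path)
}
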
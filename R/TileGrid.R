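#' TileGrid: the microtile partition of a slide
#'
#' A regular square grid of microtiles covering the image exactly once.
#' Interior tiles are \code{tileEdgePx} square; tiles in the last row or
#' column may be smaller (their density uses their true pixel count as
#' denominator). Tiles are indexed row-major.
#'
#' @slot heightPx,widthPx image dimensions in pixels.
#' @slot tileEdgePx tile edge in pixels.
#' @slot nRows,nCols grid dimensions.
#' @export
setClass("TileGrid",
  representation(
    heightPx = "integer", widthPx = "integer",
    tileEdgePx = "integer", nRows = "integer", nCols = "integer"
  )
)

setValidity("TileGrid", function(object) {
  msgs <- character(0)
  if (object@heightPx < 1L || object@widthPx < 1L || object@tileEdgePx < 1L)
    msgs <- c(msgs, "heightPx, widthPx, tileEdgePx must all be >= 1")
  if (object@nRows != ceiling(object@heightPx / object@tileEdgePx) ||
      object@nCols != ceiling(object@widthPx / object@tileEdgePx))
    msgs <- c(msgs, "nRows/nCols inconsistent with image size and tile edge")
  if (length(msgs)) msgs else TRUE
})

#' Build the microtile grid for an image
#'
#' @param heightPx,widthPx image dimensions in pixels (>= 1).
#' @param tileEdgePx tile edge in pixels (>= 1). The package default at
#'   quantification time is \code{round(50 / micronsPerPixel)}, i.e. a
#'   50-micron microtile (about 111 px at 0.452 um/px).
#' @return A \code{\linkS4class{TileGrid}}.
#' @examples
#' buildTileGrid(1050, 1000, 100)  # 11 x 10 grid, last-row tiles 50 px tall
#' @export
buildTileGrid <- function(heightPx, widthPx, tileEdgePx) {
  for (nm in c("heightPx", "widthPx", "tileEdgePx")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      .stopValidation(sprintf("'%s' must be a positive integer", nm))
  }
  new("TileGrid",
      heightPx = as.integer(heightPx), widthPx = as.integer(widthPx),
      tileEdgePx = as.integer(tileEdgePx),
      nRows = as.integer(ceiling(heightPx / tileEdgePx)),
      nCols = as.integer(ceiling(widthPx / tileEdgePx)))
}

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d x %d tiles of %d px over a %d x %d px image\n",
              object@nRows, object@nCols, object@tileEdgePx,
              object@heightPx, object@widthPx))
})

#' Per-pixel tile index matrix
#'
#' Maps every pixel to its (row-major) tile id in 1..nRows*nCols. Every
#' pixel belongs to exactly one tile.
#'
#' @param grid a \code{\linkS4class{TileGrid}}.
#' @return Integer \code{H x W} matrix of tile ids.
#' @export
tileIndexMatrix <- function(grid) {
  stopifnot(is(grid, "TileGrid"))
  rt <- ceiling(seq_len(grid@heightPx) / grid@tileEdgePx)
  ct <- ceiling(seq_len(grid@widthPx) / grid@tileEdgePx)
  m <- outer(rt - 1L, ct, function(a, b) a * grid@nCols + b)
  storage.mode(m) <- "integer"
  m
}

#' Pixel extents of one tile
#'
#' @param grid a \code{\linkS4class{TileGrid}}.
#' @param tileRow,tileCol 1-based tile coordinates.
#' @return List with inclusive pixel ranges \code{rows} and \code{cols}.
#' @export
tileExtent <- function(grid, tileRow, tileCol) {
  stopifnot(is(grid, "TileGrid"),
            tileRow >= 1, tileRow <= grid@nRows,
            tileCol >= 1, tileCol <= grid@nCols)
  e <- grid@tileEdgePx
  list(rows = (((tileRow - 1L) * e + 1L):min(tileRow * e, grid@heightPx)),
       cols = (((tileCol - 1L) * e + 1L):min(tileCol * e, grid@widthPx)))
}
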
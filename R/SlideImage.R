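#' SlideImage: an RGB whole-slide raster with physical pixel size
#'
#' The unit of analysis: one stained lung section as an 8-bit RGB raster
#' plus the physical pixel size in microns. \code{stainMode} selects the
#' stain chemistry the classifier expects: \code{"PSR_AB"} (picrosirius red
#' with alcian blue counter-discrimination of mucus) or \code{"IHC_CD68"}
#' (DAB chromogen on hematoxylin counterstain).
#'
#' @slot pixels integer array \code{H x W x 3}, values in [0, 255].
#' @slot micronsPerPixel positive numeric; physical edge of one pixel in
#'   microns (the reference acquisition uses 0.452 um at 20x).
#' @slot slideId character identifier.
#' @slot stainMode \code{"PSR_AB"} or \code{"IHC_CD68"}.
#'
#' @seealso \code{\link{readSlide}}, \code{\link{quantifySection}}
#' @export
setClass("SlideImage",
  representation(
    pixels = "array",
    micronsPerPixel = "numeric",
    slideId = "character",
    stainMode = "character"
  )
)

.validSlideImage <- function(object) {
  msgs <- character(0)
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msgs <- c(msgs, "pixels must be an H x W x 3 array")
  else if (d[1] < 1L || d[2] < 1L)
    msgs <- c(msgs, "image must be at least 1 x 1")
  rng <- range(object@pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    msgs <- c(msgs, "pixel values must lie in [0, 255]")
  if (length(object@micronsPerPixel) != 1L ||
      !is.finite(object@micronsPerPixel) || object@micronsPerPixel <= 0)
    msgs <- c(msgs, "micronsPerPixel must be a positive scalar")
  if (!object@stainMode %in% c("PSR_AB", "IHC_CD68"))
    msgs <- c(msgs, "stainMode must be 'PSR_AB' or 'IHC_CD68'")
  if (length(msgs)) msgs else TRUE
}
setValidity("SlideImage", .validSlideImage)

#' Construct a SlideImage from an in-memory array
#'
#' @param pixels numeric or integer \code{H x W x 3} array with values in
#'   [0, 255].
#' @param micronsPerPixel physical pixel edge in microns (default 0.452).
#' @param slideId slide identifier.
#' @param stainMode \code{"PSR_AB"} or \code{"IHC_CD68"}.
#' @return A \code{\linkS4class{SlideImage}}.
#' @export
SlideImage <- function(pixels, micronsPerPixel = 0.452, slideId = "slide",
                       stainMode = c("PSR_AB", "IHC_CD68")) {
  stainMode <- match.arg(stainMode)
  if (is.numeric(micronsPerPixel) && length(micronsPerPixel) == 1L &&
      is.finite(micronsPerPixel) && micronsPerPixel <= 0)
    .stopValidation("micronsPerPixel must be > 0")
  px <- round(pixels)
  storage.mode(px) <- "integer"
  new("SlideImage", pixels = px, micronsPerPixel = micronsPerPixel,
      slideId = as.character(slideId), stainMode = stainMode)
}

#' @describeIn SlideImage raw pixel array accessor
#' @param x,object a \code{SlideImage}.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname SlideImage
#' @export
setMethod("pixels", "SlideImage", function(x) x@pixels)

#' @rdname SlideImage
#' @export
setGeneric("micronsPerPixel", function(x) standardGeneric("micronsPerPixel"))

#' @rdname SlideImage
#' @export
setMethod("micronsPerPixel", "SlideImage", function(x) x@micronsPerPixel)

#' @rdname SlideImage
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' @rdname SlideImage
#' @export
setMethod("slideId", "SlideImage", function(x) x@slideId)

#' @rdname SlideImage
#' @export
setGeneric("stainMode", function(x) standardGeneric("stainMode"))

#' @rdname SlideImage
#' @export
setMethod("stainMode", "SlideImage", function(x) x@stainMode)

#' @rdname SlideImage
#' @export
setMethod("dim", "SlideImage", function(x) dim(x@pixels)[1:2])

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SlideImage '%s': %d x %d px (%.3f x %.3f mm), %s, %.3f um/px\n",
              object@slideId, d[1], d[2],
              d[1] * object@micronsPerPixel / 1000,
              d[2] * object@micronsPerPixel / 1000,
              object@stainMode, object@micronsPerPixel))
})

#' Read a stained-section image from disk
#'
#' Reads an 8-bit RGB PNG or TIFF. Alpha channels are dropped; grayscale or
#' otherwise non-RGB images are rejected (stain classification needs three
#' channels).
#'
#' @param path path to a PNG or TIFF file.
#' @param micronsPerPixel physical pixel edge in microns (default 0.452).
#' @param stainMode \code{"PSR_AB"} or \code{"IHC_CD68"}.
#' @param slideId identifier; defaults to the file name without extension.
#' @return A \code{\linkS4class{SlideImage}}.
#' @examples
#' f <- tempfile(fileext = ".png")
#' gt <- generateSection(syntheticSpec(width = 64, height = 64, seed = 1))
#' writeSlide(gt$slide, f)
#' readSlide(f, micronsPerPixel = 0.452)
#' @export
readSlide <- function(path, micronsPerPixel = 0.452,
                      stainMode = c("PSR_AB", "IHC_CD68"),
                      slideId = NULL) {
  stainMode <- match.arg(stainMode)
  .assertScalarNum(micronsPerPixel, "micronsPerPixel")
  if (!file.exists(path))
    .stopIO(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) .stopFormat(conditionMessage(e))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) .stopFormat(conditionMessage(e))),
    .stopFormat(sprintf("unsupported image format '.%s' (PNG or TIFF)", ext))
  )
  if (length(dim(img)) < 3L || dim(img)[3] < 3L)
    .stopFormat("image is not RGB: a 3-channel raster is required")
  img <- img[, , 1:3, drop = FALSE]  # drop alpha if present
  if (is.null(slideId))
    slideId <- tools::file_path_sans_ext(basename(path))
  SlideImage(round(img * 255), micronsPerPixel = micronsPerPixel,
             slideId = slideId, stainMode = stainMode)
}

#' Write a SlideImage to a PNG file
#'
#' @param slide a \code{\linkS4class{SlideImage}}.
#' @param path output path (PNG).
#' @return Invisibly, \code{path}.
#' @export
writeSlide <- function(slide, path) {
  stopifnot(is(slide, "SlideImage"))
  ok <- tryCatch({
    png::writePNG(slide@pixels / 255, target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .stopIO(sprintf("cannot write PNG to %s", path))
  invisible(path)
}
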
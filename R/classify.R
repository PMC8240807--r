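#' StainMasks: the per-pixel stain-class partition of a slide
#'
#' Every pixel belongs to exactly one class (mutually exclusive, jointly
#' exhaustive); the partition is stored as an integer label matrix indexed
#' into \code{classNames}. Use \code{\link{classMask}} to extract one class
#' as a logical raster.
#'
#' @slot labels integer \code{H x W} matrix of class indices.
#' @slot classNames character vector of class names (tie-break priority
#'   order, background last).
#' @slot stainMode \code{"PSR_AB"} or \code{"IHC_CD68"}.
#' @export
setClass("StainMasks",
  representation(labels = "matrix", classNames = "character",
                 stainMode = "character")
)

setValidity("StainMasks", function(object) {
  msgs <- character(0)
  if (!is.integer(object@labels))
    msgs <- c(msgs, "labels must be an integer matrix")
  rng <- range(object@labels)
  if (rng[1] < 1L || rng[2] > length(object@classNames))
    msgs <- c(msgs, "labels out of range of classNames")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StainMasks", function(object) {
  d <- dim(object@labels)
  cat(sprintf("StainMasks (%s): %d x %d px\n", object@stainMode, d[1], d[2]))
  tab <- tabulate(object@labels, length(object@classNames))
  for (k in seq_along(object@classNames))
    cat(sprintf("  %-20s %9d px (%5.1f%%)\n", object@classNames[k], tab[k],
                100 * tab[k] / prod(d)))
})

#' @rdname StainMasks
#' @param x a \code{StainMasks}.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname StainMasks
#' @export
setMethod("classNames", "StainMasks", function(x) x@classNames)

#' @rdname StainMasks
#' @export
setMethod("dim", "StainMasks", function(x) dim(x@labels))

#' Extract one stain class as a logical raster
#'
#' @param masks a \code{\linkS4class{StainMasks}}.
#' @param cls class name, e.g. \code{"collagen_red"}.
#' @return Logical \code{H x W} matrix.
#' @export
classMask <- function(masks, cls) {
  stopifnot(is(masks, "StainMasks"))
  k <- match(cls, masks@classNames)
  if (is.na(k))
    .stopValidation(sprintf("unknown class '%s' for mode %s (classes: %s)",
                            cls, masks@stainMode,
                            paste(masks@classNames, collapse = ", ")))
  masks@labels == k
}

#' Per-class pixel counts
#'
#' @param masks a \code{\linkS4class{StainMasks}}.
#' @return Named integer vector; counts sum to \code{H * W}.
#' @export
classCounts <- function(masks) {
  stopifnot(is(masks, "StainMasks"))
  setNames(tabulate(masks@labels, length(masks@classNames)),
           masks@classNames)
}

#' Classify every pixel of a slide into a stain class
#'
#' Assignment rule: (1) pixels at or above the profile's background
#' luminance with channel spread at or below the saturation cutoff are
#' background; (2) otherwise the pixel is compared, by cosine similarity of
#' its RGB direction, against each class's reference chromaticity, and is
#' assigned to the angularly nearest class among those meeting their
#' acceptance threshold; (3) ties resolve by the profile's fixed class
#' priority order; (4) pixels passing no threshold fall to background.
#' The mapping is a pure function of the pixel value, so classification is
#' deterministic and translation-invariant.
#'
#' @param slide a \code{\linkS4class{SlideImage}}.
#' @param profile a \code{\linkS4class{StainProfile}}; defaults to
#'   \code{defaultStainProfile(stainMode(slide))}.
#' @return A \code{\linkS4class{StainMasks}}.
#' @export
classifyPixels <- function(slide, profile = NULL) {
  stopifnot(is(slide, "SlideImage"))
  if (is.null(profile)) profile <- defaultStainProfile(slide@stainMode)
  stopifnot(is(profile, "StainProfile"))
  if (profile@stainMode != slide@stainMode)
    .stopValidation(sprintf("profile stain mode (%s) != slide stain mode (%s)",
                            profile@stainMode, slide@stainMode))

  d <- dim(slide@pixels)
  n <- d[1] * d[2]
  px <- matrix(as.numeric(slide@pixels), n, 3L)

  lum <- rowMeans(px)
  mx <- pmax(px[, 1], px[, 2], px[, 3])
  mn <- pmin(px[, 1], px[, 2], px[, 3])
  isBg <- lum >= profile@backgroundLuminance &
    (mx - mn) <= profile@saturationSpread

  cls <- rownames(profile@referenceRGB)
  bgIdx <- match("background_white", cls)
  ref <- profile@referenceRGB /
    sqrt(rowSums(profile@referenceRGB^2))        # unit chromaticities
  nrm <- sqrt(rowSums(px^2))
  nrm[nrm == 0] <- Inf                           # black: fails all classes
  cosSim <- (px / nrm) %*% t(ref)                # n x K

  pass <- sweep(cosSim, 2L, profile@thresholds[cls], ">=")
  score <- ifelse(pass, cosSim, -Inf)
  lab <- max.col(score, ties.method = "first")   # columns in priority order
  lab[!is.finite(score[cbind(seq_len(n), lab)])] <- bgIdx
  lab[isBg] <- bgIdx

  labels <- matrix(as.integer(lab), d[1], d[2])
  new("StainMasks", labels = labels, classNames = cls,
      stainMode = slide@stainMode)
}

#' Mucus raster of a PSR_AB slide
#'
#' Returns the alcian-blue mucus class as a logical raster. Downstream
#' density and collagen computations treat these pixels as airspace (they
#' stay inside the section outline but never count as stained tissue) —
#' the point of adding alcian blue to picrosirius red.
#'
#' @param masks a \code{\linkS4class{StainMasks}} in PSR_AB mode.
#' @return Logical \code{H x W} matrix.
#' @export
mucusMask <- function(masks) {
  stopifnot(is(masks, "StainMasks"))
  if (masks@stainMode != "PSR_AB")
    .stopValidation("mucusMask is defined only for PSR_AB slides")
  classMask(masks, "mucus_blue")
}

#' Export the class partition as an 8-bit label PNG with a JSON legend
#'
#' @param masks a \code{\linkS4class{StainMasks}}.
#' @param path output PNG path; the legend is written to
#'   \code{paste0(path, ".json")}.
#' @return Invisibly, \code{path}.
#' @export
writeLabelImage <- function(masks, path) {
  stopifnot(is(masks, "StainMasks"))
  png::writePNG((masks@labels - 1L) / 255, target = path)
  legend <- setNames(as.list(seq_along(masks@classNames) - 1L),
                     masks@classNames)
  jsonlite::write_json(legend, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
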
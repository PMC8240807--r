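#' StainProfile: reference chromaticities and thresholds for pixel classes
#'
#' A stain profile holds, for every pixel class of a stain mode, a reference
#' RGB chromaticity (unit-length direction in RGB space) and an acceptance
#' threshold expressed as a minimum cosine similarity in (0, 1]. A pixel is
#' assigned to the passing class whose chromaticity is angularly nearest;
#' bright low-saturation pixels are assigned to background by a luminance
#' rule before any chromatic comparison. Classes are listed in tie-break
#' priority order (collagen > mucus > parenchyma > counterstain >
#' immunopositive > background).
#'
#' @slot referenceRGB numeric matrix, one row per class, columns R,G,B in
#'   [0,255]; rows carry the class names.
#' @slot thresholds named numeric vector of minimum cosine similarities.
#' @slot backgroundLuminance integer in [0,255]: mean-channel luminance at
#'   or above which a low-saturation pixel is background.
#' @slot saturationSpread maximum channel spread (max - min) for the
#'   background rule.
#' @slot stainMode \code{"PSR_AB"} or \code{"IHC_CD68"}.
#' @export
setClass("StainProfile",
  representation(
    referenceRGB = "matrix",
    thresholds = "numeric",
    backgroundLuminance = "numeric",
    saturationSpread = "numeric",
    stainMode = "character"
  )
)

setValidity("StainProfile", function(object) {
  msgs <- character(0)
  if (ncol(object@referenceRGB) != 3L)
    msgs <- c(msgs, "referenceRGB must have 3 columns (R,G,B)")
  if (is.null(rownames(object@referenceRGB)))
    msgs <- c(msgs, "referenceRGB rows must be named by class")
  if (!identical(sort(names(object@thresholds)),
                 sort(rownames(object@referenceRGB))))
    msgs <- c(msgs, "thresholds must be named for every class")
  if (any(object@thresholds <= 0 | object@thresholds > 1))
    msgs <- c(msgs, "thresholds must lie in (0, 1]")
  if (object@backgroundLuminance < 0 || object@backgroundLuminance > 255)
    msgs <- c(msgs, "backgroundLuminance must lie in [0, 255]")
  if (!object@stainMode %in% c("PSR_AB", "IHC_CD68"))
    msgs <- c(msgs, "stainMode must be 'PSR_AB' or 'IHC_CD68'")
  if (length(msgs)) msgs else TRUE
})

# Reference stain colors (8-bit RGB). These are the package's nominal
# appearance of each stain class and double as the rendering palette of the
# synthetic generator.
.stainPalette <- matrix(c(
  185,  40,  55,   # collagen_red
   70, 165, 165,   # mucus_blue
  225, 175,  90,   # parenchyma_yellow
   95, 110, 175,   # counterstain_blue
  120,  75,  35,   # immunopositive_brown
  248, 248, 248),  # background_white
  ncol = 3, byrow = TRUE,
  dimnames = list(c("collagen_red", "mucus_blue", "parenchyma_yellow",
                    "counterstain_blue", "immunopositive_brown",
                    "background_white"), c("R", "G", "B")))

.classesForMode <- function(stainMode) {
  # priority (tie-break) order; background last
  if (stainMode == "PSR_AB")
    c("collagen_red", "mucus_blue", "parenchyma_yellow", "background_white")
  else
    c("counterstain_blue", "immunopositive_brown", "background_white")
}

#' Default stain profile for a stain mode
#'
#' @param stainMode \code{"PSR_AB"} or \code{"IHC_CD68"}.
#' @param threshold minimum cosine similarity applied to every stain class
#'   (default 0.90); the background class uses 0.98.
#' @param backgroundLuminance luminance cutoff (default 220).
#' @param saturationSpread background channel-spread cutoff (default 45).
#' @return A \code{\linkS4class{StainProfile}}.
#' @export
defaultStainProfile <- function(stainMode = c("PSR_AB", "IHC_CD68"),
                                threshold = 0.90,
                                backgroundLuminance = 220,
                                saturationSpread = 45) {
  stainMode <- match.arg(stainMode)
  cls <- .classesForMode(stainMode)
  ref <- .stainPalette[cls, , drop = FALSE]
  thr <- setNames(rep(threshold, length(cls)), cls)
  thr["background_white"] <- 0.98
  new("StainProfile", referenceRGB = ref, thresholds = thr,
      backgroundLuminance = backgroundLuminance,
      saturationSpread = saturationSpread, stainMode = stainMode)
}

setMethod("show", "StainProfile", function(object) {
  cat(sprintf("StainProfile (%s): %d classes, background luminance >= %g\n",
              object@stainMode, nrow(object@referenceRGB),
              object@backgroundLuminance))
  for (cl in rownames(object@referenceRGB))
    cat(sprintf("  %-20s RGB(%s)  cos >= %.2f\n", cl,
                paste(object@referenceRGB[cl, ], collapse = ","),
                object@thresholds[cl]))
})

#' Serialize a stain profile to JSON
#'
#' @param profile a \code{\linkS4class{StainProfile}}.
#' @param path output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeStainProfile <- function(profile, path) {
  stopifnot(is(profile, "StainProfile"))
  obj <- list(
    stain_mode = profile@stainMode,
    background_luminance = profile@backgroundLuminance,
    saturation_spread = profile@saturationSpread,
    classes = lapply(rownames(profile@referenceRGB), function(cl) {
      list(name = cl, rgb = as.integer(profile@referenceRGB[cl, ]),
           threshold = unname(profile@thresholds[cl]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stain profile from JSON
#'
#' @param path JSON path written by \code{\link{writeStainProfile}}.
#' @return A \code{\linkS4class{StainProfile}}.
#' @export
readStainProfile <- function(path) {
  if (!file.exists(path)) .stopIO(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- vapply(obj$classes, `[[`, character(1), "name")
  ref <- t(vapply(obj$classes,
                  function(x) as.numeric(unlist(x$rgb)), numeric(3)))
  rownames(ref) <- cls
  colnames(ref) <- c("R", "G", "B")
  thr <- setNames(vapply(obj$classes, function(x) as.numeric(x$threshold),
                         numeric(1)), cls)
  new("StainProfile", referenceRGB = ref, thresholds = thr,
      backgroundLuminance = as.numeric(obj$background_luminance),
      saturationSpread = as.numeric(obj$saturation_spread),
      stainMode = obj$stain_mode)
}
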
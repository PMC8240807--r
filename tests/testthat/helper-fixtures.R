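# Shared fixtures: desk-scale synthetic slides (1.8 um/px so that the
# physical lumen-area thresholds stay feasible at a few hundred pixels) and
# a matching quantification config. Structural parameters are fixed here
# once and reused by every test.

smallSpec <- function(seed = 1, ...) {
  args <- list(width = 400, height = 400, micronsPerPixel = 1.8,
               parenchymaFraction = 0.30, collagenFraction = 0.06,
               mucusFraction = 0.015, fibroticFocusFraction = 0.15,
               nLargeLumina = 0, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(syntheticSpec, args)
}

smallConfig <- function(...) {
  args <- list(tileEdgePx = 28, minLumenAreaMm2 = 0.2)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(quantConfig, args)
}

# A uniform-color slide (for classifier contract cases).
flatSlide <- function(rgb, h = 8, w = 8, mode = "PSR_AB", mpp = 0.452) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  SlideImage(px, micronsPerPixel = mpp, slideId = "flat", stainMode = mode)
}

# Build a StainMasks object directly from an integer label matrix.
masksFromLabels <- function(labels, mode = "PSR_AB") {
  cls <- if (mode == "PSR_AB")
    c("collagen_red", "mucus_blue", "parenchyma_yellow", "background_white")
  else c("counterstain_blue", "immunopositive_brown", "background_white")
  storage.mode(labels) <- "integer"
  new("StainMasks", labels = labels, classNames = cls, stainMode = mode)
}

sectionFromLogical <- function(section, tissue = section) {
  new("SectionMask", section = section,
      excludedLumina = matrix(FALSE, nrow(section), ncol(section)),
      tissue = tissue, sectionAreaPx = as.integer(sum(section)))
}

# Independent per-pixel density-map oracle: explicit loops over tile
# extents, no tabulate()-based shortcuts shared with the implementation.
naiveDensityOracle <- function(masks, section, grid, minTileCoverage = 0.5) {
  tissueCls <- if (masks@stainMode == "PSR_AB")
    c("collagen_red", "parenchyma_yellow")
  else c("counterstain_blue", "immunopositive_brown")
  stained <- matrix(FALSE, nrow(masks@labels), ncol(masks@labels))
  for (cl in tissueCls) stained <- stained | classMask(masks, cl)
  dens <- matrix(NA_real_, grid@nRows, grid@nCols)
  inc <- matrix(FALSE, grid@nRows, grid@nCols)
  for (tr in seq_len(grid@nRows)) for (tc in seq_len(grid@nCols)) {
    ext <- tileExtent(grid, tr, tc)
    sec <- section@section[ext$rows, ext$cols]
    nSec <- sum(sec)
    nTile <- length(ext$rows) * length(ext$cols)
    if (nSec > 0 && nSec / nTile >= minTileCoverage) {
      inc[tr, tc] <- TRUE
      dens[tr, tc] <- sum(stained[ext$rows, ext$cols] & sec) / nSec
    }
  }
  list(density = dens, included = inc)
}

# Independent area-fraction oracle.
naiveAreaFraction <- function(masks, cls, section) {
  m <- classMask(masks, cls)
  acc <- 0L
  for (j in seq_len(ncol(m))) acc <- acc + sum(m[, j] & section@section[, j])
  100 * acc / sum(section@section)
}
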
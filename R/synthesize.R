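#' Specification for one synthetic stained section
#'
#' Describes a synthetic slide with known ground truth: an alveolar lattice
#' of parenchyma ribbons around airspaces, dense (airspace-free) fibrotic
#' foci, collagen bundles concentrated in the foci, mucus blobs strictly
#' inside airspaces, optional large airway/vessel lumina with a solid wall
#' collar, and class colors drawn from the stain palette plus Gaussian
#' jitter. Every random stage consumes its own substream derived from
#' \code{seed}, so changing one structural parameter (say, the mucus
#' fraction) leaves all other stages' draws bit-identical — the property
#' the mucus-exclusion and monotonicity tests rely on.
#'
#' @param width,height image size in pixels.
#' @param micronsPerPixel physical pixel edge (default 0.452).
#' @param stainMode \code{"PSR_AB"} or \code{"IHC_CD68"}.
#' @param parenchymaFraction target parenchymal-tissue fraction of total
#'   image area (drives alveolar openness).
#' @param collagenFraction target collagen fraction of total image area.
#' @param mucusFraction target mucus fraction of total image area.
#' @param cd68Fraction target immunopositive fraction (IHC mode).
#' @param fibroticFocusFraction proportion of the section rendered as
#'   dense, airspace-free tissue.
#' @param nLargeLumina number of large airway/vessel lumina to carve.
#' @param lumenRadiusUm range (min, max) of lumen radii in microns.
#' @param alveolusRadiusUm nominal alveolar airspace radius (default 45).
#' @param focusRadiusUm nominal fibrotic-focus radius (default 120).
#' @param colorJitterSd Gaussian per-channel color jitter SD on the 0-255
#'   scale (default 8).
#' @param sectionMarginPx background margin around the section footprint.
#' @param seed integer fixing the full generation stream.
#' @return A list of class \code{"fqSyntheticSpec"}.
#' @export
syntheticSpec <- function(width = 1200, height = 1200,
                          micronsPerPixel = 0.452,
                          stainMode = c("PSR_AB", "IHC_CD68"),
                          parenchymaFraction = 0.42,
                          collagenFraction = 0.08,
                          mucusFraction = 0.02,
                          cd68Fraction = 0.05,
                          fibroticFocusFraction = 0.15,
                          nLargeLumina = 0,
                          lumenRadiusUm = c(130, 180),
                          alveolusRadiusUm = 45,
                          focusRadiusUm = 120,
                          colorJitterSd = 8,
                          sectionMarginPx = 8,
                          seed = 1) {
  stainMode <- match.arg(stainMode)
  if (any(c(parenchymaFraction, collagenFraction, mucusFraction,
            cd68Fraction, fibroticFocusFraction) < 0))
    .stopValidation("target fractions must be >= 0")
  if (parenchymaFraction + collagenFraction + mucusFraction > 1)
    .stopValidation("parenchyma + collagen + mucus fractions exceed 1")
  if (fibroticFocusFraction > 1)
    .stopValidation("fibroticFocusFraction must be <= 1")
  .assertScalarNum(micronsPerPixel, "micronsPerPixel")
  if (width < 2 * sectionMarginPx + 20 || height < 2 * sectionMarginPx + 20)
    .stopValidation("image too small for the section margin")
  structure(as.list(environment()), class = "fqSyntheticSpec")
}

# paint disc pixels (value 'value') where canvas currently equals 'onto';
# returns updated canvas and number painted, honoring a pixel budget.
.paintClipped <- function(labels, idx, onto, value, budget) {
  keep <- labels[idx] %in% onto
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) > budget) idx <- idx[seq_len(budget), , drop = FALSE]
  labels[idx] <- value
  list(labels = labels, n = nrow(idx))
}

#' Generate one synthetic stained section with ground truth
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return A list with elements \code{slide}
#'   (\code{\linkS4class{SlideImage}}) and \code{truth} (class
#'   \code{"fqGroundTruth"}: the pre-jitter label map, structure masks for
#'   foci/lumina/airspace, and realized per-class fractions counted
#'   exactly from the label map, both over total image area
#'   (\code{fractionsTotal}) and over the section footprint excluding
#'   lumina (\code{fractionsSection})).
#' @examples
#' gt <- generateSection(syntheticSpec(width = 200, height = 200,
#'                                     micronsPerPixel = 1.8, seed = 42))
#' gt$truth$fractionsTotal
#' @export
generateSection <- function(spec) {
  stopifnot(inherits(spec, "fqSyntheticSpec"))
  H <- spec$height; W <- spec$width
  mpp <- spec$micronsPerPixel
  psr <- spec$stainMode == "PSR_AB"
  cls <- .classesForMode(spec$stainMode)
  bgIdx <- match("background_white", cls)
  tisIdx <- if (psr) match("parenchyma_yellow", cls)
            else match("counterstain_blue", cls)

  labels <- matrix(bgIdx, H, W)
  m <- spec$sectionMarginPx
  rRows <- (m + 1L):(H - m); rCols <- (m + 1L):(W - m)
  rect <- matrix(FALSE, H, W); rect[rRows, rCols] <- TRUE
  rectPx <- sum(rect)
  labels[rect] <- tisIdx
  # inner region keeps a solid tissue rim so the section footprint is exact
  rim <- 3L
  inner <- list(r = c(m + 1L + rim, H - m - rim),
                c = c(m + 1L + rim, W - m - rim))

  # -- stage 1: alveolar airspaces (lattice of jittered discs) ------------
  rAlv <- max(2, spec$alveolusRadiusUm / mpp)
  # openness of the aerated (non-focus) tissue; independent of the
  # fibrotic-focus fraction so that growing foci only ever add tissue
  tissueTarget <- min(0.98, max(
    0.05, (spec$parenchymaFraction + spec$collagenFraction) * H * W / rectPx))
  ff <- min(spec$fibroticFocusFraction, 0.999)
  airFrac <- min(0.9, max(0.05, 1 - tissueTarget))
  spacing <- rAlv * sqrt(pi / airFrac)
  .withSeed(spec$seed + 101L, {
    ci <- seq(inner$r[1] + rAlv, inner$r[2] - rAlv, by = spacing)
    cj <- seq(inner$c[1] + rAlv, inner$c[2] - rAlv, by = spacing)
    if (length(ci) && length(cj)) {
      centers <- expand.grid(i = ci, j = cj)
      n <- nrow(centers)
      centers$i <- centers$i + runif(n, -0.3, 0.3) * spacing
      centers$j <- centers$j + runif(n, -0.3, 0.3) * spacing
      rr <- runif(n, 0.8, 1.2) * rAlv
      innerMask <- matrix(FALSE, H, W)
      innerMask[inner$r[1]:inner$r[2], inner$c[1]:inner$c[2]] <- TRUE
      for (k in seq_len(n)) {
        idx <- .discIndices(centers$i[k], centers$j[k], rr[k], H, W)
        if (!nrow(idx)) next
        idx <- idx[innerMask[idx], , drop = FALSE]
        labels[idx] <- bgIdx
      }
    }
  })

  # -- stage 2: fibrotic foci (dense, airspace-free tissue; nested in the
  #    target fraction because discs are drawn from a fixed substream) ----
  foci <- matrix(FALSE, H, W)
  if (ff > 0) .withSeed(spec$seed + 102L, {
    target <- ff * rectPx
    rF <- max(4, spec$focusRadiusUm / mpp)
    it <- 0L
    while (sum(foci) < target && it < 10000L) {
      it <- it + 1L
      idx <- .discIndices(runif(1, inner$r[1], inner$r[2]),
                          runif(1, inner$c[1], inner$c[2]),
                          runif(1, 0.8, 1.3) * rF, H, W)
      if (!nrow(idx)) next
      idx <- idx[rect[idx], , drop = FALSE]
      foci[idx] <- TRUE
    }
  })
  labels[foci] <- tisIdx

  # -- stage 3: large airway/vessel lumina with a solid wall collar -------
  lumen <- matrix(FALSE, H, W)
  if (spec$nLargeLumina > 0) .withSeed(spec$seed + 103L, {
    collarPx <- round(35 / mpp)
    for (k in seq_len(spec$nLargeLumina)) {
      rUm <- runif(1, spec$lumenRadiusUm[1], spec$lumenRadiusUm[2])
      rpx <- rUm / mpp
      pad <- rpx + collarPx + 2
      if (inner$r[1] + pad >= inner$r[2] - pad ||
          inner$c[1] + pad >= inner$c[2] - pad)
        .stopValidation("image too small for the requested lumen radius")
      ci <- runif(1, inner$r[1] + pad, inner$r[2] - pad)
      cj <- runif(1, inner$c[1] + pad, inner$c[2] - pad)
      collar <- .discIndices(ci, cj, rpx + collarPx, H, W)
      labels[collar[rect[collar], , drop = FALSE]] <- tisIdx
      hole <- .discIndices(ci, cj, rpx, H, W)
      labels[hole] <- bgIdx
      lumen[hole] <- TRUE
    }
  })

  # -- stage 4: collagen bundles (PSR) or CD68 clusters (IHC) -------------
  if (psr) {
    colIdx <- match("collagen_red", cls)
    target <- round(spec$collagenFraction * H * W)
    if (target > 0) .withSeed(spec$seed + 104L, {
      fociIdx <- which(foci & labels == tisIdx)
      count <- 0L; it <- 0L
      while (count < target && it < 20000L) {
        it <- it + 1L
        if (length(fociIdx) && runif(1) < 0.6) {
          p <- fociIdx[sample.int(length(fociIdx), 1L)]
          ci <- (p - 1L) %% H + 1L; cj <- (p - 1L) %/% H + 1L
        } else {
          ci <- runif(1, inner$r[1], inner$r[2])
          cj <- runif(1, inner$c[1], inner$c[2])
        }
        a <- max(2, runif(1, 25, 80) / mpp)
        b <- max(1, runif(1, 3, 8) / mpp)
        idx <- .ellipseIndices(ci, cj, a, b, runif(1, 0, pi), H, W)
        if (!nrow(idx)) next
        res <- .paintClipped(labels, idx, tisIdx, colIdx, target - count)
        labels <- res$labels; count <- count + res$n
      }
    })
  } else {
    posIdx <- match("immunopositive_brown", cls)
    target <- round(spec$cd68Fraction * H * W)
    if (target > 0) .withSeed(spec$seed + 106L, {
      count <- 0L; it <- 0L
      while (count < target && it < 20000L) {
        it <- it + 1L
        ci <- runif(1, inner$r[1], inner$r[2])
        cj <- runif(1, inner$c[1], inner$c[2])
        nc <- 3L + stats::rpois(1, 8)
        for (cc in seq_len(nc)) {
          if (count >= target) break
          idx <- .discIndices(ci + rnorm(1, 0, 25 / mpp),
                              cj + rnorm(1, 0, 25 / mpp),
                              max(1.5, runif(1, 4, 9) / mpp), H, W)
          if (!nrow(idx)) next
          res <- .paintClipped(labels, idx, tisIdx, posIdx, target - count)
          labels <- res$labels; count <- count + res$n
        }
      }
    })
  }

  # -- stage 5: mucus blobs strictly inside alveolar airspaces (PSR) ------
  if (psr && spec$mucusFraction > 0) {
    mucIdx <- match("mucus_blue", cls)
    target <- round(spec$mucusFraction * H * W)
    .withSeed(spec$seed + 105L, {
      airspace <- labels == bgIdx & rect & !lumen
      airIdx <- which(airspace)
      count <- 0L; it <- 0L
      while (count < target && it < 20000L && length(airIdx)) {
        it <- it + 1L
        p <- airIdx[sample.int(length(airIdx), 1L)]
        ci <- (p - 1L) %% H + 1L; cj <- (p - 1L) %/% H + 1L
        idx <- .discIndices(ci, cj, max(2, runif(1, 8, 20) / mpp), H, W)
        if (!nrow(idx)) next
        idx <- idx[rect[idx] & !lumen[idx], , drop = FALSE]
        res <- .paintClipped(labels, idx, bgIdx, mucIdx, target - count)
        labels <- res$labels; count <- count + res$n
      }
    })
  }

  # -- render: palette color per class plus Gaussian jitter ---------------
  ref <- .stainPalette[cls, , drop = FALSE]
  img <- array(0, c(H, W, 3L))
  .withSeed(spec$seed + 107L, {
    for (ch in 1:3)
      img[, , ch] <- matrix(ref[labels, ch], H, W) +
        if (spec$colorJitterSd > 0)
          matrix(rnorm(H * W, 0, spec$colorJitterSd), H, W)
        else 0
  })
  img <- array(pmin(255, pmax(0, round(img))), dim = c(H, W, 3L))

  counts <- setNames(tabulate(labels, length(cls)), cls)
  secDen <- rectPx - sum(lumen)
  inSec <- rect & !lumen
  countsSec <- setNames(tabulate(labels[inSec], length(cls)), cls)
  truth <- structure(list(
    labels = labels, classNames = cls,
    sectionRect = rect, lumenMask = lumen, fociMask = foci,
    airspaceMask = labels == bgIdx & rect & !lumen,
    fractionsTotal = counts / (H * W),
    fractionsSection = countsSec / secDen,
    realizedFocusFraction = sum(foci & rect) / rectPx,
    spec = spec), class = "fqGroundTruth")

  slide <- SlideImage(img, micronsPerPixel = mpp,
                      slideId = sprintf("synthetic_seed%d", spec$seed),
                      stainMode = spec$stainMode)
  list(slide = slide, truth = truth)
}

#' Generate a synthetic cohort with coupled lung-function values
#'
#' Generates \code{n} sections per group from each group's
#' \code{\link{syntheticSpec}} (child seeds derived deterministically from
#' \code{seed}), and simulates per-section lung-function values as linear
#' functions of the group's fibrotic-focus fraction plus Gaussian noise. A
#' negative slope makes the inverse density–lung-function correlations of
#' fibrotic disease recoverable from the synthetic cohort.
#'
#' @param groups list of groups, each a list with elements \code{label},
#'   \code{spec} (a \code{\link{syntheticSpec}}) and \code{n}.
#' @param coupling list with \code{intercepts} (named numeric: baseline
#'   percent-predicted at zero fibrotic focus for FVC/FEV1/TLC/DLCO),
#'   \code{slopes} (named numeric, percent-predicted per unit fibrotic
#'   focus fraction) and \code{noiseSd}.
#' @param seed master integer seed.
#' @param outDir if non-NULL, slides are written there as PNG plus
#'   \code{truth.csv} and \code{lung_function.csv}.
#' @param keepSlides return the generated \code{SlideImage}s in memory
#'   (default \code{TRUE}; set \code{FALSE} for large cohorts written to
#'   disk).
#' @return List with \code{truth} (data.frame: slide_id, group,
#'   patient_id, realized fractions, fibrotic focus fraction),
#'   \code{lungFunction} (data.frame: patient_id plus FVC/FEV1/TLC/DLCO
#'   percent-predicted) and \code{slides} (list or NULL).
#' @export
generateCohort <- function(groups,
                           coupling = list(
                             intercepts = c(FVC = 95, FEV1 = 95, TLC = 92,
                                            DLCO = 88),
                             slopes = c(FVC = -80, FEV1 = -70, TLC = -75,
                                        DLCO = -85),
                             noiseSd = 6),
                           seed = 1, outDir = NULL, keepSlides = TRUE) {
  if (!length(groups)) .stopValidation("at least one group is required")
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  truth <- list(); lungfn <- list(); slides <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    stopifnot(inherits(g$spec, "fqSyntheticSpec"), g$n >= 1)
    for (i in seq_len(g$n)) {
      childSeed <- (seed + gi * 100003L + i * 97L) %% 2147483629L
      sp <- g$spec; sp$seed <- childSeed
      gen <- generateSection(sp)
      sid <- sprintf("%s_s%02d", g$label, i)
      gen$slide@slideId <- sid
      if (!is.null(outDir))
        writeSlide(gen$slide, file.path(outDir, paste0(sid, ".png")))
      fr <- gen$truth$fractionsSection
      truth[[length(truth) + 1L]] <- data.frame(
        slide_id = sid, group = g$label, patient_id = sid,
        true_collagen_pct = 100 * unname(fr["collagen_red"] %||% NA_real_),
        true_mucus_pct = 100 * unname(fr["mucus_blue"] %||% NA_real_),
        true_cd68_pct =
          100 * unname(fr["immunopositive_brown"] %||% NA_real_),
        fibrotic_focus_fraction = sp$fibroticFocusFraction,
        realized_focus_fraction = gen$truth$realizedFocusFraction,
        seed = childSeed, stringsAsFactors = FALSE)
      lf <- .withSeed(childSeed + 500L, {
        v <- coupling$intercepts +
          coupling$slopes * sp$fibroticFocusFraction +
          rnorm(length(coupling$intercepts), 0, coupling$noiseSd)
        setNames(pmax(v, 1), names(coupling$intercepts))
      })
      lungfn[[length(lungfn) + 1L]] <- data.frame(
        patient_id = sid, t(lf), stringsAsFactors = FALSE)
      if (keepSlides) slides[[sid]] <- gen$slide
    }
  }
  truth <- do.call(rbind, truth)
  lungfn <- do.call(rbind, lungfn)
  if (!is.null(outDir)) {
    write.csv(truth, file.path(outDir, "truth.csv"), row.names = FALSE)
    write.csv(lungfn, file.path(outDir, "lung_function.csv"),
              row.names = FALSE)
  }
  list(truth = truth, lungFunction = lungfn,
       slides = if (keepSlides) slides else NULL)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
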
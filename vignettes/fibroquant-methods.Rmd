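---
title: "Methods: automated density-based fibrosis morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated density-based fibrosis morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroquant)
```

## The measurement model

Pulmonary fibrosis replaces aerated alveolar architecture with dense
tissue. `fibroquant` measures this directly: it asks, for every small
square neighbourhood of the section (a *microtile*), what fraction of the
neighbourhood is stained tissue rather than airspace. Healthy aerated
parenchyma has local densities well below 1 (thin alveolar walls around
open airspace); fibrotic foci are solid and approach 1. Two section-level
summaries follow:

* **mean tissue density**, the average microtile density over the
  section — a continuous burden measure;
* **fibrosis score**, the percentage of microtiles with density strictly
  above a threshold τ — the fraction of the section occupied by
  fibrotic-grade tissue.

Collagen, mucus and CD68 content are plain area fractions: class pixels
inside the analyzable section divided by section area.

The assumptions are worth stating. Density conflates all stained tissue —
collagen, cellular infiltrate, epithelium — so it measures architectural
consolidation, not collagen specifically; that is why collagen content is
reported separately from the same slide. Tissue density is also sensitive
to inflation state: an under-inflated healthy lung looks denser. The
method therefore compares like with like (sections processed the same
way) and makes no absolute claim about any single slide.

## Pixel classification

Stain chemistry gives each class a stable hue: picrosirius red collagen,
yellow parenchyma, blue-green alcian-blue mucus; DAB brown and hematoxylin
blue in the immunohistochemistry mode. Classification is by nearest
reference chromaticity: a pixel's RGB vector is compared by cosine
similarity against unit reference directions, must pass a per-class
threshold (default 0.90), and goes to the nearest passing class; bright
low-saturation pixels (mean channel ≥ 220 of 255, spread ≤ 45) are
background before any chromatic test, and pixels passing no threshold
fall back to background. Ties resolve by a fixed priority order
(collagen > mucus > parenchyma > counterstain > immunopositive), so the
map from color to class is a total, deterministic function — the basis of
the pipeline's bit-identical reruns. The profile (reference colors,
thresholds, cutoffs) is plain JSON and fully configurable; a
color-deconvolution backend could replace this rule behind the same
interface without touching any downstream code.

We chose nearest-chromaticity over machine-learned or deconvolution
classifiers deliberately: it is auditable (every decision reducible to a
cosine against a published reference color), has no training data to
version, and its failure mode — a pixel near two reference directions —
is visible in the QC overlays.

## Section segmentation and lumen exclusion

The *section* is the union of non-background pixels, morphologically
closed (radius 2 px) to bridge staining gaps, cleaned of components below
500 px (debris), and hole-filled so that enclosed airspace belongs to the
section footprint. Hole-filling matters: density is stained tissue over
*section* area, so open alveolar airspace inside the section must count
in the denominator; without it every tile would trivially have density 1.

Large airway and vessel lumina would deflate density without reflecting
fibrosis, so interior background holes with physical area ≥ 0.05 mm²
are excluded automatically, together with a surrounding wall band
(default 20 µm) to remove the non-alveolar wall tissue; the ≥ comparison
makes the boundary case explicit and testable. Alveolar-scale holes stay.
The 0.05 mm² default sits an order of magnitude above alveolar area at
full scan scale; at reduced desk scale (see below) the threshold must be
chosen relative to the synthetic geometry, which is why the test fixtures
pass an explicit value rather than relying on the default.

Whether airway *walls* (beyond the band) should also be excluded is
genuinely open; we exclude lumina plus a configurable band and keep the
wall width as an exposed parameter.

## Mucus

Human fibrotic lungs accumulate airspace mucus that picrosirius red
cannot separate from tissue; the alcian-blue counterstain exists to make
it separable. The package's convention: mucus pixels remain *inside* the
section outline (they occupy airspace within the section) but never count
as stained tissue — they drop out of the density numerator and the
collagen numerator while leaving both denominators unchanged. The
alternative convention (mucus removed from the denominator too) is one
config switch away (`mucusAsSection = FALSE`); we default to
airspace-occupancy because mucus physically sits in airspace, and because
it makes the mucus-invariance property exact: adding mucus to a slide
changes the mucus percentage and nothing else.

## Microtiles and the density map

Tile geometry is a free parameter of the method (the tile notion itself
is standard; no canonical size exists). The default edge is 50 µm
(≈ 111 px at the 0.452 µm/px reference scan resolution) — roughly
alveolar-wall scale, small enough to resolve adjacent fibrotic and
aerated regions, large enough that a tile's density is a meaningful
fraction. Tiles partition the image exactly (edge tiles may be smaller
and use their true pixel count); a tile enters the statistics only if at
least half of it is section (`minTileCoverage = 0.5`), which stops
background-dominated boundary tiles from deflating the mean. The mean is
unweighted over included tiles by default, with a section-pixel-weighted
variant (`weightedMean = TRUE`) equivalent to a per-pixel mean; the
fibrosis-score denominator is section-covered tiles (all-grid-tiles
variant via `fibrosisDenominator = "all"`). τ = 0.75 with a strict
inequality is the field's threshold for fibrotic-grade density and is
configurable.

## The synthetic generator

Real annotated whole-slide images cannot ship with a package, so every
claim is tested against synthetic sections with pixel-exact ground truth.
The generator emulates the features the pipeline must cope with, and only
those: a rectangular section footprint with a solid rim; an alveolar
lattice of jittered discs of airspace (nominal radius 45 µm) punched into
parenchyma, with openness derived from the target parenchyma fraction;
fibrotic foci — discs of solid tissue — covering a target fraction of the
section; collagen bundles as rotated ellipses placed preferentially
(60 %) inside foci, painted until the target pixel count is met exactly;
mucus blobs strictly inside airspaces; optional large lumina carved with
a solid 35 µm wall collar; and per-pixel Gaussian color jitter (SD 8 of
255 — large enough to exercise the classifier thresholds, far from
flipping classes between the well-separated reference hues).

Two design points carry the test suite:

* **Per-stage RNG substreams.** Each stage (airspaces, foci, lumina,
  collagen, mucus, jitter) seeds its own substream from the master seed.
  Changing the mucus fraction therefore changes *only* mucus pixels, and
  growing the fibrotic-focus fraction yields *nested* foci. The
  mucus-invariance and monotonicity properties then hold by construction,
  which is exactly what a ground-truth generator is for: the tests verify
  that the *pipeline* preserves these truths, not that randomness was
  kind.
* **Exact pixel budgets.** Collagen/mucus/CD68 painting trims the last
  shape to hit the target count, so realized fractions equal targets to
  within one shape's discretization (well inside ±0.01).

What the generator does not emulate — stain variability across scanners,
chromatic aberration, tissue folds, compression artifacts, true alveolar
duct topology — bounds what passing tests show: they validate the
geometry and arithmetic of the pipeline and the discriminability of
nominal stain colors under noise, not robustness to real-world staining
drift. On real slides the stain profile must be adjusted to the scanner,
and that calibration is out of scope here.

Cohort simulation couples lung function to disease: percent-predicted
FVC/FEV1/TLC/DLCO are linear in the group's fibrotic-focus fraction
(default slopes −70…−85 per unit fraction, baseline ≈ 90–95 %, Gaussian
noise SD 6) — numbers chosen once to span the observed range from
mild-biopsy to end-stage-explant disease and to make the inverse
density–lung-function correlations recoverable at cohort sizes of a few
dozen sections.

## Statistics

Group comparisons use two-tailed two-sample t tests (pooled Student by
default, matching the classical usage; Welch by flag), with the
zero-variance degenerate cases given explicit contracts (t = 0/p = 1 or
t = ±∞/p = 0, flagged). Spearman's ρ is the Pearson correlation of
average ranks; for n ≤ 9 the two-tailed p comes from exhaustive
permutation of one rank vector (362 880 permutations at n = 9, exact also
under ties), otherwise from the t approximation. Inter-rater reliability
of ordinal Ashcroft scores uses the intraclass correlation from two-way
ANOVA without replication, consistency form ICC(3,1) — the natural
estimator when raters are a fixed factor and systematic rater offsets
should not count against reliability; absolute-agreement ICC(2,1) is
available by flag, and negative estimates are reported as computed with a
flag rather than clamped. No multiple-testing correction is applied (the
validation context reports a handful of planned tests); the report
carries the test count so users can apply their own.

Sections, not patients, are the default unit of analysis (several
sections per patient are typical); aggregating to patients first is a
data-frame operation left to the caller.

## Numerical and degenerate-input choices

* All pixel bookkeeping is in integer counts; densities and fractions are
  formed once, at the end, so tile metrics equal a naive per-pixel
  recount to machine precision.
* Empty section, empty density map, constant correlation input, and
  incomplete ICC matrices raise typed conditions
  (`fqEmptySectionError`, `fqEmptyMapError`, `fqValidationError`) with
  the slide id attached where relevant.
* Black pixels (zero RGB norm) have undefined chromaticity and fall to
  background.
* Tile ranges are half-open partitions in concept; in R they are realized
  as 1-based inclusive index ranges with identical coverage semantics
  (every pixel in exactly one tile).

## Problem sizes used in tests

The suite and the acceptance script run on synthetic sections of 240–500
px at 1.8 µm/px (desk-scale: physical thresholds in mm² stay meaningful
on a small canvas) with 28 px (≈ 50 µm) tiles, plus one full-scale
2000×2000 px slide at 0.452 µm/px for the determinism check; ladders use
5 collagen fractions (0.02–0.30), 5 fibrotic-focus levels (0–0.55), and a
16-section cohort. These sizes were chosen as the smallest at which each
property is meaningfully exercised — e.g. tiles several alveoli wide for
density maps, lumen radii whose area clears 0.05 mm² at the chosen
resolution.

## Known limitations

* The stain profile is nominal; real scanners need per-batch calibration
  of reference colors, and no cross-scanner normalization is attempted.
* Density is not collagen-specific and is inflation-sensitive (see
  model assumptions above).
* CD68 is quantified as positive-area fraction only — no cell counting
  or instance segmentation.
* Pyramidal slide formats are not read directly; slides are expected as
  flat 8-bit RGB PNG/TIFF at a known µm/px.
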
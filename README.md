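# fibroquant

Automated, reader-independent quantification of pulmonary fibrosis in
whole-slide images of stained lung sections.

Semi-quantitative histological grading of fibrosis (Ashcroft scoring) is
subjective, coarse (nine integers), and samples only a handful of fields
per section. `fibroquant` implements the alternative: a fully automated
morphometric pipeline that analyzes the *entire* section of a lung slide
stained with picrosirius red + alcian blue (collagen red, parenchyma
yellow, airspace mucus blue-green) or immunostained for CD68 (DAB brown on
hematoxylin), and reports continuous, deterministic severity metrics. It
is aimed at researchers quantifying fibrotic lung disease (IPF,
Hermansky–Pudlak syndrome pulmonary fibrosis, experimental models) from
scanned sections.

## The method

Each pixel of the RGB slide is assigned to a stain class by nearest
reference chromaticity (cosine similarity in RGB space with per-class
acceptance thresholds, plus a luminance rule for background). The section
footprint is segmented from the stained-tissue union (holes enclosed by
tissue — alveolar airspace — belong to the section), and large
airway/vessel lumina with area ≥ 0.05 mm² are automatically excluded
together with a surrounding wall band. The section is then partitioned
into square *microtiles* (default edge 50 µm ≈ 111 px at the reference
0.452 µm/px), and for every tile a tissue **density**

d = (collagen ∪ parenchyma pixels in tile ∩ section) / (tile pixels ∩ section) ∈ [0, 1]

is computed; mucus and airspace count as unstained. Three per-section
metrics follow, all from the same slide in one pass:

* **mean tissue density** — mean of d over section-covered tiles;
* **fibrosis score** — % of tiles with d > τ (τ = 0.75, strict), high
  densities being specific to fibrotic foci;
* **area fractions** — collagen, mucus, or CD68-positive pixels as % of
  the section area.

The alcian-blue step exists so that airspace mucus — which picrosirius
red alone cannot separate from tissue — is classified and excluded
automatically, leaving fibrosis and collagen metrics untouched.

Every step is a pure function of the pixel data and the configuration, so
repeated runs are bit-identical (standard error of 0 pixels across runs).

A validation-statistics module covers the companion analyses: group
mean ± SEM, two-tailed Student/Welch t tests, Spearman correlation with
lung-function values (exact permutation p for n ≤ 9), and the inter-rater
intraclass correlation of Ashcroft scores from two-way ANOVA without
replication (ICC(3,1); absolute-agreement ICC(2,1) by flag).

Because real annotated slides are rarely shareable, the package ships a
synthetic-section generator — jittered alveolar lattices, fibrotic foci,
collagen bundles, airspace mucus, carved lumina, Gaussian color jitter —
with a pixel-exact ground-truth label map, so the whole pipeline is
testable against known truth.

## Worked example

```r
library(fibroquant)

spec <- syntheticSpec(width = 1200, height = 1200, collagenFraction = 0.08,
                      mucusFraction = 0.02, fibroticFocusFraction = 0.25,
                      nLargeLumina = 1, seed = 7)
gen <- generateSection(spec)

result <- quantifySection(gen$slide)
result
#> MorphometryResult 'synthetic_seed7' (PSR_AB)
#>   mean tissue density : 0.8130
#>   fibrosis score      : 67.90 % (tau = 0.75)
#>   collagen content    : 11.26 %
#>   mucus               : 3.20 %
#>   section area        : 899446 px (0.184 mm^2), 502410 px excluded lumina
#>   microtiles          : 81 included, edge 111 px

round(100 * gen$truth$fractionsSection[c("collagen_red", "mucus_blue")], 2)
#> collagen_red   mucus_blue
#>        11.47         2.87
```

A quarter of the section was generated as dense fibrotic tissue, which
drives the mean density (0.81) and fibrosis score (68 % of microtiles
above τ); the measured collagen and mucus percentages track the
generator's ground truth to a few tenths of a point (the residual comes
from the excluded wall band around the carved airway, which the pipeline
removes from the denominator but the ground-truth bookkeeping does not).

Batch use, from a shell:

```sh
Rscript inst/scripts/fibroquant.R quantify --in slides/ --out results/ --mpp 0.452
Rscript inst/scripts/fibroquant.R simulate --seed 3 --n 5 --out synth/
Rscript inst/scripts/fibroquant.R stats --cohort results/cohort.csv \
        --lungfn pft.csv --ashcroft scores.csv --out stats/
```

`quantify` writes one CSV row per section, QC overlays (fibrotic tiles
orange, mucus green), and a JSON manifest with the resolved configuration
and per-file checksums, so a rerun is verifiably identical.

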
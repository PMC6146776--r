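---
title: "Focused steatosis scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focused steatosis scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoscore)
```

## The measurement problem

Macrovesicular steatosis — fat accumulating as large single droplets in
hepatocytes — is assessed on H&E-stained liver sections, where droplets
appear as white roundish vacuoles that must be told apart from other white
structures (vessel lumina, tissue cracks, the bare slide). Automated
methods usually report the *standard score*: the steatosis area fraction,
i.e. droplet area over total tissue area of the whole section.

Steatosis is spatially heterogeneous: steatotic areas with many droplets
alternate with non-steatotic areas with none, diffusely (following the
lobular architecture) or focally (confined regions). The standard score is
therefore sensitive to how much non-steatotic tissue happens to be in the
sample — something difficult to standardize — and, when steatotic areas
are small, it is also close to zero and easily swamped by segmentation
errors.

*Focused scores* address this with the machinery of tile-based hotspot
analysis. The section is divided into a regular grid of square tiles of a
physical edge length; each tile gets its own steatosis area fraction; and
the score is a summary statistic (mean, or a percentile) over the
*steatotic tiles only* — tiles containing tissue whose fraction exceeds
zero. Restricting to steatotic tiles makes the statistic invariant to the
amount of non-steatotic tissue sampled, which is the mechanism behind its
improved reliability.

## Score definitions

For a tile map with per-tile tissue pixel counts $t_i$ and droplet pixel
counts $d_i$ ($d_i \le t_i$):

* **Standard score (exact mode, the default):**
  $S = \sum_i d_i \, / \, \sum_i t_i$. Being tissue-area weighted, this is
  *exactly* the whole-section area fraction and exactly invariant to the
  tile size. The conventional alternative — the unweighted mean of tile
  fractions on a small 8 µm grid — is available as
  `standard_score(map, mode = "tile-mean")`. The two agree closely
  whenever tiles cover the tissue accurately, i.e. when the section is
  large relative to a tile: on millimetre-scale synthetic sections the
  difference is below $10^{-3}$; on very small test images the partial
  boundary tiles make it visibly larger. We made the exact form the
  default because it is parameter-free and conserves total areas
  regardless of grid alignment.
* **Focused scores:** let $F = \{d_i/t_i : t_i > 0,\, d_i > 0\}$ be the
  fractions of steatotic tiles. The focused mean is the unweighted mean of
  $F$; the focused percentile is a percentile of $F$. If
  $|F| < m$ (default $m = 100$) the score is **undefined** rather than
  estimated from an unsound sample. Undefined scores are excluded from all
  downstream statistics, with a logged count, and the affected score
  specification is flagged in the evaluation table.

The focused mean is unweighted over tiles rather than tissue-weighted:
the statistic is about the *distribution of tile fractions*, and tiles
are the sampling unit of hotspot analysis. Partial edge tiles therefore
carry the same weight as full tiles; they are retained (with their true
pixel counts) so that the standard score stays exact. Tiles without any
tissue are neither steatotic nor non-steatotic and never enter any
statistic.

Percentiles use linear interpolation between order statistics (the common
type-7 rule): with $n$ sorted values and $h = (n-1)p/100$, the result is
$v_{\lfloor h \rfloor + 1} + (h - \lfloor h \rfloor)(v_{\lfloor h \rfloor + 2} -
v_{\lfloor h \rfloor + 1})$. An inverse-CDF mode (type 1) is available via
`percentile(..., interpolation = "inverted_cdf")`; both modes are verified
against the reference quantile implementation in the test suite.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tile_size_um` | 32 | tile edge; 8–128 µm sweep supported |
| `min_steatotic_tiles` | 100 | definedness threshold for focused scores |
| `percentile_p` | — | 10…90 conventional sweep |
| analysis resolution | 454 nm/px | images are resampled here before segmentation |

Tile sizes are physical lengths; the pixel edge is
`round(tile_size_um * 1000 / resolution_nm_per_px)`, clamped to at least
1 px. The tile grid is anchored at the image origin (no offset search) —
a deliberate determinism-over-optimality choice; grid alignment is part of
what the reliability analysis treats as sampling noise.

The tile-size dependence of focused scores is physical: tiles much smaller
than a droplet are almost entirely inside or outside one, so fractions
collapse toward {0, 1} and carry little graded information; tiles much
larger than a hepatocyte mix steatotic and non-steatotic tissue and
reinstate the sampling sensitivity the focus was meant to remove. The
reliability optimum on our synthetic cohorts sits at 16–32 µm,
approximately hepatocyte scale.

## Segmentation

Droplet segmentation is a two-stage classification. Pixels are classified
white vs. stained from HSV saturation and brightness (white iff
saturation ≤ 0.25 and brightness ≥ 0.8 by default); blobs — 8-connected
components of white pixels inside the tissue — are classified droplet
vs. other-white-structure from shape features:

* equivalent diameter within 5–100 µm (vessels are larger, dust smaller),
* circularity $4\pi A / P^2 \ge 0.5$ (cracks are elongated),
* solidity (area over convex-hull area) ≥ 0.85 (ragged structures).

These deterministic threshold rules use the same feature families a
learned classifier would; the blob rule is a plain predicate function and
can be swapped (`classify_blobs(..., predicate = )`) for a trained model
without touching anything else. Shape thresholds cannot, by construction,
separate a perfectly round white structure of droplet size from a droplet
— that separation genuinely needs learned appearance features.

The perimeter on the discrete grid uses the 4-direction Crofton estimator:
$P = \frac{\pi}{4}\left(n_h + n_v + (n_{d1} + n_{d2})/\sqrt{2}\right)$,
where the $n$ are counts of maximal runs of the blob along rows, columns
and the two diagonal directions. It is near-unbiased for discs (rendered
disc circularity approaches 1 as the radius grows), which makes the
circularity threshold interpretable. Circularity is capped at 1; blobs of
a few pixels can exceed it under any discrete estimator.

The tissue mask — the denominator of every fraction — is the
morphological closing (Euclidean disc, radius 50 µm, implemented with
distance transforms) of the stained region followed by hole filling, so
droplets and enclosed lumina count as tissue while the slide background
does not. "Total tissue area" has no universally agreed operational
definition; this one is conservative and deterministic.

## Clinimetric evaluation

Reliability is the intraclass correlation coefficient from one-way ANOVA
variance components: with mean squares $MS_B, MS_W$ and effective group
size $n_0 = (N - \sum n_i^2/N)/(k-1)$,

$$\hat\sigma^2_w = MS_W, \qquad
  \hat\sigma^2_b = \max\!\left(0, \frac{MS_B - MS_W}{n_0}\right), \qquad
  \mathrm{ICC} = \frac{\hat\sigma^2_b}{\hat\sigma^2_b + \hat\sigma^2_w}.$$

Negative between-group components are clamped to zero (the standard ANOVA
convention, keeping ICC in $[0,1]$); $MS_W = 0$ with distinct group means
gives ICC exactly 1. This is the single-measure form implied by "between
variance over total variance"; average-measure variants are out of scope.

One caveat worth stating plainly: with $k$ groups the estimator's
sampling dispersion is governed by its $k-1$ between-group degrees of
freedom. At $k = 20$ groups of $n = 20$, the estimate follows
$\max(0, F-1)/(F+n-1)$ with $F \sim \lambda F_{k-1,\,N-k}$ and has a
standard deviation of roughly 0.06–0.09 across the ratio range 0.2–0.8 —
the test suite verifies both its centring and its dispersion against this
law. No point estimator at that design size resolves the ICC to ±0.05
with high confidence; studies needing that precision need more groups.

Validity is Kendall's tau-b against an ordered covariate (diet index,
feeding weeks), computed by exact pair enumeration with tie corrections
in both variables — covariates repeat within groups, so x-ties are the
normal case, and tau-b handles them exactly. When no natural group order
exists, groups can be ranked by their mean standard score
(`order_groups_by_standard = TRUE`).

Undefined scores are excluded, never imputed; exclusion can unbalance
groups, which the $n_0$ correction absorbs; a group left with fewer than
two defined values flags the score specification and suppresses its ICC.

## The synthetic-data generator

Real whole-slide cohorts of this kind are not publicly deposited, so the
package ships a generator with two engines.

**Rendered sections** (`generate_section`): an irregular eosin-pink
tissue region with Gaussian channel noise; steatotic regions as the whole
tissue (uniform), unions of compact ~300 µm foci (focal), or a thresholded
smooth random field with ~500 µm correlation length standing in for
lobular periodicity (diffuse); non-overlapping white discs with lognormal
diameters (median 15 µm) placed by rejection sampling until the realized
droplet area is within ±5% relative of the target fraction; optional
vessel-scale white ellipses (150–280 µm lumina with a denser wall rim)
and thin white crack polylines. Ground-truth droplet/tissue/region masks
are returned alongside the raster. The colour model is deliberately
minimal — no nuclei, no stain variation, no scanner artifacts — it is
sufficient to exercise saturation/brightness segmentation, and passing
Dice ≥ 0.9 on it demonstrates correctness of the pipeline, *not*
performance on real histology.

**Analytic tile maps** (`generate_cohort(..., tile_maps_only = TRUE)`):
for statistical studies the renderer is bypassed. Tissue is a rectangle of
8 µm cells; inside steatotic regions (same thresholded-field layout) each
cell holds droplet matter with probability $q$ and then a coverage drawn
from Beta(8, 1.5); elsewhere fractions are zero. The 8 µm tile map *is*
this zero-inflated Beta field; coarser maps are block aggregations of the
counts. Aggregation is what reproduces the tile-size physics: at 8 µm the
focused mean saturates near the Beta mean regardless of $q$; at 16–64 µm
it tracks $q$; at ≥64 µm boundary-straddling tiles mix in non-steatotic
cells whose share jitters between images.

**Serial-section mode** (`cohort_spec_serial`) emulates a design of five
groups of six consecutive sections of one liver, groups ~300 µm apart:
all images share one steatotic-region layout perturbed per image by a
smooth field of 0.15 sd (sections millimetres apart are nearly, not
exactly, congruent); groups differ only by a small monotone drift in the
within-region density $q$ (+0.02 absolute per group from 0.32, i.e. very
small level differences); each image gets a per-image density jitter of
1.5% relative and independent non-steatotic tissue margins of width
U(0, 1200 µm) per side, emulating unstandardized tissue sampling. The
margins move the standard score (they change the tissue denominator) but
cannot move any focused score (they only add zero-fraction tiles) — the
package's central claim, testable at score level. With the drift set to
0 the construction is a null: group means are indistinguishable and ICC
collapses.

These defaults are testability choices consistent with the biology
(droplet ≈ 15 µm, hepatocyte ≈ 25 µm, lobule ≈ 500 µm), not quantitative
claims about any particular tissue. All randomness flows from a single
seed through a private RNG stream; identical specs give byte-identical
outputs.

## Numerical choices and degenerate inputs

* Tile rectangles are half-open, row-major, 0-based; partial right/bottom
  tiles keep true counts; per-tile fractions are never serialized, only
  recomputed from counts (no rounding drift through CSV round-trips).
* `round()` in the µm→px conversion follows the platform's
  round-half-to-even; the result is clamped to ≥1 px.
* Empty images, empty tile sets, all-tied rank vectors, groups with fewer
  than two values, and droplet counts exceeding tissue counts are all
  rejected with named domain errors rather than propagated as NaN; an
  all-tied tau is reported as undefined (NA), matching its denominator
  of zero.
* Morphological closing/erosion use exact Euclidean distance transforms,
  so the 50 µm radius is resolution-independent.
* Blob labelling is 4-connected labelling plus a union-find merge across
  diagonal adjacencies, yielding true 8-connectivity.

## Problem sizes used in the bundled studies

The test-suite and acceptance studies run on: 50 serial-section cohorts of
5 × 6 analytic images (2560 µm core at 8 µm cells, five tile sizes), ten
rendered 1024² sections for segmentation fidelity, two vessels/cracks-only
sections, and 200 × 3 simulated grouped designs at k = 20 × n = 20 for the
ICC estimator. These sizes make the full suite run in a few minutes while
keeping every statistical check comfortably powered.

## Known limitations

* The rule-based blob classifier is a stand-in with the same feature
  families as learned classifiers, not a reimplementation of any trained
  model; on real H&E it will miss droplet/vessel distinctions that need
  appearance cues.
* No stain normalization, no pyramidal WSI decoding (a single
  fixed-resolution raster per section), no microvesicular steatosis.
* The synthetic generator does not render nuclei, portal fields, or
  scanner artifacts; segmentation results on it bound correctness, not
  real-world accuracy.
* ICC point estimates carry the sampling dispersion described above; the
  package deliberately reports no confidence intervals (none were part of
  the evaluation design it implements).
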
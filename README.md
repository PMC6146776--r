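# steatoscore

Tile-based quantification of macrovesicular steatosis in H&E-stained
liver sections, built around **focused scores**: summary statistics
computed over steatotic image tiles only.

## The problem

Automated steatosis analysis conventionally reports the **standard
score** — the steatosis area fraction of the whole section,
`S = droplet area / tissue area`. Steatosis, however, is spatially
heterogeneous: steatotic and non-steatotic areas alternate across the
tissue, so `S` depends strongly on how much non-steatotic tissue happens
to be in the sample and, at low steatosis levels, it is easily swamped by
segmentation errors. In grouped studies (diet arms, feeding times, serial
sections) this makes small level differences unreliable to discriminate.

**Focused scores** apply tile-based hotspot analysis: divide the section
into square tiles of edge length `t` (8–128 µm), compute each tile's area
fraction `f_i = d_i / t_i`, keep only the *steatotic* tiles (`f_i > 0`),
and report a statistic of those values —

* focused mean: `mean{ f_i : f_i > 0 }`
* focused percentile: `P_p{ f_i : f_i > 0 }`, `p = 10 … 90`

with the score **undefined** when fewer than `min_steatotic_tiles`
(default 100) steatotic tiles exist. Restricting to steatotic tiles makes
the score invariant to the sampling of non-steatotic tissue, which is
what improves its reliability.

The package is for image-analysis and preclinical researchers who need
reproducible steatosis readouts from section images and a quantitative
way to compare scoring variants. It provides:

* rule-based fat-droplet segmentation (HSV pixel classification +
  blob shape morphometry with a pluggable classifier predicate),
* tile fraction maps with exact area conservation and CSV round-trips,
* the standard score (exact and 8 µm tile-mean modes) and the focused
  score family,
* clinimetrics: one-way ANOVA intraclass correlation (reliability) and
  Kendall's tau-b with tie corrections (validity) over grouped designs,
* a synthetic H&E-like section and cohort generator with ground-truth
  masks, including a fast analytic tile-map engine and a serial-section
  ("groups of consecutive sections") mode,
* a CLI (`inst/cli/steatoscore.R`) with `simulate`, `segment`, `tilemap`,
  `score`, `evaluate` and `pipeline` subcommands.

## Worked example

```r
library(steatoscore)

# synthetic section with ground truth: 768 px @ 454 nm/px, diffuse
# steatosis pattern, 8% target area fraction
s   <- generate_section(section_spec(width_px = 768, height_px = 768,
                                     target_area_fraction = 0.08,
                                     pattern = "diffuse", seed = 42))
seg <- segment_section(s$raster)                  # white/tissue/droplet masks
map <- compute_tile_map(seg$droplet, seg$tissue,
                        s$raster$resolution_nm_per_px, 32, source_id = "demo")

standard_score(map)
#> <score 'demo' [standard]: 0.06838 (93 tissue tiles, 31 steatotic)>
focused_score(map, score_spec("focused", "mean"))
#> <score 'demo' [focused mean @ 32 um]: undefined (93 tissue tiles, 31 steatotic)>
focused_score(map, score_spec("focused", "mean", min_steatotic_tiles = 25))
#> <score 'demo' [focused mean @ 32 um]: 0.1696 (93 tissue tiles, 31 steatotic)>
focused_score(map, score_spec("focused", "percentile", percentile_p = 70,
                              min_steatotic_tiles = 25))
#> <score 'demo' [focused p70 @ 32 um]: 0.2165 (93 tissue tiles, 31 steatotic)>
```

Reading the output: the whole-section fraction is 0.068, but only 31 of
93 tissue tiles are steatotic — at the default minimum of 100 steatotic
tiles the focused score is *undefined* (a small demo image simply holds
too few tiles for a sound statistic). Lowering the threshold for the
demo, the focused mean within steatotic tiles is 0.170, i.e. steatotic
areas are locally ~2.5× denser than the whole-section average suggests,
and the 70th percentile of tile fractions is 0.217.

Reliability of score variants on a serial-section cohort (five groups of
six consecutive-section images sharing one steatosis layout, tiny
monotone drift between groups, random non-steatotic margins):

```r
co <- generate_cohort(cohort_spec_serial(seed = 7), tile_maps_only = TRUE)
tile_size_reliability(co)
#>           score tile_size_um        icc
#> 1      standard           NA 0.04899791
#> 2   focused_8um            8 0.00000000
#> 3  focused_16um           16 0.92176920
#> 4  focused_32um           32 0.93864691
#> 5  focused_64um           64 0.92225375
#> 6 focused_128um          128 0.89248922
```

The standard score barely separates the groups (ICC 0.05) because the
random margins shift its denominator; focused means at hepatocyte-scale
tiles (16–32 µm) reach ICC ≈ 0.93–0.94, with degradation at 8 µm
(fractions collapse to ≈ {0,1}) and at 128 µm (tiles mix non-steatotic
tissue again).

See `vignettes/focused-scores.Rmd` for the model, parameter meanings and
design choices.

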
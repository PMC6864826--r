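# cropgeobia

Per-plant health mapping for row crops from very-high-resolution 4-band
(G/R/RE/NIR) orthomosaics, using geographic object-based image analysis
(GEOBIA). The package is aimed at precision-agriculture practitioners and
remote-sensing researchers who need a health rating at each *seeding point*
— the position where a group of seeds was planted — rather than a pixel-wise
vegetation index.

## The method

Given a multispectral raster and a set of georeferenced, labeled training
signatures, the pipeline runs:

1. **Mean-shift segmentation.** Each pixel's joint spatial–spectral vector
   iterates to its density mode: `y ← Σ K(x_k − y) x_k / Σ K(x_k − y)` over
   neighbors within spatial range `hs` (default 5 px) and spectral range
   `hr` (default 15 band units); 4-connected pixels with matching modes form
   segments. A tiled mode handles rasters larger than memory.
2. **Maximum-likelihood classification.** Segment spectral modes ω are
   assigned `argmax_C  log P(C) + log N(ω; μ_C, Σ_C)` over the classes
   {Soil, Shadow, HL1…HL5}, with posteriors from Bayes' rule. Minimum
   distance to means (MDM) and spectral angle mapping (SAM) baselines are
   included.
3. **Seeding-point detection.** HL-labeled segments form a vegetation mask;
   each 4-connected component of area `a` gets `k = max(1, round(4a/(πd²)))`
   KMeans centers (Lloyd, ≤ 20 iterations, seeded deterministic init) on its
   pixel coordinates, `d` = 0.3 m being the seeding distance. Detection runs
   independently per plowing row, which parallelizes with no data
   dependencies.
4. **Health index.** At each center `p`, `I(p)` is the mean health level of
   the segments intersecting the disc `B(p, r)` (`r` = 7.5 cm); a point
   whose disc meets no health-labeled segment is the no-plant marker ∅.
5. **Validation.** Detections pair to a reference layout by nearest-neighbor
   matching within `d/2`; the confusion matrix over {∅, 1…5} and per-class
   precision (diagonal / row total) are reported, alongside NDVI
   `(NIR − R)/(NIR + R)` for comparison.

A synthetic row-crop scene generator with full ground truth (positions,
classes, per-pixel labels) makes the whole chain testable end to end without
field data, and Amdahl's-law utilities (`amdahl_speedup`,
`parallel_fraction`) cover the strong-scaling bookkeeping of the parallel
clustering stage.

## Worked example

```r
library(cropgeobia)

# a 4-double-row field, 12 seeding points per row, 2% band noise
sc  <- generate_scene(scene_config(rows = 4, points_per_row = 12, seed = 42))
sig <- scene_training_signatures(sc, per_class = 50, seed = 43)
rm_ <- scene_row_model(sc$cfg)

res <- run_pipeline(sc$raster, sig,
                    pipeline_config(seed = 42, row_pitch = rm_$row_pitch,
                                    row_y0 = rm_$y0),
                    reference = data.frame(x = sc$truth_points$x,
                                           y = sc$truth_points$y,
                                           class = sc$truth_points$class))

sc
#> <synthetic_scene> 200 x 75 px, 48 seeding point(s) (36 alive)
res$segmap
#> <segment_map> 200 x 75 px, 106 segment(s)
head(res$points[c("x", "y", "row_id", "health_index", "health_class")], 4)
#>         x        y row_id health_index health_class
#> 1 0.75375 6.740000      1            5            5
#> 2 1.06000 6.740000      1            1            1
#> 3 1.36000 6.767692      1            4            4
#> 4 1.35000 7.246667      1            2            2
```

Each row is one detected seeding point: its world position (meters), plowing
row, the real-valued health index `I(p)` (1 = worst, 5 = best) and its
discretized class. The per-row summary and the validation against ground
truth:

```r
health_count_table(res$points)
#>   R1 R2 R3 R4 Sum
#> ∅  0  0  0  0   0
#> 1  1  2  2  2   7
#> 2  1  1  0  1   3
#> 3  2  2  4  3  11
#> 4  4  1  1  2   8
#> 5  2  0  4  1   7
res$validation$confusion$precision
#> ∅ 1 2 3 4 5
#> 1 1 1 1 1 1
```

On this small field every surviving plant is recovered and classed
correctly (`recovered = 1.000`, `exact = 1.000`); on the default 10 × 30
scene, recovery and exact-class agreement are typically 98–99%. The scaling
utilities reproduce strong-scaling tables directly:

```r
amdahl_speedup(0.9651, 2)     #> 1.932554
parallel_fraction(7.8008, 10) #> 0.9687
```

A command-line front end ships in `inst/cli/cropgeobia.R` with verbs
`simulate`, `run-all` and `validate`.

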
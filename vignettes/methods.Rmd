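---
title: "Object-based plant-health mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based plant-health mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropgeobia)
```

## The problem

A very-high-resolution multispectral orthomosaic of a row crop (bands G
550 nm, R 660 nm, RE 735 nm, NIR 790 nm, ~4 cm/px) contains enough signal to
rate the health of each *individual seeding point* — the position where a
group of seeds was planted — on a five-level scale. Pixel-wise indices such
as NDVI separate vegetation from soil well but flatten the differences
between stressed and vigorous plants of the same species. `cropgeobia`
implements an object-based chain instead: pixels are first grouped into
spectrally homogeneous segments that follow leaf and branch contours, the
segments are classified, and per-plant statistics are aggregated over the
segments around each seeding point.

The chain is: mean-shift segmentation → Gaussian maximum-likelihood
classification of segment spectral modes → vegetation mask → connected
components → area-calibrated KMeans for seeding-point centers → disc-
neighborhood health index → validation against a reference layout.

## Mean-shift segmentation

Every pixel starts a mode-seeking iteration in the joint spatial–spectral
domain. The current estimate `y = (y_s, y_r)` moves to the kernel-weighted
mean of the neighboring pixels within spatial range `hs` and spectral range
`hr`; the spatial and spectral coordinates are normalized by `hs` and `hr`
respectively before distances and kernel weights are computed. Iteration
stops when the joint normalized displacement falls below `conv_threshold`
or after `max_iter` steps. Adjacent (4-connected) pixels whose converged
spectral modes agree are merged into one segment.

Tunables (`ms_params()`):

| parameter | default | units | role |
|---|---|---|---|
| `hs` | 5 | pixels | spatial kernel range; sets the scale of objects (≈20 cm at 4 cm/px, the scale of leaf clusters) |
| `hr` | 15 | band units | spectral kernel range; raw radiance/reflectance units of the input raster — no rescaling is applied internally |
| `kernel` | Epanechnikov | — | Gaussian selectable; Epanechnikov gives compact support and faster convergence |
| `max_iter` | 100 | — | iteration cap per pixel |
| `conv_threshold` | 0.1 | normalized | joint displacement below which a pixel is converged |
| `merge_tol` | 0.5 | × `hr` | two adjacent modes are "the same mode" when their range-normalized distance is ≤ `hr/2`; the merging literature leaves this open, so it is explicit and configurable |
| `min_segment_size` | 4 | pixels | speckle suppression; smaller segments are absorbed by the adjacent segment with the nearest spectral mode (ties to the lower label) |

`segment_tiled()` processes large rasters in tiles with an overlap margin
(default `ceiling(2·hs·sqrt(max_iter))`, capped at half the tile), keeps each
tile's core modes, and merges the assembled mode grid globally, so segments
crossing tile borders are unified. The result equals the untiled run
wherever a pixel's mode depends on context no farther than the margin;
pathological flat gradients can differ on a sub-percent pixel fraction.

Re-running the filter on its own output is not a strict fixed point: the
spatial coordinate restarts at the pixel position, so pixels on basin
boundaries can hop basins. The bulk of the image (empirically ≥ 90% of
pixels) stays within the convergence threshold; tests assert this form.

## Classification of segments

Features are exactly the 4-vector segment spectral modes — classification is
per segment, not per pixel. For each class the model stores the sample mean,
the maximum-likelihood (1/n) covariance, and a prior; a ridge of
`1e-6·trace(Σ)/4` is added when the smallest eigenvalue drops below
`1e-10·trace(Σ)`, so point-mass classes stay usable. A segment is assigned
the class maximizing `log P(C) + log N(ω; μ_C, Σ_C)`, ties broken by class
order; posteriors follow from Bayes' rule. The constant term of the log
density cancels in both the decision rule and the posterior normalization,
so the choice of constant (dimension vs. class count) is irrelevant to every
reported quantity; the implementation uses the dimension.

Whether the reference workflow used empirical or uniform priors is not
documented; both are supported and uniform is the default (training-area
class frequencies are a deliberate oversample of rare classes, not an
estimate of field prevalence). Two baselines are included for comparison:
minimum distance to means and spectral angle mapping.

Per-class precision is reported as the diagonal count divided by its row
total. The alternative form TP/(TP+TN) is exposed as `mode = "tp_tn"` but is
not the default: on the published validation table only the row-total form
reproduces the printed precision column, so that is the statistic the
package treats as canonical.

## Seeding-point detection

Segments classified HL1–HL5 form the vegetation mask; 4-connected mask
regions become components. A component of area `a` (m²) receives
`k = max(1, round(4a/(πd²)))` cluster centers — the number of inscribed
circles of diameter `d` (the seeding distance, default 0.3 m) that fit by
area; rounding is half-up, since the source formula is stated without an
integerization rule. Lloyd's KMeans (≤ 20 iterations) on the component's
pixel *coordinates only* places the centers; initialization is a
deterministic k-means++-style seeding driven by an integer seed, and a
cluster that empties is re-seeded to the farthest point. The per-component
seed derives from the master seed and the component id, so per-row parallel
execution reproduces the serial result exactly. Components smaller than 3
pixels yield their centroid directly.

Rows are modeled as horizontal bands of configurable pitch (explicit row
intervals override); components in different rows share no pixels, which is
the no-data-dependency contract that makes per-row parallelism safe. The
worker pool (`run_parallel()`) is a convenience; its correctness criterion
is set-equality with the serial run, which the tests assert, not wall-clock
scaling.

## Health index

At each detected point `p`, the index is the mean health level (1–5) of the
segments whose footprints intersect the closed disc `B(p, r)`, `r = 7.5 cm`
by default. Segment footprints are unions of pixel squares, so the
intersection predicate is evaluated as the exact closed-form distance from
`p` to each member pixel's square — exact polygon–disc geometry for these
rectilinear footprints, with boundary contact counting as intersection.

Soil and shadow segments carry no health level. By default they are
excluded from both numerator and denominator, which keeps the index on the
1–5 scale; `include_nonvegetation = TRUE` counts them in the denominator
(diluting the index toward 0) for sensitivity analyses. A point whose disc
meets no health-labeled segment is the no-plant marker (∅). The real-valued
index is discretized to a class by rounding half-up; floor and no
discretization are selectable.

Detected points are paired to a reference layout by greedy nearest-neighbor
matching within `d/2`; unmatched reference positions are ∅ predictions and
unmatched detections are flagged spurious. On well-separated layouts the
greedy pairing coincides with the optimal assignment (asserted against a
brute-force oracle on small instances).

## Synthetic scenes

No imagery is distributed with the package, so every end-to-end claim is
exercised on synthetic fields with complete ground truth. The generator
reproduces the layout the pipeline targets: seeding points every 0.3 m
along double rows with 0.5 m internal and 1.5 m external separation, 4 cm
pixels, a soil background, per-plant discs whose radius grows with health
level, a 1-px shadow fringe around each canopy, and additive Gaussian band
noise. Default choices, fixed once:

- *Band means* (G, R, RE, NIR per class) follow the qualitative shape of
  field-measured class signatures: soil moderate and flat, shadow low and
  flat, and health classes ordered chiefly by RE and NIR response — the
  red-edge/NIR region is where stress expresses most strongly at these
  wavelengths. Adjacent health classes differ by ~10 units (Euclidean),
  mostly in RE/NIR.
- *Noise*: 2% of the mean per-band spread of the class means (≈0.7 units),
  a low-noise radiometric regime appropriate for calibrated mosaics.
- *Radii*: 7–13 cm mean by class with ~1 cm spread, i.e. mid-season canopies
  that occasionally touch along the row but rarely bridge rows.
- *Class mix*: 10% failed seeding points, the rest uniform over HL1–HL5.
- *Position jitter*: 1 cm standard deviation around the nominal grid.

What the generator does *not* emulate: irregular canopy shapes (discs and
optional multi-disc unions only), BRDF and illumination gradients, terrain,
mixed pixels at sensor level, and georeferencing error. Passing the
synthetic recovery tests therefore demonstrates the correctness of the
algorithmic chain under the stated radiometric model, not field-grade
robustness. One realistic failure mode does appear and is worth knowing:
segments on canopy edges can straddle the plant/shadow transition and be
classified one or two levels off, and a point whose disc catches such a
segment can misreport its class by more than one level in roughly 1 in 300
matched points across seeds. Small fields (tens of points) are usually
recovered perfectly.

Reference figures for the default 10-row × 30-point scene (recomputed by
`scripts/acceptance.R` and the test suite on every run): ≥ 90% of surviving
seeding points recovered within `d/2`, ≥ 85% of matched points classed
exactly, noiseless scenes classified without error.

## Numerical and format choices

- All randomness flows from integer seeds: scene generation and training
  sampling re-seed R's RNG locally (global state is saved and restored);
  KMeans uses its own small LCG stream, so detection is reproducible
  independently of the caller's RNG.
- Rasters are exchanged as per-band ESRI ASCII grids (full double
  precision, lossless round-trip; the reference format for tests) or as
  multiband float TIFF with an ESRI world file and a JSON sidecar holding
  per-band linear scaling (float32 precision; the GIS interchange form).
  Vector layers are GeoJSON, with a WKT-CSV alternative.
- Unknown CRS identifiers are tolerated (synthetic scenes use a local
  metric frame); no reprojection is ever attempted, and mixing CRS ids is
  the caller's error to resolve.
- Phenotype trait bins are closed so that every value maps to exactly one
  level: lower bounds inclusive, upper bounds exclusive, the top
  height/surface bins closed at their printed upper edge, and a symptom
  percentage of exactly 0 imposing no constraint. A plant's category is the
  minimum (worst) per-trait level — a single severe symptom caps the
  rating; a majority rule is available as an alternative.
- Problem sizes in the test suite (scenes of 3–10 rows, oracle rasters of
  ≤ 8×8 pixels, 20-case property loops) are chosen so the whole suite
  exercises every code path in well under a minute of segmentation time
  while keeping the brute-force oracles exact.

## Known limitations

- Plant spacing `d` must be known and roughly uniform; the area-to-k rule
  breaks down for crops with irregular spacing.
- The tiled segmentation is equivalent to the untiled run only up to the
  margin's influence bound; exact bit-compatibility with any external
  large-scale implementation is a non-goal.
- Shapefile output is not supported (GeoJSON and WKT-CSV are); no
  reprojection, no DEM handling, no radiometric calibration of raw camera
  digital numbers.
- The health index is undefined (∅) where no health-labeled segment meets
  the disc; widening `r` trades this off against mixing neighboring plants.
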
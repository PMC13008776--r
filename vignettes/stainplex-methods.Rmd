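---
title: "Methods: composite analysis of iterative multiplex immunostaining"
author: "stainplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite analysis of iterative multiplex immunostaining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainplex)
```

## The problem

Iterative chromogenic multiplex staining (MICSSS-style protocols) images
one whole tissue section many times: each round stains one marker with a
red AEC chromogen, counterstains all nuclei with haematoxylin, is
scanned, bleached, and re-stained. The result is a stack of RGB
brightfield whole-slide images of the *same* section that are neither
pixel-aligned nor spectrally separated. Turning that stack into a
single-cell table — which cell is where, which markers it expresses,
which pathologist-annotated compartment it sits in — requires colour
unmixing, geometric co-registration, a segmentation that is consistent
across rounds, and a classification step a reviewer can audit.

`stainplex` implements that pipeline as a library of composable modules,
each testable on ground-truthed synthetic slides, so no clinical images
are needed to verify any stage.

## Coordinate and intensity conventions

All modules share one convention: origin at the top-left pixel, x
rightward (columns), y downward (rows), 0-based indices, and *half-open*
rectangles (right/bottom edge exclusive). Half-openness is not cosmetic:
tile cores partition the slide exactly, which is what makes per-tile
deduplication exact (every cell centroid lies in exactly one core).

Physical scale is carried as microns per pixel (`mpp`, default 0.5, so a
1000-pixel tile spans about 500 µm); every µm threshold is converted
through `mpp` at use time. Intensities are converted to optical density,
`OD = -log10(max(I,1)/255)`, because stain concentrations mix linearly in
OD (Beer–Lambert). OD base 10 with a 255 white point is pinned so tests
can assert exact values. The features table records OD statistics; OD is
a monotone transform of transmitted intensity, so rank-based downstream
decisions (clustering order, binarization sweeps) are unaffected by the
choice.

## Colour deconvolution

Each round has its own stain matrix — three unit-norm OD vectors for
chromogen, nuclear counterstain and a residual — estimated from the
round's thumbnail: tissue pixels (OD norm above 0.15) are projected onto
the plane of the two leading principal components of OD, and the stain
vectors are read off at the 1%/99% extremes of the angular distribution
in that plane (the Macenko family of estimators). The residual vector is
the unit cross product, so the matrix is always invertible; unmixing is
then an exact per-pixel linear solve with negative concentrations
clipped to zero (clipped values are *not* renormalised — a deliberate,
documented choice, since renormalisation would distort the two retained
channels by an amount that depends on out-of-model pigment).

Assigning the two estimated vectors to "chromogen" vs "nuclear" uses
cosine similarity against reference hues (AEC is red-shifted,
haematoxylin blue-purple). One matrix per round is estimated because
every staining iteration has its own chromogen/counterstain balance.

## Masking and tiling

Background glass is bright and unsaturated, so the tissue mask
thresholds the thumbnail in HSV (saturation > 0.05, value < 0.95),
followed by morphological closing, hole filling and removal of
components under 64 mask pixels. A manually drawn region *replaces* the
automatic mask entirely — override semantics, not intersection, so a
reviewer's decision is final. All thresholds live in the run
configuration.

Tiles are 1000-px non-overlapping cores laid over the mask bounding box;
tiles whose core holds less than 5% tissue are dropped (their area is
excluded from "analysed tissue area", and both areas are recorded).
"10% overlapping borders" is implemented as a margin of
`overlap_frac/2 × tile_size` per side — 50 px at the defaults — so that
neighbouring *padded* tiles share a 100-px strip while the cores still
partition the slide. The symmetric margin gives registration and
segmentation context on every edge without double counting.

## Registration

Registration uses only the deconvolved nuclear channel: the counterstain
is the one signal assumed consistent across rounds, while chromogen
patterns change by design. Three stages:

1. **Coarse translation** between round thumbnails by phase correlation
   (Hann-windowed, cross-power spectrum peak), rescaled to level-0
   pixels. A peak whose post-shift correlation is below 0.3 is flagged
   low-confidence and zeroed. The offset is applied when cropping the
   moving round's padded tile, so tile pairs already cover roughly the
   same tissue.
2. **Affine stage** per tile: Nelder–Mead maximisation of normalized
   cross-correlation over rotation, log-scale and translation, run
   multiresolution (downscale 4, 2, 1) and initialised from tile-level
   phase correlation.
3. **Elastic stage**: block matching on a control grid — at each node
   the displacement (integer search ±8 px, quadratic subpixel
   refinement) that best correlates a 41-px fixed patch with the
   affine-warped moving tile; nodes with peak correlation below 0.2 or
   flat texture keep zero displacement. Node displacements are
   bilinearly interpolated to a dense field and composed with the
   affine map.

The control-grid spacing default is 50 px with 41-px patches: on smooth
synthetic warps of a few pixels amplitude this resolves the field to
about one pixel of mean residual, and it is pinned in the run
configuration for reproducibility. The candidates identity / affine /
affine+elastic are each scored by NCC and the best is returned, so the
reported post-metric can never fall below the identity metric — empty or
low-texture tiles degrade gracefully to the identity field. The final
field is applied unchanged to all three RGB (or OD) channels by backward
bilinear warping with white fill.

## Composite segmentation

Nuclei are segmented per round. The built-in backend — Gaussian
smoothing (σ 1.5 px), Otsu foreground threshold, small-object removal,
distance-map watershed to split touching nuclei — is deterministic,
dependency-light and accurate on the synthetic fixtures; deep pretrained
backends (StarDist/Cellpose-style) are exposed as named strategies but
not bundled, and requesting one raises an error naming it.

The per-round detections are then reconciled: a candidate nucleus is
kept iff its centroid is re-detected within 3 µm (30% of a typical 10-µm
immune-cell diameter; 6 px at mpp 0.5) in at least 60% of rounds —
*inclusive*, so 3 of 5 passes, implemented with an exact rational
comparison. Matching is greedy in (round, label) order, each candidate
claiming the nearest unconsumed centroid per other round (ties to the
lowest label), and emitted members are consumed so every detection
belongs to at most one composite cell. The candidate's own round counts
in the numerator. Greedy matching is O(n log n)-ish and, at realistic
nuclear densities (objects separated by far more than twice the match
radius), provably identical to exhaustive optimal matching — the test
suite checks it against a union-find oracle. Composite geometry comes
from the earliest detecting round (the registration reference frame);
union or intersection geometries were rejected because registration
noise inflates or erodes them.

Red-blood-cell-like objects segment (they absorb some counterstain) but
are anucleate: low nuclear OD with high residual-channel OD. The filter
flags a cell when its median nuclear OD falls below the Otsu split of
the cohort's nuclear medians *and* its median residual OD lies above the
residual split — but only when the residual split itself exceeds 0.1 OD,
so a cohort with no off-stain population is never mined for false flags.
The criterion is a documented stand-in validated on synthetic fixtures
only. Flagged cells leave the features table but are kept in a QC
output.

The cytoplasm is simulated by dilating each nucleus by 3 px (a disc
brush); expansions are independent per cell, so neighbouring rings may
overlap — a deliberate simplification that avoids sharing pixel
ownership decisions across cells.

## Quantification and deduplication

Per cell, per round, per compartment (nucleus, cytoplasm ring, whole
cell): chromogen OD min, max, percentiles {10, 25, 50, 75, 90} (linear
interpolation), mean, sd, and the median nuclear OD (the RBC filter's
input). Morphology — area, crack-boundary perimeter, ellipse axes from
second moments, eccentricity — is measured once on the composite nucleus
mask, which is by construction shared across rounds. Empty compartments
yield `NA`, never zero; for clustering only, `NA` is imputed to 0 OD.

Features are computed on padded tiles, but a record is kept only by the
tile whose half-open core contains the centroid. Cell ids serialize
(tile row, tile col, reference round, label), the table is sorted
canonically, and an id collision is a hard error because it can only
mean the deduplication invariant broke.

## Classification

Each marker is clustered independently, using that round's intensity
statistics plus the shared morphology block. Features are z-scored and
reduced by PCA to the components explaining 90% of variance. The fast
path is mini-batch k-means (k-means++ on the first batch, per-centre
counts as decaying learning rates, batch 1024, 100 iterations,
deterministic given the seed), with k = 20 clusters per marker by
default — fine enough to isolate positive populations, coarse enough to
review. Any tier can be *reclassified*: k-means on that tier's cells
only, extending hierarchical paths ("3" → "3.2"), with children always
partitioning their parent.

The slower alternative samples up to 50,000 cells, reduces by PCA, and
projects to a deterministic 2-D embedding — the two leading principal
components (chosen over neighbour-graph embeddings to keep the path
deterministic and dependency-free) — then splits the sample into up to
60 batches (~833 cells each), fits one Gaussian mixture per batch by EM
started from shared k-means centroids, pools the component means,
z-scores them per feature and merges by k-means into the final cluster
count. Unsampled cells inherit the label of their nearest sampled
neighbour in PCA space.

Binarization is data, not interaction: a decision object lists the
positive tier paths (descendants inherit positivity) and optional
per-cell overrides, which take precedence. Precision–recall sweeps
order tiers by descending mean chromogen OD; the random baseline is the
prevalence line.

## Compartments and proximity

Compartment polygons arrive as GeoJSON in level-0 pixel coordinates
(both the `classification.name` and plain `name` property dialects are
read). Point-in-polygon counts the boundary as inside; overlapping
polygons resolve by file order, the only priority signal a pathologist's
annotation file carries. Densities are positive cells per mm² with
polygon areas converted through `mpp²`.

Proximity between populations A and B is the distribution of exact
Euclidean nearest-neighbour distances (centroid to centroid, in µm —
*not* membrane contact distances) from each A cell to B, summarised by
the mode of a Gaussian KDE evaluated on a 512-point grid over
[0, max + 3·bandwidth]; bandwidth defaults to Scott's rule
`sd · n^(-1/5)`; KDE ties resolve to the smallest distance, and an
all-identical distance vector short-circuits to that value. Each
summary row carries `n_A` so downstream aggregation across samples can
weight modes if desired — the package deliberately does not choose a
weighting.

## Validation statistics

Manual pathologist clicks are matched to segmented polygons
point-in-polygon with consumption: each polygon absorbs at most one
click, points are processed in file order (the matching criterion is
defined by the data; the processing order is made visible in the QC
overlay, where unmatched clicks are drawn as 3-px circles). From the
TP/FP/FN counts come the Dice score `2TP/(2TP+FP+FN)` and specificity.

Spearman's rho is computed from ranks; for n ≤ 9 without ties the
two-sided p-value is exact — the tail probability `P(|ρ_perm| ≥ |ρ|)`
over all n! equally likely rank permutations, enumerated in full. The
plain two-sided tail was chosen over mid-p variants because it is the
standard exact definition and reproduces published small-sample values;
ties or larger n fall back to a flagged t-approximation.

## The synthetic generator

`render_micsss_panel()` emulates the data model the pipeline consumes:
white background; elliptical nuclei (semi-axes 4.5–6.5 px) rendered
through Beer–Lambert mixing with a known stain matrix; AEC chromogen in
3-px cytoplasm rings of marker-positive cells on their round;
anucleate high-residual discs as RBC stand-ins; single-round nuclear
artefacts; per-round cell dropout; known per-round affine plus smooth
sinusoidal elastic warps (generated *forward* and stored, so
registration error is measurable in pixels against analytic truth
rather than by image similarity); Gaussian pixel noise. Default study
conditions for the composite-segmentation checks are 5 rounds, 500
cells, 20 artefacts, 10% dropout on a 1400² px slide — dense enough to
exercise consensus matching, small enough that the whole suite runs on
one CPU. The registration checks use a 400² px tile with 120 nuclei
warped by a 2° rotation, a (6, 3) px shift and a 5-px sinusoidal
elastic field.

What the generator does **not** emulate — and therefore what passing
tests do not show about clinical slides: histological texture and
stromal background, chromogen co-localisation within one round, uneven
illumination and scanner artefacts, tissue folds and tears, and true
segmentation ambiguity (overlapping nuclei in 3-D). Synthetic results
bound algorithmic correctness, not biological performance.

## Numerical choices and degenerate inputs

* Otsu thresholds are computed on 256-bin histograms; constant vectors
  return the constant.
* Consensus comparison uses a 1e-9 tolerance so 3/5 ≥ 0.6 holds exactly
  in floating point.
* Percentiles use the linear-interpolation definition (R type 7).
* Empty tiles, blank rasters, empty masks and empty point sets return
  empty results (with warnings where the spec of the operation demands
  one); violated preconditions (zero-area bounds, empty population B,
  singular stain matrices, k > n) raise errors naming the problem.
* All stochastic steps (mini-batch k-means, GMM batching, the
  generator) take explicit seeds and restore the caller's RNG state.

## Known limitations

* The built-in segmentation backend is tuned for rounded nuclei on
  clean backgrounds; clinical brightfield tiles will generally need a
  pretrained deep backend plugged into the same strategy interface.
* The elastic model (50-px control grid) cannot follow deformations
  sharper than its grid, and block matching needs local texture; the
  fallback ladder only guarantees no *degradation*.
* Doublet resolution (reassigning co-positive cells by probability) is
  out of scope, as is membrane-marker segmentation and any
  intensity-calibrated cross-scanner comparison.
* The GMM path's embedding is linear; strongly non-linear population
  structure may merge in 2-D that k-means on full PCA scores would
  separate.
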
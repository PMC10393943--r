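---
title: "Pixel-level phenotyping: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-level phenotyping: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pixphen)
```

## The problem

A multiplexed imaging experiment yields one grayscale image per marker per
field of view (FOV). Cell-centric analysis integrates marker signal inside
segmentation masks and clusters the resulting per-cell vectors, which has
two structural weaknesses. First, much informative signal lies outside
cells (extracellular matrix, vessels, deposits) or in objects segmentation
cannot capture (dendrites, elongated or anucleated structures). Second, in
dense tissue, bright signal along a cell's perimeter bleeds into the
integration region of its neighbors, so a dim cell flanked by a bright one
inherits a contaminated profile. `pixphen` addresses both by phenotyping
individual pixels with unsupervised clustering and, optionally, re-deriving
cell phenotypes from the *composition* of pixel phenotypes inside each
mask, where a handful of contaminating boundary pixels can no longer
dominate.

## The model and its assumptions

Pixel phenotyping assumes that a pixel's phenotype is encoded in the
*ratios* of its marker intensities, not in their absolute level. The
normalization cascade embodies this assumption:

| Step | Operation | Default | Why |
|---|---|---|---|
| smoothing | per-channel Gaussian blur | σ = 2 px | counting dropout makes single-pixel values unreliable; smoothing restores the local expression distribution. Smaller σ (e.g. 1.5) suits small histological regions; σ = 0 suits inherently low-resolution modalities |
| exclusion | drop pixels at zero across all clustering markers | — | all-zero rows carry no ratio information and would break pixel normalization |
| pixel norm | divide each pixel by its total signal | on | removes per-pixel absolute-intensity effects: instrument drift, staining batches, per-cell biological brightness |
| marker norm | divide each marker by its dataset-wide 99.9th percentile | quantile 0.999 | equalizes marker contributions so systematically bright channels cannot dominate Euclidean distances |

Both normalizations can be disabled individually
(`pixel_norm`/`marker_norm` in `pixel_run_config()`) to reproduce ablation
experiments; with a gain difference between FOVs, dropping pixel
normalization demonstrably changes the clustering (this is a unit test).

Clustering is deliberate *over*-clustering: a 10 × 10 SOM (100 clusters)
followed by consensus hierarchical metaclustering down to a user-chosen
`k`. Overclustering preserves rare phenotypes that a direct k-clustering
would absorb; the metaclustering step, and a manually editable remap table,
turn the fine clusters into interpretable phenotypes. `k` is a scientific
choice, not an optimization target, so the package offers no automatic
selection.

### SOM specifics

Online training: `passes` (default 10) seeded-shuffled sweeps; learning
rate decays linearly 0.05 → 0.01 over all steps; the neighborhood is
Gaussian in grid Chebyshev distance with radius decaying linearly from half
the grid diagonal to 1. Nodes are initialized from sampled training rows,
which avoids dead units. Assignment is exact nearest-node with ties broken
to the lowest node id, and is a pure per-row function, so appending rows
never changes existing assignments.

The exact neighborhood schedule is not canonical; any schedule honoring the
stated start/end learning rates is defensible, so equivalence with other
implementations should be asserted at the level of recovered partitions,
not weight matrices. All schedule constants, including the radius
endpoints, are exposed in `som_config()`. One practical note: with the
default end radius of 1, small grids (4 × 4 and below) stay strongly
coupled and may populate fewer distinct nodes than expected; for cell-level
clustering of small datasets use a 5 × 5 grid or lower `radius_end`. The
grid never shrinks silently — too few observations for the grid is an
error.

### Consensus metaclustering

"Consensus hierarchical clustering" names a family rather than one fixed
algorithm; the package follows the recipe standard in cytometry
metaclustering: 100 rounds, each drawing 80% of the cluster rows (item
resampling; feature resampling is not used), average-linkage hierarchical
clustering of each draw cut at `k`, co-assignment tallied as
(co-clustered / co-sampled), and a final average-linkage clustering of
`1 − consensus` cut at `k`. With `item_subsample = 1` and one iteration
this reduces exactly to plain hierarchical clustering, which the tests use
as an oracle. `k = n` returns the identity partition directly.

Cluster profiles are z-scored per marker with the sample SD and capped at
z = 3 *from above only*: the cap exists to flatten bright outliers, so it
is a ceiling, not a clamp — negative z-scores pass through. A symmetric
cap is available behind a flag, default off. Zero-variance markers map to
z = 0 rather than dividing by zero.

## Cluster consistency score

Stochastic clustering must be reproducible to be trusted. The score runs
the identical configuration `n = 5` times with seeds `base_seed + 0..4`,
then, for each cluster `c` of each replicate `r`, finds for every other
replicate the minimum number of clusters needed to cover 95% of `c`'s
members (counts sorted descending, ties by ascending cluster id), and
averages the pairwise values. Observations inherit the score of their
cluster in each replicate, averaged over replicates. The coverage target is
the exact real-valued product — 95% of 1,000 pixels is 950; 95% of 4 pixels
(3.8) requires all 4 — with a 1e-9 slack that only absorbs binary
representation error of `coverage × n`, never a whole pixel. Per-cluster
averaging is unweighted; no
size-weighting is applied. The metric is clustering-agnostic: any aligned
label vectors can be scored, not only this package's runs.

Properties asserted as tests: 1 is the exact floor (attained by any five
identical partitions however relabeled), scores never exceed the compared
replicate's cluster count, relabeling never changes scores, and the mean
score is monotone non-decreasing in coverage.

## The synthetic world

The generator exists so every stage has checkable ground truth. It
emulates: latent phenotypes with sparse marker signatures (one dominant
marker ~10 counts, secondaries ~3, all other markers exactly zero),
elliptical non-overlapping cells placed by rejection sampling, Poisson
counting noise (`poisson_scale`, 0 = noise-free), per-pixel-and-marker
dropout (default 5%, chosen so the dominant marker stays recoverable for
≥ 90% of in-cell pixels at default noise — dropout of 10% would sit at the
margin), per-FOV gain factors (instrument drift), optional per-cell
lognormal brightness variation (biological intensity differences within a
phenotype), and additive boundary spillover: pixels of a neighboring cell
within `spillover_width` of a cell's footprint receive
`spillover_frac = 0.5` of its boundary intensity. Marker subsets are drawn
as blocks of concatenated random permutations so that every marker is used
by some phenotype whenever capacity allows — a panel with a dead marker
would (correctly) abort the cascade with the zero-percentile error.

What it does **not** emulate: realistic tissue morphology, nuclear /
membrane channels, segmentation errors, platform-specific artifacts,
autofluorescence, or background noise outside cells. A green recovery test
therefore establishes the pipeline's correctness on its own stated terms —
separable ratio-encoded phenotypes — not performance on real tissue.

The spillover comparison world (the basis of the composition-vs-integrated
acceptance criterion) is deliberately harsh in exactly the way dense tissue
is: 150 small cells (radii 2.5–4.5 px) per 128 × 128 FOV (~35% of the image
is cell mass, most cells touching), spillover width 2, and per-cell
brightness varying with lognormal SD log 2 (cells of one phenotype span
roughly a 4× intensity range). Under these conditions integrated expression
mixes dim cells with their bright neighbors' markers while pixel-composition
features — which see only discretized pixel phenotypes — stay clean; with
homogeneous brightness and sparse placement both featurizations are
trivially perfect and the comparison degenerates to a tie.

## Numerical choices

- Quantiles use the linear-interpolation definition (R type 7) everywhere.
- The blur kernel is truncated at 4σ and normalized; boundaries reflect.
- Zero-pixel exclusion is evaluated on *blurred* values (the cascade order
  lists blurring first, so a raw-zero pixel with nonzero neighbors enters
  the analysis as a mixture). Percentiles are fitted once on the full
  retained pixel set of all FOVs pooled, before any subsampling, so
  training and assignment see identical scaling.
- Fully-normalized values are rounded to single precision before
  clustering. Raw marker images are 32-bit floats, so deeper digits are
  spurious; concretely, this makes the clustering input bit-identical under
  global intensity rescaling. Without it, one-ulp differences can flip an
  early best-matching-unit choice and online SOM training amplifies the
  flip into visibly different (if statistically equivalent) maps, breaking
  the exact scale-invariance property the cascade is supposed to have.
- Ties everywhere break deterministically: lowest node id (SOM), ascending
  cluster id (coverage counting), first-seen class (majority F1 mapping).
- Positivity filters are strictly greater-than, matching the "expression
  > 0" convention for region sub-setting.

## Open design points and how they were resolved

- *Percentile scope*: dataset-wide, not per-FOV — normalization must be a
  single map applied to training and assignment data alike. Flagged
  because per-FOV percentiles would partially re-introduce batch
  robustness at the cost of comparability; the pixel-normalization step
  already handles batch scale.
- *Cell features at which cluster level*: both the ~100 SOM clusters and
  the annotated metaclusters are supported (`cell_pixel_composition` takes
  whichever id vector you pass); metacluster level is the documented
  default as it matches the annotated-phenotype workflow.
- *Consistency score level*: metacluster by default, SOM level via
  `level = "som"`.
- *F1 averaging*: macro (unweighted) and support-weighted are both
  reported, since the averaging convention for the published comparison is
  unstated.
- *Spearman "R²"*: plain ρ and ρ² are both reported.

## Known limitations

- Phenotypes distinguished only by the *level* of the same markers cannot
  be separated — pixel normalization erases level information by design.
  The workflow answer is a second clustering pass restricted (via the
  positivity filter / region mask) to the cluster of interest.
- The package consumes segmentation masks; it does not produce them, and
  it deliberately performs no background subtraction, denoising, or
  channel-spillover compensation — inputs are expected to be artifact-
  cleaned.
- The TIFF codec is intentionally minimal: uncompressed single-channel
  grayscale baseline TIFF only. It exists because the runtime environment
  offers no TIFF package; compressed or multi-sample files are rejected
  with clear errors.
- The consistency score requires identical retained-pixel lists across
  replicates; pixel exclusion is deterministic, so this holds by
  construction, but externally supplied label vectors must be aligned by
  the caller.

Every empirical number quoted in the package documentation is computed by
the test suite or the acceptance script; nothing is asserted that the code
does not itself measure.
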
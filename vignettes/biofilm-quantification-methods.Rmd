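---
title: "Quantifying heterogeneous biofilm colonization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterogeneous biofilm colonization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmq)
```

## The problem

Acidophilic bacteria such as *Sulfobacillus acidophilus* colonize elemental
sulfur and sulfide minerals in highly heterogeneous patches, which makes
quantifying biofilm formation image-intensive: a single condition can require
hundreds of epifluorescence fields before summary statistics stabilize.
`biofilmq` implements the quantitative half of such a study as a reusable,
testable pipeline:

1. **Imaging model** — tiled DAPI-channel mosaics (typically 4 × 4 fields per
   mosaic) acquired over sulfur pearls, organized as
   condition → biological replicate → pearl → mosaic → tile. At the
   reference calibration, a 5,135 px mosaic width images 947.5 µm, i.e.
   0.1845 µm/px, and the reference design (3 replicates × 4 pearls ×
   4 mosaics × 16 tiles) yields 64 tiles per pearl, 256 per replicate and
   768 per condition.
2. **Per-tile quantification** — colony density (microcolonies/mm²) and
   percent colonized area from a classical fluorescence processing chain.
3. **Sampling sufficiency** — a coefficient-of-variation (CV) procedure over
   random image subsets certifying that enough tiles were analyzed.
4. **Condition comparison** — Kruskal–Wallis omnibus and Dunn's post-hoc
   tests on the per-tile metrics.
5. **Transporter screening** — a separate, rule-based module that builds a
   sugar-transporter inventory from tabular homology/topology/operon
   records.

Because no public micrograph collection accompanies this kind of assay, the
package ships a synthetic tile generator with exact ground truth; every
processing stage is validated against it or against independent brute-force
oracles.

## The synthetic tile generator

`tile_spec()` / `generate_tile()` emulate one DAPI field:

- **Colony count** is Poisson with mean `colony_density_per_mm2 ×` tile area.
  The default density (2,500/mm²) puts ~22 colonies on a default 512 × 512 px
  tile — enough for stable per-tile statistics while keeping overlap merging
  rare (~3% of area covered).
- **Placement** is uniform (`clustering_factor = 1`) or a Thomas cluster
  process: ~`n/clustering_factor` uniform parent points with Gaussian
  offspring scatter (`cluster_sd_um`, default 15 µm). The Thomas process is
  the standard model for patchy surface colonization; offspring falling
  outside the tile are redrawn so counts are preserved.
- **Colony shape** is a filled disk with a Gaussian-feathered edge
  (σ = 1 px), approximating diffraction blur without an optics model. Radii
  are Gaussian (mean 2 µm, SD 0.6 µm, truncated at 0.2 µm). The colony size
  distribution on sulfur is not characterized in the literature; these
  defaults are free parameters of the artifact, not biological claims.
- **Background** is `background_level × (1 + amplitude × field)` with a
  linear (diagonal) or radial field spanning ±amplitude/2 — the smooth
  uneven illumination the rolling ball is meant to remove.
- **Noise** is additive zero-mean Gaussian (`noise_sd`, default 200 on a
  16-bit scale). Poisson shot noise is deliberately omitted: the chain is
  threshold-based, not photometric, and an additive model keeps ground
  truth exact.
- **Determinism**: one integer seed makes a tile bit-reproducible.
  `generate_experiment()` derives per-tile seeds by stable string hashing of
  the design coordinates from one master seed, so any subset of a dataset
  can be regenerated independently.

Ground truth records placed colony count, the count after overlap merging
(connected components of the true mask), the binary mask, percent area and
per-colony centers/radii.

What the generator does *not* emulate: z-stacks (inputs are assumed
depth-compiled), multi-channel lectin staining, optical PSFs, autofluorescent
sulfur texture, and spatially correlated noise. Passing tests therefore show
that the chain recovers known truth under the stated noise model — not that
it is robust to every artifact of real acquisitions.

## The per-tile processing chain

`process_tile()` runs, in order:

1. `enhance_contrast()` — linear stretch of the [0.05, 99.95] intensity
   percentiles onto the full range (a robust "best fit" stretch).
2. `sharpen()` — unsharp mask, `out = in + amount × (in − G_σ(in))`
   (default amount 1, σ = 2 px).
3. `rolling_ball_background()` — grayscale opening by a **spherical**
   structuring element (default radius 25 px ≈ 4.6 µm, comfortably larger
   than a microcolony), subtracted from the image. The opening is computed
   exactly (no downsampling approximation) by branchless streaming
   erosion/dilation in C++; it never exceeds the image, so the corrected
   tile is non-negative, and it is idempotent.
4. `binarize()` — Otsu's threshold on the corrected histogram (256 levels)
   by default; fixed and percentile thresholds are available.
5. `label_colonies()` — connected components (8-connectivity by default),
   removal of components under `min_area_px` (default 5 px; a 1 µm coccus
   covers ≈ 23 px² at the default scale), and boundary tracing.
6. `compute_tile_metrics()` — density = count / area(mm²) and
   % area = 100 × mask pixels / total pixels.

Colonies touching tile borders are counted, not discarded: no exclusion rule
is standard for this assay, and keeping them leaves densities unbiased on
average (a border-straddling colony is simply attributed to each tile it
touches when a mosaic is split).

### Numerical choices worth knowing

- **Otsu separability guard.** On a tile with no colonies at all, the
  corrected histogram is a single noise mode and Otsu's threshold would
  split it in half, producing dozens of spurious one-to-ten-pixel
  "colonies". `binarize()` therefore computes Otsu's effectiveness measure
  η (between-class variance over total variance) and declares the tile
  colony-free when η < 0.75. In synthetic experiments the two regimes are
  cleanly separated (η ≈ 0.68 for pure noise vs ≥ 0.91 with colonies);
  `min_separability = 0` disables the guard.
- **Spherical, not flat, structuring element.** The ball has height
  `sqrt(r² − d²)` (in intensity units, scalable via `ball_height_scale`).
  One consequence: under an isolated 1 px spike the background may bulge by
  up to `z(0) − z(1)` (≈ 0.1 for r = 5) rather than stay perfectly flat.
  Because the heights are irrational, float rounding can push the opening
  above the image by ~1e−10; both the implementation and its test oracle
  clamp to the image, which is the anti-extensivity contract.
- **Border handling**: morphology restricts the structuring element to
  in-bounds pixels; convolution uses edge replication. Pixel coordinates are
  0-based, row-major, origin top-left; mosaics split into half-open
  intervals with the remainder absorbed by the last row/column.
- Intensities are processed in double precision; TIFFs are read/written as
  8- or 16-bit integer (16-bit default, full scale 65,535).

## Sampling sufficiency by subset CV

For each group size *g* in {1, 2, 9, 18, 36, 72}, `subset_cv_curve()` draws
four random subsets of *g* tiles (without replacement within a subset;
subsets independent of each other), takes each subset's mean of the chosen
metric, and reports the CV (sample SD / mean × 100) across the four means.
Sampling is *sufficient* when the CV at the largest size is below the
threshold (default 10%); the report also names the first size from which all
later CVs stay below it.

Interpretation decisions, made once and documented here: "CV across subsets"
means the CV of the subset means (between-subset stability of the estimate,
which is what sufficiency is about); the sample (n−1) SD is used; and the
procedure is run per biological replicate for both colony density and
percent area, since the source workflow does not say which metric was used.
For i.i.d. tiles the curve scales as 1/√g — the package's property tests
verify a log–log slope of −0.5 ± 0.15 — so the four-subset CV at 72 tiles
sits near 1% under homogeneous colonization, far below the 10% criterion.

## Comparing conditions

`kruskal_wallis()` computes the tie-corrected H (via `stats::kruskal.test`)
with a chi-square reference on k − 1 degrees of freedom; `dunn_posthoc()`
implements the rank-based pairwise z-tests with tie-corrected standard
errors, run by default only when the omnibus test is significant. The
adjustment default is Holm — conservative and order-respecting — with
Bonferroni, Šidák and none as options, since the original workflow does not
state its adjustment. Stars follow the four-level convention
(**** = p < 0.0001).

Tests default to tile-level values, the unit the sampling design counts.
Tiles within a replicate are pseudo-replicates in the strict sense; for a
conservative alternative `compare_conditions(level = "replicate")` tests
replicate medians. Both pooling modes are provided because the source
workflow does not state which was used.

The chi-square approximation is accurate well below the design's tile
counts: at n = 7 it is within 0.023 of the exact permutation p-value, and
under the null (identical Poisson-count conditions, 3 × 64 tiles) the
rejection rate at α = 0.05 stays within [0.03, 0.08] across 500 seeded
simulations.

## The transporter screen

The screening module applies published decision rules to plain TSV tables
(the package deliberately replaces live homology/topology servers with
file-based inputs; the rules, not the tools, are the content):

- retain homology hits with bit score **strictly greater than** 100;
- keep MFS and NCS-1 candidates only with exactly 12 predicted TM helices,
  ABC TM subunits only with 3 or 6;
- classify ABC carbohydrate-uptake operons: two TM genes → CUT-1 (complete
  even without an operon-local NBP when a shared NBP exists genome-wide),
  one TM gene with adjacent NBP and SBP → CUT-2, otherwise incomplete;
- call orthologs by bidirectional best hit; ties in either direction yield
  no call (no tie rule is published; abstaining is the conservative choice);
- signal peptides are recorded as annotation, never used for rejection, and
  substrate labels are carried through from the inputs, never inferred.

Operon roles extend the core {SBP, NBP, TM} set with `EII` so
phosphotransferase (PTS) systems fit the same table; a PTS operon needs at
least three components to count as a system, so isolated
dihydroxyacetone-kinase-like homologs contribute nothing. The packaged
fixture under `inst/extdata/sulfobacillus/` is a synthetic reconstruction of
a published two-genome inventory (see its README for what is reconstructed
vs invented); the screen recovers its family counts and the four MFS
ortholog pairs exactly, with decoy rows proving each filter does work.

## Problem sizes in the test suite

The suite validates at sizes chosen to exercise every rule while keeping a
full run in a few minutes: unit tests use 32–256 px tiles and radius-5–15
balls against brute-force oracles; the sufficiency check quantifies one full
256-tile replicate at the default 512 px tile size; parameter recovery runs
64 tiles per condition through the full imaging chain (its 100-replication
power companion uses ground-truth Poisson counts at the same parameters —
repeating the imaging chain 100 times would add hours without changing what
is being tested); the Poisson-law check uses 400 seeded tiles.

## Known limitations

- The generator's colony-appearance model is simple (feathered disks,
  additive Gaussian noise); detection accuracy on real sulfur-pearl imagery
  will depend on artifacts it does not model.
- Otsu thresholding assumes a bimodal corrected histogram; very dense
  biofilms (coverage approaching 50%) or very low contrast would need the
  fixed/percentile threshold modes.
- The exact rolling-ball opening is O(image × ball area); the default
  512 px tile with a 25 px ball takes well under a second, but full
  5,135 × 3,841 mosaics are better split first (`split_mosaic()`), which is
  also the unit the sampling design counts.
- Tile-level testing inherits the pseudo-replication caveat above; no
  mixed-effects modelling is provided.
- The CUT-1/CUT-2 classifier trusts the input role assignments; it does not
  re-derive roles from sequence.
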
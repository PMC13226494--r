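# biofilmq

Quantitative analysis of heterogeneous biofilm colonization on mineral
surfaces from tiled epifluorescence micrographs — plus a rule-based screen
for candidate sugar transporters from tabular genome-survey records.

Bioleaching bacteria such as *Sulfobacillus acidophilus* colonize elemental
sulfur in irregular patches, so "how much biofilm formed?" is answered by
imaging hundreds of DAPI-stained fields per condition and reducing each to
two numbers: **colony density** (microcolonies/mm²) and **percent colonized
area**. `biofilmq` implements that workflow end to end for researchers
running (or re-analyzing) such assays:

- a seeded **synthetic tile generator** with exact ground truth
  (Poisson/Thomas colony placement, uneven illumination, sensor noise), so
  the whole chain is testable without microscope data;
- the **per-tile processing chain**: percentile contrast stretch → unsharp
  mask → **rolling-ball background subtraction** (exact grayscale opening by
  a spherical element, in C++) → Otsu thresholding → microcolony labeling →
  metrics;
- the **sampling-sufficiency check**: for group sizes 1, 2, 9, 18, 36, 72,
  the coefficient of variation CV = 100·sd/mean across four random
  subset means of a metric; sampling suffices when CV at the largest size is
  below 10%;
- **nonparametric condition comparison**: tie-corrected Kruskal–Wallis H
  with χ²(k−1) reference, Dunn's post-hoc z-tests
  (z = (R̄ᵢ − R̄ⱼ)/SE with tie-corrected SE), Holm-adjusted by default;
- the **transporter screen**: bit score > 100 retention, 12-TM filter for
  MFS/NCS-1, 3-or-6-TM filter for ABC TM subunits, CUT-1/CUT-2 operon
  classification, bidirectional-best-hit orthology.

Everything user-facing takes and returns tibbles and chains with the pipe;
results have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

A small synthetic experiment — two conditions, one replicate, 2 pearls ×
2 mosaics × 4 tiles each, with fructose supplementation programmed as a 2×
density and coverage effect:

```r
library(biofilmq)

cfg <- pipeline_config(
  design = experiment_design(c("control", "fructose"), replicates = 1,
                             pearls = 2, mosaics = 2,
                             tile_rows = 2, tile_cols = 2),
  base_spec = tile_spec(width_px = 256, height_px = 256),
  condition_effects = list(control  = c(density = 1, coverage = 1),
                           fructose = c(density = 2, coverage = 2)),
  quant = quant_config(ball_radius_px = 20),
  cv_group_sizes = c(1, 2, 9),
  seed = 42
)
res <- run_experiment(cfg, "demo_run")

summarize_conditions(res$metrics, "colony_density_mm2")
#> # A tibble: 2 × 6
#>   condition     n median   q25   q75   iqr
#>   <chr>     <int>  <dbl> <dbl> <dbl> <dbl>
#> 1 control      16  2241. 1345. 2802. 1457.
#> 2 fructose     16  4483. 3586. 5379. 1793.

res$comparison$omnibus
#> <kw_test> H = 18.2282, df = 1, p = 1.96e-05 (n = 32, 2 groups)

res$comparison$pairwise
#> # A tibble: 1 × 6
#>   group1  group2       z   p.value p.adjusted stars
#>   <chr>   <chr>    <dbl>     <dbl>      <dbl> <chr>
#> 1 control fructose -4.27 0.0000196  0.0000196 ****

res$cv[["control/rep1/pct_colonized_area"]]
#> <sufficiency_report> metric pct_colonized_area: sufficient (threshold 10.0%)
#>   stabilized below threshold from group size 9
#> # A tibble: 3 × 2
#>    size cv_pct
#>   <int>  <dbl>
#> 1     1  27.3
#> 2     2  37.5
#> 3     9   5.56
```

Reading the output: the detected median density roughly doubles under
fructose (4,483 vs 2,241 colonies/mm² — the programmed 2× effect), the
omnibus rank test rejects equality (H = 18.2 on 1 df), Dunn's post hoc flags
the pair at the **** level, and the CV curve for the control replicate drops
below the 10% criterion by group size 9, i.e. this (tiny) replicate was
sampled sufficiently for percent area. `run_experiment()` also writes
`metrics.csv`, `cv_report.csv`, `stats.json` and a manifest with the
configuration hash into the output directory.

The transporter screen runs from TSV tables; the packaged synthetic
reconstruction of a two-genome *Sulfobacillus* survey is at
`system.file("extdata", "sulfobacillus", package = "biofilmq")`:

```r
ext <- system.file("extdata", "sulfobacillus", package = "biofilmq")
inv <- screen_transporters(
  file.path(ext, "synthetic_hits.tsv"),
  file.path(ext, "synthetic_topology.tsv"),
  file.path(ext, "synthetic_operons.tsv"),
  file.path(ext, "synthetic_mfs_scores_ab.tsv"),
  file.path(ext, "synthetic_mfs_scores_ba.tsv")
)
inv
#> <transporter_inventory> 50 systems across 2 genome(s), 4 ortholog pair(s)
#> # A tibble: 2 × 6
#>   genome                 `CUT-1` `CUT-2`   MFS `NCS-1`   PTS
#>   <chr>                    <int>   <int> <int>   <int> <int>
#> 1 S_acidophilus                5       3     8       7     1
#> 2 S_thermosulfidooxidans       5       3     8      10     0
```

A thin command-line wrapper with `simulate` / `quantify` / `sufficiency` /
`compare` / `screen` / `run-all` subcommands is installed at
`system.file("scripts", "biofilmq-cli.R", package = "biofilmq")`.

## Package layout

- `R/` — generator (`tile_spec`, `generate_tile`, `generate_experiment`),
  imaging chain (`process_tile` and its stages), sufficiency
  (`subset_cv_curve`, `sufficiency_check`), statistics (`kruskal_wallis`,
  `dunn_posthoc`, `compare_conditions`), screen (`screen_transporters` and
  its rules), orchestration (`pipeline_config`, `run_experiment`).
- `src/` — exact ball-morphology, labeling, rendering and blur kernels.
- `vignettes/biofilm-quantification-methods.Rmd` — models, parameter
  rationale, numerical choices, limitations.
- `tests/testthat/` — unit and property tests with brute-force oracles,
  plus the end-to-end acceptance checks.
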
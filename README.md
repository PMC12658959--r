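# depthfd

Taxonomic and functional diversity of demersal fish assemblages across
depth gradients.

## The problem

Stereo-video transect surveys of reef and deep-slope fish communities
produce per-individual records (taxon, length) on transects nested in depth
bands and atolls. Ecologists use these to ask how community structure and
*vulnerability to disturbance* change with depth: communities whose species
share few life-history strategies (low trait redundancy) lose ecological
functions more easily when species are lost. `depthfd` implements the whole
chain from raw observations to conservation-priority scores, for analysts
working with multi-depth-band visual survey data:

- **Survey processing.** Stereo-camera calibration faults that underestimate
  lengths by a fraction *u* are corrected by the multiplier 1/(1 − *u*)
  (e.g. *u* = 0.46 → 1.85). Missing lengths are filled from conspecific
  means (transect, then atoll). Biomass uses the allometric relation
  *W* = *a·L^b* (*L* in cm, *W* in g), with surrogate *a*, *b* constants
  for taxa unresolved below genus/order. Abundance and biomass are
  standardised per 100 m² of transect.
- **Taxonomic diversity.** Kruskal–Wallis and FDR-corrected pairwise
  Mann–Whitney tests across depth bands; Bray–Curtis dissimilarity on
  square-root transformed densities; PCoA ordination; one-way PERMANOVA
  (pseudo-*F* from the distance decomposition, label permutations) and
  PERMDISP (distances to group centroids in the real/imaginary PCoA
  embedding) — all seeded and reproducible, with an exhaustive-enumeration
  mode for small designs.
- **Trait space.** Eight categorical life-history traits (age at first
  maturity, generation time, maximum length, minimum population doubling
  time, fishing vulnerability, water-column position, temperature range,
  vertical home range). Traits with pairwise Kendall |τ| > 0.8 are pruned;
  missing cells (and DD/NE IUCN statuses) are imputed by iterative
  random-forest imputation (100 trees, out-of-bag PFC reported); species
  coordinates come from a PCoA of Gower distances, with the mean absolute
  deviation (mAD) index scoring each candidate dimensionality.
- **Functional diversity.** Functional entities (unique trait combinations)
  give redundancy FRed = S/K, over-redundancy FOR (percent of species in
  excess in above-average entities) and vulnerability FVul (percent of
  single-species entities). In trait space: FRic (convex-hull volume as a
  fraction of the pool hull, computed by a general-dimension incremental
  hull), FDis (abundance-weighted mean distance to the weighted centroid),
  FEve (regularity along the minimum spanning tree), FSpe (scaled distance
  to the pool centroid) and FUn (scaled mean distance to the *k* nearest
  neighbours).
- **FUSE.** The conservation-priority index
  `FUSE = ln(1 + FUn·GE) + ln(1 + FSpe·GE)`, where GE is the IUCN threat
  rank (LC = 0, NT = 1, VU = 2, EN = 3, CR = 4), with a ranked species
  table annotated by habitat class (shallow ≤ 30 m, MCE 30–150 m, deep
  > 150 m), atoll occurrence and density.

A synthetic survey generator (`simulate_survey()`) emulates the field
design — 7 depth bands (2–500 m) × 5 atolls × 3 replicate 250 × 5 m
transects, a ~300-species pool with depth-band affinities, habitat-filtered
traits, negative-binomial counts and lognormal lengths — so every stage is
testable without field data.

## Worked example

```r
library(depthfd)
survey <- simulate_survey(n_species = 300, design = survey_design(seed = 42))
fit <- depthfd(survey$observations, survey$transects, survey$traits,
               survey$lw_constants, scheme = survey$scheme,
               n_perm = 999, seed = 42)
print(fit)
summary(fit)
```

```
Depth-gradient diversity analysis
   105 transects, 295 species, 150 functional entities
  trait space: 4 PCoA axes (mAD-best m = 6 )
  PERMANOVA depth effect: pseudo-F = 4.726 , p = 0.001
  top FUSE species: sp063, sp031, sp118
Per-depth-band medians:
 depth_band_m richness abundance   FRic FRed  FVul
            2       33     25.84 0.1097 1.27  78.6
           10       43     40.08 0.2415 1.19  85.7
           30       38     28.96 0.2440 1.12  88.2
           60       20      9.68 0.1160 1.12  87.5
          120       13      4.80 0.0521 1.00 100.0
          250        7      1.44 0.0111 1.00 100.0
          500        8      2.48 0.0154 1.12  87.5
```

Richness and functional richness (FRic, hull-volume fraction of the pool)
peak at 10–30 m and collapse towards 250 m; redundancy (FRed, species per
functional entity) is lower — and the fraction of single-species entities
(FVul) higher — in the 120–500 m bands than at 10–60 m. That is the
depth-vulnerability signature the package is built to quantify: deep
assemblages have almost no trait overlap, so each species loss removes a
trait combination outright. The PERMANOVA confirms depth structures
community composition (pseudo-F = 4.73, p = 0.001 at 999 permutations).

Species-level scores work directly from published inputs too, e.g. a
critically endangered species with FUn = 0.44 and FSpe = 0.91:

```r
fuse(0.44, 0.91, ge_rank("CR"))
#> [1] 2.549945
```

## Documentation

The methods vignette (`vignettes/depth-gradient-fd.Rmd`) describes the
statistical procedures, the generator's assumptions, numerical choices and
known limitations. Every exported function has roxygen documentation.
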
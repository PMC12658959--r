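---
title: "Methods: depth-gradient taxonomic and functional diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-gradient taxonomic and functional diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthfd)
```

`depthfd` analyses demersal fish communities sampled by stereo-video
transects across depth bands. This vignette is the package's own account of
the methods: the statistical procedures and their assumptions, the tunable
parameters, what the synthetic generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## 1. From observations to density matrices

The analytical unit is a *transect*: a belt of known length (250 m by
default, 140 m where a camera failed mid-survey) and width (5 m), assigned
to a depth band and an atoll. The raw input is one row per observed fish:
taxon, identification level (species / genus / order), and total length in
cm where measured.

**Length correction.** Stereo-camera calibration faults shrink measured
lengths by a known fraction `u`; affected transects carry a
`calibration_flag` and their lengths are multiplied by
`1 / (1 - u)` (`correction_factor()`; `u = 0.46` gives 1.85 at two
decimals). The correction is applied before any length is used.

**Missing lengths.** An unmeasured individual takes the mean measured
length of conspecifics on the same transect. The same-transect rule is the
primary convention; where no conspecific was measured there, we fall back
to the species mean within the same atoll, and where none exists anywhere
the individual is excluded from biomass but kept in abundance. The
fallback chain is a package design choice (the alternative — silently
dropping such fish — loses data without notice); every fallback and
exclusion is counted in the `fill_log` attribute and exclusions warn.

**Biomass.** Weight in grams is `W = a * L^b` with species-specific
constants. Taxa identified only to genus or order (e.g. anthias at 60 m,
eels at 500 m) inherit the constants of the most abundant resolved species
of the same group on the same transect, then in the same *location*. We
interpret "location" as atoll x depth band — the natural sampling stratum
of the design; a study-wide donor is used as a last resort, and taxa with
no resolved group member anywhere are a hard error. Ties are broken by
study-wide abundance, then lexicographically, so surrogate assignment is
deterministic under row reordering.

**Densities.** Matrix cell (t, s) is the count (or summed grams) of s on t
times `100 / (length_m * width_m)`. Unresolved taxa live in reserved
`unid.*` columns: they count in density totals but never in species
richness or composition analyses. Three invariants are enforced by tests:
biomass is conserved by aggregation, length correction and surrogate
assignment never change counts, and doubling transect area halves every
density.

## 2. Taxonomic diversity and composition

Depth band is treated as a categorical fixed factor throughout: bands are
survey targets, not a continuous covariate.

Univariate metrics (richness, abundance and biomass density) are compared
across bands with a Kruskal–Wallis test and pairwise two-sided
Mann–Whitney tests under Benjamini–Hochberg FDR. The Mann–Whitney switches
to exact enumeration when both groups have at most 8 observations and no
ties — where enumeration is cheap it is preferred to the normal
approximation; elsewhere the approximation uses tie and continuity
corrections.

Composition uses Bray–Curtis dissimilarity on square-root transformed
species-level abundances. Two all-zero transects are given distance 0
(with a warning) rather than NaN, so ordination never silently drops
samples. PCoA is Gower double-centering plus eigendecomposition; axes with
negative eigenvalues (Bray–Curtis is not Euclidean-embeddable in general)
are dropped from coordinates and their total magnitude reported.

**PERMANOVA** is the one-way distance decomposition
`SS_total = (1/N) sum_{i<j} d_ij^2`,
`SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
`pseudo-F = ((SS_total - SS_within)/(g-1)) / (SS_within/(N-g))`,
with p from label permutations using the `(b+1)/(m+1)` estimator (9999
permutations by default; never exactly zero). With a single factor, type
III partial sums of squares reduce to exactly this one-way form. For small
two-group designs `exact = TRUE` enumerates all label splits. Pairwise
comparisons are PERMANOVA on two-group submatrices, FDR-adjusted across
all band pairs.

**PERMDISP** embeds the distance matrix keeping real and imaginary PCoA
parts; the squared distance of a sample to its group centroid is the
real-part squared distance minus the imaginary-part squared distance,
floored at zero. Group centroids (not spatial medians) are used. The test
permutes group labels across the distance-to-centroid values and compares
one-way ANOVA F statistics. Published implementations permute model
residuals instead; on balanced one-way designs the two schemes target the
same null, but p values can differ slightly — the F statistic itself
matches `vegan::betadisper(type = "centroid")` to 1e-9 in our tests.

All permutation tests take a seed and reproduce bit-for-bit.

## 3. Trait space

Eight categorical life-history traits describe each species; ordered
traits (e.g. maximum-length bins) carry a total order on their modalities.
Continuous-to-categorical bin boundaries are configuration, not science:
the defaults (e.g. maximum length at 15/30/50/80/150 cm) are conventional
size classes, and nothing downstream depends on the particular bins.

**Pruning.** Kendall's tau-b is computed between every pair of *ordered*
traits on their modality ranks (tau is undefined for unordered modalities,
so unordered traits are never screened — consistent with screening trios
like age at maturity / generation time / doubling time, which are all
ordered). While any pair exceeds |tau| > 0.8, the member with more missing
cells is dropped (tie: the later-declared trait). The rule is iterated, and
is invariant to column order by construction.

**Imputation.** Missing cells are imputed by the iterative random-forest
scheme: initialise with column modes; visit columns in order of increasing
missingness; fit a 100-tree classification forest of each column on all
others over its observed rows; replace the column's missing cells by
predictions; stop as soon as the proportion of changed imputations rises
relative to the previous sweep and return the previous iterate. The
out-of-bag Proportion of Falsely Classified (PFC) is reported; NRMSE is
reserved for continuous columns and is 0 for all-categorical tables.
Not-evaluated and data-deficient IUCN categories are treated as missing
and imputed from the traits alongside. Two implementation notes: factors
are passed to the forests natively (the forest's canonical categorical
handling) rather than one-hot encoded, and taxonomy is not a predictor
because high-cardinality factors exceed the forest implementation's
category limit — the traits themselves carry the signal.

**Gower distance and the space.** Per-trait dissimilarity is 0/1 for
unordered traits and `|rank_i - rank_j| / (L - 1)` with evenly spaced
ranks for ordered traits (Podani-style); the distance is the unweighted
mean across traits, bounded in [0, 1]. The working trait space is the
first `m` positive-eigenvalue PCoA axes of this distance, `m = 4` by
default — a pragmatic dimensionality that keeps convex-hull computation
fast while the mAD index (mean absolute deviation between max-rescaled
embedded distances and Gower distances, argmin over m, ties to the smaller
m) reports the quality of every candidate dimensionality for the data at
hand.

## 4. Functional metrics

*Functional entities* (FEs) are unique trait combinations. With S species
in K entities of sizes `n_k`: FRed = S/K, FVul = 100 x (share of
singleton entities), and FOR = `100 * sum_k max(0, n_k - FRed) / S`. The
one-line verbal definition of over-redundancy ("species in entities with
more species than expected") is ambiguous between counting *all* members
of above-mean entities and counting only the members *in excess* of the
mean; we default to the excess convention, which follows the metric's
methodological lineage, and expose `variant = "total"` for the other
reading.

Distance-based metrics in the m-dimensional space:

- **FRic**: convex-hull volume of the community divided by the pool hull
  volume. The hull is computed by a general-dimension incremental
  (beneath-beyond) algorithm validated against Cayley–Menger determinants
  and 2-D shoelace areas. FRic is undefined (NA, never silently zero) for
  communities with at most m species or affinely dependent coordinates;
  transects below the richness threshold (5 species by default) are
  excluded from FRic/FDis/FEve only.
- **FDis**: abundance-weighted mean distance to the abundance-weighted
  community centroid.
- **FEve**: with MST branch weights `EW_l = length(l) / (w_i + w_j)` and
  `PEW_l = EW_l / sum EW`,
  `FEve = (sum min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`; the MST
  is built by deterministic Prim with lexicographic tie-breaks, so results
  do not depend on species ordering. Undefined below 3 species.
- **FSpe**: distance to the *unweighted* pool centroid, scaled by the pool
  maximum (a species-level index; abundance-weighting the centroid would
  make a species' specialization depend on sampling effort). Community
  FSpe is the abundance-weighted mean over members.
- **FUn**: mean distance to the k = 5 nearest pool neighbours, scaled by
  the pool maximum. k = 5 is the customary default of the metric family;
  it is exposed in the API.

The *pool* for centroids, scaling maxima and hull standardisation is every
species observed at species level across the whole study.

**FUSE** combines the scaled indices with the IUCN threat rank GE (LC 0 …
CR 4): `FUSE = ln(1 + FUn*GE) + ln(1 + FSpe*GE)`. This combination
reproduces published worked-example scores from their printed two-decimal
inputs within ±0.02 (the tests assert ten such rows), is zero for any
least-concern species, and is nondecreasing in each argument. FUn and FSpe
are computed on the default 4 axes; the axis count is configurable where a
5-axis space is preferred.

## 5. The synthetic survey generator

The generator exists so the pipeline has a fully specified, seeded input
whose structure matches what the analysis assumes. Defaults are the study
conditions: 7 depth bands (2, 10, 30, 60, 120, 250, 500 m) x 5 atolls x 3
replicate 250 x 5 m transects (105 transects; the field campaign it
emulates lost one to weather, which we do not simulate), a 300-species
pool, expected per-transect richness peaking at 10 m (45) and lowest at
250 m (6), negative-binomial per-species counts (dispersion 1.2) since
transect counts are overdispersed, lognormal lengths, 5% unmeasured
lengths, 2% genus-level identifications, 30% of submersible-depth (>= 60 m)
transects carrying the 46% length-calibration bias, and 7% missing trait
cells.

Species traits are driven by three latent variables — pace of life, body
size and depth — so that the life-history trio (age at maturity,
generation time, doubling time) is strongly rank-correlated (exercising
the pruning rule), fishing vulnerability tracks size, and habitat
filtering restricts the modality subsets available to deeper-band
specialists (water-column position, temperature range). Threat status is
drawn with probability increasing in body size, which makes large, deep,
isolated species the FUSE-relevant ones, as observed in real faunas.
Sub-streams are derived per transect from the master seed, so adding
transects never perturbs earlier draws.

What the generator does **not** emulate: bathymetric or spatial
autocorrelation between atolls, true species identities or real trait
tables, observation error in identification, size-selective detectability,
and abundance distributions calibrated to any particular survey (only the
qualitative depth profile is targeted). Passing the pattern-recovery tests
therefore shows the *pipeline* recovers structure a survey of this shape
carries; it does not validate any field estimate.

## 6. Numerical choices and degenerate inputs

- Permutation p values use `(b+1)/(m+1)` and never report 0.
- All-equal samples: Kruskal–Wallis returns H = 0, p = 1; an all-zero
  distance matrix gives PERMANOVA p = 1 by convention.
- Convex hulls use a relative visibility tolerance of 1e-9 of the point
  cloud scale; affinely dependent sets return NA with a reason attribute.
- PCoA eigenvalues within 1e-10 (relative) of zero are treated as null.
- MST and FE identifiers use lexicographic tie-breaks; surrogate donors
  use abundance, then study-wide abundance, then label.
- Gower requires a fully imputed table and errors towards the imputation
  step rather than guessing.

## 7. Problem sizes used by the tests

The shipped test-suite exercises the full pipeline at the default design
(300 species, 105 transects) for pattern recovery, smaller seeded surveys
(40–150 species) for unit and determinism tests, 10 masked replicates of a
250-species pool for the imputation-versus-mode experiment, and hundreds
of randomised toys for the metric and geometry properties. Permutation
tests in the suite run at 9–999 permutations; analyses of real data should
keep the 9999 default.

## 8. Known limitations

- PERMDISP's permutation scheme (label permutation of centroid distances)
  can differ in p value from residual-permutation implementations; the F
  statistic is identical.
- The hull algorithm is exact but O(n x facets) per insertion in pure R;
  pools beyond a few thousand species in 4-D would be slow.
- Trait-space quality (mAD) is reported, not enforced: the default 4 axes
  may not be the mAD optimum for a given dataset.
- Imputation quality degrades when traits are mutually independent; the
  OOB PFC should always be inspected before trusting imputed cells.
- The generator's IUCN, commercial-value and trait-filtering models are
  plausibility devices, not fitted distributions.
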
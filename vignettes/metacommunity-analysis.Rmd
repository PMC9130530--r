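---
title: "Metacommunity structure and landscape pattern analysis with emsland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metacommunity structure and landscape pattern analysis with emsland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsland)
```

## The problem

A metacommunity is a set of local communities — here, woody plant
assemblages in native forest fragments — linked by potential dispersal and
analysed jointly through a species-by-sites incidence (presence/absence)
matrix. The Elements of Metacommunity Structure (EMS) framework summarises
such a matrix with three statistics measured on its reciprocal-averaging
ordination, and classifies the metacommunity into one of a small set of
idealized distribution patterns: Clementsian, Gleasonian, evenly spaced,
nested (clumped / random / evenly spaced species loss), checkerboard,
random, and quasi-variants of the first six.

`emsland` implements that workflow end to end, together with the
surrounding accounting a forest survey needs (species frequency tables,
age-class comparisons, richness summaries), Fragstats-style landscape
metrics for categorical land-use rasters, pairwise community similarity
with great-circle distances, and synthetic generators that produce
incidence matrices of known structure and toy rasters with closed-form
metrics, so the whole pipeline can be validated without any external data.

## The EMS model and its three elements

All analyses operate on a binary matrix with **rows = species, columns =
sites**. The matrix is first ordinated by reciprocal averaging
(correspondence analysis): site and species scores on the first
non-trivial axis are computed from the SVD of the standardized residual
matrix `S = D_r^{-1/2}(P - rc')D_c^{-1/2}`, and rows and columns are
reordered by their scores. Scores are standard coordinates scaled by the
singular value; the sign is fixed so site scores correlate non-negatively
with the input column order, and exact ties keep input order (stable
sort).

1. **Coherence** — the number of embedded absences: 0-cells lying strictly
   inside a species' range along the ordinated site axis and, by default,
   inside a site's range along the species axis (`direction = "rowcol"`,
   the convention of the Matlab script lineage this field has used;
   `direction = "row"` restricts to species ranges). Significantly *fewer*
   embedded absences than the null expectation is positive coherence;
   significantly *more* is a checkerboard; a non-significant test is a
   random pattern.
2. **Turnover** — the number of replacements: over every pair of species
   and pair of sites (on the range-filled matrix), configurations where
   each species occupies exactly one, different, site of the pair.
   Nested patterns show significantly fewer replacements than the null;
   Clementsian/Gleasonian/evenly spaced patterns show significantly more.
3. **Boundary clumping** — Morisita's index of dispersion over the counts
   of range limits per site (a species occupying a single site contributes
   its start and end, i.e. two counts, at that site). Clumped boundaries
   (index above its reference) with significant evidence give Clementsian
   or nested-clumped labels; significantly over-dispersed boundaries give
   the evenly spaced variants; no evidence gives Gleasonian or
   nested-random.

Quasi-structures arise when coherence is significantly positive but
turnover is non-significant; the sub-type follows the *sign* of the
turnover z statistic, as in the framework's standard extension.

## The null model and significance

Coherence and turnover are tested against the "random 0" null model: each
simulated matrix keeps every site's observed species richness and fills
sites by drawing species uniformly without replacement from the pool.
Every null matrix is re-ordinated before counting — the observed
statistics are ordination-dependent, so comparing them against
unordinated nulls would bias the tests (and would destroy the type-I
calibration checked in the test suite). The default p-value is the
two-tailed normal approximation `2(1 - Phi(|z|))` with
`z = (obs - mean)/sd` over the null distribution; an exact two-tailed
permutation p (`method = "empirical"`) is available. The default run uses
1000 iterations and `alpha = 0.05`; a seed is required for exact
reproducibility.

## Boundary clumping: reference distribution

Two design points deserve emphasis, because the naive composition of the
pieces above misbehaves.

First, the index is evaluated on **interior** site positions (the first
and last ordinated sites are excluded by default, `boundary =
"interior"`). Range limits at the extremes are structural rather than
informative: any coherent range that reaches the edge of the gradient ends
there, and in a perfectly nested pattern *every* species' range is
anchored at the richest site, so the anchor would otherwise swamp the
index and push every nested metacommunity into the "clumped" branch.

Second, the significance reference. The classical chi-square test compares
boundary counts with a uniform multinomial, but reciprocal averaging
itself induces spurious clumping: sites with nearly tied scores are
ordered arbitrarily, which fragments and stacks boundary counts even when
ranges are placed independently. Judged against the fixed multinomial
reference, individualistically assembled (Gleasonian) matrices are
routinely mislabelled as Clementsian. The default (`clump_test =
"montecarlo"`) therefore builds the reference from a **range-shuffle
null**: each species' range is re-placed with its free limits drawn
uniformly over the site positions, limits pinned at the ordination
extremes stay pinned, and every shuffled matrix is pushed through the same
re-ordination pipeline before its interior Morisita index is recorded.
The observed index is then compared by empirical two-tailed tail
probabilities (the null MI distribution is right-skewed, so a normal
approximation would under-detect evenly spaced boundaries). The
chi-square path remains available as `clump_test = "chisq"` and as the
stand-alone `morisita_boundary_index()`, whose directional p uses the
upper tail when MI >= 1 and the lower tail otherwise so that
under-dispersion is detectable at all.

## The synthetic generators

`make_structure()` produces incidence matrices whose ground-truth label is
known. Matrices are built in their ideal order, then rows and columns are
randomly permuted so tests exercise the ordination, not just the counters.
Conventions, chosen once:

* *Clementsian*: contiguous site blocks, species occupying every site of
  their compartment (3 compartments by default).
* *Gleasonian*: each range is the interval between two uniform random cut
  points, so every boundary position is marginally uniform —
  "individualistic placement" in its exact form.
* *Evenly spaced*: equal-width contiguous ranges with maximally staggered
  starts. The width default is half the number of sites: that is the
  geometry at which the `2S` staggered boundary events tile the axis at
  uniform density (narrower ranges double-stack starts and ends in the
  interior and reintroduce clumps).
* *Nested*: ranges anchored at the first site with widths drawn from a few
  shared levels (clumped), uniformly at random (random), or evenly spread
  (evenly spaced). The framework gives no quantitative definition of
  "evenly spaced" boundary spacing; even spacing of the width sequence is
  adopted.
* *Checkerboard*: the anti-coherent extreme. Pairwise-exclusive masks
  drawn at random are statistically indistinguishable from the richness-
  matched null (their rows are marginally random), and any single shared
  gradient collapses into compartments, so the generator instead
  hill-climbs margin-preserving 2x2 swaps from a random matrix to maximize
  post-ordination embedded absences — the defining property of the
  checkerboard branch. Fixed margins keep the result comparable with its
  own null.
* *Random*: iid Bernoulli occupancy at a matched fill (0.35 by default,
  the mean fill of the structured generators at their defaults).

`noise` flips each cell independently after construction; recovery of the
true label degrades smoothly with noise, and the test suite checks it is
at least 90% at zero noise for 30 species x 20 sites over 50 seeds with
200 null iterations.

What the generators do **not** emulate: spatial autocorrelation among
sites, abundance structure, detection error correlated with rarity, and
the richness gradients of real surveys. Passing the recovery tests
therefore demonstrates the machinery is correct on idealized patterns,
not that any field matrix will be classified with that accuracy.

## Species frequency accounting

`frequency_table()` reports absolute frequency (AF, occupied sites),
relative frequency (RF = 100 AF / n sites) and the cumulative relative
frequency (CRF), the running sum of unrounded RF down the AF-descending
order with ties kept in input order. RF is reported rounded half-up to
integer percent — the convention that reproduces the published values
(31/32 to 97, 30/32 to 94, 29/32 to 91) — while CRF accumulates the
unrounded values. Age-class logic (adults dbh >= 5 cm, juveniles < 5 cm,
total = union) lives in `merge_age_classes()` and
`count_exclusive_species()`.

The packaged fixture (`table1_fixture()`) transcribes the published
101-species frequency-and-traits table of the Uruguayan native-forest
survey the package's defaults emulate; `table1_matrices()` draws a
synthetic incidence realization whose per-layer and union frequencies
match the fixture exactly (site assignments are random — the original
matrix is only available in an external repository). Taxon counts follow
the printed table: genus = first name token, synonyms not collapsed.

## Landscape metrics

`label_patches()` finds patches as 8-connected components of same-class
cells (delegated to igraph); adjacency-based quantities (like-class joins
for AI, class-to-class edges for LSI and IJI) use rook (4-neighbour)
adjacency — the Fragstats convention. Per-patch perimeter counts edges
against a different class, no-data, or the raster boundary. Metrics:

* `LSI = 0.25 E* / sqrt(A)` with `E*` the total edge length including the
  boundary; 1 for a compact single-class square.
* `SHEI = -sum(p_i ln p_i)/ln m` over classes present; 0 when `m = 1`.
* `AI = 100 g_ii / max g_ii`, with the compact-block maximum
  (`n = floor(sqrt(a))`, `m = a - n^2`; `2n(n-1)`, `+2m-1`, or `+2m-2`); a
  single-cell class is defined as 100; landscape AI is the area-weighted
  class mean.
* `IJI`: evenness of the focal class's edge apportionment among other
  classes, NA when fewer than 3 classes are present or the focal class has
  no inter-class edge (never coerced to 0).
* `ENN`: per-patch minimum center-to-center distance to another patch of
  the same class, averaged; NA with fewer than 2 patches.
* `PARA = P/a` (scale-dependent by construction) and
  `SHAPE = 0.25 P / sqrt(a)` (scale-free, 1 for square blocks). The
  divisors use the square roots of area — the standard raster
  normalization under which compact squares score exactly 1.

`summarize_buffer()` assembles the per-site table (NP, LSI, SHEI, AI,
P_NF, P_GL, P_TF, P_C, N_NF, IJI, ENN, AREA, PARA, SHAPE). Water and
urban classes are accepted in rasters but treated as background by
default, mirroring analyses that exclude those uses; `buffer_mask()`
clips a scene to a circular buffer (3 km default) by cell-center
distance. Raster I/O supports the ESRI ASCII grid format (`read_asc()` /
`write_asc()`).

## Community similarity

`jaccard()` uses shared/(shared + unique); two empty communities are
defined as identical (J = 1). Pairwise overlap between sites uses the
Morisita-Horn form, which is well defined for incidence treated as 0/1
counts (the abundance-based Morisita index is not). Distances are
haversine great circles on a 6371-km sphere (via geosphere).
`distance_overlap_matrix()` combines both into the square matrix layout
used in survey reports (distances below the diagonal, overlap above,
empty diagonal, rows ordered by distance from a reference site).

## Numerical choices and degenerate inputs

* Ordination requires at least 2 non-empty species and sites after
  dropping empty rows/columns (dropped ids are recorded and messaged);
  an all-ones or rank-one matrix raises "degenerate ordination".
* Equal ordination scores are ordered by stable sort (input order).
* Monte-Carlo tests refuse a zero-variance null rather than returning a
  misleading p.
* Null replicates that lose a species (empty row) are re-ordinated after
  dropping it; replicates whose ordination degenerates are skipped and
  the test uses the remainder.
* Reports: per-age-class EMS failures are recorded as error entries while
  the run continues; per-scene landscape failures produce an NA row with
  the message.

## Problem sizes used by the tests

The suite checks oracle equivalence on 1000 random matrices up to 6x6
(embedded absences and replacements against brute-force enumeration) and
100 random matrices against a dense eigensolver at 1e-8; structure
recovery at 30 species x 20 sites, 50 seeds, 200 null iterations; and
type-I calibration of the coherence test at 15 species x 10 sites with
10,000 replicates of 99 iterations — sizes chosen as the smallest at
which the framework's behaviour is representative while the full suite
stays quick to run.

## Interfaces

The package is function-first: analyses are tibble-in/tibble-out and
compose with the pipe, `tidy()`/`glance()` expose fitted-object summaries,
and `autoplot()` draws the ordinated matrix and raster scenes. The
report layer (`report_frequency()`, `report_ems()`, `report_landscape()`,
`write_report()`) provides the batch surface a pipeline script would call;
no shell entry point is shipped because the package's users work from R.

## Known limitations

* Only the first ordination axis is used (no detrended or higher-axis
  variants), and only binary incidence (no abundance weighting).
* The checkerboard generator optimizes the coherence statistic itself;
  it is the definitional extreme of that branch, not a mechanistic
  community model.
* Landscape metrics assume square cells and treat the raster as flat;
  geo-referencing beyond the cell size is out of scope, as is any
  satellite image classification.
* The boundary-clumping Monte-Carlo reference adds roughly half again the
  null-model cost; `clump_test = "chisq"` is cheaper but inherits the
  ordination-tie artifact described above.
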
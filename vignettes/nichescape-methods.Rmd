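---
title: "Methods: spatial cellular neighborhood analysis with nichescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial cellular neighborhood analysis with nichescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nichescape implements a complete analysis chain for multiplexed tissue
imaging at single-cell resolution — from segmentation-mask post-processing
to cohort-level spatial statistics — together with the combined z-score
gene-signature machinery used alongside such imaging studies. This
vignette is the package's methodological record: the models and their
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical conventions adopted where the
underlying procedures are commonly left under-specified.

## 1. Stochastic whole-cell mask dilation

Nuclear segmentation produces tight nuclear masks; per-cell intensity
quantification wants approximate whole-cell masks. `dilateMasks()` grows
each labelled mask by a stochastic process resembling diffusion: in each
of `rounds` passes (default 9), every background pixel adjacent to a mask
flips into it with probability equal to the fraction of its neighboring
pixels already assigned to that mask. Nine rounds of this process inflate
a nucleus by up to nine pixels of radius while letting the growth
probability taper off at irregular borders, which yields organic,
cell-like shapes rather than the flat offset of a morphological dilation.

Three conventions pin the algorithm down exactly:

* **Synchronous rounds.** Flip probabilities in a round are computed from
  the start-of-round assignment and all accepted flips are applied
  together. This removes scan-order artifacts that a sequential update
  would introduce.
* **Contested pixels.** A background pixel touching two masks belongs to
  the *candidate* mask holding the largest number of its neighbors (ties
  to the smallest label id), and a single uniform draw decides the flip
  with p = (candidate-mask neighbors) / (in-bounds neighbors). Whether the
  original procedure resolved such pixels jointly or sequentially is not
  knowable from its description; this rule is a declared convention chosen
  for determinism.
* **RNG contract.** `set.seed(seed)` once; per round, candidates are
  visited in row-major order and consume exactly one uniform variate
  each, flipping when u < p. The contract is what makes the vectorized
  implementation replayable by the naive per-pixel reference used in the
  test suite, where the two are compared bit for bit.

Pixel connectivity (4 or 8) is a free parameter; the default is
8-connectivity, which gives denser, more diffusion-like growth. The
algorithm guarantees monotone growth, label containment (no assigned
pixel is ever removed or relabelled) and bounded reach (no pixel farther
than `rounds` connectivity steps from a mask's original support), all of
which are asserted as invariants in the tests.

## 2. Marker normalization and phenotyping

`normalizeMarkers()` applies `x -> asinh(x / cofactor)` per marker within
each ROI. The inverse hyperbolic sine is the standard
variance-stabilizing transform for fluorescence data — logarithmic for
large intensities but defined and smooth at zero. The default cofactor of
1 corresponds to applying a bare `asinh`; the parameter is exposed because
different platforms place their noise floors differently.

"z-scaled across both cells and markers" admits two readings, so both are
implemented. The default (`scale = "both"`) standardizes each marker
across the cells of its ROI — absorbing ROI-level staining and
acquisition shifts, which is the point of transforming per ROI — and then
standardizes each cell across markers, reading the phrase literally. The
`scale = "marker"` mode stops after the first stage, which is the more
common convention in cytometry pipelines. A marker with zero variance
within an ROI cannot be z-scaled; by default this is an error naming the
marker, or (`zeroVariance = "zero"`) the marker is flagged and centred to
zero so that it carries no signal downstream.

`clusterCells()` then mirrors the standard graph-based phenotyping recipe:
PCA to 20 components, an exact Euclidean k-nearest-neighbor graph
(k = 30, self excluded, distance ties broken by cell index, edges
symmetrized and left unweighted), and Leiden community detection at
resolution 1.0. Two decisions deserve note:

* **Quality function.** "Leiden at resolution 1.0" does not name an
  objective. The package defaults to modularity on the unweighted
  symmetrized graph — the widely shared convention under which resolution
  1.0 is the classical modularity — with CPM available. Results on real
  data can differ by objective; no claim is made about which one any
  particular study used.
* **Determinism.** All stochastic refinement runs under the caller's
  seed, and the exact kNN search with index tie-breaking makes the graph
  itself reproducible; the full parameter provenance (components,
  neighbors, resolution, objective, seed, cofactor) is recorded in the
  result's metadata.

Cluster annotation (`annotateCells()`) is deliberately manual — a
user-supplied mapping from cluster label to phenotype name — since on real
tissue it is validated by inspecting the underlying immunostains.

## 3. Cellular neighborhoods

`buildKnnGraph()` records, for every cell, its 10 nearest neighbors by
centroid distance in microns, strictly within the same ROI (an ROI with
fewer than k + 1 cells is an error naming the ROI, not a silent
truncation). `neighborComposition()` turns each cell's neighbor list into
a phenotype-proportion vector; the index cell is excluded from its own
composition — the vector describes the cell's *neighbors* — with an
`includeSelf` switch for compatibility with windowed CN conventions that
count the center cell.

`discoverNeighborhoods()` clusters the composition vectors with k-means
(10 restarts per candidate, best within-cluster sum of squares kept,
because k-means initialization is otherwise unspecified) over candidate
neighborhood counts 2–10, and picks the candidate maximizing the mean
silhouette width. Silhouette width is computed with Euclidean distance on
the proportion vectors over a seeded random subsample of at most 5,000
rows — the full computation is quadratic in cells and available by raising
the cap — and ties in the trace resolve to the smaller k. Proportions
(rather than raw counts) are clustered by default, matching the
row-normalization step of the published procedure; counts can be supplied
directly since the function does not renormalize its input.

## 4. Spatial statistics

**Average minimal distance.** For source type A and target type B,
`minDistance()` computes per ROI the mean over A cells of the distance to
the nearest B cell. The statistic is *directional* — the mean of minima
from A to B generally differs from B to A — and the implementation never
assumes symmetry; the test suite asserts the asymmetry on a 3-vs-2
fixture against brute force. An ROI lacking either type yields a flagged
missing value rather than an error or a fake zero, and with A = B each
cell is excluded from its own minimum. Cohort comparison
(`compareDistance()`) is Welch's two-sample t-test (unequal variances,
Welch–Satterthwaite degrees of freedom, two-sided) on the per-ROI
summaries.

**CN proportions.** `compareCnProportions()` transforms per-ROI CN
proportions and Welch-tests each CN between two cohorts with Bonferroni
correction over the number of CNs. The transform question is resolved in
favor of the named function: descriptions of this procedure conflate the
inverse hyperbolic *tangent* with an inverse-hyperbolic-*sine* routine,
and the package defaults to asinh — the function actually named — which
is also defined at proportion 1; `transform = "atanh"` (clamped at
1 − 1e−9) is available. A CN that is degenerate in a cohort is flagged
with a missing p-value but still counts in the Bonferroni denominator, so
the family-wise guarantee is never quietly strengthened.

**Interaction enrichment.** The published analyses report pairwise
cell-cell interactions on the 10-neighbor spatial graph within a 3–100 µm
range without describing the statistic; `interactionEnrichment()` is a
clearly labelled re-implementation choice: observed counts of ordered
phenotype-pair edges inside the band are compared to a null in which
phenotype labels are permuted within each ROI while the graph stays
fixed, summarized as z = (obs − null mean) / null sd and a two-sided
empirical p-value with the +1 correction (so p is never exactly zero). A
degenerate null (sd = 0, e.g. a single phenotype) flags the z-score as
undefined instead of dividing by zero.

## 5. Combined z-score signatures

`scoreSignature()` z-standardizes each member gene across samples and
averages using √n as the denominator: score(s) = Σ_g z_g(s) / √n. Dividing
by √n rather than n stabilizes the variance of the mean — for independent
member genes the null score stays approximately standard normal
regardless of signature size, a property the test suite checks empirically
(sd within [0.95, 1.05] over 2,000 simulated samples). Member genes
missing from the matrix, or with zero variance, are excluded with a
warning and n shrinks accordingly; imputing them instead would silently
break the scale property. Gene matching is exact and case-sensitive.

Downstream: median stratification assigns scores strictly above the
median to "high" and ties at the median to "low" (a declared convention —
the customary description of a median split does not say); Welch's t-test
for two groups and Welch's ANOVA (`stats::oneway.test`,
heteroscedastic F approximation) for three or more; Fisher's exact test
for stratified count tables; paired t-tests for matched pre/post designs
with Benjamini–Hochberg step-up q-values at gene level. A pre/post pair
with identical values reports t = 0, p = 1 rather than a zero-variance
failure.

## 6. The synthetic-data generator

`simulateTissue()` emulates exactly the structure the pipeline consumes,
with planted ground truth emitted alongside so that tests never
reverse-engineer labels:

* ROIs are 2,000 µm square fields of ~10³ cells (both configurable),
  assigned alternately to two cohorts.
* Each ROI receives 6 neighborhood region centers placed uniformly;
  each center draws a neighborhood identity (default: tumor core /
  lymphoid / myeloid) from its cohort's prevalence weights — responder
  ROIs lymphoid-enriched, non-responder ROIs tumor-dominated. Cells pick
  a region uniformly and scatter uniformly within a 300 µm radius;
  overlapping regions are resolved by nearest center, which is simple and
  reproducible.
* Cell types are drawn from the neighborhood's mixture. The default
  mixtures are dominance-disjoint (tumor-pure core, B/T-dominated
  lymphoid, DC/macrophage-dominated myeloid) to realize genuinely
  well-separated niches, as organized structures like lymphoid aggregates
  are in tissue.
* Marker intensities are lognormal around per-type means
  (meanlog = log mean, sdlog = `noise_sd`, default 0.5), so raw values
  are non-negative like fluorescence. The default panel has 25 markers
  with lineage markers at 120 units over a background of 5: a log-scale
  separation of log(120/5)/0.5 ≈ 6.4 noise-sd for defining markers,
  comfortably above the ≥ 5 sd regime in which phenotype recovery is
  validated. The panel width matters: a realistic ~25-marker panel
  makes the within-type kNN graph high-dimensional and expander-like, so
  modularity-based community detection at resolution 1.0 keeps each
  population intact, whereas very low-dimensional panels geometrically
  fragment under any Leiden objective.

`simulateLabelImage()` places non-overlapping discs (radius 3–6 px by
default) by rejection sampling with a bounded attempt budget — exhausting
the budget is an explicit error, never an infinite loop.
`simulateExpression()` generates Normal(0, noise_sd) genes with the
signature genes shifted by `group_shift` in the responder group; the
default configuration (20 samples per group, 24 signature genes, shift of
3 noise-sd) is the planted-effect condition used for power checks, and
`group_shift = 0` is the null.

What the generator does **not** emulate: raw image stacks, optical noise
or cycle registration error; segmentation error (cells are points with
exact centroids); marker correlation structure beyond type identity
(within a type, markers are independent lognormals, while real antibody
panels are correlated); spillover/compensation artifacts; cohort-level
confounders such as batch or patient effects (ROIs are exchangeable
within cohort). Passing tests therefore demonstrate that the
implementations are correct and calibrated on data with the assumed
structure — not that any particular biological dataset satisfies those
assumptions.

## 7. Validation design and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`, re-run from
scratch by `scripts/acceptance.R`) uses problem sizes chosen as the
package's standard validation conditions:

* dilation: 20 seeded 64×64 fixtures with 5 nuclei for the bit-level
  oracle comparison, and 100 random 32×32 fixtures for the invariants;
* phenotyping: 3 planted types at ≥ 5 noise-sd separation, 2,000 cells,
  10 seeds, requiring adjusted Rand index ≥ 0.95;
* neighborhoods: 3 planted niches, 5,000 cells, 20 seeds, requiring the
  silhouette-selected k = 3 in ≥ 18/20 runs and median ARI ≥ 0.9;
* distances: 50 random 200-vs-200 fixtures against an O(n²) brute-force
  oracle, exact equality;
* calibration: 200 null replicates per test family, requiring empirical
  rejection ≤ 0.05 plus binomial slack;
* power: 200 replicates each for a 1.5 pooled-sd distance shift with 15
  ROIs per cohort — a sample size fixed a priori from closed-form power
  (`power.t.test`: ≈ 0.96) so the ≥ 95% detection requirement is
  achievable by design — and for a 3 noise-sd signature shift at 20
  samples per group.

Statistical components with textbook closed forms (Welch t and ANOVA,
Fisher's exact test, Bonferroni and Benjamini–Hochberg) are delegated to
base R and validated in the tests against independent references:
permutation re-computation for the Welch p-value, exhaustive
hypergeometric enumeration for Fisher, and a hand-written step-up
recursion for BH. The hand-written components — dilation, spatial kNN,
composition, minimal distances, permutation enrichment, combined z — are
each tested against brute-force oracles that share no code with the
implementation.

## 8. Known limitations

* The interaction statistic is a permutation stand-in for an
  under-specified published method; its z-scores are comparable within an
  analysis but not across methods.
* Silhouette-based CN model selection inherits silhouette's bias toward
  compact, balanced clusters; rare niches below a few percent of cells
  may be folded into larger ones before the trace favors a larger k.
* Distances are Euclidean on 2D centroids in microns; no account is taken
  of tissue folds, section thickness or anisotropic pixel sizes beyond a
  uniform scale factor applied upstream.
* Leiden phenotyping at a fixed resolution determines cluster granularity
  jointly with panel dimensionality and population separation; on real
  panels the resolution (and objective) should be treated as analysis
  parameters, not constants.
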
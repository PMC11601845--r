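# nichescape

Spatial single-cell analysis for CODEX-style multiplexed tissue imaging,
plus combined z-score gene-signature statistics — the kind of analysis used
to ask whether the *spatial organization* of immune cells in a tumor, and
not just their abundance or a bulk expression signature, separates patients
who respond to immune checkpoint therapy from patients who do not.

The package is aimed at computational biologists working with segmented
multiplexed-imaging data (per-cell marker intensities with centroids and
region-of-interest membership) and companion bulk expression panels. It
implements the full pipeline as tested, reusable functions, and ships a
synthetic-data module that generates tissues with *planted* phenotype and
neighborhood structure so that every stage can be validated against known
ground truth.

## What it computes

**Whole-cell mask dilation.** Nuclear segmentation masks are expanded into
approximate whole-cell masks by a stochastic, diffusion-like dilation: for
each of 9 rounds, every background pixel adjacent to a mask joins it with
probability equal to the fraction of its neighboring pixels already
assigned to that mask. Rounds are synchronous and the RNG contract is
documented, so the vectorized implementation is bit-reproducible against a
naive per-pixel reference.

**Phenotyping.** Marker intensities are variance-stabilized per ROI with
`asinh`, z-scaled across cells and markers, reduced by PCA (20
components), connected in an exact Euclidean k-nearest-neighbor graph
(k = 30) and partitioned with Leiden community detection at resolution
1.0 (modularity objective). Cluster mean-expression profiles support
manual annotation.

**Cellular neighborhoods (CNs).** For every cell, the phenotype
composition of its 10 nearest spatial neighbors (per ROI, in microns)
forms a proportion vector; k-means over these vectors — with the number
of neighborhoods chosen by maximizing the mean silhouette width — yields
recurring local composition motifs such as tumor cores or lymphoid
aggregates.

**Spatial statistics.** Average minimal inter-type distance per ROI
(mean over cells of type A of the distance to the nearest type-B cell),
compared between cohorts by Welch's t-test; CN proportions per ROI,
asinh-transformed and compared per CN with Bonferroni correction;
permutation enrichment of pairwise adjacencies in the 3–100 µm band
(labels shuffled within ROI, graph fixed) summarized as z-scores.

**Gene signatures.** Stouffer-style combined z-score for a gene set
(sum of member-gene z-scores divided by √n, which keeps the null score on
unit scale), median high/low stratification, Welch t / Welch ANOVA group
tests, Fisher's exact association, and paired pre/post tests with
Benjamini–Hochberg correction at gene level.

## Worked example

```r
library(nichescape)
library(SummarizedExperiment)

## simulated cohort: 16 ROIs x 1,000 cells, planted neighborhoods,
## responder ROIs enriched for lymphoid niches
ce <- simulateTissue(tissueSimConfig(n_rois = 16, seed = 1))

## phenotyping: asinh + z-scaling, PCA-20, kNN-30 graph, Leiden at 1.0
ce <- clusterCells(normalizeMarkers(ce), seed = 1)
table(clusterLabels(ce), colData(ce)$true_type)
#>        B CD4T CD8T   DC Macrophage Tumor
#>   1    0    0 2068    0          0    57
#>   2    0 1772    0    1          0    53
#>   3    0    0    0    0       2213    79
#>   4    0    0    0 2623          0   131
#>   5    0    0    0   11          1  5194
#>   6 1740    0    0    2          0    55
```

Six clusters, each dominated by one planted type (a thin smear of tumor
cells — the type with the most diffuse marker profile — lands in immune
clusters, as on real data).

```r
g    <- buildKnnGraph(ce, k = 10)
comp <- neighborComposition(g, colData(ce)$true_type)
mod  <- discoverNeighborhoods(comp, kCandidates = 2:10, seed = 1)
mod
#> NeighborhoodModel: 3 cellular neighborhoods over 16000 cells
#>   silhouette trace: k=2:0.595  k=3:0.667  k=4:0.591  k=5:0.509 ...
```

The silhouette trace peaks at k = 3, recovering the three planted niches
(tumor core / lymphoid / myeloid). Cohorts then separate on CN
prevalence:

```r
props <- cnRoiProportions(cnLabels(mod), ce)
cmap  <- setNames(cohorts(ce)[!duplicated(roiIds(ce))], unique(roiIds(ce)))
compareCnProportions(props, cmap)[, c("contrast", "statistic",
                                      "p_value", "p_adjusted")]
#>   contrast  statistic     p_value  p_adjusted
#> 1      CN1 -0.8035166 0.437030957 1.000000000
#> 2      CN2  3.8554061 0.002282288 0.006846865
#> 3      CN3 -2.6592739 0.024640981 0.073922944
```

CN2 — the tumor-core neighborhood — is significantly more prevalent in
non-responder ROIs after Bonferroni correction (adjusted p ≈ 0.007). The
per-ROI B→CD8 average minimal distance is computed the same way
(`minDistance()` + `compareDistance()`); at this cohort size its Welch
test is not significant (p ≈ 0.23), illustrating that the CN readout is
the more sensitive spatial summary here.

```r
se <- simulateExpression(expressionSimConfig(seed = 1))
sc <- scoreSignature(se, sprintf("gene%03d", 1:24), name = "TLS")
groupTests(sc, colData(se)$group)[, c("contrast", "statistic", "p_value")]
#>                    contrast statistic      p_value
#> 1 nonresponder vs responder -58.46474 5.313026e-37
table(stratifyByMedian(sc), colData(se)$group)
#>        nonresponder responder
#>   low            20         0
#>   high            0        20
```

A 24-gene signature shifted by 3 noise-sd separates the groups completely,
both on the combined z-score and after median stratification.

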
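test_that("normalization matches a hand-computed asinh + z-score reference", {
    set.seed(1)
    n <- 40
    raw <- matrix(rlnorm(4 * n, log(20), 0.4), nrow = 4,
                  dimnames = list(paste0("M", 1:4), sprintf("c%03d", 1:n)))
    roi <- rep(c("r1", "r2"), each = n / 2)
    ce <- CodexExperiment(raw, data.frame(roi_id = roi, x_um = runif(n),
                                          y_um = runif(n)))
    cofactor <- 5
    ce <- normalizeMarkers(ce, cofactor = cofactor, scale = "marker")
    got <- t(assay(ce, "normalized"))                 # cells x markers
    want <- t(asinh(raw / cofactor))
    for (r in unique(roi)) {
        sel <- roi == r
        want[sel, ] <- scale(want[sel, , drop = FALSE])
    }
    expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
    # per-marker columns standardized within each ROI stratum
    for (r in unique(roi)) {
        sel <- roi == r
        expect_equal(unname(colMeans(got[sel, ])), rep(0, 4),
                     tolerance = 1e-8)
        expect_equal(unname(apply(got[sel, ], 2, sd)), rep(1, 4),
                     tolerance = 1e-8)
    }
    # asinh with cofactor 1 at intensity 1 is log(1 + sqrt(2))
    expect_equal(asinh(1), log(1 + sqrt(2)), tolerance = 1e-10)
})

test_that("the dual-scaling mode additionally standardizes each cell", {
    ce <- simulateTissue(tissueSimConfig(n_rois = 1, cells_per_roi = 60,
                                         seed = 2))
    ce <- normalizeMarkers(ce, scale = "both")
    m <- t(assay(ce, "normalized"))
    expect_equal(unname(rowMeans(m)), rep(0, nrow(m)), tolerance = 1e-8)
    expect_equal(unname(apply(m, 1, sd)), rep(1, nrow(m)), tolerance = 1e-8)
    expect_identical(metadata(ce)$normalization$scale, "both")
})

test_that("zero-variance markers error by name or are flagged on request", {
    raw <- matrix(c(rep(3, 10), rlnorm(10, log(5), 0.5)), nrow = 2,
                  byrow = TRUE,
                  dimnames = list(c("FLAT", "OK"), sprintf("c%02d", 1:10)))
    ce <- CodexExperiment(raw, data.frame(roi_id = "r1", x_um = 1:10,
                                          y_um = 1:10))
    expect_error(normalizeMarkers(ce), "FLAT")
    ce2 <- normalizeMarkers(ce, scale = "marker", zeroVariance = "zero")
    expect_identical(metadata(ce2)$normalization$flagged_markers, "FLAT")
    expect_equal(unname(assay(ce2, "normalized")["FLAT", ]), rep(0, 10))
})

test_that("re-standardizing a standardized matrix is a no-op", {
    set.seed(3)
    m <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("M", 1:5)))
    z1 <- nichescape:::.zscoreColumns(m)
    z2 <- nichescape:::.zscoreColumns(z1)
    expect_equal(unclass(z1), unclass(z2), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("two marker-disjoint populations are recovered exactly", {
    cfg <- tissueSimConfig(
        n_rois = 1, cells_per_roi = 1000,
        cell_types = c("Tumor", "B"),
        neighborhood_profiles = list(mix = c(Tumor = 0.6, B = 0.4)),
        marker_means = defaultMarkerMeans(c("Tumor", "B")),
        cohort_effect = list(responder = c(mix = 1),
                             nonresponder = c(mix = 1)),
        seed = 4)
    ce <- clusterCells(normalizeMarkers(simulateTissue(cfg)), seed = 4)
    expect_identical(length(unique(clusterLabels(ce))), 2L)
    expect_equal(ari(clusterLabels(ce), colData(ce)$true_type), 1)
})

test_that("clustering is reproducible and invariant to cell order", {
    cfg <- three_type_config(6, cells_per_roi = 400, n_rois = 1)
    ce <- normalizeMarkers(simulateTissue(cfg))
    a <- clusterLabels(clusterCells(ce, seed = 10))
    b <- clusterLabels(clusterCells(ce, seed = 10))
    expect_identical(a, b)
    set.seed(1)
    perm <- sample(ncol(ce))
    cperm <- clusterLabels(clusterCells(ce[, perm], seed = 10))
    expect_equal(ari(cperm, a[perm]), 1)
})

test_that("with all components kept, PCA is a rotation: same partition as no PCA", {
    cfg <- three_type_config(8, cells_per_roi = 300, n_rois = 1)
    ce <- normalizeMarkers(simulateTissue(cfg))
    full <- clusterCells(ce, nPcs = nrow(ce), seed = 2)
    # reference: identical pipeline wired directly on the normalized matrix
    m <- t(assay(ce, "normalized"))
    knn <- nichescape:::.knnExact(m, 30)
    el <- cbind(rep(seq_len(nrow(m)), each = 30), as.vector(t(knn$index)))
    gr <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
    set.seed(2)
    ref <- as.integer(igraph::membership(igraph::cluster_leiden(
        gr, objective_function = "modularity", resolution = 1,
        n_iterations = 5)))
    expect_equal(ari(clusterLabels(full), ref), 1)
})

test_that("duplicating every cell keeps duplicates in the same cluster", {
    cfg <- three_type_config(9, cells_per_roi = 250, n_rois = 1)
    ce <- normalizeMarkers(simulateTissue(cfg))
    n <- ncol(ce)
    dup <- ce[, rep(seq_len(n), each = 2)]
    colnames(dup) <- sprintf("d%04d", seq_len(2 * n))
    lab <- clusterLabels(clusterCells(dup, seed = 3))
    expect_identical(lab[seq(1, 2 * n, 2)], lab[seq(2, 2 * n, 2)])
})

test_that("cluster profiles equal brute-force per-cluster means", {
    cfg <- three_type_config(12, cells_per_roi = 50, n_rois = 1)
    ce <- clusterCells(normalizeMarkers(simulateTissue(cfg)), graphK = 10,
                       seed = 5)
    prof <- profileClusters(ce)
    m <- assay(ce, "normalized")
    lab <- clusterLabels(ce)
    for (cl in sort(unique(lab))) {
        want <- rowMeans(m[, lab == cl, drop = FALSE])
        expect_equal(unname(prof[as.character(cl), ]), unname(want),
                     tolerance = 1e-12)
    }
    # a single all-encompassing cluster is just the column-mean vector
    one <- ce
    colData(one)$cluster <- rep(1L, ncol(one))
    expect_equal(unname(profileClusters(one)[1, ]),
                 unname(rowMeans(assay(one, "normalized"))),
                 tolerance = 1e-12)
})

test_that("annotation maps, merges, and rejects partial mappings", {
    cfg <- three_type_config(13, cells_per_roi = 200, n_rois = 1)
    ce <- clusterCells(normalizeMarkers(simulateTissue(cfg)), seed = 6)
    labs <- sort(unique(clusterLabels(ce)))
    ident <- setNames(as.character(labs), labs)
    ce2 <- annotateCells(ce, ident)
    expect_identical(phenotypes(ce2), as.character(clusterLabels(ce)))
    merged <- setNames(rep("all", length(labs)), labs)
    expect_identical(unique(phenotypes(annotateCells(ce, merged))), "all")
    expect_error(annotateCells(ce, ident[-1]), "does not cover")
    # mapping survives a file round trip
    f <- tempfile(fileext = ".csv")
    write.csv(data.frame(cluster = names(ident), phenotype = ident), f,
              row.names = FALSE)
    rt <- read.csv(f, colClasses = "character")
    ce3 <- annotateCells(ce, setNames(rt$phenotype, rt$cluster))
    expect_identical(phenotypes(ce3), phenotypes(ce2))
})

test_that("clustering records its parameter provenance", {
    cfg <- three_type_config(14, cells_per_roi = 100, n_rois = 1)
    ce <- clusterCells(normalizeMarkers(simulateTissue(cfg)), nPcs = 10,
                       graphK = 15, resolution = 0.8, seed = 77)
    pv <- metadata(ce)$phenotyping
    expect_identical(pv[c("n_pcs", "graph_k", "resolution", "seed")],
                     list(n_pcs = 10L, graph_k = 15L, resolution = 0.8,
                          seed = 77))
})

test_that("too few cells for the similarity graph is an explicit error", {
    cfg <- three_type_config(15, cells_per_roi = 20, n_rois = 1)
    ce <- normalizeMarkers(simulateTissue(cfg))
    expect_error(clusterCells(ce, graphK = 30), "graphK \\+ 1")
})
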
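test_that("one source and one target give the plain Euclidean distance", {
    ce <- make_ce(c(0, 3), c(0, 4), phenotype = c("A", "B"))
    res <- minDistance(ce, "A", "B")
    expect_equal(res$avg_min_dist, 5)
    expect_identical(res$n_source, 1L)
    expect_true(res$defined)
})

test_that("coincident source and target cells give distance zero", {
    ce <- make_ce(c(1, 1, 7, 7), c(2, 2, 3, 3),
                  phenotype = c("A", "B", "A", "B"))
    expect_equal(minDistance(ce, "A", "B")$avg_min_dist, 0)
})

test_that("self-distance excludes the cell itself", {
    ce <- make_ce(c(0, 10, 21), c(0, 0, 0), phenotype = rep("A", 3))
    res <- minDistance(ce, "A", "A")
    expect_equal(res$avg_min_dist, mean(c(10, 10, 11)))
})

test_that("min distance equals brute force and is directional", {
    set.seed(4)
    n <- 120
    ph <- rep(c("A", "B"), c(70, 50))
    ce <- make_ce(runif(n, 0, 400), runif(n, 0, 400), phenotype = ph)
    xy <- spatialCoords(ce)
    ab <- minDistance(ce, "A", "B")$avg_min_dist
    ba <- minDistance(ce, "B", "A")$avg_min_dist
    expect_equal(ab, brute_avg_min_dist(xy[ph == "A", 1], xy[ph == "A", 2],
                                        xy[ph == "B", 1], xy[ph == "B", 2]),
                 tolerance = 0)
    expect_equal(ba, brute_avg_min_dist(xy[ph == "B", 1], xy[ph == "B", 2],
                                        xy[ph == "A", 1], xy[ph == "A", 2]),
                 tolerance = 0)
    # directional asymmetry on a 3-vs-2 fixture
    ce2 <- make_ce(c(0, 1, 30, 0, 31), c(0, 0, 0, 1, 0),
                   phenotype = c("A", "A", "A", "B", "B"))
    d_ab <- minDistance(ce2, "A", "B")$avg_min_dist
    d_ba <- minDistance(ce2, "B", "A")$avg_min_dist
    expect_false(isTRUE(all.equal(d_ab, d_ba)))
})

test_that("an ROI lacking a type is flagged, not an error", {
    ce <- make_ce(1:6, 1:6, roi = rep(c("r1", "r2"), each = 3),
                  phenotype = c("A", "A", "B", "A", "A", "A"))
    res <- minDistance(ce, "A", "B")
    expect_identical(res$defined, c(TRUE, FALSE))
    expect_true(is.na(res$avg_min_dist[2]))
})

test_that("cohort comparison is a faithful Welch t-test", {
    d <- data.frame(roi_id = sprintf("r%d", 1:8), type_a = "A", type_b = "B",
                    avg_min_dist = c(10, 12, 11, 13, 11, 12.5, 10.5, 12),
                    n_source = 5, defined = TRUE)
    cohorts <- setNames(rep(c("PR", "PD"), each = 4), d$roi_id)
    res <- compareDistance(d, cohorts)
    ref <- t.test(d$avg_min_dist[5:8], d$avg_min_dist[1:4])
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
    # identical groups: t = 0, p = 1
    d2 <- d
    d2$avg_min_dist <- rep(c(1, 2, 3, 4), 2)
    res2 <- compareDistance(d2, cohorts)
    expect_equal(res2$statistic, 0)
    expect_equal(res2$p_value, 1)
    # fewer than two usable ROIs in a cohort
    d3 <- d
    d3$defined[1:3] <- FALSE
    expect_error(compareDistance(d3, cohorts), ">= 2 ROIs")
})

test_that("with equal variances Welch coincides with the pooled t", {
    v1 <- c(1, 2, 3, 4)
    v2 <- c(10, 11, 12, 13)   # same sample variance
    d <- data.frame(roi_id = sprintf("r%d", 1:8), type_a = "A",
                    type_b = "B", avg_min_dist = c(v1, v2), n_source = 5,
                    defined = TRUE)
    cohorts <- setNames(rep(c("g1", "g2"), each = 4), d$roi_id)
    res <- compareDistance(d, cohorts)
    pooled <- t.test(v1, v2, var.equal = TRUE)
    expect_equal(res$statistic, unname(pooled$statistic), tolerance = 1e-12)
    expect_equal(res$df, unname(pooled$parameter), tolerance = 1e-12)
    expect_equal(res$p_value, pooled$p.value, tolerance = 1e-12)
})

test_that("the Welch p-value agrees with a permutation reference", {
    set.seed(6)
    v1 <- rnorm(10, 0.0, 1)
    v2 <- rnorm(10, 0.8, 1)
    d <- data.frame(roi_id = sprintf("r%d", 1:20), type_a = "A",
                    type_b = "B", avg_min_dist = c(v1, v2), n_source = 5,
                    defined = TRUE)
    cohorts <- setNames(rep(c("g1", "g2"), each = 10), d$roi_id)
    p_welch <- compareDistance(d, cohorts)$p_value
    pool <- c(v1, v2)
    obs <- abs(mean(v1) - mean(v2))
    set.seed(7)
    exceed <- replicate(20000, {
        idx <- sample(20, 10)
        abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
    })
    p_perm <- mean(exceed)
    expect_lt(abs(p_welch - p_perm), 0.04)
})

test_that("CN proportion comparison transforms, tests and corrects", {
    set.seed(11)
    props <- matrix(abs(rnorm(12 * 6, 0.2, 0.1)), 12, 6,
                    dimnames = list(sprintf("r%02d", 1:12),
                                    paste0("CN", 1:6)))
    props <- props / rowSums(props)
    cohorts <- setNames(rep(c("PR", "PD"), each = 6), rownames(props))
    res <- compareCnProportions(props, cohorts)
    expect_identical(nrow(res), 6L)
    # Bonferroni is exactly min(1, m * p)
    expect_equal(res$p_adjusted, pmin(1, 6 * res$p_value))
    # per-CN Welch t on asinh-transformed proportions
    ref <- t.test(asinh(props[7:12, 3]), asinh(props[1:6, 3]))
    expect_equal(res$statistic[3], unname(ref$statistic))
    # atanh mode stays finite at proportion 1 and asinh(0) is 0
    props2 <- props
    props2[1, ] <- c(1, 0, 0, 0, 0, 0)
    expect_true(all(is.finite(
        compareCnProportions(props2, cohorts,
                             transform = "atanh")$statistic)))
    expect_identical(asinh(0), 0)
})

test_that("a CN absent everywhere is flagged but still counted in the family", {
    props <- cbind(matrix(runif(12 * 2, 0.3, 0.7), 12, 2), 0)
    props <- props / rowSums(props)
    colnames(props) <- paste0("CN", 1:3)
    rownames(props) <- sprintf("r%02d", 1:12)
    cohorts <- setNames(rep(c("PR", "PD"), each = 6), rownames(props))
    res <- compareCnProportions(props, cohorts)
    expect_true(res$flagged[3])
    expect_true(is.na(res$p_value[3]))
    # denominator m = 3 even with the flagged CN
    expect_equal(res$p_adjusted[1], min(1, 3 * res$p_value[1]))
})

test_that("interaction enrichment flags degenerate nulls and never returns p = 0", {
    set.seed(13)
    ce <- make_ce(runif(80, 0, 200), runif(80, 0, 200))
    g <- buildKnnGraph(ce, k = 5)
    res <- interactionEnrichment(g, rep("A", 80), nPerm = 100, seed = 1)
    expect_true(res$degenerate[1])
    expect_true(is.na(res$z[1]))
    res2 <- interactionEnrichment(g, sample(c("A", "B"), 80, TRUE),
                                  nPerm = 100, seed = 1)
    expect_true(all(res2$p_value > 0))
    expect_true(all(res2$p_value <= 1))
})

test_that("planted co-aggregation yields positive interaction z-scores", {
    hits <- 0L
    for (s in 1:5) {
        ce <- simulateTissue(tissueSimConfig(n_rois = 2,
                                             cells_per_roi = 800,
                                             seed = 100 + s))
        g <- buildKnnGraph(ce, k = 10)
        res <- interactionEnrichment(g, colData(ce)$true_type,
                                     nPerm = 200, seed = s)
        z <- res$z[res$type_a == "B" & res$type_b == "CD8T"]
        if (is.finite(z) && z > 0) hits <- hits + 1L
    }
    expect_gte(hits, 4L)
})

test_that("interaction counts respect the distance band", {
    # pairs 2 um apart (below band) and one A->B edge of 50 um (inside)
    ce <- make_ce(c(0, 2, 200, 250, 600, 601), c(0, 0, 0, 0, 0, 0))
    g <- buildKnnGraph(ce, k = 2)
    ph <- c("A", "B", "A", "B", "A", "B")
    res <- interactionEnrichment(g, ph, nPerm = 100, seed = 2,
                                 band = c(3, 100))
    ab <- res$observed[res$type_a == "A" & res$type_b == "B"]
    # only the 50-um A->B edge survives the band filter
    expect_identical(ab, 1L)
})
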
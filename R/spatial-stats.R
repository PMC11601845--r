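#' Average minimal distance from one cell type to another
#'
#' For every ROI: each cell of type `typeA` contributes its Euclidean
#' distance (microns) to the nearest cell of type `typeB`; the ROI summary
#' is the mean of those minima. The statistic is directional (mean of
#' minima from A to B differs, in general, from B to A). With
#' `typeA == typeB` the cell itself is excluded from its own minimum.
#'
#' @param x a [CodexExperiment-class] with phenotype labels.
#' @param typeA,typeB phenotype names (source and target).
#' @param labels which label column to use, default `"phenotype"` (fall
#'   back on any per-cell vector of the right length).
#' @return `data.frame` with one row per ROI: `roi_id`, `type_a`, `type_b`,
#'   `avg_min_dist`, `n_source` and `defined`. ROIs lacking either type are
#'   flagged `defined = FALSE` with `NA` distance, not an error.
#' @export
minDistance <- function(x, typeA, typeB, labels = "phenotype") {
    if (is.character(labels) && length(labels) == 1) {
        ph <- colData(x)[[labels]]
        if (is.null(ph)) stop("no '", labels, "' column in colData")
    } else {
        ph <- labels
    }
    ph <- as.character(ph)
    if (length(ph) != ncol(x)) stop("need one label per cell")
    coords <- spatialCoords(x)
    roi <- roiIds(x)
    rois <- unique(roi)
    res <- lapply(rois, function(r) {
        sel <- roi == r
        ia <- which(sel & ph == typeA)
        ib <- which(sel & ph == typeB)
        if (!length(ia) || !length(ib) ||
            (typeA == typeB && length(ia) < 2)) {
            return(data.frame(roi_id = r, type_a = typeA, type_b = typeB,
                              avg_min_dist = NA_real_,
                              n_source = length(ia), defined = FALSE,
                              stringsAsFactors = FALSE))
        }
        d2 <- outer(coords[ia, 1], coords[ib, 1], "-")^2 +
              outer(coords[ia, 2], coords[ib, 2], "-")^2
        if (typeA == typeB) {
            d2[outer(ia, ib, "==")] <- Inf   # a cell is not its own target
        }
        mins <- sqrt(apply(d2, 1, min))
        data.frame(roi_id = r, type_a = typeA, type_b = typeB,
                   avg_min_dist = mean(mins), n_source = length(ia),
                   defined = TRUE, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Compare average minimal distances between two cohorts
#'
#' Welch's two-sample t-test (unequal variances, Welch-Satterthwaite
#' degrees of freedom, two-sided) on the per-ROI average minimal distance.
#'
#' @param distances output of [minDistance()] (rows with
#'   `defined = FALSE` are dropped).
#' @param cohorts named character vector mapping `roi_id` to cohort; must
#'   yield exactly two cohorts with at least two usable ROIs each.
#' @return One-row `data.frame` (contrast, Welch t statistic, df, p-value,
#'   per-cohort n/mean/sd).
#' @export
compareDistance <- function(distances, cohorts) {
    d <- distances[distances$defined & is.finite(distances$avg_min_dist), ,
                   drop = FALSE]
    co <- cohorts[d$roi_id]
    if (anyNA(co)) {
        stop("no cohort assignment for ROI(s): ",
             paste(unique(d$roi_id[is.na(co)]), collapse = ", "))
    }
    groups <- sort(unique(co))
    if (length(groups) != 2) stop("exactly two cohorts required, got ",
                                  length(groups))
    v1 <- d$avg_min_dist[co == groups[1]]
    v2 <- d$avg_min_dist[co == groups[2]]
    if (length(v1) < 2 || length(v2) < 2) {
        stop("each cohort needs >= 2 ROIs with a defined distance (",
             groups[1], ": ", length(v1), ", ", groups[2], ": ",
             length(v2), ")")
    }
    tt <- t.test(v1, v2, var.equal = FALSE)
    .comparisonRow(
        contrast = sprintf("%s->%s: %s vs %s", d$type_a[1], d$type_b[1],
                           groups[1], groups[2]),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, method = "welch_t",
        g1 = groups[1], g2 = groups[2], v1 = v1, v2 = v2)
}

#' Compare per-ROI cellular-neighborhood proportions between cohorts
#'
#' For each CN, transforms the per-ROI proportions (inverse hyperbolic
#' sine by default; `atanh` with clamping at `1 - 1e-9` available),
#' applies a two-sample Welch t-test between the two cohorts and corrects
#' the family of per-CN p-values by the Bonferroni method. A CN that is
#' degenerate in a cohort (e.g. absent from all its ROIs, giving zero
#' variance) is flagged with an `NA` p-value but still counts in the
#' Bonferroni denominator.
#'
#' @param props ROI x CN proportion matrix from [cnRoiProportions()].
#' @param cohorts named vector mapping ROI id to cohort (exactly two).
#' @param transform `"asinh"` (default) or `"atanh"`.
#' @return `data.frame`, one row per CN, with the Welch statistic, raw and
#'   Bonferroni-adjusted p-values (`p_adjusted = min(1, m * p)` with `m =`
#'   number of CNs) and group summaries.
#' @export
compareCnProportions <- function(props, cohorts,
                                 transform = c("asinh", "atanh")) {
    transform <- match.arg(transform)
    props <- as.matrix(props)
    co <- cohorts[rownames(props)]
    if (anyNA(co)) stop("every ROI needs a cohort assignment")
    groups <- sort(unique(co))
    if (length(groups) != 2) stop("exactly two cohorts required")
    f <- if (transform == "asinh") {
        asinh
    } else {
        function(p) atanh(pmin(p, 1 - 1e-9))
    }
    m <- ncol(props)
    rows <- lapply(seq_len(m), function(j) {
        v1 <- f(props[co == groups[1], j])
        v2 <- f(props[co == groups[2], j])
        tt <- tryCatch(t.test(v1, v2, var.equal = FALSE),
                       error = function(e) NULL)
        bad <- is.null(tt) || !is.finite(tt$statistic)   # degenerate CN
        row <- .comparisonRow(
            contrast = colnames(props)[j],
            statistic = if (bad) NA_real_ else unname(tt$statistic),
            df = if (bad) NA_real_ else unname(tt$parameter),
            p = if (bad) NA_real_ else tt$p.value,
            method = paste0("welch_t_", transform),
            g1 = groups[1], g2 = groups[2], v1 = v1, v2 = v2)
        row$flagged <- bad
        row
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- p.adjust(out$p_value, method = "bonferroni", n = m)
    out
}

#' Permutation enrichment of pairwise cell-cell adjacencies
#'
#' Counts, for every ordered phenotype pair (A, B), the spatial-graph edges
#' from an A cell to a B neighbor whose length falls inside the distance
#' band (3-100 microns by default), and compares the observed count to a
#' permutation null in which phenotype labels are shuffled within each ROI
#' while the graph stays fixed. Enrichment is summarized as
#' `z = (observed - null mean) / null sd` and a two-sided empirical
#' p-value, `min(1, 2 * (1 + smaller tail count) / (nPerm + 1))`, which can
#' never be exactly zero. When the null is degenerate (sd 0) the z-score is
#' undefined and the p-value reports the empirical tail alone.
#'
#' @param graph a [SpatialGraph-class].
#' @param phenotypes per-cell phenotype labels (aligned or named by cell
#'   id).
#' @param nPerm number of label permutations (>= 100).
#' @param seed integer RNG seed.
#' @param band numeric length-2, inclusive distance band in microns.
#' @return `data.frame`, one row per ordered phenotype pair: observed
#'   count, null mean and sd, `z`, `p_value`, `n_perm`, band bounds and a
#'   `degenerate` flag.
#' @export
interactionEnrichment <- function(graph, phenotypes, nPerm = 1000,
                                  seed = 1L, band = c(3, 100)) {
    if (!is(graph, "SpatialGraph")) stop("'graph' must be a SpatialGraph")
    if (nPerm < 100) stop("nPerm must be >= 100")
    if (length(band) != 2 || band[1] > band[2]) {
        stop("band must be c(min, max) microns")
    }
    n <- length(graph@cellIds)
    if (!is.null(names(phenotypes))) phenotypes <- phenotypes[graph@cellIds]
    if (length(phenotypes) != n || anyNA(phenotypes)) {
        stop("need a phenotype for every cell in the graph")
    }
    ph <- factor(phenotypes)
    P <- nlevels(ph)
    k <- graph@k
    src <- rep(seq_len(n), each = k)
    dst <- as.vector(t(graph@nnIndex))
    len <- as.vector(t(graph@nnDist))
    keep <- len >= band[1] & len <= band[2]
    src <- src[keep]; dst <- dst[keep]
    phi <- as.integer(ph)
    pairIdx <- function(lab) (lab[src] - 1L) * P + lab[dst]
    obs <- tabulate(pairIdx(phi), nbins = P * P)
    roiSplit <- split(seq_len(n), graph@roi)
    set.seed(seed)
    nullCounts <- matrix(0L, nPerm, P * P)
    for (b in seq_len(nPerm)) {
        lab <- phi
        for (idx in roiSplit) lab[idx] <- phi[idx[sample.int(length(idx))]]
        nullCounts[b, ] <- tabulate(pairIdx(lab), nbins = P * P)
    }
    mu <- colMeans(nullCounts)
    sdv <- apply(nullCounts, 2, sd)
    ge <- colSums(nullCounts >= rep(obs, each = nPerm))
    le <- colSums(nullCounts <= rep(obs, each = nPerm))
    degenerate <- sdv == 0
    z <- ifelse(degenerate, NA_real_, (obs - mu) / sdv)
    p <- ifelse(degenerate,
                (1 + pmin(ge, le)) / (nPerm + 1),
                pmin(1, 2 * (1 + pmin(ge, le)) / (nPerm + 1)))
    levs <- levels(ph)
    data.frame(
        type_a = rep(levs, each = P), type_b = rep(levs, times = P),
        observed = obs, null_mean = mu, null_sd = sdv, z = z,
        p_value = p, n_perm = nPerm, band_min = band[1], band_max = band[2],
        degenerate = degenerate, stringsAsFactors = FALSE
    )
}
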
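# Independent brute-force references used to validate the package's
# implementations. These deliberately use naive per-element loops rather
# than the vectorized code paths under test.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Naive per-pixel stochastic dilation sharing the package's documented RNG
# contract: set.seed once, per round visit candidate background pixels in
# row-major order, one runif(1) per candidate, flip when u < p. Candidate
# mask = most frequent neighbor label (ties -> smallest label); p = that
# count over the number of in-bounds neighbors. Rounds are synchronous.
naive_dilate <- function(grid, rounds, connectivity = 8, seed = 1) {
    offs <- if (connectivity == 4) {
        list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    } else {
        list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
             c(1, -1), c(1, 0), c(1, 1))
    }
    nr <- nrow(grid); nc <- ncol(grid)
    set.seed(seed)
    for (r in seq_len(rounds)) {
        g0 <- grid
        flips <- list()
        for (i in seq_len(nr)) {
            for (j in seq_len(nc)) {
                if (g0[i, j] != 0) next
                labs <- integer(0); total <- 0L
                for (o in offs) {
                    ni <- i + o[1]; nj <- j + o[2]
                    if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
                    total <- total + 1L
                    if (g0[ni, nj] > 0) labs <- c(labs, g0[ni, nj])
                }
                if (!length(labs)) next
                tb <- tabulate(labs)
                bc <- max(tb)
                lab <- which(tb == bc)[1]
                if (runif(1) < bc / total) {
                    flips[[length(flips) + 1]] <- c(i, j, lab)
                }
            }
        }
        for (f in flips) grid[f[1], f[2]] <- f[3]
    }
    grid
}

# Deterministic binary dilation of a logical mask by `steps` neighborhood
# steps; used for the bounded-reach invariant.
binary_dilate <- function(mask, steps, connectivity = 8) {
    offs <- if (connectivity == 4) {
        list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    } else {
        list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
             c(1, -1), c(1, 0), c(1, 1))
    }
    nr <- nrow(mask); nc <- ncol(mask)
    for (s in seq_len(steps)) {
        out <- mask
        for (o in offs) {
            ri <- max(1, 1 + o[1]):min(nr, nr + o[1])
            ci <- max(1, 1 + o[2]):min(nc, nc + o[2])
            out[ri - o[1], ci - o[2]] <- out[ri - o[1], ci - o[2]] |
                mask[ri, ci]
        }
        mask <- out
    }
    mask
}

# All-pairs k nearest neighbors by explicit loops.
brute_knn <- function(coords, k) {
    n <- nrow(coords)
    idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
    for (i in seq_len(n)) {
        d2 <- numeric(n)
        for (j in seq_len(n)) {
            d2[j] <- (coords[i, 1] - coords[j, 1])^2 +
                     (coords[i, 2] - coords[j, 2])^2
        }
        d2[i] <- Inf
        o <- order(d2)[seq_len(k)]
        idx[i, ] <- o
        dst[i, ] <- sqrt(d2[o])
    }
    list(index = idx, dist = dst)
}

# Mean over A cells of the squared-distance minimum to B cells, by loops.
brute_avg_min_dist <- function(ax, ay, bx, by, same = FALSE) {
    mins <- numeric(length(ax))
    for (i in seq_along(ax)) {
        d2 <- (ax[i] - bx)^2 + (ay[i] - by)^2
        if (same) d2[i] <- Inf
        mins[i] <- sqrt(min(d2))
    }
    mean(mins)
}

# Two-sided Fisher exact p by exhaustive enumeration over all tables with
# the observed margins, summing hypergeometric probabilities <= observed.
fisher_enum_p <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(ks, r1, n - r1, c1)
    p_obs <- dhyper(tab[1, 1], r1, n - r1, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up recursion written out by hand.
bh_by_hand <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        prev <- min(prev, m * p[o[i]] / i)
        q[o[i]] <- prev
    }
    q
}

# Small CodexExperiment from explicit coordinates.
make_ce <- function(x, y, roi = "roi1", markers = NULL, ...) {
    n <- length(x)
    if (is.null(markers)) {
        markers <- matrix(rlnorm(3 * n, log(10), 0.3), nrow = 3,
                          dimnames = list(c("M1", "M2", "M3"), NULL))
    }
    colnames(markers) <- sprintf("c%04d", seq_len(n))
    cd <- data.frame(roi_id = rep_len(roi, n), x_um = x, y_um = y, ...)
    rownames(cd) <- colnames(markers)
    CodexExperiment(markers, cd)
}

# SpatialGraph with hand-chosen neighbor lists.
make_graph <- function(nnIndex, nnDist = NULL, roi = NULL) {
    n <- nrow(nnIndex)
    if (is.null(nnDist)) nnDist <- matrix(10, n, ncol(nnIndex))
    if (is.null(roi)) roi <- rep("roi1", n)
    new("SpatialGraph", k = ncol(nnIndex), cellIds = sprintf("c%04d", 1:n),
        roi = roi, nnIndex = nnIndex, nnDist = nnDist)
}

# Criterion-style phenotyping fixture: three cell types whose defining
# marker means sit >= 5 lognormal noise-sd apart, one well-mixed
# neighborhood (spatial structure is irrelevant for phenotyping).
three_type_config <- function(seed, cells_per_roi = 1000, n_rois = 2) {
    tissueSimConfig(
        n_rois = n_rois, cells_per_roi = cells_per_roi,
        cell_types = c("Tumor", "CD8T", "B"),
        neighborhood_profiles = list(
            mixed = c(Tumor = 0.4, CD8T = 0.35, B = 0.25)),
        cohort_effect = list(responder = c(mixed = 1),
                             nonresponder = c(mixed = 1)),
        seed = seed)
}
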
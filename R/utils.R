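# Internal numerical helpers shared across modules.

# Exact k-nearest neighbors by blocked brute force (Euclidean).
# Ties in distance are broken by point index (order() is stable), so the
# result is deterministic. Returns list(index = n x k, dist = n x k).
.knnExact <- function(X, k, block = 512L) {
    n <- nrow(X)
    if (k >= n) stop("need more points than neighbors: k = ", k,
                     " but only ", n, " points")
    X <- as.matrix(X)
    sq <- rowSums(X^2)
    idx <- matrix(0L, n, k)
    dst <- matrix(0, n, k)
    for (start in seq(1L, n, by = block)) {
        rows <- start:min(start + block - 1L, n)
        d2 <- outer(sq[rows], sq, "+") - 2 * (X[rows, , drop = FALSE] %*% t(X))
        d2[cbind(seq_along(rows), rows)] <- Inf   # exclude self
        d2[d2 < 0] <- 0
        for (i in seq_along(rows)) {
            o <- order(d2[i, ])[seq_len(k)]
            idx[rows[i], ] <- o
            dst[rows[i], ] <- sqrt(d2[i, o])
        }
    }
    list(index = idx, dist = dst)
}

# Standardize columns; zero-variance columns are either an error (naming the
# offender) or centred to zero, per `onZeroVar`.
.zscoreColumns <- function(m, onZeroVar = c("error", "zero"), context = "") {
    onZeroVar <- match.arg(onZeroVar)
    mu <- colMeans(m)
    sdv <- apply(m, 2, sd)
    bad <- which(sdv == 0 | !is.finite(sdv))
    if (length(bad)) {
        if (onZeroVar == "error") {
            stop("zero-variance marker column(s) ", context, ": ",
                 paste(colnames(m)[bad], collapse = ", "),
                 " (cannot z-scale; use zeroVariance = \"zero\" to flag ",
                 "and neutralize them)")
        }
        sdv[bad] <- 1   # centred to 0, carries no signal downstream
    }
    out <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
    attr(out, "flagged") <- colnames(m)[bad]
    out
}

# One tidy row of a two-group comparison (the shared ComparisonResult shape).
.comparisonRow <- function(contrast, statistic, df, p, method,
                           g1, g2, v1, v2) {
    data.frame(
        contrast = contrast, statistic = statistic, df = df,
        p_value = p, p_adjusted = NA_real_, method = method,
        n_1 = length(v1), mean_1 = mean(v1), sd_1 = sd(v1),
        n_2 = length(v2), mean_2 = mean(v2), sd_2 = sd(v2),
        group_1 = g1, group_2 = g2,
        stringsAsFactors = FALSE
    )
}
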
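#' Combined z-score of a gene signature
#'
#' Scores each sample by the Stouffer-style combined z: every member gene
#' is z-standardized across samples and the per-sample sum of member-gene
#' z-scores is divided by the square root of the number of member genes,
#' stabilizing the variance so the score of an uninformative signature
#' stays approximately standard normal regardless of its size.
#'
#' Member genes missing from the matrix, and genes with zero variance
#' across samples, are excluded with a warning and the denominator shrinks
#' accordingly; a signature with no usable member genes is an error.
#'
#' @param x expression data: a samples x genes numeric matrix (sample ids
#'   as row names) or a [SummarizedExperiment::SummarizedExperiment]
#'   (genes x samples, first assay).
#' @param genes character vector of member gene symbols (case-sensitive,
#'   no duplicates).
#' @param name signature name recorded in the output.
#' @return `data.frame` with one row per sample: `sample_id`, `signature`,
#'   `score`, `n_genes` (member genes actually used).
#' @examples
#' se <- simulateExpression(expressionSimConfig(seed = 1))
#' sc <- scoreSignature(se, sprintf("gene%03d", 1:24), name = "TLS")
#' head(sc)
#' @export
scoreSignature <- function(x, genes, name = "signature") {
    if (is(x, "SummarizedExperiment")) {
        m <- t(assay(x, 1))                  # samples x genes
    } else {
        m <- as.matrix(x)
    }
    if (length(genes) == 0) stop("signature has no member genes")
    if (anyDuplicated(genes)) stop("duplicate gene symbols in signature")
    if (nrow(m) < 3) stop("need at least 3 samples to standardize genes")
    present <- intersect(genes, colnames(m))
    missing <- setdiff(genes, present)
    if (length(missing)) {
        warning("signature '", name, "': ", length(missing),
                " member gene(s) absent from the matrix, excluded: ",
                paste(head(missing, 5), collapse = ", "),
                if (length(missing) > 5) ", ..." else "")
    }
    if (length(present)) {
        sdv <- apply(m[, present, drop = FALSE], 2, sd)
        novar <- present[sdv == 0]
        if (length(novar)) {
            warning("signature '", name, "': zero-variance gene(s) ",
                    "excluded: ", paste(novar, collapse = ", "))
            present <- setdiff(present, novar)
        }
    }
    if (!length(present)) {
        stop("signature '", name, "': no usable member genes in the matrix")
    }
    z <- scale(m[, present, drop = FALSE])
    score <- rowSums(z) / sqrt(length(present))
    data.frame(sample_id = if (is.null(rownames(m))) {
                   sprintf("s%03d", seq_len(nrow(m)))
               } else rownames(m),
               signature = name, score = unname(score),
               n_genes = length(present), stringsAsFactors = FALSE)
}

#' Median stratification of signature scores
#'
#' Splits samples into `high` (score strictly above the median) and `low`
#' (at or below the median; ties at the median go to `low` by convention).
#' For an odd number of distinct scores this reproduces the familiar
#' near-balanced split (sizes differing by one).
#'
#' @param scores numeric vector of signature scores (optionally named), or
#'   the `data.frame` returned by [scoreSignature()].
#' @return Factor with levels `c("low", "high")`, one per sample, named
#'   when sample ids are available.
#' @export
stratifyByMedian <- function(scores) {
    if (is.data.frame(scores)) {
        v <- setNames(scores$score, scores$sample_id)
    } else {
        v <- scores
    }
    if (length(v) < 2) stop("need at least 2 samples to stratify")
    if (diff(range(v)) == 0) {
        stop("all scores identical; no median stratification possible")
    }
    med <- median(v)
    factor(ifelse(v > med, "high", "low"), levels = c("low", "high"))
}

#' Compare signature scores between groups (Welch t / Welch ANOVA)
#'
#' Two groups are compared by Welch's two-sample t-test; three or more by
#' Welch's heteroscedastic one-way ANOVA (the F approximation implemented
#' by [stats::oneway.test()]). Two-sided throughout.
#'
#' @param scores numeric score vector (or [scoreSignature()] output).
#' @param groups group labels, one per sample; every group needs >= 2
#'   samples.
#' @return One-row `data.frame` with the test statistic, degrees of
#'   freedom and p-value (`method` is `"welch_t"` or `"welch_anova"`).
#' @export
groupTests <- function(scores, groups) {
    if (is.data.frame(scores)) scores <- setNames(scores$score,
                                                  scores$sample_id)
    groups <- as.factor(groups)
    if (length(groups) != length(scores)) {
        stop("need one group label per score")
    }
    sizes <- table(groups)
    if (any(sizes < 2)) {
        stop("group(s) with fewer than 2 samples: ",
             paste(names(sizes)[sizes < 2], collapse = ", "))
    }
    if (nlevels(groups) < 2) stop("need at least two groups")
    if (nlevels(groups) == 2) {
        v1 <- scores[groups == levels(groups)[1]]
        v2 <- scores[groups == levels(groups)[2]]
        tt <- t.test(v1, v2, var.equal = FALSE)
        .comparisonRow(
            contrast = paste(levels(groups), collapse = " vs "),
            statistic = unname(tt$statistic), df = unname(tt$parameter),
            p = tt$p.value, method = "welch_t",
            g1 = levels(groups)[1], g2 = levels(groups)[2],
            v1 = v1, v2 = v2)
    } else {
        ow <- oneway.test(scores ~ groups, var.equal = FALSE)
        data.frame(contrast = paste(levels(groups), collapse = " vs "),
                   statistic = unname(ow$statistic),
                   df = unname(ow$parameter[1]),
                   df2 = unname(ow$parameter[2]),
                   p_value = ow$p.value, p_adjusted = NA_real_,
                   method = "welch_anova", stringsAsFactors = FALSE)
    }
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact p-value for association between two binary sample
#' classifications (e.g. signature-high/low stratum versus clinical
#' response), summing hypergeometric probabilities no larger than that of
#' the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts with both
#'   margins positive.
#' @return One-row `data.frame` with the odds-ratio estimate and exact
#'   p-value.
#' @export
fisherAssociation <- function(table) {
    table <- as.matrix(table)
    if (!identical(dim(table), c(2L, 2L))) stop("a 2x2 table is required")
    if (any(table < 0) || any(table != round(table))) {
        stop("counts must be non-negative integers")
    }
    if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
        stop("both margins must be positive")
    }
    ft <- fisher.test(table)
    data.frame(contrast = "2x2 association",
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               p_adjusted = NA_real_, method = "fisher_exact",
               stringsAsFactors = FALSE)
}

#' Paired pre/post comparison with per-gene Benjamini-Hochberg correction
#'
#' Paired t-test on matched pre- and post-treatment signature scores.
#' When matched gene-level matrices are supplied, every gene additionally
#' gets a paired t-test, and the per-gene p-value family is corrected by
#' the Benjamini-Hochberg step-up procedure.
#'
#' Samples are matched by name; unmatched samples are an error listing the
#' orphans. Identical pre/post values give `t = 0`, `p = 1` (rather than a
#' zero-variance failure).
#'
#' @param pre,post numeric score vectors named by sample id (or
#'   [scoreSignature()] outputs).
#' @param preMatrix,postMatrix optional samples x genes matrices (same
#'   sample names as `pre`/`post`, same gene columns) for the per-gene
#'   analysis.
#' @return A list with `score` (one-row comparison `data.frame`) and,
#'   when gene matrices are given, `genes` (per-gene `data.frame` with
#'   `statistic`, `p_value` and BH `q_value`).
#' @export
pairedComparison <- function(pre, post, preMatrix = NULL,
                             postMatrix = NULL) {
    if (is.data.frame(pre)) pre <- setNames(pre$score, pre$sample_id)
    if (is.data.frame(post)) post <- setNames(post$score, post$sample_id)
    if (is.null(names(pre)) || is.null(names(post))) {
        if (length(pre) != length(post)) {
            stop("unnamed score vectors must have equal length")
        }
    } else {
        orphans <- c(setdiff(names(pre), names(post)),
                     setdiff(names(post), names(pre)))
        if (length(orphans)) {
            stop("unmatched sample(s): ", paste(orphans, collapse = ", "))
        }
        post <- post[names(pre)]
    }
    res <- list(score = .pairedT("signature_score", pre, post))
    if (!is.null(preMatrix) || !is.null(postMatrix)) {
        if (is.null(preMatrix) || is.null(postMatrix)) {
            stop("supply both preMatrix and postMatrix or neither")
        }
        preMatrix <- as.matrix(preMatrix)
        postMatrix <- as.matrix(postMatrix)
        if (!identical(colnames(preMatrix), colnames(postMatrix))) {
            stop("gene columns of preMatrix and postMatrix must match")
        }
        if (!is.null(rownames(preMatrix))) {
            orphans <- c(setdiff(rownames(preMatrix), rownames(postMatrix)),
                         setdiff(rownames(postMatrix), rownames(preMatrix)))
            if (length(orphans)) {
                stop("unmatched sample(s) in gene matrices: ",
                     paste(orphans, collapse = ", "))
            }
            postMatrix <- postMatrix[rownames(preMatrix), , drop = FALSE]
        }
        genes <- colnames(preMatrix)
        per <- do.call(rbind, lapply(seq_along(genes), function(j) {
            .pairedT(genes[j], preMatrix[, j], postMatrix[, j])
        }))
        per$q_value <- p.adjust(per$p_value, method = "BH")
        res$genes <- per
    }
    res
}

# Paired t robust to a zero-variance difference vector.
.pairedT <- function(label, pre, post) {
    d <- post - pre
    if (sd(d) == 0) {
        stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        p <- if (mean(d) == 0) 1 else 0
        df <- length(d) - 1
    } else {
        tt <- t.test(post, pre, paired = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value
        df <- unname(tt$parameter)
    }
    data.frame(contrast = label, statistic = stat, df = df, p_value = p,
               p_adjusted = NA_real_, method = "paired_t",
               mean_difference = mean(d), n_pairs = length(d),
               stringsAsFactors = FALSE)
}

#' Read gene-set definitions
#'
#' `readSignatureCsv()` reads a two-column CSV (`signature`, `gene`);
#' `readGmt()` reads GMT via `fgsea::gmtPathways()`. Both return a named
#' list of character vectors of member genes (exact, case-sensitive
#' symbols).
#'
#' @param path file path.
#' @return Named list of gene vectors.
#' @rdname signatureIO
#' @export
readSignatureCsv <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("signature", "gene") %in% colnames(df))) {
        stop("expected columns 'signature' and 'gene' in ", path)
    }
    lapply(split(df$gene, df$signature), unique)
}

#' @rdname signatureIO
#' @export
readGmt <- function(path) {
    if (!requireNamespace("fgsea", quietly = TRUE)) {
        stop("reading GMT requires the 'fgsea' package")
    }
    fgsea::gmtPathways(path)
}
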
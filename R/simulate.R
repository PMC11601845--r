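#' Default 25-marker CODEX-style panel
#'
#' Marker names for the simulator's default panel, mirroring a typical
#' 25-plex tumor-immune CODEX staining panel (lineage, activation and
#' structural markers).
#'
#' @return Character vector of 25 marker names.
#' @export
defaultMarkerPanel <- function() {
    c("CD107A", "CD11C", "CD15", "CD20", "CD21", "CD23", "CD3", "CD31",
      "CD4", "CD44", "CD45RO", "CD47", "CD68", "CD8", "ECADHERIN",
      "EOMES", "FOXP3", "HLADR", "ICOS", "KI67", "LAG3", "MMP9",
      "PANCK", "PD1", "TBET")
}

#' Default per-type mean marker intensities
#'
#' Mean raw intensities (arbitrary fluorescence units) for the default cell
#' types over [defaultMarkerPanel()]. Lineage-defining markers sit well
#' above the common background level so that, at the default lognormal
#' noise (`noise_sd = 0.5` on the log scale), types are separated by
#' several noise standard deviations.
#'
#' @param cellTypes character vector; any subset of the six default types
#'   `"Tumor"`, `"CD8T"`, `"CD4T"`, `"B"`, `"DC"`, `"Macrophage"`.
#' @return Numeric matrix, one row per cell type, one column per marker.
#' @export
defaultMarkerMeans <- function(cellTypes = c("Tumor", "CD8T", "CD4T", "B",
                                             "DC", "Macrophage")) {
    panel <- defaultMarkerPanel()
    base <- 5
    mm <- matrix(base, nrow = 6, ncol = length(panel),
                 dimnames = list(c("Tumor", "CD8T", "CD4T", "B", "DC",
                                   "Macrophage"), panel))
    set_hi <- function(type, markers, value) {
        mm[type, markers] <<- value
    }
    set_hi("Tumor", c("PANCK", "ECADHERIN"), 120)
    set_hi("Tumor", "KI67", 60)
    set_hi("Tumor", "CD44", 80)
    set_hi("CD8T", c("CD3", "CD8"), 120)
    set_hi("CD8T", "CD45RO", 70)
    set_hi("CD8T", c("EOMES", "PD1", "TBET"), 40)
    set_hi("CD4T", c("CD3", "CD4"), 120)
    set_hi("CD4T", "CD45RO", 70)
    set_hi("CD4T", c("ICOS", "FOXP3"), 35)
    set_hi("B", "CD20", 120)
    set_hi("B", c("CD21", "HLADR"), 85)
    set_hi("B", "CD23", 55)
    set_hi("DC", "CD11C", 120)
    set_hi("DC", "HLADR", 110)
    set_hi("DC", "CD107A", 40)
    set_hi("Macrophage", "CD68", 120)
    set_hi("Macrophage", c("CD107A", "CD47"), 75)
    set_hi("Macrophage", c("MMP9", "CD11C"), 50)
    unknown <- setdiff(cellTypes, rownames(mm))
    if (length(unknown)) {
        stop("no default marker means for type(s): ",
             paste(unknown, collapse = ", "))
    }
    mm[cellTypes, , drop = FALSE]
}

#' Tissue simulation configuration
#'
#' Parameters for [simulateTissue()]. Defaults emulate the study design the
#' pipeline is meant for: a handful of ~10^3-cell ROIs (2 mm fields) whose
#' cells aggregate into planted spatial neighborhoods (tumor core, lymphoid
#' aggregate, myeloid-rich stroma), with responder ROIs enriched for
#' lymphoid neighborhoods and non-responder ROIs tumor-dominated.
#'
#' @param n_rois number of ROIs to generate.
#' @param cells_per_roi cells per ROI.
#' @param cell_types character vector of type names.
#' @param neighborhood_profiles named list; each element a probability
#'   vector over `cell_types` (must sum to 1 within 1e-9).
#' @param neighborhood_radius radius (microns) of the disc around a region
#'   center within which that neighborhood's cells are scattered.
#' @param roi_extent side length (microns) of the square ROI.
#' @param regions_per_roi number of neighborhood region centers per ROI.
#' @param marker_means matrix of mean raw intensities, one row per cell
#'   type (rownames = `cell_types`), identical marker ordering across types.
#' @param noise_sd lognormal scale (sd of log intensity), >= 0.
#' @param cohort_effect named list mapping cohort name to a non-negative
#'   prevalence weight vector over the neighborhoods.
#' @param seed integer RNG seed; the simulation is deterministic per seed.
#'
#' @return A validated configuration (list of class `TissueSimConfig`).
#' @export
tissueSimConfig <- function(
    n_rois = 8,
    cells_per_roi = 1000,
    cell_types = c("Tumor", "CD8T", "CD4T", "B", "DC", "Macrophage"),
    neighborhood_profiles = list(
        tumor_core = c(Tumor = 0.92, CD8T = 0.02, CD4T = 0.02, B = 0.01,
                       DC = 0.01, Macrophage = 0.02),
        lymphoid   = c(Tumor = 0.02, CD8T = 0.34, CD4T = 0.28, B = 0.31,
                       DC = 0.03, Macrophage = 0.02),
        myeloid    = c(Tumor = 0.03, CD8T = 0.04, CD4T = 0.04, B = 0.02,
                       DC = 0.47, Macrophage = 0.40)
    ),
    neighborhood_radius = 300,
    roi_extent = 2000,
    regions_per_roi = 6,
    marker_means = defaultMarkerMeans(cell_types),
    noise_sd = 0.5,
    cohort_effect = list(
        responder    = c(tumor_core = 0.25, lymphoid = 0.45, myeloid = 0.30),
        nonresponder = c(tumor_core = 0.65, lymphoid = 0.15, myeloid = 0.20)
    ),
    seed = 1L
) {
    if (length(cell_types) < 1) stop("at least one cell type is required")
    if (n_rois < 1 || cells_per_roi < 1) {
        stop("n_rois and cells_per_roi must be positive")
    }
    if (neighborhood_radius <= 0 || roi_extent <= 0) {
        stop("neighborhood_radius and roi_extent must be positive microns")
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (length(neighborhood_profiles) < 1) {
        stop("at least one neighborhood profile is required")
    }
    for (nm in names(neighborhood_profiles)) {
        p <- neighborhood_profiles[[nm]]
        if (length(p) == 0) stop("empty mixture for neighborhood '", nm, "'")
        if (!setequal(names(p), cell_types)) {
            stop("mixture for '", nm, "' must be named by cell_types")
        }
        if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
            stop("mixture for '", nm, "' must be a probability vector ",
                 "summing to 1 (within 1e-9)")
        }
        neighborhood_profiles[[nm]] <- p[cell_types]
    }
    marker_means <- as.matrix(marker_means)
    if (is.null(rownames(marker_means)) ||
        !setequal(rownames(marker_means), cell_types)) {
        stop("marker_means must have one row per cell type")
    }
    if (any(marker_means < 0)) stop("marker_means must be >= 0")
    marker_means <- marker_means[cell_types, , drop = FALSE]
    for (nm in names(cohort_effect)) {
        w <- cohort_effect[[nm]]
        if (!setequal(names(w), names(neighborhood_profiles))) {
            stop("cohort_effect[['", nm, "']] must be named by neighborhoods")
        }
        if (any(w < 0) || sum(w) <= 0) {
            stop("cohort_effect weights must be non-negative, not all zero")
        }
        cohort_effect[[nm]] <- w[names(neighborhood_profiles)]
    }
    structure(
        list(n_rois = as.integer(n_rois),
             cells_per_roi = as.integer(cells_per_roi),
             cell_types = cell_types,
             neighborhood_profiles = neighborhood_profiles,
             neighborhood_radius = neighborhood_radius,
             roi_extent = roi_extent,
             regions_per_roi = as.integer(regions_per_roi),
             marker_means = marker_means,
             noise_sd = noise_sd,
             cohort_effect = cohort_effect,
             seed = as.integer(seed)),
        class = "TissueSimConfig"
    )
}

#' Simulate a planted-neighborhood tissue
#'
#' Generates ROIs whose cells cluster spatially around neighborhood region
#' centers. Region centers are placed uniformly in each ROI; each center is
#' given a neighborhood identity drawn from the ROI cohort's prevalence
#' weights; cells pick a region uniformly and scatter uniformly within
#' `neighborhood_radius` of its center. A cell falling in the overlap of
#' several regions belongs to the nearest center (ground truth
#' `true_neighborhood`); its type is drawn from that neighborhood's mixture
#' and its marker intensities are lognormal around the type's mean
#' (`meanlog = log(mean)`, `sdlog = noise_sd`), so raw values are
#' non-negative like fluorescence data.
#'
#' @param config a [tissueSimConfig()] object.
#' @return A [CodexExperiment-class] whose `colData` carries `roi_id`,
#'   `cohort`, `x_um`, `y_um` and the ground-truth labels `true_type` and
#'   `true_neighborhood`.
#' @examples
#' ce <- simulateTissue(tissueSimConfig(n_rois = 2, cells_per_roi = 200))
#' table(colData(ce)$true_type)
#' @export
simulateTissue <- function(config) {
    if (!inherits(config, "TissueSimConfig")) {
        config <- do.call(tissueSimConfig, config)
    }
    set.seed(config$seed)
    nbs <- names(config$neighborhood_profiles)
    cohortsAvail <- names(config$cohort_effect)
    nPerRoi <- config$cells_per_roi
    total <- config$n_rois * nPerRoi
    out <- vector("list", config$n_rois)
    for (r in seq_len(config$n_rois)) {
        roi <- sprintf("roi%02d", r)
        cohort <- cohortsAvail[(r - 1L) %% length(cohortsAvail) + 1L]
        w <- config$cohort_effect[[cohort]]
        centers <- cbind(runif(config$regions_per_roi, 0, config$roi_extent),
                         runif(config$regions_per_roi, 0, config$roi_extent))
        regionNb <- sample(nbs, config$regions_per_roi, replace = TRUE,
                           prob = w / sum(w))
        g <- sample.int(config$regions_per_roi, nPerRoi, replace = TRUE)
        theta <- runif(nPerRoi, 0, 2 * pi)
        rad <- config$neighborhood_radius * sqrt(runif(nPerRoi))
        x <- pmin(pmax(centers[g, 1] + rad * cos(theta), 0),
                  config$roi_extent)
        y <- pmin(pmax(centers[g, 2] + rad * sin(theta), 0),
                  config$roi_extent)
        d2 <- outer(x, centers[, 1], "-")^2 + outer(y, centers[, 2], "-")^2
        nearest <- max.col(-d2, ties.method = "first")
        trueNb <- regionNb[nearest]
        type <- character(nPerRoi)
        for (nb in unique(trueNb)) {
            sel <- trueNb == nb
            type[sel] <- sample(config$cell_types, sum(sel), replace = TRUE,
                                prob = config$neighborhood_profiles[[nb]])
        }
        out[[r]] <- data.frame(roi_id = roi, cohort = cohort, x_um = x,
                               y_um = y, true_type = type,
                               true_neighborhood = trueNb,
                               stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, out)
    typeIdx <- match(cells$true_type, rownames(config$marker_means))
    mm <- config$marker_means[typeIdx, , drop = FALSE]
    intens <- matrix(0, nrow = total, ncol = ncol(mm),
                     dimnames = list(NULL, colnames(mm)))
    pos <- mm > 0
    intens[pos] <- rlnorm(sum(pos), meanlog = log(mm[pos]),
                          sdlog = config$noise_sd)
    cellIds <- sprintf("cell%06d", seq_len(total))
    rownames(cells) <- cellIds
    m <- t(intens)
    colnames(m) <- cellIds
    CodexExperiment(m, cells, metadata = list(sim_config = config))
}

#' Simulate a non-overlapping nuclear mask raster
#'
#' Places `nMasks` filled discs with distinct positive labels on a
#' background-zero pixel grid by rejection sampling; disc borders are kept
#' at least one pixel apart so masks are disjoint.
#'
#' @param nMasks number of nuclei to place (0 gives an all-zero image).
#' @param shape image dimensions in pixels, `c(rows, cols)`.
#' @param minRadius,maxRadius disc radius range in pixels.
#' @param seed integer RNG seed.
#' @param maxAttempts placement attempt budget; exhausting it (masks cannot
#'   be placed without overlap) is an error.
#' @return A [LabelImage-class].
#' @examples
#' img <- simulateLabelImage(5, shape = c(64, 64), seed = 7)
#' table(labelGrid(img))
#' @export
simulateLabelImage <- function(nMasks, shape = c(64, 64), minRadius = 3,
                               maxRadius = 6, seed = 1L,
                               maxAttempts = 1000L * max(nMasks, 1L)) {
    if (nMasks < 0) stop("nMasks must be non-negative")
    if (minRadius <= 0 || maxRadius < minRadius) {
        stop("need 0 < minRadius <= maxRadius")
    }
    if (2 * maxRadius + 2 > min(shape)) {
        stop("image too small for maxRadius = ", maxRadius)
    }
    set.seed(seed)
    grid <- matrix(0L, shape[1], shape[2])
    if (nMasks == 0) return(LabelImage(grid))
    placed <- matrix(numeric(0), ncol = 3)   # row, col, radius
    attempts <- 0L
    while (nrow(placed) < nMasks) {
        attempts <- attempts + 1L
        if (attempts > maxAttempts) {
            stop("mask placement budget exhausted after ", maxAttempts,
                 " attempts: ", nrow(placed), " of ", nMasks,
                 " masks placed; reduce nMasks or radii, or enlarge shape")
        }
        rad <- runif(1, minRadius, maxRadius)
        ci <- runif(1, rad + 1, shape[1] - rad)
        cj <- runif(1, rad + 1, shape[2] - rad)
        if (nrow(placed) > 0) {
            d <- sqrt((placed[, 1] - ci)^2 + (placed[, 2] - cj)^2)
            if (any(d <= placed[, 3] + rad + 1)) next
        }
        placed <- rbind(placed, c(ci, cj, rad))
    }
    for (m in seq_len(nMasks)) {
        ci <- placed[m, 1]; cj <- placed[m, 2]; rad <- placed[m, 3]
        ii <- max(1, floor(ci - rad)):min(shape[1], ceiling(ci + rad))
        jj <- max(1, floor(cj - rad)):min(shape[2], ceiling(cj + rad))
        sub <- outer(ii - ci, jj - cj, function(a, b) a^2 + b^2) <= rad^2
        grid[ii, jj][sub] <- m
    }
    LabelImage(grid)
}

#' Expression simulation configuration
#'
#' Parameters for [simulateExpression()]. Defaults match the planted-effect
#' study condition used throughout the package's validation: 20 samples per
#' group, a 24-gene signature shifted by `3 * noise_sd` in the responder
#' group; set `group_shift = 0` for the null configuration.
#'
#' @param n_samples_per_group samples per group (two groups: `responder`,
#'   `nonresponder`).
#' @param n_genes total genes; names are `gene001`, `gene002`, ...
#' @param signature_genes subset of gene names forming the signature.
#' @param group_shift mean shift (in units of `noise_sd` being 1 means raw
#'   expression units) added to signature genes in the responder group.
#' @param noise_sd residual standard deviation, > 0.
#' @param seed integer RNG seed.
#' @return A validated configuration (list of class `ExpressionSimConfig`).
#' @export
expressionSimConfig <- function(n_samples_per_group = 20, n_genes = 200,
                                signature_genes =
                                    sprintf("gene%03d", seq_len(min(24, n_genes))),
                                group_shift = 3, noise_sd = 1, seed = 1L) {
    if (n_samples_per_group < 1 || n_genes < 1) {
        stop("n_samples_per_group and n_genes must be positive")
    }
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    genes <- sprintf("gene%03d", seq_len(n_genes))
    if (!all(signature_genes %in% genes)) {
        stop("signature_genes must be a subset of the generated gene names (",
             "gene001 .. ", sprintf("gene%03d", n_genes), ")")
    }
    structure(
        list(n_samples_per_group = as.integer(n_samples_per_group),
             n_genes = as.integer(n_genes), genes = genes,
             signature_genes = signature_genes,
             group_shift = group_shift, noise_sd = noise_sd,
             seed = as.integer(seed)),
        class = "ExpressionSimConfig"
    )
}

#' Simulate a group-shifted expression matrix
#'
#' Non-signature genes are Normal(0, `noise_sd`) in every sample; signature
#' genes gain `group_shift` in the responder group. Deterministic per seed.
#'
#' @param config an [expressionSimConfig()] object.
#' @return A [SummarizedExperiment::SummarizedExperiment] (genes x samples,
#'   assay `"exprs"`) with `colData$group` in
#'   `c("responder", "nonresponder")`.
#' @examples
#' se <- simulateExpression(expressionSimConfig(group_shift = 0, seed = 3))
#' table(colData(se)$group)
#' @export
simulateExpression <- function(config) {
    if (!inherits(config, "ExpressionSimConfig")) {
        config <- do.call(expressionSimConfig, config)
    }
    set.seed(config$seed)
    nS <- 2L * config$n_samples_per_group
    group <- rep(c("responder", "nonresponder"),
                 each = config$n_samples_per_group)
    m <- matrix(rnorm(config$n_genes * nS, 0, config$noise_sd),
                nrow = config$n_genes, ncol = nS,
                dimnames = list(config$genes, sprintf("s%03d", seq_len(nS))))
    sig <- match(config$signature_genes, config$genes)
    m[sig, group == "responder"] <- m[sig, group == "responder"] +
        config$group_shift
    SummarizedExperiment(
        assays = list(exprs = m),
        colData = DataFrame(group = group,
                            row.names = colnames(m)),
        metadata = list(sim_config = config)
    )
}
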
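#' Run the full analysis pipeline
#'
#' Orchestrates the stages in their study order: barcode-rank knee filtering
#' of empty droplets, cell-level QC filtering, pooled size-factor
#' normalization and log2 transform, HVG selection with a batch design
#' matrix, k-means immune pre-clustering and removal of immune clusters,
#' HVG re-selection on the non-immune cells, graph clustering on the first
#' principal components, two-stage marker identification (Wilcoxon + VIP
#' permutation), merging of clusters into groups, and a per-condition
#' trajectory analysis (principal tree, pseudotime, rolling-window
#' smoothing with the condition-specific window, early/middle/late pattern
#' classification) over the non-AFEC trajectory groups, with optional
#' EASE enrichment of the pattern gene sets.
#'
#' Every stage is a pure function of its inputs, the configuration and the
#' seed; the returned manifest records the configuration snapshot, the seed
#' and an md5 hash of every stage output, so two runs with identical inputs
#' produce identical manifests.
#'
#' @param sce a counts \code{SingleCellExperiment}
#'   (\code{\link{makeUMIMatrix}}, \code{\link{readMtxDir}} or the
#'   \code{sce} element of \code{\link{simulateDropletData}}).
#' @param config pipeline configuration (\code{\link{loadPipelineConfig}}
#'   output, a named list of overrides, or NULL for defaults).
#' @param immune_markers character vector of hematopoietic marker genes
#'   used for the immune pre-filter (skipped when NULL).
#' @param start_group_markers marker genes of the root (progenitor) state
#'   used to root the trajectories; when NULL the pipeline uses the final
#'   markers of the cluster least represented at late positions, and with
#'   \code{run_trajectory = FALSE} the trajectory stages are skipped.
#' @param gene_sets optional \code{\link{readGMT}} collection for pattern
#'   enrichment.
#' @param run_trajectory logical; run the trajectory stages.
#' @return list with the stage outputs (\code{qc}, \code{kept_cells},
#'   \code{norm} (the normalized \code{SingleCellExperiment}),
#'   \code{hvg_table}, \code{hvgs}, \code{clusters} (a
#'   \code{ClusterModel} with groups), \code{markers}, \code{trajectories}
#'   (per condition: Trajectory, smoothed profiles and pattern assignments
#'   per path), \code{enrichment}) and \code{manifest}.
#' @export
runPipeline <- function(sce, config = NULL, immune_markers = NULL,
                        start_group_markers = NULL, gene_sets = NULL,
                        run_trajectory = TRUE) {
    cfg <- if (is.list(config) && !is.null(config$mito_max)) config
           else loadPipelineConfig(config)
    seed <- cfg$seed
    manifest <- list(config = cfg, seed = seed, stages = character(0),
                     hashes = character(0))
    note <- function(stage, x) {
        manifest$stages <<- c(manifest$stages, stage)
        manifest$hashes <<- c(manifest$hashes,
                              structure(.hashObject(x), names = stage))
    }
    note("input", .getCounts(sce))

    ## empty-droplet removal ------------------------------------------------
    totals <- Matrix::colSums(.getCounts(sce))
    knee <- detectKneePoint(totals)
    sce1 <- sce[, totals >= knee]
    note("knee", list(knee, colnames(sce1)))

    ## cell QC ---------------------------------------------------------------
    qc <- computeCellQC(sce1)
    kept <- filterCells(qc, mito_max = cfg$mito_max,
                        unexpressed_max = cfg$unexpressed_max)
    sce1 <- sce1[, kept]
    note("qc", kept)

    ## normalization ----------------------------------------------------------
    sf <- pooledSizeFactors(sce1)
    sce1 <- logNormalize(sce1, sf)
    note("normalize", sf)

    ## HVGs (batch design) ----------------------------------------------------
    batch <- SummarizedExperiment::colData(sce1)$batch
    hvt <- decomposeVariance(sce1, batch = batch,
                             fdr_max = cfg$hvg_fdr, bio_min = cfg$hvg_bio)
    hvgs <- selectHVGs(hvt, cfg$hvg_fdr, cfg$hvg_bio)
    note("hvg", hvgs)

    ## immune pre-filter ------------------------------------------------------
    if (!is.null(immune_markers)) {
        sc0 <- pcaScores(sce1, genes = hvgs,
                         n_pcs = min(cfg$n_pcs, length(hvgs)))
        km <- kmeansCluster(sc0, k = cfg$kmeans_k, seed = seed)
        keep_cells <- filterImmuneCells(sce1, km, immune_markers)
        sce1 <- sce1[, keep_cells]
        # HVGs re-identified in the non-immune cells (size factors kept)
        batch <- SummarizedExperiment::colData(sce1)$batch
        hvt <- decomposeVariance(sce1, batch = batch,
                                 fdr_max = cfg$hvg_fdr,
                                 bio_min = cfg$hvg_bio)
        hvgs <- selectHVGs(hvt, cfg$hvg_fdr, cfg$hvg_bio)
        note("immune_filter", keep_cells)
    }

    ## graph clustering -------------------------------------------------------
    scores <- pcaScores(sce1, genes = hvgs,
                        n_pcs = min(cfg$n_pcs, length(hvgs)))
    cm <- graphCluster(scores, k_nn = cfg$k_nn,
                       resolution = cfg$resolution, seed = seed)
    note("cluster", clusterLabels(cm))

    ## markers ---------------------------------------------------------------
    labels <- clusterLabels(cm)
    markers <- clusterMarkers(sce1, labels, alpha = cfg$alpha,
                              fc_min = cfg$fc_min, n_perm = cfg$n_perm,
                              n_components = cfg$n_components, seed = seed)
    note("markers", as.data.frame(markers))

    ## merge clusters into groups --------------------------------------------
    # merging uses the initial (screen-passing, significantly upregulated)
    # markers: shared group-level genes drive the dendrogram and are exactly
    # what the VIP refinement removes from the final per-cluster sets
    marker_genes <- unique(markers$gene[markers$is_initial])
    n_groups <- min(cfg$n_groups, length(unique(labels)))
    mg <- mergeClusters(sce1, labels, marker_genes, n_groups = n_groups)
    cm@groups <- structure(paste0("G", mg$mapping), names = names(mg$mapping))
    cm@dendrogram <- mg$dendrogram
    note("groups", cm@groups)

    out <- list(qc = qc, kept_cells = colnames(sce1), norm = sce1,
                hvg_table = hvt, hvgs = hvgs, clusters = cm,
                markers = markers, trajectories = NULL, enrichment = NULL)

    ## trajectories, one per condition ---------------------------------------
    if (run_trajectory && !is.null(start_group_markers)) {
        groups <- groupLabels(cm)
        # trajectory runs over the non-niche groups: exclude the group with
        # the lowest mean expression of the root-state markers' complement,
        # i.e. keep the groups connected to the start state. Here the caller
        # designates the start state; groups are kept unless they are the
        # best-scoring group for exclusion marker sets supplied via
        # attr(start_group_markers, "exclude_markers").
        excl <- attr(start_group_markers, "exclude_markers")
        traj_cells_all <- names(groups)
        if (!is.null(excl)) {
            y <- .getLogExpr(out$norm)
            sc <- colMeans(y[intersect(excl, rownames(y)), , drop = FALSE])
            gm <- tapply(sc, groups, mean)
            drop_grp <- names(gm)[which.max(gm)]
            traj_cells_all <- names(groups)[groups != drop_grp]
        }
        conds <- unique(SummarizedExperiment::colData(out$norm)$condition)
        trajs <- list()
        for (cd in conds) {
            cells <- intersect(
                traj_cells_all,
                colnames(out$norm)[
                    SummarizedExperiment::colData(out$norm)$condition == cd])
            if (length(cells) < 60) next
            esub <- out$norm[, cells]
            feats <- selectTrajectoryFeatures(
                esub, cells,
                batch = SummarizedExperiment::colData(esub)$batch,
                n_pcs = cfg$n_pcs, k_nn = min(cfg$k_nn, length(cells) - 1L),
                resolution = cfg$resolution, n_perm = cfg$n_perm,
                alpha = cfg$alpha, fc_min = cfg$fc_min,
                n_components = cfg$n_components, seed = seed)
            tr <- fitPrincipalTree(esub, feats,
                                   n_nodes = min(cfg$n_tree_nodes,
                                                 length(cells) - 1L),
                                   seed = seed)
            tr <- orderCellsByPseudotime(tr, start_group_markers, e = esub)
            window <- if (grepl("treat", cd, ignore.case = TRUE))
                cfg$window_treated else cfg$window_control
            branches <- sort(unique(branchIds(tr)))
            branches <- setdiff(branches, 0L)
            paths <- if (length(branches)) branches else 0L
            pt_tr <- pseudotime(tr); br_tr <- branchIds(tr)
            path_out <- lapply(paths, function(b) {
                on_path <- if (b == 0L) !is.na(pt_tr)
                           else !is.na(pt_tr) & br_tr %in% c(0L, b)
                sm <- smoothAlongPseudotime(esub, tr, genes = feats,
                                            window = min(window,
                                                         sum(on_path)),
                                            branch = if (b == 0L) NULL
                                                     else b)
                pat <- classifyPatterns(sm$relative, k = cfg$k_patterns)
                list(smoothed = sm, patterns = pat)
            })
            names(path_out) <- paste0("path", if (length(branches))
                branches else 1L)
            trajs[[cd]] <- list(trajectory = tr, features = feats,
                                window = window, paths = path_out)
        }
        out$trajectories <- trajs
        note("trajectory", lapply(trajs, function(x)
            list(pseudotime(x$trajectory), branchIds(x$trajectory),
                 lapply(x$paths, function(p) as.data.frame(p$patterns)))))

        if (!is.null(gene_sets) && length(trajs)) {
            universe <- rownames(out$norm)[
                Matrix::rowSums(.getCounts(out$norm) > 0) > 0]
            lists <- list()
            for (cd in names(trajs))
                for (pn in names(trajs[[cd]]$paths)) {
                    pat <- trajs[[cd]]$paths[[pn]]$patterns
                    for (l in unique(pat$label))
                        lists[[paste(cd, pn, l, sep = "_")]] <-
                            pat$gene[pat$label == l]
                }
            out$enrichment <- suppressWarnings(
                enrichGeneLists(lists, gene_sets, universe,
                                alpha = cfg$alpha))
            note("enrichment", as.data.frame(out$enrichment))
        }
    }

    out$manifest <- manifest
    out
}
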
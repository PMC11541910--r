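#' Principal component scores of cells
#'
#' PCA of per-gene-centered log expression over a gene set, components
#' ordered by decreasing variance. The sign of each component is fixed by
#' making its largest-magnitude gene loading positive, so results are fully
#' deterministic.
#'
#' @param e \code{SingleCellExperiment} with \code{logcounts}, or matrix.
#' @param genes gene set to use (default: all genes).
#' @param n_pcs number of components; capped (with a warning) at what the
#'   data can support.
#' @return cells x components score matrix.
#' @export
pcaScores <- function(e, genes = NULL, n_pcs = 50) {
    y <- .getLogExpr(e)
    if (!is.null(genes)) {
        miss <- setdiff(genes, rownames(y))
        if (length(miss)) stop("genes not in matrix: ", miss[1], " ...")
        y <- y[genes, , drop = FALSE]
    }
    maxr <- min(nrow(y), ncol(y) - 1L)
    if (n_pcs > maxr) {
        warning("n_pcs reduced from ", n_pcs, " to ", maxr)
        n_pcs <- maxr
    }
    pc <- stats::prcomp(t(y), center = TRUE, scale. = FALSE, rank. = n_pcs)
    flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
        v <- pc$rotation[, k]
        sign(v[which.max(abs(v))])
    }, 0)
    flip[flip == 0] <- 1
    scores <- sweep(pc$x, 2, flip, "*")
    rownames(scores) <- colnames(y)
    scores
}

#' k-means clustering of cells
#'
#' Seeded k-means with multiple restarts (best within-cluster sum of squares
#' kept), used for the immune pre-clustering step.
#'
#' @param scores cells x components matrix (see \code{\link{pcaScores}}).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart restarts.
#' @return named integer labels.
#' @export
kmeansCluster <- function(scores, k = 4, seed = 1, nstart = 10) {
    if (k > nrow(scores)) stop("k exceeds the number of cells")
    fit <- .withSeed(seed,
        stats::kmeans(scores, centers = k, nstart = nstart, iter.max = 100))
    structure(as.integer(fit$cluster), names = rownames(scores))
}

#' Graph-based clustering of cells
#'
#' Builds a shared-nearest-neighbor graph (Jaccard-weighted) on the score
#' matrix and optimizes modularity (Louvain) at the given resolution.
#' Cluster ids are relabeled in order of decreasing size.
#'
#' @param scores cells x components matrix.
#' @param k_nn neighbors for the SNN graph.
#' @param resolution modularity resolution (> 0).
#' @param seed integer seed.
#' @return a \code{\link{ClusterModel-class}} (labels only).
#' @export
graphCluster <- function(scores, k_nn = 20, resolution = 1, seed = 1) {
    if (resolution <= 0) stop("resolution must be > 0")
    if (nrow(scores) <= k_nn) stop("need more cells than k_nn")
    g <- scran::buildSNNGraph(scores, k = k_nn, transposed = TRUE,
                              type = "jaccard")
    comm <- .withSeed(seed,
        igraph::cluster_louvain(g, resolution = resolution))
    memb <- igraph::membership(comm)
    sizes <- sort(table(memb), decreasing = TRUE)
    relab <- structure(seq_along(sizes), names = names(sizes))
    labels <- as.integer(relab[as.character(memb)])
    new("ClusterModel", cells = rownames(scores), cluster = labels,
        params = list(k_nn = k_nn, resolution = resolution, seed = seed,
                      method = "snn-louvain"))
}

#' Drop immune-contaminant clusters by marker score
#'
#' Scores each cell as its mean log expression over a hematopoietic marker
#' set; a cluster is dropped when its mean score strictly exceeds the mean
#' plus two standard deviations of the other clusters' mean scores
#' (leave-one-out, so a single contaminated cluster cannot mask itself)
#' and the excess is at least \code{min_diff} log2 units (so with few
#' clusters a tiny between-cluster SD cannot flag noise-level
#' fluctuations). With identical cluster scores nothing is dropped.
#'
#' @param e \code{SingleCellExperiment} or log-expression matrix.
#' @param labels per-cell cluster labels (named, or ordered as columns).
#' @param immune_markers non-empty character vector of marker genes.
#' @param n_sd multiplier on the between-cluster SD.
#' @param min_diff minimum absolute excess (log2 units) of the cluster's
#'   mean marker score over the other clusters' mean.
#' @return character vector of retained cell names.
#' @export
filterImmuneCells <- function(e, labels, immune_markers, n_sd = 2,
                              min_diff = 0.25) {
    if (!length(immune_markers)) stop("immune marker set is empty")
    y <- .getLogExpr(e)
    genes <- intersect(immune_markers, rownames(y))
    if (!length(genes)) stop("no immune markers present in the matrix")
    score <- colMeans(y[genes, , drop = FALSE])
    cl <- as.character(labels)
    ms <- tapply(score, cl, mean)
    drop <- vapply(names(ms), function(cc) {
        others <- ms[names(ms) != cc]
        if (length(others) < 2) return(FALSE)
        ms[[cc]] > mean(others) +
            max(n_sd * stats::sd(others), min_diff)
    }, NA)
    keep_clusters <- names(ms)[!drop]
    colnames(y)[cl %in% keep_clusters]
}

#' Merge clusters into groups by their mean expression profiles
#'
#' Hierarchically clusters (average linkage, correlation distance) the
#' cluster-mean expression profiles over a marker gene set and cuts the
#' dendrogram into \code{n_groups} groups.
#'
#' @param e \code{SingleCellExperiment} or log-expression matrix.
#' @param labels per-cell cluster labels.
#' @param marker_genes genes over which profiles are computed.
#' @param n_groups number of groups to cut.
#' @return list with \code{mapping} (named integer group per cluster) and
#'   \code{dendrogram} (an \code{hclust}).
#' @export
mergeClusters <- function(e, labels, marker_genes, n_groups = 4) {
    y <- .getLogExpr(e)
    genes <- intersect(marker_genes, rownames(y))
    if (!length(genes)) stop("no marker genes present in the matrix")
    cl <- as.character(labels)
    ids <- sort(unique(cl))
    if (length(ids) < n_groups)
        stop("need at least n_groups clusters")
    prof <- vapply(ids, function(cc)
        rowMeans(y[genes, cl == cc, drop = FALSE]), numeric(length(genes)))
    sds <- apply(prof, 2, stats::sd)
    if (any(sds == 0)) {
        d <- stats::dist(t(prof))  # correlation undefined for flat profiles
    } else {
        d <- stats::as.dist(1 - stats::cor(prof))
    }
    hc <- stats::hclust(d, method = "average")
    mapping <- stats::cutree(hc, k = n_groups)
    list(mapping = mapping, dendrogram = hc)
}

#' Co-expression overlap of two genes
#'
#' Counts cells expressing gene A (normalized value > 0), gene B, and both;
#' \code{share} is the fraction of A-expressing cells that also express B
#' (defined 0 when no cell expresses A).
#'
#' @param e \code{SingleCellExperiment} or log-expression matrix.
#' @param geneA,geneB gene names.
#' @param cells cells to consider (default: all).
#' @return list with \code{nA}, \code{nB}, \code{nBoth}, \code{share}.
#' @export
coexpressionOverlap <- function(e, geneA, geneB, cells = NULL) {
    y <- .getLogExpr(e)
    if (!all(c(geneA, geneB) %in% rownames(y)))
        stop("both genes must be present")
    if (!is.null(cells)) y <- y[, cells, drop = FALSE]
    a <- y[geneA, ] > 0
    b <- y[geneB, ] > 0
    nA <- sum(a); nB <- sum(b); nBoth <- sum(a & b)
    list(nA = nA, nB = nB, nBoth = nBoth,
         share = if (nA > 0) nBoth / nA else 0)
}

#' Rank-based inverse normal (Blom) transform
#'
#' Per gene across cells, values are replaced by
#' \code{qnorm((rank - 0.375) / (n + 0.25))} with average ranks for ties, so
#' a tied (constant) gene maps to Z = 0 everywhere and order is preserved.
#'
#' @param e \code{SingleCellExperiment} or log-expression matrix.
#' @param genes genes to transform (default: all).
#' @param cells cells to include (default: all).
#' @return genes x cells matrix of Z scores.
#' @export
rankInverseNormalZ <- function(e, genes = NULL, cells = NULL) {
    y <- .getLogExpr(e)
    if (!is.null(genes)) y <- y[genes, , drop = FALSE]
    if (!is.null(cells)) y <- y[, cells, drop = FALSE]
    n <- ncol(y)
    z <- t(apply(y, 1, function(v)
        stats::qnorm((rank(v, ties.method = "average") - 0.375) /
                     (n + 0.25))))
    dimnames(z) <- dimnames(y)
    z
}
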
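#' Feature genes for trajectory inference
#'
#' Restricted to the supplied cells (the Progen, Prolif and Diff groups),
#' re-runs HVG selection, graph clustering on the HVG principal components
#' and the two-stage marker pipeline, and returns the union of the final
#' marker genes across the clusters found. If only one cluster is found the
#' HVG set itself is returned (a one-vs-rest contrast is undefined).
#'
#' @param e \code{SingleCellExperiment} with \code{logcounts}.
#' @param cells cells to use.
#' @param batch optional per-cell batch labels for the HVG design.
#' @param n_pcs,k_nn,resolution clustering parameters.
#' @param n_perm,alpha,fc_min,n_components marker-pipeline parameters.
#' @param seed integer seed.
#' @return character vector of feature genes.
#' @export
selectTrajectoryFeatures <- function(e, cells, batch = NULL, n_pcs = 50,
                                     k_nn = 20, resolution = 1,
                                     n_perm = 1000, alpha = 0.05,
                                     fc_min = 1.3, n_components = 2,
                                     seed = 1) {
    y <- .getLogExpr(e)[, cells, drop = FALSE]
    hv <- decomposeVariance(y, batch = batch)
    hvgs <- selectHVGs(hv)
    if (length(hvgs) < 2)
        stop("fewer than 2 HVGs among the trajectory cells")
    scores <- pcaScores(y, genes = hvgs,
                        n_pcs = min(n_pcs, length(hvgs)))
    cm <- graphCluster(scores, k_nn = min(k_nn, ncol(y) - 1L),
                       resolution = resolution, seed = seed)
    labels <- clusterLabels(cm)
    if (length(unique(labels)) < 2) return(hvgs)
    tab <- clusterMarkers(y, labels, alpha = alpha, fc_min = fc_min,
                          n_perm = n_perm, n_components = n_components,
                          seed = seed)
    feats <- unique(tab$gene[tab$is_final])
    if (!length(feats)) hvgs else feats
}

#' Fit a principal tree to cells
#'
#' Reduces the feature-gene expression to \code{n_dims} principal
#' components, places \code{n_nodes} k-means centroids, connects them by a
#' minimum spanning tree (Euclidean edge weights) and projects every cell
#' onto the nearest point of the tree's edges.
#'
#' Minor side branches of the minimum spanning tree that attract fewer than
#' \code{min_branch_frac} of the cells are pruned (iteratively, smallest
#' first), so noise spurs do not masquerade as biological bifurcations.
#'
#' @param e \code{SingleCellExperiment} or log-expression matrix.
#' @param features feature genes spanning the trajectory.
#' @param n_dims embedding dimensionality.
#' @param n_nodes number of tree nodes (must be < number of cells).
#' @param seed integer seed for the centroid placement.
#' @param min_branch_frac minimum fraction of cells a leaf branch must carry
#'   to survive pruning.
#' @return a \code{\link{Trajectory-class}} without pseudotime (see
#'   \code{\link{orderCellsByPseudotime}}).
#' @export
fitPrincipalTree <- function(e, features = NULL, n_dims = 2, n_nodes = 20,
                             seed = 1, min_branch_frac = 0.05) {
    y <- .getLogExpr(e)
    if (!is.null(features)) {
        if (!length(features)) stop("empty feature set")
        y <- y[intersect(features, rownames(y)), , drop = FALSE]
    }
    n_cells <- ncol(y)
    if (n_cells < 50) stop("need at least 50 cells")
    if (n_nodes >= n_cells) stop("n_nodes must be smaller than the cell count")
    emb <- pcaScores(y, n_pcs = n_dims)
    km <- .withSeed(seed, stats::kmeans(emb, centers = n_nodes, nstart = 5,
                                        iter.max = 100))
    nodes <- km$centers
    dn <- as.matrix(stats::dist(nodes))
    g <- igraph::graph_from_adjacency_matrix(dn, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    edges <- igraph::as_edgelist(mst, names = FALSE)
    storage.mode(edges) <- "integer"

    pruned <- .pruneSpurs(emb, nodes, edges, min_branch_frac)
    nodes <- pruned$nodes; edges <- pruned$edges
    proj <- .projectToTree(emb, nodes, edges)
    new("Trajectory", cells = colnames(y), embedding = emb, nodes = nodes,
        edges = edges, cellEdge = proj$edge, cellPos = proj$pos,
        projection = proj$coords,
        pseudotime = rep(NA_real_, n_cells),
        branch = rep(NA_integer_, n_cells),
        params = list(n_dims = n_dims, n_nodes = n_nodes, seed = seed))
}

# Iteratively remove leaf branches (leaf up to the nearest junction) that
# attract fewer than min_frac of the projected cells; smallest spur first.
.pruneSpurs <- function(emb, nodes, edges, min_frac) {
    repeat {
        deg <- tabulate(as.vector(edges), nbins = nrow(nodes))
        leaves <- which(deg == 1L)
        if (length(leaves) <= 2L) break
        proj <- .projectToTree(emb, nodes, edges)
        # nodes of each leaf branch: walk from the leaf to the junction
        branch_nodes <- lapply(leaves, function(lf) {
            path <- lf
            cur <- lf
            repeat {
                nb <- setdiff(as.vector(edges[edges[, 1] == cur |
                                              edges[, 2] == cur, ]),
                              path)
                if (length(nb) != 1L || deg[nb] >= 3L) break
                path <- c(path, nb)
                cur <- nb
            }
            path
        })
        # count cells projected onto each leaf branch (its internal edges)
        fracs <- vapply(seq_along(leaves), function(i) {
            bn <- branch_nodes[[i]]
            on_edge <- edges[proj$edge, 1] %in% bn &
                edges[proj$edge, 2] %in% bn
            mean(on_edge)
        }, 0)
        if (min(fracs) >= min_frac) break
        drop_nodes <- branch_nodes[[which.min(fracs)]]
        keep <- setdiff(seq_len(nrow(nodes)), drop_nodes)
        remap <- integer(nrow(nodes)); remap[keep] <- seq_along(keep)
        edges <- edges[!(edges[, 1] %in% drop_nodes |
                         edges[, 2] %in% drop_nodes), , drop = FALSE]
        edges <- cbind(remap[edges[, 1]], remap[edges[, 2]])
        storage.mode(edges) <- "integer"
        nodes <- nodes[keep, , drop = FALSE]
    }
    list(nodes = nodes, edges = edges)
}

# Orthogonal projection of points onto the nearest tree edge (segment).
.projectToTree <- function(points, nodes, edges) {
    n <- nrow(points)
    ne <- nrow(edges)
    best <- rep(Inf, n)
    edge <- integer(n); pos <- numeric(n)
    coords <- matrix(0, n, ncol(points))
    for (k in seq_len(ne)) {
        a <- nodes[edges[k, 1], ]; b <- nodes[edges[k, 2], ]
        ab <- b - a
        len2 <- sum(ab^2)
        t <- if (len2 > 0)
            pmin(1, pmax(0, (sweep(points, 2, a) %*% ab) / len2))
        else matrix(0, n, 1)
        pr <- sweep(t %*% rbind(ab), 2, a, "+")
        d2 <- rowSums((points - pr)^2)
        upd <- d2 < best
        best[upd] <- d2[upd]
        edge[upd] <- k
        pos[upd] <- t[upd]
        coords[upd, ] <- pr[upd, , drop = FALSE]
    }
    list(edge = edge, pos = pos, coords = coords)
}

#' Order cells along the principal tree
#'
#' Resolves the root (a node index, or a marker gene set whose
#' highest-scoring leaf becomes the root), computes each cell's pseudotime
#' as the arc-length geodesic distance from the root to its projection,
#' rescaled to [0, 1], and assigns branch ids: 0 for cells on the root side
#' of the main branch point (the first node of degree >= 3 on paths from
#' the root), and 1, 2, ... for the subtrees past it. With no branch point
#' the topology is "linear" and all cells take branch 0.
#'
#' @param traj a fitted \code{\link{Trajectory-class}}.
#' @param root integer node index, or a character vector of root-state
#'   marker genes (requires \code{e}).
#' @param e expression source used when \code{root} is a marker set.
#' @return the \code{Trajectory} with pseudotime, branch ids and topology.
#' @export
orderCellsByPseudotime <- function(traj, root, e = NULL) {
    stopifnot(is(traj, "Trajectory"))
    edges <- traj@edges
    nn <- nrow(traj@nodes)
    deg <- tabulate(as.vector(edges), nbins = nn)
    leaves <- which(deg == 1L)
    elen <- sqrt(rowSums((traj@nodes[edges[, 1], , drop = FALSE] -
                          traj@nodes[edges[, 2], , drop = FALSE])^2))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::E(g)$weight <- elen

    if (is.character(root)) {
        if (is.null(e)) stop("root marker genes require 'e'")
        y <- .getLogExpr(e)[, traj@cells, drop = FALSE]
        genes <- intersect(root, rownames(y))
        if (!length(genes)) stop("no root marker genes in the matrix")
        score <- colMeans(y[genes, , drop = FALSE])
        # node of each cell = nearer endpoint of its projected edge
        cn <- ifelse(traj@cellPos < 0.5, edges[traj@cellEdge, 1],
                     edges[traj@cellEdge, 2])
        leaf_score <- vapply(leaves, function(lf) {
            reach <- igraph::distances(g, v = lf)[1, cn]
            near <- rank(reach) <= max(10, length(cn) %/% 10)
            mean(score[near])
        }, 0)
        root <- leaves[which.max(leaf_score)]
    }
    root <- as.integer(root)
    if (root < 1 || root > nn) stop("root node out of range")

    nd <- igraph::distances(g, v = root)[1, ]
    u <- edges[traj@cellEdge, 1]; v <- edges[traj@cellEdge, 2]
    el <- elen[traj@cellEdge]
    pt <- pmin(nd[u] + traj@cellPos * el, nd[v] + (1 - traj@cellPos) * el)
    if (max(pt) > 0) pt <- pt / max(pt)

    # main branch point: the degree->=3 node closest to the root
    bnodes <- which(deg >= 3L)
    branch <- rep(0L, length(pt))
    topology <- "linear"
    if (length(bnodes)) {
        bp <- bnodes[which.min(nd[bnodes])]
        g2 <- igraph::delete_vertices(g, bp)
        comp <- rep(NA_integer_, nn)
        comp[-bp] <- igraph::components(g2)$membership
        root_comp <- comp[root]
        # subtree components past the branch point, excluding the root side
        far <- setdiff(unique(comp[!is.na(comp)]), root_comp)
        relab <- structure(seq_along(far), names = far)
        cell_node <- ifelse(nd[u] + traj@cellPos * el <=
                            nd[v] + (1 - traj@cellPos) * el, u, v)
        past <- comp[cell_node] != root_comp & cell_node != bp
        past[is.na(past)] <- FALSE
        branch[past] <- relab[as.character(comp[cell_node[past]])]
        topology <- if (length(far) == 2L) "bifurcating" else "branched"
    }
    traj@root <- root
    traj@pseudotime <- as.numeric(pt)
    traj@branch <- as.integer(branch)
    traj@topology <- topology
    traj
}

#' Rolling-window smoothing along pseudotime
#'
#' Orders the cells of one path by pseudotime and applies a centered rolling
#' mean of the given window to each gene; edge positions use truncated
#' (partial) windows, so the output has one position per cell. The relative
#' profile divides each gene's smoothed values by their own maximum.
#'
#' @param e \code{SingleCellExperiment} or log-expression matrix.
#' @param ordering a \code{Trajectory} (cells on branch 0 plus the given
#'   branch are used) or a character vector of cells already in pseudotime
#'   order.
#' @param genes genes to smooth (default: all).
#' @param window window size in cells (150 for the control condition, 300
#'   for the treated one in the study design).
#' @param branch branch id defining the path when \code{ordering} is a
#'   bifurcating \code{Trajectory}.
#' @return list with \code{smoothed} and \code{relative} (gene x position
#'   matrices) and \code{cells} (the pseudotime order used).
#' @export
smoothAlongPseudotime <- function(e, ordering, genes = NULL, window = 150,
                                  branch = NULL) {
    y <- .getLogExpr(e)
    if (is(ordering, "Trajectory")) {
        pt <- pseudotime(ordering)
        br <- branchIds(ordering)
        keep <- if (is.null(branch)) !is.na(pt)
                else !is.na(pt) & br %in% c(0L, as.integer(branch))
        cells <- names(sort(pt[keep]))
    } else {
        cells <- ordering
    }
    if (window > length(cells))
        stop("window exceeds the number of cells on the path")
    if (!is.null(genes)) y <- y[genes, , drop = FALSE]
    y <- y[, cells, drop = FALSE]
    sm <- t(zoo::rollapply(t(y), width = window, FUN = mean,
                           align = "center", partial = TRUE))
    dimnames(sm) <- dimnames(y)
    mx <- apply(sm, 1, max)
    rel <- sm / ifelse(mx > 0, mx, 1)
    list(smoothed = sm, relative = rel, cells = cells)
}

#' Classify gene programs as early, middle or late
#'
#' Z-scores each gene's smoothed profile, hierarchically clusters the genes
#' (Ward linkage, Euclidean distance) into \code{k} clusters, and labels
#' each cluster from the shape of its (min-max normalized) mean profile.
#' A transient program -- one whose profile falls back below 2/3 of its
#' maximum before the end of the path -- is "middle"; a sustained program
#' is "early" or "late" by the pseudotime quantile at which it first
#' attains 2/3 of its maximum (the activation onset): early (< 1/3),
#' late (> 2/3). Onset and transience rather than peak position are used
#' because a saturating early program holds its maximum anywhere on the
#' plateau, while its upregulation time and persistence are well defined.
#'
#' @param profiles gene x position matrix (\code{smoothed} or
#'   \code{relative} from \code{\link{smoothAlongPseudotime}}).
#' @param k number of gene clusters.
#' @return \code{DataFrame} per gene: \code{gene}, \code{gene_cluster},
#'   \code{label}, \code{peak_quantile}.
#' @export
classifyPatterns <- function(profiles, k = 3) {
    pr <- as.matrix(profiles)
    if (nrow(pr) < k) stop("fewer genes than clusters")
    z <- t(apply(pr, 1, function(v) {
        s <- stats::sd(v)
        if (s > 0) (v - mean(v)) / s else rep(0, length(v))
    }))
    hc <- stats::hclust(stats::dist(z), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
    npos <- ncol(pr)
    onsets <- offsets <- numeric(k)
    for (cc in seq_len(k)) {
        mp <- colMeans(z[cl == cc, , drop = FALSE])
        rng <- max(mp) - min(mp)
        mp <- if (rng > 0) (mp - min(mp)) / rng else rep(1, npos)
        hi <- which(mp >= 2 / 3)
        onsets[cc] <- (hi[1] - 1) / (npos - 1)
        offsets[cc] <- (hi[length(hi)] - 1) / (npos - 1)
    }
    # transient programs (expression returns to baseline before the end of
    # the path) are "middle"; sustained ones are early or late by onset
    labels <- ifelse(offsets < 0.9, "middle",
                     ifelse(onsets < 1 / 3, "early",
                            ifelse(onsets <= 2 / 3, "middle", "late")))
    S4Vectors::DataFrame(gene = rownames(pr), gene_cluster = cl,
                         label = labels[cl], onset_quantile = onsets[cl],
                         offset_quantile = offsets[cl],
                         row.names = rownames(pr))
}

#' Overlap of pattern gene sets between two paths
#'
#' Per pattern label, the Jaccard overlap of the gene sets assigned that
#' label on each path (used to compare the two branches of a bifurcating
#' trajectory).
#'
#' @param assignA,assignB outputs of \code{\link{classifyPatterns}}.
#' @return \code{DataFrame} with per-label counts and Jaccard index.
#' @export
comparePaths <- function(assignA, assignB) {
    labs <- union(unique(assignA$label), unique(assignB$label))
    rows <- lapply(labs, function(l) {
        a <- assignA$gene[assignA$label == l]
        b <- assignB$gene[assignB$label == l]
        un <- union(a, b)
        S4Vectors::DataFrame(label = l, n_pathA = length(a),
                             n_pathB = length(b),
                             n_shared = length(intersect(a, b)),
                             jaccard = if (length(un))
                                 length(intersect(a, b)) / length(un)
                             else 0)
    })
    do.call(rbind, rows)
}
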
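#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ClusterModel: per-cell cluster labels with cluster-to-group structure
#'
#' Holds the result of graph-based clustering of cells together with the
#' parameters used, an optional mapping of clusters into merged groups and
#' the dendrogram (as an \code{hclust} object) from which the merge was cut.
#'
#' @slot cells character vector of cell identifiers.
#' @slot cluster integer cluster id per cell (parallel to \code{cells}).
#' @slot groups named character vector mapping cluster id (name) to group
#'   label; may be empty before \code{\link{mergeClusters}} is applied.
#' @slot dendrogram an \code{hclust} object over clusters, or \code{NULL}.
#' @slot params list of clustering parameters (n_pcs, k_nn, resolution, seed).
#'
#' @aliases ClusterModel-class
#' @exportClass ClusterModel
setClass("ClusterModel",
    representation(
        cells = "character",
        cluster = "integer",
        groups = "character",
        dendrogram = "ANY",
        params = "list"
    ),
    prototype(groups = character(0), dendrogram = NULL, params = list())
)

setValidity("ClusterModel", function(object) {
    msg <- NULL
    if (length(object@cells) != length(object@cluster))
        msg <- c(msg, "'cells' and 'cluster' lengths differ")
    if (anyNA(object@cluster))
        msg <- c(msg, "every retained cell must have exactly one cluster")
    if (length(object@groups)) {
        cl <- unique(as.character(object@cluster))
        if (!all(cl %in% names(object@groups)))
            msg <- c(msg, "group mapping does not cover all clusters")
    }
    if (is.null(msg)) TRUE else msg
})

#' Trajectory: principal-tree embedding with per-cell pseudotime
#'
#' A principal tree fitted in a low-dimensional embedding: tree nodes with
#' coordinates, tree edges, per-cell projections onto tree edges, and (after
#' \code{\link{orderCellsByPseudotime}}) pseudotime on [0, 1] plus branch ids.
#'
#' @slot cells character cell identifiers.
#' @slot embedding numeric matrix, cells x dims.
#' @slot nodes numeric matrix of tree-node coordinates, nodes x dims.
#' @slot edges two-column integer matrix of tree edges (node indices).
#' @slot cellEdge integer index into \code{edges} rows, per cell.
#' @slot cellPos numeric position in [0,1] along the cell's edge.
#' @slot projection numeric matrix of projected cell coordinates.
#' @slot root integer root node index (NA before ordering).
#' @slot pseudotime numeric per-cell pseudotime in [0,1] (NA before ordering).
#' @slot branch integer per-cell branch id (0 = trunk before any split).
#' @slot topology character, "linear" or "bifurcating" (set on ordering).
#' @slot params list of fitting parameters.
#'
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
    representation(
        cells = "character",
        embedding = "matrix",
        nodes = "matrix",
        edges = "matrix",
        cellEdge = "integer",
        cellPos = "numeric",
        projection = "matrix",
        root = "integer",
        pseudotime = "numeric",
        branch = "integer",
        topology = "character",
        params = "list"
    ),
    prototype(root = NA_integer_, topology = NA_character_, params = list())
)

setValidity("Trajectory", function(object) {
    msg <- NULL
    n <- length(object@cells)
    if (nrow(object@embedding) != n || length(object@cellEdge) != n ||
        length(object@cellPos) != n)
        msg <- c(msg, "per-cell slots must match the number of cells")
    if (ncol(object@edges) != 2L)
        msg <- c(msg, "'edges' must have two columns")
    if (nrow(object@edges) > 0 &&
        max(object@edges) > nrow(object@nodes))
        msg <- c(msg, "edge indices exceed node count")
    if (length(object@pseudotime) == n && !all(is.na(object@pseudotime))) {
        pt <- object@pseudotime
        if (any(pt < -1e-9 | pt > 1 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "pseudotime must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' SimTruth: planted ground truth of a simulated droplet dataset
#'
#' @slot barcodes a \code{DataFrame} with one row per barcode: flags
#'   (is_empty, is_lowq, is_immune), cluster and group labels, condition,
#'   batch, true size factor, true pseudotime and branch.
#' @slot genes a \code{DataFrame} with one row per gene: is_mito flag,
#'   marker_of (comma-joined cluster labels), program label and the paths
#'   on which the program is active.
#' @slot params list; the configuration used to simulate.
#'
#' @aliases SimTruth-class
#' @exportClass SimTruth
setClass("SimTruth",
    representation(barcodes = "DataFrame", genes = "DataFrame",
                   params = "list"))

setValidity("SimTruth", function(object) {
    msg <- NULL
    bc <- object@barcodes
    need <- c("barcode", "is_empty", "is_lowq", "is_immune", "cluster",
              "group", "condition", "batch", "size_factor", "pseudotime",
              "branch")
    if (!all(need %in% colnames(bc)))
        msg <- c(msg, paste("barcodes table missing:",
                            paste(setdiff(need, colnames(bc)), collapse = ", ")))
    else {
        emp <- bc$is_empty
        if (any(!is.na(bc$cluster[emp])) || any(!is.na(bc$pseudotime[emp])))
            msg <- c(msg, "empty droplets must have no cluster or pseudotime")
    }
    gn <- object@genes
    if (!all(c("gene_id", "is_mito", "marker_of", "program") %in% colnames(gn)))
        msg <- c(msg, "genes table missing required columns")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ClusterModel-class Cluster labels as a named integer vector.
#' @param object a \code{ClusterModel}.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @export
setMethod("clusterLabels", "ClusterModel", function(object) {
    structure(object@cluster, names = object@cells)
})

#' @describeIn ClusterModel-class Cluster-to-group mapping.
#' @export
setGeneric("groupMapping", function(object) standardGeneric("groupMapping"))

#' @export
setMethod("groupMapping", "ClusterModel", function(object) object@groups)

#' @describeIn ClusterModel-class Group label per cell.
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @export
setMethod("groupLabels", "ClusterModel", function(object) {
    if (!length(object@groups)) stop("no group mapping; run mergeClusters()")
    structure(unname(object@groups[as.character(object@cluster)]),
              names = object@cells)
})

#' @describeIn Trajectory-class Pseudotime as a named numeric vector.
#' @param object a \code{Trajectory}.
#' @export
setGeneric("pseudotime", function(object) standardGeneric("pseudotime"))

#' @export
setMethod("pseudotime", "Trajectory", function(object) {
    structure(object@pseudotime, names = object@cells)
})

#' @describeIn Trajectory-class Branch id per cell (0 = trunk).
#' @export
setGeneric("branchIds", function(object) standardGeneric("branchIds"))

#' @export
setMethod("branchIds", "Trajectory", function(object) {
    structure(object@branch, names = object@cells)
})

#' @describeIn SimTruth-class Per-barcode truth table.
#' @param object a \code{SimTruth}.
#' @export
setGeneric("truthBarcodes", function(object) standardGeneric("truthBarcodes"))

#' @export
setMethod("truthBarcodes", "SimTruth", function(object) object@barcodes)

#' @describeIn SimTruth-class Per-gene truth table.
#' @export
setGeneric("truthGenes", function(object) standardGeneric("truthGenes"))

#' @export
setMethod("truthGenes", "SimTruth", function(object) object@genes)

setMethod("show", "ClusterModel", function(object) {
    cat("ClusterModel:", length(object@cells), "cells,",
        length(unique(object@cluster)), "clusters")
    if (length(object@groups))
        cat(",", length(unique(object@groups)), "groups")
    cat("\n")
    if (length(object@params))
        cat("  params:", paste(names(object@params),
            vapply(object@params, function(x) paste(format(x), collapse = ","),
                   ""), sep = "=", collapse = " "), "\n")
})

setMethod("show", "Trajectory", function(object) {
    deg <- tabulate(object@edges, nbins = nrow(object@nodes))
    cat("Trajectory:", length(object@cells), "cells,",
        nrow(object@nodes), "nodes,", sum(deg == 1L), "leaves\n")
    if (!is.na(object@topology))
        cat("  topology:", object@topology, "| root node:", object@root, "\n")
})

setMethod("show", "SimTruth", function(object) {
    bc <- object@barcodes
    cat("SimTruth:", nrow(bc), "barcodes (",
        sum(bc$is_empty), "empty,", sum(bc$is_immune, na.rm = TRUE),
        "immune ),", nrow(object@genes), "genes\n")
})
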
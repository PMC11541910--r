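#' Build a UMI count SingleCellExperiment
#'
#' Assembles the pipeline's entry object: a \code{SingleCellExperiment}
#' carrying a sparse nonnegative integer gene-by-barcode \code{counts} assay,
#' gene annotations (\code{gene_symbol}, \code{is_mito}) in \code{rowData}
#' and barcode annotations (\code{condition}, \code{batch}) in \code{colData}.
#'
#' @param counts sparse or dense nonnegative integer matrix, genes x barcodes.
#' @param gene_ids unique gene identifiers (rownames).
#' @param gene_symbols gene symbols, same length as \code{gene_ids}.
#' @param barcode_ids unique barcode identifiers (colnames).
#' @param is_mito logical per gene; mitochondrial-encoded flag. Defaults to
#'   symbols starting with \code{"mt-"} (case-insensitive).
#' @param condition,batch per-barcode labels (recycled if length 1).
#' @return a \code{SingleCellExperiment}.
#' @export
makeUMIMatrix <- function(counts, gene_ids, gene_symbols = gene_ids,
                          barcode_ids, is_mito = NULL,
                          condition = "unknown", batch = "b1") {
    counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
    if (any(counts@x < 0) || any(counts@x != round(counts@x)))
        stop("counts must be nonnegative integers")
    if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
    if (anyDuplicated(barcode_ids)) stop("barcode_ids must be unique")
    if (length(gene_ids) != nrow(counts))
        stop(sprintf("length of gene annotations (%d) does not match rows (%d)",
                     length(gene_ids), nrow(counts)))
    if (length(barcode_ids) != ncol(counts))
        stop(sprintf("length of barcodes (%d) does not match columns (%d)",
                     length(barcode_ids), ncol(counts)))
    if (is.null(is_mito))
        is_mito <- grepl("^mt-", gene_symbols, ignore.case = TRUE)
    dimnames(counts) <- list(gene_ids, barcode_ids)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_symbol = gene_symbols,
                                       is_mito = is_mito,
                                       row.names = gene_ids),
        colData = S4Vectors::DataFrame(
            condition = rep_len(condition, ncol(counts)),
            batch = rep_len(batch, ncol(counts)),
            row.names = barcode_ids))
}

.openText <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.findFile <- function(dir, base) {
    for (cand in c(base, paste0(base, ".gz")))
        if (file.exists(file.path(dir, cand))) return(file.path(dir, cand))
    NULL
}

#' Read a 10x-style Matrix Market directory
#'
#' Reads \code{matrix.mtx} plus \code{features.tsv} (or \code{genes.tsv}) and
#' \code{barcodes.tsv} from \code{path} (gzipped variants accepted) into a
#' counts \code{SingleCellExperiment}. The 1-based Matrix Market coordinates
#' are mapped onto the internal row/column order; header dimensions are
#' checked against the annotation files.
#'
#' @param path directory with the three files.
#' @param condition,batch optional per-barcode labels.
#' @return a \code{SingleCellExperiment} (see \code{\link{makeUMIMatrix}}).
#' @export
readMtxDir <- function(path, condition = "unknown", batch = "b1") {
    mtx <- .findFile(path, "matrix.mtx")
    if (is.null(mtx)) stop("no matrix.mtx in ", path)
    feat <- .findFile(path, "features.tsv")
    if (is.null(feat)) feat <- .findFile(path, "genes.tsv")
    if (is.null(feat)) stop("no features.tsv/genes.tsv in ", path)
    bcf <- .findFile(path, "barcodes.tsv")
    if (is.null(bcf)) stop("no barcodes.tsv in ", path)

    if (grepl("\\.gz$", mtx)) {
        tmp <- tempfile(fileext = ".mtx")
        on.exit(unlink(tmp), add = TRUE)
        writeLines(readLines(con <- gzfile(mtx)), tmp); close(con)
        mtx <- tmp
    }
    m <- Matrix::readMM(mtx)
    if (any(m@x != round(m@x)))
        stop("parse error: non-integer values in matrix.mtx")
    ft <- utils::read.table(.openText(feat), sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    bc <- readLines(.openText(bcf))
    if (nrow(ft) != nrow(m))
        stop(sprintf("parse error: features.tsv has %d lines but header says %d rows",
                     nrow(ft), nrow(m)))
    if (length(bc) != ncol(m))
        stop(sprintf("parse error: barcodes.tsv has %d lines but header says %d columns",
                     length(bc), ncol(m)))
    if (anyDuplicated(ft[[1]])) stop("parse error: duplicate gene ids")
    if (anyDuplicated(bc)) stop("parse error: duplicate barcode ids")
    sym <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
    makeUMIMatrix(m, gene_ids = ft[[1]], gene_symbols = sym,
                  barcode_ids = bc, condition = condition, batch = batch)
}

#' Write a 10x-style Matrix Market directory
#'
#' Writes \code{matrix.mtx} (coordinate integer format, 1-based indices),
#' \code{features.tsv} (gene id TAB symbol) and \code{barcodes.tsv}.
#'
#' @param m a counts \code{SingleCellExperiment}.
#' @param path output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
writeMtxDir <- function(m, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    x <- as(.getCounts(m), "TsparseMatrix")
    con <- file(file.path(path, "matrix.mtx"), "wt")
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 sprintf("%d %d %d", nrow(x), ncol(x), length(x@x))), con)
    if (length(x@x))
        writeLines(sprintf("%d %d %d", x@i + 1L, x@j + 1L,
                           as.integer(x@x)), con)
    close(con)
    rd <- SummarizedExperiment::rowData(m)
    sym <- if ("gene_symbol" %in% colnames(rd)) rd$gene_symbol else rownames(m)
    writeLines(paste(rownames(m), sym, sep = "\t"),
               file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is \code{name TAB description TAB member...}; members are
#' de-duplicated. Set names must be unique and sets non-empty.
#'
#' @param path GMT file (gzipped accepted).
#' @return named list of character vectors with a \code{"description"}
#'   attribute per set.
#' @export
readGMT <- function(path) {
    lines <- readLines(.openText(path))
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (ln in lines) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop("GMT parse error: line with fewer than 3 fields: ",
                 substr(ln, 1, 40))
        members <- unique(f[-(1:2)])
        members <- members[nzchar(members)]
        if (!length(members)) stop("GMT parse error: empty set ", f[1])
        sets[[f[1]]] <- structure(members, description = f[2])
    }
    if (anyDuplicated(names(sets))) stop("GMT parse error: duplicate set names")
    sets
}

# Defaults and validation ranges for the pipeline configuration.
.configSpec <- function() {
    list(
        mito_max        = list(default = 0.10,  min = 0, max = 1),
        unexpressed_max = list(default = 0.995, min = 0, max = 1),
        hvg_fdr         = list(default = 0.05,  min = 0, max = 1),
        hvg_bio         = list(default = 0.1,   min = -Inf, max = Inf),
        fc_min          = list(default = 1.3,   min = 0, max = Inf),
        alpha           = list(default = 0.05,  min = 0, max = 1),
        n_perm          = list(default = 1000,  min = 1, max = Inf, int = TRUE),
        window_control  = list(default = 150,   min = 1, max = Inf, int = TRUE),
        window_treated  = list(default = 300,   min = 1, max = Inf, int = TRUE),
        n_pcs           = list(default = 50,    min = 1, max = Inf, int = TRUE),
        k_nn            = list(default = 20,    min = 1, max = Inf, int = TRUE),
        resolution      = list(default = 1,     min = 1e-9, max = Inf),
        kmeans_k        = list(default = 4,     min = 1, max = Inf, int = TRUE),
        n_groups        = list(default = 4,     min = 1, max = Inf, int = TRUE),
        n_components    = list(default = 2,     min = 1, max = Inf, int = TRUE),
        n_tree_nodes    = list(default = 20,    min = 2, max = Inf, int = TRUE),
        k_patterns      = list(default = 3,     min = 2, max = Inf, int = TRUE),
        seed            = list(default = 1,     min = -Inf, max = Inf, int = TRUE)
    )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a named list) of pipeline settings, rejects
#' unknown keys, checks types and ranges, and fills documented defaults:
#' mito_max 0.10, unexpressed_max 0.995, hvg_fdr 0.05, hvg_bio 0.1,
#' fc_min 1.3, alpha 0.05, n_perm 1000, window_control 150,
#' window_treated 300, n_pcs 50, among others.
#'
#' @param path YAML file path, or a named list of overrides, or NULL for all
#'   defaults.
#' @return a named list of validated settings.
#' @export
loadPipelineConfig <- function(path = NULL) {
    spec <- .configSpec()
    user <- if (is.null(path)) list()
            else if (is.list(path)) path
            else {
                y <- yaml::read_yaml(path)
                if (is.null(y)) list() else y
            }
    unknown <- setdiff(names(user), names(spec))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- lapply(names(spec), function(k) {
        s <- spec[[k]]
        v <- if (k %in% names(user)) user[[k]] else s$default
        if (!is.numeric(v) || length(v) != 1 || is.na(v))
            stop(sprintf("config key '%s': expected a single number", k))
        if (isTRUE(s$int) && v != round(v))
            stop(sprintf("config key '%s': expected an integer", k))
        if (v < s$min || v > s$max)
            stop(sprintf("config key '%s': value %g out of range [%g, %g]",
                         k, v, s$min, s$max))
        if (isTRUE(s$int)) as.integer(v) else v
    })
    names(cfg) <- names(spec)
    cfg
}
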
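# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps pipeline stages pure in (input, seed).
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# log-expression accessor: accepts a SingleCellExperiment (logcounts assay)
# or a plain genes x cells matrix.
.getLogExpr <- function(e) {
    if (is(e, "SummarizedExperiment")) {
        if (!"logcounts" %in% SummarizedExperiment::assayNames(e))
            stop("no 'logcounts' assay; run logNormalize() first")
        as.matrix(SummarizedExperiment::assay(e, "logcounts"))
    } else {
        as.matrix(e)
    }
}

.getCounts <- function(m) {
    if (is(m, "SummarizedExperiment")) {
        SummarizedExperiment::assay(m, "counts")
    } else {
        m
    }
}

# md5 of a serialized R object, via a temporary file (used for manifests).
.hashObject <- function(x) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    writeBin(serialize(x, NULL, version = 2), f)
    unname(tools::md5sum(f))
}

.logMsg <- function(..., level = "INFO") {
    message(sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%H:%M:%S"), paste0(...)))
}
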
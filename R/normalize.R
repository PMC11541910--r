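#' Pooled (deconvolution) size factors
#'
#' Estimates per-cell size factors by deconvolution: cells are ordered on a
#' ring by library size, pools of consecutive cells are summed, each pool's
#' counts are compared gene-wise to the average pseudo-cell (the median
#' ratio giving the pool's combined factor), and the resulting linear system
#' in the per-cell factors is solved by least squares. Cells whose solved
#' factor is not positive fall back to their library-size factor with a
#' warning. Factors are rescaled to mean 1.
#'
#' @param m counts \code{SingleCellExperiment} or genes x cells matrix.
#' @param pool_sizes pool sizes; values larger than the cell count are
#'   dropped (the default follows the published deconvolution scheme).
#' @return positive numeric vector of size factors, mean 1, named by cell.
#' @export
pooledSizeFactors <- function(m, pool_sizes = c(21, 41, 61, 81, 101)) {
    counts <- as(.getCounts(m), "CsparseMatrix")
    n <- ncol(counts)
    pool_sizes <- pool_sizes[pool_sizes <= n]
    if (!length(pool_sizes))
        stop("need at least min(pool_sizes) cells")
    lib <- Matrix::colSums(counts)
    if (any(lib == 0)) stop("cells with zero totals; filter first")
    ord <- order(lib)                      # ring ordering by library size
    ref <- Matrix::rowMeans(counts)        # average pseudo-cell
    use <- ref > 0
    dm <- as.matrix(counts[use, ord, drop = FALSE]) / ref[use]
    # ring cumulative sums: pool (start, w) = S[, start+w-1] - S[, start-1]
    S <- t(apply(dm, 1, cumsum))
    tot <- S[, n]

    ridx <- 0L
    ii <- vector("list", length(pool_sizes))
    jj <- vector("list", length(pool_sizes))
    vals <- vector("list", length(pool_sizes))
    for (wi in seq_along(pool_sizes)) {
        w <- pool_sizes[wi]
        hi <- ((seq_len(n) - 1L + w - 1L) %% n) + 1L
        lo <- seq_len(n) - 1L
        pooled <- S[, hi, drop = FALSE] -
            cbind(0, S[, seq_len(n - 1L), drop = FALSE])[, lo + 1L,
                                                         drop = FALSE]
        wrap <- hi < seq_len(n)
        if (any(wrap)) pooled[, wrap] <- pooled[, wrap] + tot
        vals[[wi]] <- apply(pooled, 2, stats::median)
        jj[[wi]] <- as.vector(vapply(seq_len(n), function(start)
            ord[((start - 1L + seq_len(w) - 1L) %% n) + 1L],
            integer(w)))
        ii[[wi]] <- rep(ridx + seq_len(n), each = w)
        ridx <- ridx + n
    }
    # low-weight single-cell equations keep the system full rank
    lam <- 0.1
    cell_ratio <- apply(dm, 2, stats::median)[order(ord)]
    i <- c(unlist(ii), ridx + seq_len(n))
    j <- c(unlist(jj), seq_len(n))
    x <- c(rep(1, sum(vapply(jj, length, 0L))), rep(lam, n))
    A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(ridx + n, n))
    b <- c(unlist(vals), lam * cell_ratio)
    sf <- as.numeric(Matrix::solve(Matrix::crossprod(A),
                                   Matrix::crossprod(A, b)))
    bad <- !is.finite(sf) | sf <= 0
    if (any(bad)) {
        warning(sum(bad), " cell(s) with non-positive deconvolved factors; ",
                "using library-size factors for them")
        sf[bad] <- lib[bad] / mean(lib)
    }
    sf <- sf / mean(sf)
    names(sf) <- colnames(counts)
    sf
}

#' Size-factor normalization and log2 transform
#'
#' Divides each cell's counts by its size factor and applies
#' \code{log2(x + 1)} (pseudocount of 1).
#'
#' @param m counts \code{SingleCellExperiment} (or matrix).
#' @param size_factors positive per-cell factors; estimated with
#'   \code{\link{pooledSizeFactors}} when missing.
#' @return the \code{SingleCellExperiment} with a \code{logcounts} assay and
#'   \code{sizeFactors()} set (or a plain matrix for matrix input).
#' @export
logNormalize <- function(m, size_factors = NULL) {
    counts <- .getCounts(m)
    if (is.null(size_factors)) size_factors <- pooledSizeFactors(m)
    if (any(size_factors <= 0)) stop("size factors must be positive")
    if (length(size_factors) != ncol(counts))
        stop("one size factor per cell required")
    norm <- sweep(as.matrix(counts), 2, size_factors, "/")
    logc <- log2(norm + 1)
    if (is(m, "SingleCellExperiment")) {
        SummarizedExperiment::assay(m, "logcounts") <- logc
        SingleCellExperiment::sizeFactors(m) <- size_factors
        m
    } else {
        logc
    }
}

#' Mean-variance decomposition for highly variable genes
#'
#' Decomposes each gene's variance of log2 expression into a technical part
#' (a LOESS mean-variance trend fitted to all genes) and a biological part
#' (total minus trend). Batch structure is removed first by residualizing on
#' the batch design matrix. Significance of excess variance comes from a
#' one-sided scaled chi-square test of the total against the trend value at
#' the gene's mean, with the residual degrees of freedom; FDR is
#' Benjamini-Hochberg.
#'
#' @param e \code{SingleCellExperiment} with \code{logcounts} (or matrix of
#'   log expression).
#' @param batch per-cell batch labels (a single batch reduces the design to
#'   an intercept), or \code{NULL}.
#' @param span LOESS span for the trend.
#' @param fdr_max,bio_min thresholds stored with the table and used by
#'   \code{\link{selectHVGs}}.
#' @return \code{DataFrame} with \code{mean}, \code{total}, \code{tech},
#'   \code{bio}, \code{p_value}, \code{fdr}, \code{is_hvg}.
#' @export
decomposeVariance <- function(e, batch = NULL, span = 0.3,
                              fdr_max = 0.05, bio_min = 0.1) {
    y <- .getLogExpr(e)
    n <- ncol(y)
    if (is.null(batch)) batch <- rep("b1", n)
    batch <- as.factor(batch)
    if (any(table(batch) < 2)) stop("need at least 2 cells per batch")
    design <- if (nlevels(batch) > 1) stats::model.matrix(~batch)
              else matrix(1, n, 1)
    qrd <- qr(design)
    df_resid <- n - qrd$rank
    res <- t(qr.resid(qrd, t(y)))
    gmean <- unname(rowMeans(y))
    total <- unname(rowSums(res^2)) / df_resid

    fit_ok <- total > 0
    trend_df <- data.frame(m = gmean[fit_ok], lv = log(total[fit_ok]))
    lo <- stats::loess(lv ~ m, data = trend_df, span = span,
                       degree = 2, family = "symmetric",
                       control = stats::loess.control(surface = "direct"))
    tech <- unname(exp(stats::predict(lo, newdata = data.frame(m = gmean))))
    tech <- pmax(tech, 1e-12)
    bio <- total - tech
    p <- stats::pchisq(df_resid * total / tech, df = df_resid,
                       lower.tail = FALSE)
    fdr <- stats::p.adjust(p, method = "BH")
    out <- S4Vectors::DataFrame(mean = gmean, total = total, tech = tech,
                                bio = bio, p_value = p, fdr = fdr,
                                is_hvg = fdr <= fdr_max & bio > bio_min,
                                row.names = rownames(y))
    S4Vectors::metadata(out) <- list(df_resid = df_resid, span = span,
                                     fdr_max = fdr_max, bio_min = bio_min)
    out
}

#' Select highly variable genes
#'
#' Exactly the genes with \code{fdr <= fdr_max} and biological variance
#' strictly greater than \code{bio_min}.
#'
#' @param tab output of \code{\link{decomposeVariance}}.
#' @param fdr_max FDR cutoff (inclusive).
#' @param bio_min biological-variance cutoff (exclusive).
#' @return character vector of gene names.
#' @export
selectHVGs <- function(tab, fdr_max = 0.05, bio_min = 0.1) {
    rownames(tab)[tab$fdr <= fdr_max & tab$bio > bio_min]
}
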
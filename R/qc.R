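#' Per-barcode quality-control metrics
#'
#' Computes, for every barcode: total UMI count, number of genes detected,
#' fraction of UMIs on mitochondrial-encoded genes and fraction of genes not
#' expressed. For an all-zero barcode the mitochondrial fraction 0/0 is
#' defined as 0 and the unexpressed fraction is 1.
#'
#' @param m a counts \code{SingleCellExperiment} with an \code{is_mito}
#'   column in \code{rowData}, or a genes x barcodes matrix plus
#'   \code{is_mito}.
#' @param is_mito logical per gene (taken from \code{rowData} when missing).
#' @return \code{DataFrame} with columns \code{total_umi},
#'   \code{n_genes_detected}, \code{frac_mito}, \code{frac_unexpressed}.
#' @export
computeCellQC <- function(m, is_mito = NULL) {
    counts <- .getCounts(m)
    if (is.null(is_mito)) {
        if (!is(m, "SummarizedExperiment") ||
            !"is_mito" %in% colnames(SummarizedExperiment::rowData(m)))
            stop("is_mito flags are required")
        is_mito <- SummarizedExperiment::rowData(m)$is_mito
    }
    total <- unname(Matrix::colSums(counts))
    mito <- unname(Matrix::colSums(counts[is_mito, , drop = FALSE]))
    ndet <- unname(Matrix::colSums(counts > 0))
    frac_mito <- ifelse(total > 0, mito / total, 0)
    S4Vectors::DataFrame(
        total_umi = total,
        n_genes_detected = ndet,
        frac_mito = frac_mito,
        frac_unexpressed = (nrow(counts) - ndet) / nrow(counts),
        row.names = colnames(counts))
}

#' Knee-point threshold on the barcode rank plot
#'
#' Separates cell-containing from empty droplets on the log10(rank) vs
#' log10(total UMI) curve. After isotonic smoothing, the upper knee is the
#' point of maximum perpendicular distance above the chord joining the curve
#' endpoints (the bend where the cell plateau ends); the lower shoulder is
#' then the point of maximum distance below the chord of the sub-curve from
#' the knee to the last barcode (the bend where the ambient plateau begins).
#' The returned threshold is the geometric mean of the totals at the two bends,
#' i.e. it falls mid-cliff, strictly between the modal totals of the two
#' regimes. Barcodes with totals greater than or equal to the threshold are
#' the ones to keep; zero-total barcodes never influence the result.
#'
#' @param totals numeric vector of per-barcode total UMI counts.
#' @return the threshold (a count).
#' @export
detectKneePoint <- function(totals) {
    tot <- totals[totals > 0]
    if (length(tot) < 100)
        stop("need at least 100 barcodes with positive totals")
    tot <- sort(tot, decreasing = TRUE)
    if (max(tot) == min(tot))
        stop(paste("no knee point: all barcode totals are equal;",
                   "supply a manual threshold"))
    x <- log10(seq_along(tot))
    y <- log10(tot)
    # isotonic (non-increasing) smoothing of the rank curve
    y <- -stats::isoreg(x, -y)$yf
    n <- length(x)
    # signed perpendicular distance to the chord over index range [i, j];
    # negative = above the chord for this decreasing curve
    chord_dist <- function(i, j) {
        dx <- x[j] - x[i]; dy <- y[j] - y[i]
        idx <- i:j
        (dy * (x[idx] - x[i]) - dx * (y[idx] - y[i])) / sqrt(dx^2 + dy^2)
    }
    d1 <- chord_dist(1L, n)
    knee <- which.min(d1)                      # end of the cell plateau
    d2 <- chord_dist(knee, n)
    shoulder <- knee + which.max(d2) - 1L      # start of the ambient plateau
    if (-d1[knee] < 0.02 || d2[shoulder - knee + 1L] < 0.02)
        stop(paste("no knee point: barcode rank curve has no two-regime",
                   "structure; supply a manual threshold"))
    10^((y[knee] + y[shoulder]) / 2)
}

#' Remove low-quality cells on fixed QC thresholds
#'
#' A barcode is removed iff its mitochondrial UMI fraction exceeds
#' \code{mito_max} or its fraction of unexpressed genes exceeds
#' \code{unexpressed_max}; both comparisons are strict, so a cell sitting
#' exactly on a threshold is kept.
#'
#' @param qc output of \code{\link{computeCellQC}}.
#' @param mito_max maximum tolerated mitochondrial UMI fraction.
#' @param unexpressed_max maximum tolerated fraction of unexpressed genes.
#' @return character vector of kept barcodes.
#' @export
filterCells <- function(qc, mito_max = 0.10, unexpressed_max = 0.995) {
    keep <- !(qc$frac_mito > mito_max | qc$frac_unexpressed > unexpressed_max)
    rownames(qc)[keep]
}

#' Flag multivariate QC outliers
#'
#' Automates the visual inspection of barcodes in the 2-D principal
#' component space of standardized QC metrics: barcodes whose robust
#' (MCD-based) Mahalanobis distance in that plane exceeds the chi-square(2)
#' 0.99 quantile are flagged. Flags are advisory; nothing is removed.
#'
#' @param qc output of \code{\link{computeCellQC}}.
#' @param quantile chi-square quantile defining an outlier.
#' @return named logical vector of flags.
#' @export
flagQCOutliers <- function(qc, quantile = 0.99) {
    n <- nrow(qc)
    flags <- structure(rep(FALSE, n), names = rownames(qc))
    if (n < 10) {
        warning("fewer than 10 barcodes; no outlier flags assigned")
        return(flags)
    }
    met <- cbind(log1p(qc$total_umi), log1p(qc$n_genes_detected),
                 qc$frac_mito, qc$frac_unexpressed)
    sds <- apply(met, 2, stats::sd)
    met <- scale(met[, sds > 0, drop = FALSE])
    if (ncol(met) < 2) return(flags)
    pc <- stats::prcomp(met, rank. = 2)$x
    rob <- tryCatch(MASS::cov.rob(pc, method = "mcd"),
                    error = function(e) list(center = colMeans(pc),
                                             cov = stats::cov(pc)))
    d2 <- stats::mahalanobis(pc, rob$center, rob$cov)
    flags[] <- d2 > stats::qchisq(quantile, df = 2)
    flags
}
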
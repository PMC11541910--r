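#' Wilcoxon rank-sum screen of one cluster against the rest
#'
#' Per gene, a two-sided rank-sum test of the cluster's cells against all
#' other cells, and a fold change on the de-logged scale. Group sizes of at
#' most 8 in both groups use exact enumeration of all rank assignments
#' (correct under ties); larger groups use the normal approximation with
#' tie correction. The fold change is
#' \code{(mean(2^x - 1) in cluster + 0.01) / (mean(2^x - 1) in rest + 0.01)}
#' on normalized log2 values \code{x}.
#'
#' @param e \code{SingleCellExperiment} with \code{logcounts}, or matrix.
#' @param labels per-cell cluster labels.
#' @param cluster the cluster to contrast.
#' @return \code{DataFrame} with \code{p_value} and \code{fold_change} per
#'   gene.
#' @export
wilcoxonOneVsRest <- function(e, labels, cluster) {
    y <- .getLogExpr(e)
    cl <- as.character(labels)
    inA <- cl == as.character(cluster)
    if (!any(inA)) stop("cluster '", cluster, "' absent from labels")
    n1 <- sum(inA); n2 <- sum(!inA)
    if (n1 < 3 || n2 < 3)
        stop("need at least 3 cells in the cluster and in the rest")
    exact <- n1 <= 8 && n2 <= 8

    if (exact) {
        p <- apply(y, 1, function(v) .wilcoxExactP(v[inA], v[!inA]))
    } else {
        pre <- .rankPrecompute(y)
        p <- .wilcoxNormalP(pre, inA)
    }

    expm <- 2^y - 1
    mA <- rowMeans(expm[, inA, drop = FALSE])
    mB <- rowMeans(expm[, !inA, drop = FALSE])
    S4Vectors::DataFrame(p_value = unname(p),
                         fold_change = unname((mA + 0.01) / (mB + 0.01)),
                         row.names = rownames(y))
}

# Per-gene ranks and tie corrections, computed once and reused across the
# one-vs-rest contrasts of every cluster.
.rankPrecompute <- function(y) {
    n <- ncol(y)
    ranks <- t(apply(y, 1, rank))
    tiecor <- apply(y, 1, function(v) {
        tt <- rle(sort(v))$lengths
        sum(tt^3 - tt)
    }) / (n * (n - 1))
    list(ranks = ranks, tiecor = tiecor, n = n)
}

# Normal approximation with tie correction on precomputed ranks.
.wilcoxNormalP <- function(pre, inA) {
    n1 <- sum(inA); nn <- pre$n
    W <- rowSums(pre$ranks[, inA, drop = FALSE])
    mu <- n1 * (nn + 1) / 2
    sig2 <- n1 * (nn - n1) / 12 * ((nn + 1) - pre$tiecor)
    z <- ifelse(sig2 > 0, (W - mu) / sqrt(sig2), 0)
    pmin(1, 2 * stats::pnorm(-abs(z)))
}

# Exact two-sided rank-sum p by exhaustive enumeration of all C(n, n1)
# assignments of the pooled ranks (ties handled through average ranks).
.wilcoxExactP <- function(a, b) {
    n1 <- length(a)
    r <- rank(c(a, b))
    w_obs <- sum(r[seq_len(n1)])
    mu <- n1 * (length(r) + 1) / 2
    combs <- utils::combn(length(r), n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone, capped at 1); a thin wrapper around
#' \code{p.adjust(method = "BH")} so the procedure used throughout the
#' pipeline is explicit and testable.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values.
#' @export
adjustBH <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Initial marker table from Wilcoxon screens
#'
#' Builds the (gene, cluster) marker table from per-cluster screen results;
#' \code{is_initial} requires adjusted p strictly below \code{alpha} and
#' fold change strictly above \code{fc_min}. Adjustment is BH across genes
#' within each cluster.
#'
#' @param screens named list (by cluster) of \code{\link{wilcoxonOneVsRest}}
#'   results.
#' @param alpha significance cutoff on the adjusted p-value.
#' @param fc_min fold-change cutoff.
#' @return \code{DataFrame} with one row per (gene, cluster).
#' @export
initialMarkers <- function(screens, alpha = 0.05, fc_min = 1.3) {
    rows <- lapply(names(screens), function(cc) {
        s <- screens[[cc]]
        padj <- adjustBH(s$p_value)
        S4Vectors::DataFrame(gene = rownames(s), cluster = cc,
                             p_wilcoxon = s$p_value, p_wilcoxon_adj = padj,
                             fold_change = s$fold_change,
                             is_initial = padj < alpha &
                                 s$fold_change > fc_min)
    })
    tab <- do.call(rbind, rows)
    tab$vip <- NA_real_
    tab$p_vip <- NA_real_
    tab$p_vip_adj <- NA_real_
    tab$is_final <- FALSE
    rownames(tab) <- NULL
    tab
}

# Core PLS1 (NIPALS) with VIP, vectorized over many response columns.
# Xs: cells x genes, already centered/scaled. Ymat: cells x B of centered
# responses. Deflation-free recursion using the orthogonality of scores.
# Returns list(vip = genes x B, ss = ncomp x B).
.plsVipBatch <- function(Xs, Ymat, ncomp) {
    p <- ncol(Xs)
    B <- ncol(Ymat)
    Ws <- vector("list", ncomp)   # normalized weights, p x B
    Ts <- vector("list", ncomp)   # scores, n x B
    Ps <- vector("list", ncomp)   # loadings, p x B
    tts <- matrix(0, ncomp, B)
    ss <- matrix(0, ncomp, B)
    R <- Ymat
    for (a in seq_len(ncomp)) {
        W <- crossprod(Xs, R)                     # X_{a-1}' r = X' r
        wn <- sqrt(colSums(W^2))
        wn[wn < 1e-12] <- 1
        W <- sweep(W, 2, wn, "/")
        Tt <- Xs %*% W
        if (a > 1) {
            for (c_ in seq_len(a - 1)) {
                # t_a = X w_a - sum_c t_c (p_c' w_a)
                Tt <- Tt - Ts[[c_]] *
                    rep(colSums(Ps[[c_]] * W), each = nrow(Tt))
            }
        }
        tt <- colSums(Tt^2)
        tt[tt < 1e-12] <- 1e-12
        P <- sweep(crossprod(Xs, Tt), 2, tt, "/")
        if (a > 1) {
            for (c_ in seq_len(a - 1)) {
                P <- P - Ps[[c_]] *
                    rep(colSums(Ts[[c_]] * Tt) / tt, each = p)
            }
        }
        bcoef <- colSums(R * Tt) / tt
        ss[a, ] <- bcoef^2 * tt                   # y-variance explained
        R <- R - sweep(Tt, 2, bcoef, "*")
        Ws[[a]] <- W; Ts[[a]] <- Tt; Ps[[a]] <- P; tts[a, ] <- tt
    }
    sstot <- colSums(ss)
    sstot[sstot < 1e-300] <- 1e-300
    num <- matrix(0, p, B)
    for (a in seq_len(ncomp))
        num <- num + Ws[[a]]^2 * rep(ss[a, ], each = p)
    vip <- sqrt(p * sweep(num, 2, sstot, "/"))
    list(vip = vip, ss = ss)
}

#' PLS-DA fit with variable importance in projection (VIP)
#'
#' Fits a one-response partial least squares discriminant model (NIPALS) of
#' the one-vs-rest class indicator on column-standardized expression and
#' returns each gene's VIP:
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}}
#' where \eqn{p} is the gene count, \eqn{w_a} the X-weights and \eqn{SS_a}
#' the response variance explained by component \eqn{a}. By construction
#' the VIPs satisfy \eqn{\sum_j VIP_j^2 = p}.
#'
#' @param X cells x genes matrix (initial marker genes).
#' @param y binary (or two-level) class vector, length \code{nrow(X)}.
#' @param n_components number of PLS components (reduced with a warning if
#'   the data cannot support it).
#' @return named numeric VIP per gene; constant genes are dropped from the
#'   fit with a warning and return \code{NA}.
#' @export
fitPlsdaVip <- function(X, y, n_components = 2) {
    X <- as.matrix(X)
    if (ncol(X) < 2) stop("need at least 2 genes")
    yy <- as.numeric(as.factor(y))
    if (length(unique(yy)) != 2) stop("y must have exactly two classes")
    sds <- apply(X, 2, stats::sd)
    keep <- sds > 0
    if (!all(keep))
        warning(sum(!keep), " constant gene column(s) dropped before fit")
    Xs <- scale(X[, keep, drop = FALSE])
    ncomp <- min(n_components, ncol(Xs), nrow(Xs) - 1L)
    if (ncomp < n_components)
        warning("n_components reduced to ", ncomp)
    yc <- matrix(yy - mean(yy), ncol = 1)
    fit <- .plsVipBatch(Xs, yc, ncomp)
    vip <- rep(NA_real_, ncol(X))
    vip[keep] <- fit$vip[, 1]
    names(vip) <- colnames(X)
    vip
}

#' Permutation p-values for VIP scores via a Gaussian KDE null
#'
#' Estimates the empirical null of VIP scores by refitting the PLS-DA model
#' under \code{n_perm} random permutations of the class labels over cells,
#' pooling the permuted VIPs of all genes, and placing a Gaussian kernel
#' density (Silverman bandwidth) over the pool. Each observed VIP's p-value
#' is the exact upper-tail mass of that kernel mixture,
#' \eqn{p_j = N^{-1} \sum_i [1 - \Phi((v_j - u_i)/h)]}, so p lies strictly
#' in (0, 1).
#'
#' @param X,y as in \code{\link{fitPlsdaVip}}.
#' @param observed_vips VIPs from the unpermuted fit.
#' @param n_perm number of permutations (warning below 100).
#' @param seed integer seed (mandatory in pipeline use).
#' @param n_components PLS components, matching the observed fit.
#' @return numeric p-values, one per observed VIP (NA propagates).
#' @export
vipPermutationPvalues <- function(X, y, observed_vips, n_perm = 1000,
                                  seed = 1, n_components = 2) {
    if (n_perm < 100)
        warning("fewer than 100 permutations gives a coarse null")
    X <- as.matrix(X)
    yy <- as.numeric(as.factor(y))
    sds <- apply(X, 2, stats::sd)
    keep <- sds > 0
    Xs <- scale(X[, keep, drop = FALSE])
    ncomp <- min(n_components, ncol(Xs), nrow(Xs) - 1L)
    Ymat <- .withSeed(seed, {
        m <- replicate(n_perm, sample(yy))
        m
    })
    Ymat <- sweep(Ymat, 2, colMeans(Ymat), "-")
    null_pool <- as.vector(.plsVipBatch(Xs, Ymat, ncomp)$vip)
    h <- stats::bw.nrd0(null_pool)
    vapply(observed_vips, function(v) {
        if (is.na(v)) return(NA_real_)
        mean(stats::pnorm((v - null_pool) / h, lower.tail = FALSE))
    }, 0)
}

#' Final marker calls
#'
#' A (gene, cluster) pair is a final marker iff it passed the initial
#' Wilcoxon screen and its VIP permutation p-value is strictly below
#' \code{alpha}. The VIP p-value is already calibrated against the
#' empirical (permutation KDE) null, so by default no further
#' multiple-testing adjustment is applied; set \code{adjust = "BH"} to gate
#' on the BH-adjusted column instead.
#'
#' @param tab marker table with VIP p-values filled
#'   (\code{\link{clusterMarkers}}).
#' @param alpha cutoff on the VIP p-value.
#' @param adjust \code{"none"} (gate on \code{p_vip}) or \code{"BH"}
#'   (gate on \code{p_vip_adj}).
#' @return the table with \code{is_final} set.
#' @export
finalMarkers <- function(tab, alpha = 0.05, adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    p <- if (adjust == "BH") tab$p_vip_adj else tab$p_vip
    tab$is_final <- tab$is_initial & !is.na(p) & p < alpha
    tab
}

#' Two-stage marker identification for all clusters
#'
#' Runs the complete marker pipeline: a Wilcoxon one-vs-rest screen per
#' cluster (BH-adjusted p < \code{alpha}, fold change > \code{fc_min}
#' defining initial markers), then, per cluster, a one-vs-rest PLS-DA fit
#' on the union of all clusters' initial marker genes. The VIP scores of
#' the fit are tested against the empirical null obtained by refitting
#' under \code{n_perm} label permutations and pooling the permuted VIPs
#' into a Gaussian KDE; the resulting null-calibrated p-value is the
#' quantity gated at \code{alpha} for the final-marker call (a BH-adjusted
#' column is also reported). Fitting each cluster's model on the union
#' matters: VIP measures a gene's contribution relative to all candidate
#' markers, so the model must see the other clusters' markers as the
#' reference background.
#'
#' @param e \code{SingleCellExperiment} with \code{logcounts}, or matrix.
#' @param labels per-cell cluster labels.
#' @param alpha significance cutoff used at both stages.
#' @param fc_min fold-change cutoff for the screen.
#' @param n_perm label permutations for the VIP null.
#' @param n_components PLS components.
#' @param seed integer seed.
#' @param vip_adjust gate final calls on the KDE p (\code{"none"}, default)
#'   or its BH adjustment (\code{"BH"}).
#' @return marker \code{DataFrame}: one row per (gene, cluster) with
#'   Wilcoxon statistics, VIP, permutation p-values and the
#'   \code{is_initial}/\code{is_final} flags. VIP columns are filled for
#'   each cluster's initial markers.
#' @export
clusterMarkers <- function(e, labels, alpha = 0.05, fc_min = 1.3,
                           n_perm = 1000, n_components = 2, seed = 1,
                           vip_adjust = c("none", "BH")) {
    vip_adjust <- match.arg(vip_adjust)
    y <- .getLogExpr(e)
    cl <- as.character(labels)
    ids <- sort(unique(cl))
    # ranks and tie corrections are shared across the one-vs-rest contrasts
    pre <- if (ncol(y) > 16) .rankPrecompute(y) else NULL
    expm <- 2^y - 1
    screens <- lapply(ids, function(cc) {
        inA <- cl == cc
        n1 <- sum(inA)
        if (is.null(pre) || (n1 <= 8 && ncol(y) - n1 <= 8))
            return(wilcoxonOneVsRest(y, cl, cc))
        if (n1 < 3 || ncol(y) - n1 < 3)
            stop("need at least 3 cells in the cluster and in the rest")
        mA <- rowMeans(expm[, inA, drop = FALSE])
        mB <- rowMeans(expm[, !inA, drop = FALSE])
        S4Vectors::DataFrame(p_value = unname(.wilcoxNormalP(pre, inA)),
                             fold_change = unname((mA + 0.01) / (mB + 0.01)),
                             row.names = rownames(y))
    })
    names(screens) <- ids
    tab <- initialMarkers(screens, alpha = alpha, fc_min = fc_min)
    union_genes <- unique(tab$gene[tab$is_initial])
    if (length(union_genes) >= 2) {
        X <- t(y[union_genes, , drop = FALSE])
        for (ci in seq_along(ids)) {
            cc <- ids[ci]
            sel <- tab$cluster == cc & tab$is_initial
            if (!sum(sel)) next
            yy <- as.integer(cl == cc)
            vips <- suppressWarnings(fitPlsdaVip(X, yy, n_components))
            pv <- vipPermutationPvalues(X, yy, vips, n_perm = n_perm,
                                        seed = seed + ci,
                                        n_components = n_components)
            m <- match(tab$gene[sel], union_genes)
            tab$vip[sel] <- vips[m]
            tab$p_vip[sel] <- pv[m]
            tab$p_vip_adj[sel] <- adjustBH(pv)[m]
        }
    }
    finalMarkers(tab, alpha = alpha, adjust = vip_adjust)
}
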
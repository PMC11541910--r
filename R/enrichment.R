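#' EASE-score enrichment probability
#'
#' The conservative variant of the one-tailed Fisher/hypergeometric test
#' used by DAVID: the overlap count is penalized by one before taking the
#' hypergeometric upper tail, \eqn{p = P[X \ge k - 1]} for
#' \eqn{X \sim Hypergeom(N, K, n)}; an overlap of 0 or 1 therefore gives
#' p = 1.
#'
#' @param k overlap between the query list and the gene set.
#' @param n query list size.
#' @param K gene-set size within the universe.
#' @param N universe size.
#' @return the EASE probability in (0, 1].
#' @export
easeTest <- function(k, n, K, N) {
    if (k > min(n, K) || n > N || K > N || min(k, n, K, N) < 0)
        stop(sprintf("inconsistent counts: k=%d n=%d K=%d N=%d", k, n, K, N))
    if (k <= 1) return(1)
    stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of gene lists against a gene-set collection
#'
#' Tests each (list, set) pair with the EASE score over the supplied
#' universe. Query genes outside the universe are dropped with a warning;
#' only pairs with a positive overlap are reported. No multiple-testing
#' correction is applied by default, matching a plain p < alpha usage;
#' set \code{adjust = TRUE} for BH.
#'
#' @param lists named list of character gene vectors (e.g. the P1-P4
#'   pattern gene sets).
#' @param collection named list of gene sets (see \code{\link{readGMT}}).
#' @param universe character vector of measured genes.
#' @param alpha significance cutoff.
#' @param adjust apply BH across each list's tests.
#' @return \code{DataFrame}, one row per (list, set) with overlap k, list
#'   size n, set size K, universe N, \code{ease_p}, \code{neg_log10_p} and
#'   a \code{significant} flag, sorted by decreasing \code{neg_log10_p}.
#' @export
enrichGeneLists <- function(lists, collection, universe, alpha = 0.05,
                            adjust = FALSE) {
    N <- length(unique(universe))
    rows <- list()
    for (ln in names(lists)) {
        q <- unique(lists[[ln]])
        out <- setdiff(q, universe)
        if (length(out)) {
            warning(length(out), " gene(s) of list '", ln,
                    "' not in universe; dropped")
            q <- intersect(q, universe)
        }
        ps <- numeric(0); keep <- character(0)
        res <- list()
        for (sn in names(collection)) {
            set <- intersect(unique(collection[[sn]]), universe)
            k <- length(intersect(q, set))
            if (k == 0) next
            p <- easeTest(k, length(q), length(set), N)
            res[[sn]] <- S4Vectors::DataFrame(
                list = ln, set = sn, k = k, n = length(q),
                K = length(set), N = N, ease_p = p,
                neg_log10_p = -log10(p))
        }
        if (!length(res)) next
        tab <- do.call(rbind, res)
        pe <- if (adjust) adjustBH(tab$ease_p) else tab$ease_p
        tab$significant <- pe < alpha
        rows[[ln]] <- tab
    }
    if (!length(rows))
        return(S4Vectors::DataFrame(list = character(0), set = character(0),
                                    k = integer(0), n = integer(0),
                                    K = integer(0), N = integer(0),
                                    ease_p = numeric(0),
                                    neg_log10_p = numeric(0),
                                    significant = logical(0)))
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab[order(-tab$neg_log10_p), ]
}

#' Filter genes by membership in an annotation set
#'
#' Intersection preserving the input order (e.g. restricting candidate
#' markers to plasma-membrane annotated genes).
#'
#' @param genes character vector.
#' @param set annotation gene set.
#' @return the genes also present in \code{set}, input order preserved.
#' @export
filterByMembership <- function(genes, set) {
    genes[genes %in% set]
}
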
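# Shared fixture builders; everything is generated in code at test time.

# small but structurally complete simulation configuration
smallSimConfig <- function(seed = 1, n_true_cells = 400,
                           n_empty_droplets = 800, n_genes = 500, ...) {
    simConfig(n_true_cells = n_true_cells,
              n_empty_droplets = n_empty_droplets, n_genes = n_genes,
              seed = seed, ...)
}

# two-group configuration without trajectory structure (hard markers only);
# used where exact marker effect sizes must hold cell-wise
flatSimConfig <- function(seed = 1, n_true_cells = 1000, lowq_frac = 0,
                          marker_effect = 1.5, ...) {
    simConfig(n_true_cells = n_true_cells, n_empty_droplets = 0,
              n_genes = 400,
              group_spec = data.frame(group = c("GrpA", "GrpB"),
                                      n_clusters = c(1L, 1L),
                                      frac = c(0.5, 0.5)),
              lowq_frac = lowq_frac, batch_log_sd = 0,
              marker_effect = marker_effect,
              group_marker_effect = marker_effect,
              conditions = c(control = "linear"),
              seed = seed, ...)
}

# dense log-expression matrix with named dims
randomExpr <- function(genes = 50, cells = 100, seed = 1) {
    set.seed(seed)
    y <- matrix(abs(rnorm(genes * cells)), genes, cells,
                dimnames = list(paste0("g", seq_len(genes)),
                                paste0("c", seq_len(cells))))
    y
}

# well-separated Gaussian blobs in d dims; returns list(x, labels)
makeBlobs <- function(k = 2, n_per = 50, d = 5, sep = 10, seed = 1) {
    set.seed(seed)
    centers <- matrix(rnorm(k * d), k, d) * sep
    x <- do.call(rbind, lapply(seq_len(k), function(i)
        sweep(matrix(rnorm(n_per * d), n_per, d), 2, centers[i, ], "+")))
    rownames(x) <- paste0("c", seq_len(k * n_per))
    list(x = x, labels = rep(seq_len(k), each = n_per))
}

# adjusted Rand index (via mclust when available)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# independent exhaustive two-sided rank-sum oracle: enumerate every
# assignment of n1 positions out of the pooled values
wilcoxEnumOracle <- function(a, b) {
    vals <- c(a, b)
    n1 <- length(a)
    idx <- utils::combn(length(vals), n1)
    r <- rank(vals)
    mu <- n1 * (length(vals) + 1) / 2
    w_obs <- sum(r[seq_len(n1)])
    ws <- apply(idx, 2, function(s) sum(r[s]))
    mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# textbook NIPALS PLS1 with explicit deflation + direct VIP formula;
# the independent oracle for the optimized implementation
naiveVip <- function(X, y, ncomp = 2) {
    Xs <- scale(X)
    yv <- as.numeric(y) - mean(as.numeric(y))
    p <- ncol(Xs)
    W <- matrix(0, p, ncomp); ss <- numeric(ncomp)
    for (a in seq_len(ncomp)) {
        w <- crossprod(Xs, yv)
        w <- w / sqrt(sum(w^2))
        t_ <- Xs %*% w
        pl <- crossprod(Xs, t_) / sum(t_^2)
        b <- sum(yv * t_) / sum(t_^2)
        ss[a] <- b^2 * sum(t_^2)
        Xs <- Xs - t_ %*% t(pl)
        yv <- yv - b * t_
        W[, a] <- w
    }
    sqrt(p * as.numeric(W^2 %*% ss) / sum(ss))
}

# brute-force EASE probability by direct hypergeometric summation
easeBrute <- function(k, n, K, N) {
    if (k <= 1) return(1)
    kk <- max(k - 1, 0)
    sum(vapply(kk:min(n, K), function(i) stats::dhyper(i, K, N - K, n), 0))
}
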
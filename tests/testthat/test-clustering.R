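test_that("PCA scores: rank-1 data, sign convention, equivariance", {
    set.seed(5)
    v <- rnorm(40); u <- rnorm(30)
    y <- outer(v, u) + matrix(rnorm(1200, sd = 1e-3), 40, 30)
    dimnames(y) <- list(paste0("g", 1:40), paste0("c", 1:30))
    sc <- pcaScores(y, n_pcs = 3)
    expect_gt(var(sc[, 1]) / sum(apply(sc, 2, var)), 0.999)
    # permuting cells permutes scores identically
    perm <- sample(30)
    sc_p <- pcaScores(y[, perm], n_pcs = 3)
    expect_equal(sc_p, sc[perm, ], tolerance = 1e-8)
    # two-blob construction: PC1 separation dominates within-blob spread
    bl <- makeBlobs(k = 2, n_per = 40, d = 20, sep = 8, seed = 2)
    sc2 <- pcaScores(t(bl$x), n_pcs = 2)
    gap <- abs(diff(tapply(sc2[, 1], bl$labels, mean)))
    spread <- max(tapply(sc2[, 1], bl$labels, sd))
    expect_gt(gap, 10 * spread)
})

test_that("k-means clustering recovers separated blobs deterministically", {
    bl <- makeBlobs(k = 4, n_per = 30, d = 6, sep = 12, seed = 3)
    lab <- kmeansCluster(bl$x, k = 4, seed = 9)
    expect_equal(ari(lab, bl$labels), 1)
    expect_identical(kmeansCluster(bl$x, k = 4, seed = 9), lab)
    expect_identical(unname(unique(kmeansCluster(bl$x, k = 1, seed = 1))), 1L)
    # duplicated rows land in the same cluster
    x2 <- rbind(bl$x, bl$x[1:5, ])
    rownames(x2) <- paste0("r", seq_len(nrow(x2)))
    l2 <- kmeansCluster(x2, k = 4, seed = 2)
    expect_identical(unname(l2[121:125]), unname(l2[1:5]))
})

test_that("graph clustering: blob recovery, label order, invariances", {
    bl <- makeBlobs(k = 2, n_per = 60, d = 8, sep = 10, seed = 4)
    cm <- graphCluster(bl$x, k_nn = 10, seed = 1)
    lab <- clusterLabels(cm)
    expect_equal(ari(lab, bl$labels), 1)
    # ids ordered by decreasing size
    bl3 <- makeBlobs(k = 3, n_per = 30, d = 8, sep = 10, seed = 6)
    x <- rbind(bl3$x[1:30, ], bl3$x[31:90, ])   # sizes 30, 30, 30 -> equal ok
    cm3 <- graphCluster(bl3$x, k_nn = 10, seed = 1)
    sizes <- table(clusterLabels(cm3))
    expect_true(all(diff(as.integer(sizes)) <= 0))
    # permuting cells leaves the partition unchanged (up to label names)
    perm <- sample(nrow(bl$x))
    cm_p <- graphCluster(bl$x[perm, ], k_nn = 10, seed = 1)
    expect_equal(ari(clusterLabels(cm_p), lab[perm]), 1)
    expect_error(graphCluster(bl$x, resolution = 0), "resolution")
})

test_that("cluster count does not decrease along a resolution sweep", {
    bl <- makeBlobs(k = 4, n_per = 40, d = 10, sep = 6, seed = 8)
    ks <- vapply(c(0.25, 0.5, 1, 2, 4), function(r)
        length(unique(clusterLabels(
            graphCluster(bl$x, k_nn = 15, resolution = r, seed = 1)))), 0L)
    expect_true(all(diff(ks) >= 0))
})

test_that("immune cluster filtering drops only marker-high clusters", {
    y <- randomExpr(genes = 30, cells = 90, seed = 10)
    labels <- rep(1:3, each = 30)
    rownames(y)[1:5] <- paste0("imm", 1:5)
    y[1:5, labels == 3] <- y[1:5, labels == 3] + 5   # planted immune block
    kept <- filterImmuneCells(y, labels, paste0("imm", 1:5))
    expect_identical(kept, colnames(y)[labels != 3])
    # no excess: everything retained
    y2 <- randomExpr(genes = 30, cells = 90, seed = 11)
    rownames(y2)[1:5] <- paste0("imm", 1:5)
    expect_identical(filterImmuneCells(y2, labels, paste0("imm", 1:5)),
                     colnames(y2))
    # identical clusters: degenerate rule, nothing dropped
    y3 <- y2[, rep(1, 90)]; colnames(y3) <- paste0("c", 1:90)
    expect_identical(filterImmuneCells(y3, labels, paste0("imm", 1:5)),
                     colnames(y3))
})

test_that("cluster merging recovers block structure and degenerate cases", {
    set.seed(12)
    prof <- matrix(rnorm(40 * 4), 40, 4)
    y <- cbind(prof[, c(1, 1, 2, 2)][, rep(1:4, each = 25)] +
               matrix(rnorm(4000, sd = 0.05), 40))
    dimnames(y) <- list(paste0("g", 1:40), paste0("c", 1:100))
    labels <- rep(1:4, each = 25)
    mg <- mergeClusters(y, labels, paste0("g", 1:40), n_groups = 2)
    expect_identical(unname(mg$mapping["1"]), unname(mg$mapping["2"]))
    expect_identical(unname(mg$mapping["3"]), unname(mg$mapping["4"]))
    expect_false(mg$mapping[["1"]] == mg$mapping[["3"]])
    # identical profiles merge at height ~0
    y2 <- y; y2[, labels == 2] <- y2[, labels == 1]
    mg2 <- mergeClusters(y2, labels, paste0("g", 1:40), n_groups = 3)
    expect_lt(min(mg2$dendrogram$height), 1e-10)
    expect_identical(unname(mg2$mapping["1"]), unname(mg2$mapping["2"]))
    # n_groups == n_clusters: identity mapping
    mg4 <- mergeClusters(y, labels, paste0("g", 1:40), n_groups = 4)
    expect_identical(length(unique(mg4$mapping)), 4L)
    # invariance to cluster id permutation
    relab <- c(3L, 1L, 4L, 2L)[labels]
    mg_p <- mergeClusters(y, relab, paste0("g", 1:40), n_groups = 2)
    expect_equal(ari(mg_p$mapping[as.character(relab)],
                     mg$mapping[as.character(labels)]), 1)
    expect_error(mergeClusters(y, rep(1, 100), paste0("g", 1:40), 2),
                 "at least n_groups")
})

test_that("co-expression overlap is exact set arithmetic", {
    y <- matrix(0, 2, 5, dimnames = list(c("A", "B"), paste0("c", 1:5)))
    y["A", 1:3] <- 1
    y["B", 2:4] <- 1
    ov <- coexpressionOverlap(y, "A", "B")
    expect_identical(ov[c("nA", "nB", "nBoth")],
                     list(nA = 3L, nB = 3L, nBoth = 2L))
    expect_equal(ov$share, 2 / 3)
    y2 <- y; y2["B", ] <- c(0, 0, 0, 1, 1)
    expect_equal(coexpressionOverlap(y2, "A", "B")$share, 0)
    y3 <- y; y3["B", ] <- 1
    expect_equal(coexpressionOverlap(y3, "A", "B")$share, 1)
    # A nowhere expressed: share defined as 0
    y4 <- y; y4["A", ] <- 0
    expect_equal(coexpressionOverlap(y4, "A", "B")$share, 0)
})

test_that("inverse-normal Z uses Blom offsets with average-rank ties", {
    y <- matrix(c(3, 1, 2), 1, 3,
                dimnames = list("g", paste0("c", 1:3)))
    z <- rankInverseNormalZ(y)
    expected <- qnorm((c(3, 1, 2) - 0.375) / 3.25)
    expect_equal(unname(z[1, ]), expected)
    expect_equal(z[1, "c1"], -z[1, "c2"])          # symmetric around 0
    # tied gene: all Z zero
    yc <- matrix(5, 1, 10, dimnames = list("g", paste0("c", 1:10)))
    expect_equal(unname(rankInverseNormalZ(yc)[1, ]), rep(0, 10))
    # monotone transform preserves order
    set.seed(13)
    v <- rnorm(50)
    zz <- rankInverseNormalZ(matrix(v, 1, 50,
                                    dimnames = list("g", paste0("c", 1:50))))
    expect_identical(order(zz[1, ]), order(v))
})
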
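test_that("Wilcoxon screen: exact branch, degenerate and formula cases", {
    y <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
               g2 = rep(2, 6),
               g3 = c(7, 8, 9, 0, 0, 0))
    colnames(y) <- paste0("c", 1:6)
    labels <- rep(c("A", "B"), each = 3)
    res <- wilcoxonOneVsRest(y, labels, "A")
    expect_equal(res["g1", "p_value"], 0.1)       # 2/20 rank assignments
    expect_equal(res["g2", "p_value"], 1)
    expect_equal(res["g2", "fold_change"],
                 (mean(2^2 - 1) + 0.01) / (mean(2^2 - 1) + 0.01))
    # cluster mean expm 3.0 vs rest 0.0 -> (3.01)/(0.01) = 301
    y2 <- rbind(g = log2(c(3, 3, 3, 0, 0, 0) + 1))
    colnames(y2) <- paste0("c", 1:6)
    expect_equal(wilcoxonOneVsRest(y2, labels, "A")[1, "fold_change"], 301)
    expect_error(wilcoxonOneVsRest(y, labels, "Z"), "absent")
})

test_that("exact branch equals the exhaustive-enumeration oracle", {
    set.seed(17)
    for (i in 1:200) {
        n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
        vals <- sample(0:4, n1 + n2, replace = TRUE)  # heavy ties
        y <- matrix(vals, 1, dimnames = list("g", paste0("c", 1:(n1 + n2))))
        labels <- rep(c("A", "B"), c(n1, n2))
        p <- wilcoxonOneVsRest(y, labels, "A")[1, "p_value"]
        expect_equal(p, wilcoxEnumOracle(vals[1:n1], vals[-(1:n1)]),
                     tolerance = 1e-12)
    }
    # tie-free instances also agree with the standard exact test
    for (i in 1:20) {
        n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
        vals <- sample(seq_len(50), n1 + n2)
        y <- matrix(vals, 1, dimnames = list("g", paste0("c", 1:(n1 + n2))))
        labels <- rep(c("A", "B"), c(n1, n2))
        p <- wilcoxonOneVsRest(y, labels, "A")[1, "p_value"]
        ref <- wilcox.test(vals[1:n1], vals[-(1:n1)], exact = TRUE)$p.value
        expect_equal(p, ref, tolerance = 1e-12)
    }
})

test_that("normal-approximation branch matches the tie-corrected z test", {
    set.seed(18)
    y <- matrix(sample(0:5, 40 * 60, replace = TRUE), 40, 60,
                dimnames = list(paste0("g", 1:40), paste0("c", 1:60)))
    labels <- rep(c("A", "B"), c(20, 40))
    res <- wilcoxonOneVsRest(y, labels, "A")
    for (g in c(1, 7, 23)) {
        ref <- suppressWarnings(
            wilcox.test(y[g, 1:20], y[g, 21:60], exact = FALSE,
                        correct = FALSE))$p.value
        expect_equal(res$p_value[g], ref, tolerance = 1e-10)
    }
})

test_that("BH adjustment is the hand-computed step-up", {
    expect_equal(adjustBH(0.03), 0.03)
    expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    set.seed(19)
    p <- sort(runif(30))
    expect_true(all(diff(adjustBH(p)) >= -1e-15))  # sorted in, sorted out
    expect_true(all(adjustBH(runif(100)) <= 1))
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("initial marker gating uses strict inequalities", {
    scr <- list(A = S4Vectors::DataFrame(
        p_value = c(1e-6, 1e-6, 1e-6),
        fold_change = c(1.31, 1.3, 2.0),
        row.names = c("pass", "at_fc_boundary", "strong")))
    tab <- initialMarkers(scr, alpha = 0.05, fc_min = 1.3)
    expect_true(tab$is_initial[tab$gene == "pass"])
    expect_false(tab$is_initial[tab$gene == "at_fc_boundary"])
    # p_adj exactly at alpha is excluded
    scr2 <- list(A = S4Vectors::DataFrame(
        p_value = c(0.05, 0.049), fold_change = c(2, 2),
        row.names = c("at_alpha", "below")))
    tab2 <- initialMarkers(scr2, alpha = 0.05)
    expect_false(tab2$is_initial[tab2$gene == "at_alpha"])
})

test_that("VIP satisfies its normalization identity and symmetries", {
    set.seed(20)
    for (i in 1:5) {
        X <- matrix(rnorm(80 * 25), 80, 25)
        y <- rep(0:1, each = 40)
        v <- fitPlsdaVip(X, y)
        expect_equal(mean(v^2), 1, tolerance = 1e-8)
    }
    # duplicated gene columns get equal VIP
    X <- matrix(rnorm(60 * 10), 60, 10)
    X[, 10] <- X[, 1]
    v <- fitPlsdaVip(X, rep(0:1, each = 30))
    expect_equal(v[1], v[10], tolerance = 1e-10)
    # constant columns dropped with warning, VIP NA
    X2 <- cbind(X[, 1:5], 3)
    expect_warning(v2 <- fitPlsdaVip(X2, rep(0:1, each = 30)), "constant")
    expect_true(is.na(v2[6]))
    expect_equal(mean(v2[1:5]^2), 1, tolerance = 1e-8)
})

test_that("optimized VIP equals the textbook NIPALS oracle", {
    set.seed(21)
    X <- matrix(rnorm(200 * 50), 200, 50)
    X[, 7] <- X[, 7] + rep(c(0, 3), each = 100)   # one separating gene
    y <- rep(0:1, each = 100)
    v <- fitPlsdaVip(X, y, n_components = 2)
    expect_equal(unname(v), naiveVip(X, y, 2), tolerance = 1e-8)
    expect_identical(unname(which.max(v)), 7L)
    expect_gt(v[7], 1)
    skip_if_not_installed("mixOmics")
    # independent implementation: ranking agreement on the same matrix
    fit <- mixOmics::plsda(X, factor(y), ncomp = 2)
    vmix <- mixOmics::vip(fit)[, 2]
    expect_gt(cor(v, vmix, method = "spearman"), 0.95)
    expect_identical(unname(which.max(vmix)), 7L)
})

test_that("KDE permutation p-values behave at the null median and far tail", {
    set.seed(22)
    X <- matrix(rnorm(100 * 30), 100, 30)
    y <- rep(0:1, each = 50)
    v <- fitPlsdaVip(X, y)
    p <- vipPermutationPvalues(X, y, v, n_perm = 200, seed = 4)
    expect_true(all(p > 0 & p < 1))
    # an observed VIP equal to the null median has p ~ 0.5
    null_pool <- local({
        vv <- replicate(50, fitPlsdaVip(X, sample(y)))
        as.vector(vv)
    })
    p_med <- vipPermutationPvalues(X, y, median(null_pool), n_perm = 400,
                                   seed = 5)
    expect_lt(abs(p_med - 0.5), 0.05)
    # an observed VIP far beyond every null draw is essentially 0
    p_far <- vipPermutationPvalues(X, y, max(null_pool) + 10, n_perm = 200,
                                   seed = 6)
    expect_lt(p_far, 0.005)
    expect_warning(vipPermutationPvalues(X, y, v[1], n_perm = 50, seed = 1),
                   "coarse")
})

test_that("final marker gating requires initial status", {
    tab <- S4Vectors::DataFrame(
        gene = c("a", "b", "c"), cluster = "1",
        p_wilcoxon = 0.001, p_wilcoxon_adj = 0.001, fold_change = 2,
        is_initial = c(TRUE, TRUE, FALSE),
        vip = c(2, 1, 3), p_vip = c(0.01, 0.2, 0.001),
        p_vip_adj = c(0.03, 0.4, 0.003), is_final = FALSE)
    out <- finalMarkers(tab)
    expect_identical(out$is_final, c(TRUE, FALSE, FALSE))
    out_bh <- finalMarkers(tab, adjust = "BH")
    expect_identical(out_bh$is_final, c(TRUE, FALSE, FALSE))
})

test_that("marker pipeline is deterministic under a fixed seed", {
    sim <- simulateDropletData(flatSimConfig(seed = 23, n_true_cells = 200))
    y <- logNormalize(as.matrix(SummarizedExperiment::assay(sim$sce,
                                                            "counts")),
                      rep(1, 200))
    labels <- truthBarcodes(sim$truth)$cluster
    t1 <- clusterMarkers(y, labels, n_perm = 100, seed = 3)
    t2 <- clusterMarkers(y, labels, n_perm = 100, seed = 3)
    expect_identical(as.data.frame(t1), as.data.frame(t2))
    expect_gt(sum(t1$is_initial), 0)
})
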
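test_that("generator is bit-reproducible under a fixed seed", {
    s1 <- simulateDropletData(smallSimConfig(seed = 5))
    s2 <- simulateDropletData(smallSimConfig(seed = 5))
    expect_identical(as.matrix(SummarizedExperiment::assay(s1$sce, "counts")),
                     as.matrix(SummarizedExperiment::assay(s2$sce, "counts")))
    expect_identical(as.data.frame(truthBarcodes(s1$truth)),
                     as.data.frame(truthBarcodes(s2$truth)))
    s3 <- simulateDropletData(smallSimConfig(seed = 6))
    expect_false(identical(
        as.matrix(SummarizedExperiment::assay(s1$sce, "counts")),
        as.matrix(SummarizedExperiment::assay(s3$sce, "counts"))))
})

test_that("low-quality cells are planted exactly and above the mito floor", {
    sim <- simulateDropletData(flatSimConfig(seed = 2, n_true_cells = 100,
                                             lowq_frac = 0.1))
    tb <- truthBarcodes(sim$truth)
    expect_identical(sum(tb$is_lowq), 10L)
    expect_true(all(tb$mito_target[tb$is_lowq] > 0.15))
    expect_true(all(is.na(tb$mito_target[!tb$is_lowq])))
})

test_that("planted marker effects match the configured log2 fold change", {
    # hard (non-trajectory) clusters; Monte-Carlo check on the
    # size-factor-normalized empirical means against the generative 2^1.5
    sim <- simulateDropletData(flatSimConfig(seed = 9, marker_effect = 1.5))
    tb <- truthBarcodes(sim$truth)
    tg <- truthGenes(sim$truth)
    cnt <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
    norm <- sweep(cnt, 2, tb$size_factor, "/")
    inA <- tb$cluster == "C1"
    markersA <- rownames(tg)[tg$marker_of == "C1"]
    ratios <- rowMeans(norm[markersA, inA]) / rowMeans(norm[markersA, !inA])
    expect_true(all(ratios >= 2^1.2 & ratios <= 2^1.8))
})

test_that("empty droplets: count exact, ambient totals near ambient_scale", {
    cfg <- smallSimConfig(seed = 4, n_empty_droplets = 600,
                          ambient_scale = 0.02)
    sim <- simulateDropletData(cfg)
    tb <- truthBarcodes(sim$truth)
    expect_identical(sum(tb$is_empty), 600L)
    tot <- Matrix::colSums(SummarizedExperiment::assay(sim$sce, "counts"))
    ratio <- mean(tot[tb$is_empty]) / mean(tot[!tb$is_empty])
    expect_lt(abs(ratio - 0.02) / 0.02, 0.25)
    # empties carry no cluster or pseudotime
    expect_true(all(is.na(tb$cluster[tb$is_empty])))
    expect_true(all(is.na(tb$pseudotime[tb$is_empty])))
})

test_that("program curves respect their temporal contracts", {
    shape <- list(amplitude = 3, steepness = 15, early_mid = 0.15,
                  middle_mid = 0.5, late_mid = 0.85, middle_width = 0.12)
    # anchors
    expect_equal(programCurve("late", 0, shape), 1.0)
    expect_equal(programCurve("early", 0, shape), 1.0)
    expect_gte(programCurve("early", 0.9, shape),
               programCurve("early", 0.05, shape))
    # grid-search oracle for the extremes
    tg <- seq(0, 1, by = 0.001)
    early <- programCurve("early", tg, shape)
    expect_lt(tg[min(which(early >= 1 + 0.9 * (max(early) - 1)))], 1 / 3)
    mid <- programCurve("middle", tg, shape)
    peak <- tg[which.max(mid)]
    expect_true(peak >= 1 / 3 && peak <= 2 / 3)
    late <- programCurve("late", tg, shape)
    expect_gt(tg[min(which(late >= 1 + 0.9 * (max(late) - 1)))], 2 / 3)
    expect_true(all(c(early, mid, late) >= 1 - 1e-12))
    expect_error(programCurve("sometime", 0.5, shape), "unknown pattern")
})

test_that("truth JSON round-trips losslessly", {
    sim <- simulateDropletData(smallSimConfig(seed = 8))
    f <- tempfile(fileext = ".json")
    writeTruth(sim$truth, f)
    back <- readTruth(f)
    # doubles survive to JSON text precision (~1e-15 relative)
    expect_equal(as.data.frame(truthBarcodes(back)),
                 as.data.frame(truthBarcodes(sim$truth)),
                 tolerance = 1e-12)
    expect_identical(as.data.frame(truthGenes(back)),
                     as.data.frame(truthGenes(sim$truth)))
    # null cluster for empty droplets in the serialized file
    raw <- jsonlite::read_json(f)
    empt <- which(vapply(raw$barcodes$is_empty, isTRUE, NA))[1]
    expect_null(raw$barcodes$cluster[[empt]])
})

test_that("infeasible configurations are rejected with the constraint named", {
    expect_error(simConfig(n_genes = 100), "exceed n_genes")
    expect_error(simConfig(lowq_frac = 1.2), "fractions")
    expect_error(simConfig(nb_dispersion = 0), "dispersion")
    expect_error(
        simConfig(group_spec = data.frame(group = c("A", "B"),
                                          n_clusters = c(1L, 1L),
                                          frac = c(0.7, 0.6))),
        "sum to at most 1")
})
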
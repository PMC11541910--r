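#' Configuration for the synthetic droplet-data generator
#'
#' Builds and validates the configuration of \code{\link{simulateDropletData}}.
#' Defaults emulate a two-condition (vehicle control vs beta3-agonist
#' treated), two-batch droplet experiment on sorted PDGFRA+ stromal cells:
#' four biological groups (AFEC niche cells, resting progenitors,
#' proliferating and differentiating cells) subdivided into nine clusters
#' with planted cluster- and group-level markers, an immune contaminant
#' population, low-quality high-mitochondrial cells, empty droplets drawing
#' from the ambient profile, and a differentiation trajectory
#' (linear in the control condition, bifurcating after treatment) carrying
#' early/middle/late gene programs.
#'
#' @param n_true_cells total cell-containing droplets across conditions.
#' @param n_empty_droplets ambient-only droplets.
#' @param n_genes number of genes.
#' @param frac_mito_genes fraction of genes flagged mitochondrial.
#' @param group_spec data.frame with columns \code{group}, \code{n_clusters},
#'   \code{frac} (fraction of true cells); fractions must sum to at most 1,
#'   the remainder is assigned to the immune contaminant population.
#' @param n_markers_cluster,marker_effect cluster-specific marker genes per
#'   cluster and their log2 effect size.
#' @param n_markers_group,group_marker_effect shared marker genes per group.
#' @param n_markers_immune,immune_marker_effect hematopoietic-like marker
#'   block of the immune population.
#' @param lowq_frac fraction of true cells simulated as low-quality
#'   (mitochondrial UMI share drawn uniformly from [0.2, 0.6]).
#' @param trajectory list of trajectory/program settings: \code{branch_point}
#'   (pseudotime of the bifurcation), \code{n_early}, \code{n_middle},
#'   \code{n_late} (genes per program; a second, branch-specific late block
#'   of the same size is planted for the non-differentiating branch, with
#'   its own \code{amplitude_alt} -- stronger by default, standing for a
#'   sustained proliferation signature),
#'   \code{amplitude} (peak fold increase minus one), \code{early_mid},
#'   \code{middle_mid}, \code{late_mid} (activation midpoints on [0,1]),
#'   \code{steepness}, \code{middle_width}.
#' @param nb_dispersion negative binomial dispersion (inverse size).
#' @param size_factor_log_sd natural-log SD of true per-cell size factors.
#' @param ambient_scale mean total UMI of an empty droplet relative to the
#'   mean total of a true cell.
#' @param conditions named character vector mapping condition label to
#'   trajectory topology ("linear" or "bifurcating").
#' @param n_batches number of technical batches.
#' @param batch_log_sd natural-log SD of per-batch multiplicative gene factors.
#' @param mean_umi expected total UMI of an average true cell.
#' @param baseline_mito_share expected mitochondrial UMI share of a healthy
#'   cell.
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#' @return a validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(n_true_cells = 3000,
                      n_empty_droplets = 10000,
                      n_genes = 2000,
                      frac_mito_genes = 0.05,
                      group_spec = data.frame(
                          group = c("AFEC", "Progen", "Prolif", "Diff"),
                          n_clusters = c(2L, 4L, 1L, 2L),
                          frac = c(0.16, 0.40, 0.12, 0.24)),
                      n_markers_cluster = 10, marker_effect = 1.5,
                      n_markers_group = 10, group_marker_effect = 2,
                      n_markers_immune = 20, immune_marker_effect = 3,
                      lowq_frac = 0.05,
                      trajectory = list(),
                      nb_dispersion = 0.1,
                      size_factor_log_sd = 0.25,
                      ambient_scale = 0.01,
                      conditions = c(control = "linear",
                                     treated = "bifurcating"),
                      n_batches = 2,
                      batch_log_sd = 0.1,
                      mean_umi = 4000,
                      baseline_mito_share = 0.04,
                      seed = 1) {
    traj_default <- list(branch_point = 0.65, n_early = 20, n_middle = 20,
                         n_late = 20, amplitude = 3, amplitude_alt = 6,
                         early_mid = 0.15, middle_mid = 0.5, late_mid = 0.85,
                         steepness = 15, middle_width = 0.12)
    bad <- setdiff(names(trajectory), names(traj_default))
    if (length(bad)) stop("unknown trajectory setting(s): ",
                          paste(bad, collapse = ", "))
    traj <- utils::modifyList(traj_default, trajectory)

    cfg <- list(n_true_cells = as.integer(n_true_cells),
                n_empty_droplets = as.integer(n_empty_droplets),
                n_genes = as.integer(n_genes),
                frac_mito_genes = frac_mito_genes, group_spec = group_spec,
                n_markers_cluster = as.integer(n_markers_cluster),
                marker_effect = marker_effect,
                n_markers_group = as.integer(n_markers_group),
                group_marker_effect = group_marker_effect,
                n_markers_immune = as.integer(n_markers_immune),
                immune_marker_effect = immune_marker_effect,
                lowq_frac = lowq_frac, trajectory = traj,
                nb_dispersion = nb_dispersion,
                size_factor_log_sd = size_factor_log_sd,
                ambient_scale = ambient_scale, conditions = conditions,
                n_batches = as.integer(n_batches),
                batch_log_sd = batch_log_sd, mean_umi = mean_umi,
                baseline_mito_share = baseline_mito_share,
                seed = as.integer(seed))

    fr <- c(frac_mito_genes, lowq_frac, group_spec$frac)
    if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
    if (sum(group_spec$frac) > 1 + 1e-9)
        stop("group fractions must sum to at most 1")
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
    if (!all(conditions %in% c("linear", "bifurcating")))
        stop("condition topologies must be 'linear' or 'bifurcating'")
    n_clusters <- sum(group_spec$n_clusters)
    planted <- round(frac_mito_genes * n_genes) +
        n_clusters * n_markers_cluster +
        nrow(group_spec) * n_markers_group + n_markers_immune +
        traj$n_early + traj$n_middle + 2L * traj$n_late
    if (planted > n_genes)
        stop(sprintf(paste0("infeasible configuration: %d planted genes ",
                            "(mito + markers + programs) exceed n_genes = %d"),
                     planted, n_genes))
    cfg$immune_frac <- 1 - sum(group_spec$frac)
    class(cfg) <- "simConfig"
    cfg
}

#' Gene-program activation curve along pseudotime
#'
#' Relative expression multiplier of a program gene as a function of
#' pseudotime on [0, 1]. "early" and "late" are normalized logistic rises
#' (exactly 1 at t = 0, 1 + amplitude at t = 1) with midpoints near the
#' start and the end of the trajectory; "middle" is a Gaussian bump peaking
#' mid-trajectory.
#'
#' @param pattern one of "early", "middle", "late".
#' @param t pseudotime value(s) in [0, 1].
#' @param shape list with \code{amplitude}, \code{steepness}, the logistic
#'   midpoints \code{early_mid}/\code{late_mid} and \code{middle_mid},
#'   \code{middle_width} for the bump.
#' @return numeric multiplier(s), \code{>= 1} at the configured amplitudes.
#' @export
programCurve <- function(pattern, t,
                         shape = list(amplitude = 3, steepness = 15,
                                      early_mid = 0.15, middle_mid = 0.5,
                                      late_mid = 0.85, middle_width = 0.12)) {
    if (any(t < -1e-9 | t > 1 + 1e-9)) stop("pseudotime must lie in [0, 1]")
    A <- shape$amplitude; s <- shape$steepness
    sig <- function(z) 1 / (1 + exp(-z))
    norm_sig <- function(t, m) {
        lo <- sig(s * (0 - m)); hi <- sig(s * (1 - m))
        (sig(s * (t - m)) - lo) / (hi - lo)
    }
    g <- switch(pattern,
        early = norm_sig(t, shape$early_mid),
        middle = exp(-(t - shape$middle_mid)^2 / (2 * shape$middle_width^2)),
        late = norm_sig(t, shape$late_mid),
        stop("unknown pattern label: ", pattern))
    1 + A * g
}

# deterministic layout of planted gene blocks; returns index vectors
.geneLayout <- function(cfg) {
    g <- cfg$group_spec
    n_clusters <- sum(g$n_clusters)
    tr <- cfg$trajectory
    n_mito <- round(cfg$frac_mito_genes * cfg$n_genes)
    cursor <- 0L
    take <- function(n) {
        idx <- seq_len(n) + cursor
        cursor <<- cursor + n
        idx
    }
    mito <- take(n_mito)
    cluster_markers <- lapply(seq_len(n_clusters),
                              function(i) take(cfg$n_markers_cluster))
    group_markers <- lapply(seq_len(nrow(g)),
                            function(i) take(cfg$n_markers_group))
    immune <- take(cfg$n_markers_immune)
    early <- take(tr$n_early); middle <- take(tr$n_middle)
    late <- take(tr$n_late); late_alt <- take(tr$n_late)
    list(mito = mito, cluster_markers = cluster_markers,
         group_markers = group_markers, immune = immune,
         early = early, middle = middle, late = late, late_alt = late_alt)
}

#' Simulate a droplet scRNA-seq dataset with planted ground truth
#'
#' Draws a gene-by-barcode UMI matrix under a negative binomial model
#' (mean = size factor x cell-type profile x program multiplier x batch
#' factor, per-gene dispersion) for the cell-containing droplets, and
#' multinomial draws from the library-wide ambient profile with Poisson
#' totals for the empty droplets. Identical seeds give bit-identical output.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{sce} (a counts \code{SingleCellExperiment}, see
#'   \code{\link{makeUMIMatrix}}) and \code{truth} (a \code{SimTruth}).
#' @export
simulateDropletData <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    .withSeed(config$seed, .simulateImpl(config))
}

.simulateImpl <- function(cfg) {
    gs <- cfg$group_spec
    tr <- cfg$trajectory
    lay <- .geneLayout(cfg)
    n_clusters <- sum(gs$n_clusters)
    cluster_names <- paste0("C", seq_len(n_clusters))
    cluster_group <- rep(gs$group, gs$n_clusters)

    ## ---- genes -----------------------------------------------------------
    rel <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.2)
    # planted marker/program genes get moderate baseline abundance, the way
    # real markers (Dpp4, Ucp1, ...) are reliably detected genes
    planted <- unique(c(unlist(lay$cluster_markers),
                        unlist(lay$group_markers), lay$immune,
                        lay$early, lay$middle, lay$late, lay$late_alt))
    rel[planted] <- stats::rlnorm(length(planted), meanlog = 1, sdlog = 0.5)
    # pin the aggregate mitochondrial share of a healthy cell
    if (length(lay$mito)) {
        cur <- sum(rel[lay$mito]) / sum(rel)
        f <- cfg$baseline_mito_share * (1 - cur) /
            (cur * (1 - cfg$baseline_mito_share))
        rel[lay$mito] <- rel[lay$mito] * f
    }
    p0 <- rel / sum(rel)
    gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
    symbols <- sprintf("g%d", seq_len(cfg$n_genes))
    symbols[lay$mito] <- sprintf("mt-g%d", seq_along(lay$mito))

    ## ---- cells -----------------------------------------------------------
    conds <- names(cfg$conditions)
    n_cond <- diff(round(seq(0, cfg$n_true_cells, length.out =
                                 length(conds) + 1)))
    cell_condition <- rep(conds, n_cond)
    n_true <- cfg$n_true_cells

    traj_groups <- intersect(c("Progen", "Prolif", "Diff"), gs$group)
    frac_traj <- gs$frac[match(traj_groups, gs$group)]
    bounds <- cumsum(frac_traj) / sum(frac_traj)

    group <- character(n_true); cluster <- character(n_true)
    ptime <- rep(NA_real_, n_true); branch <- rep(NA_integer_, n_true)
    stage_t <- rep(NA_real_, n_true)  # stalled on the non-differentiating arm
    is_immune <- logical(n_true)
    for (cd in conds) {
        idx <- which(cell_condition == cd)
        n_imm <- round(cfg$immune_frac * length(idx))
        imm <- idx[seq_len(n_imm)]
        is_immune[imm] <- TRUE
        group[imm] <- "Immune"; cluster[imm] <- "Immune"
        rest <- setdiff(idx, imm)
        # non-trajectory groups (e.g. the AFEC niche) take their share first
        other <- setdiff(gs$group, traj_groups)
        pos <- 0L
        for (og in other) {
            n_og <- if (length(traj_groups) == 0 && og == other[length(other)])
                length(rest) - pos
            else round(gs$frac[gs$group == og] / sum(gs$frac) * length(rest))
            take <- rest[pos + seq_len(n_og)]
            pos <- pos + n_og
            group[take] <- og
            kcl <- cluster_names[cluster_group == og]
            cluster[take] <- sample(kcl, length(take), replace = TRUE)
        }
        if (pos >= length(rest) || length(traj_groups) == 0) next
        pool <- rest[(pos + 1L):length(rest)]
        # trajectory pool: pseudotime uniform; groups are consecutive
        # pseudotime stages (cumulative group fractions), and each group's
        # clusters are consecutive sub-stages, so the state sequence is a
        # 1-D continuum (as in real progenitor maturation)
        t <- stats::runif(length(pool))
        if (cfg$conditions[[cd]] == "bifurcating") {
            bp <- tr$branch_point
            branch[pool] <- ifelse(t <= bp, 0L,
                                   stats::rbinom(length(pool), 1L, 0.5) + 1L)
        } else {
            branch[pool] <- 0L
        }
        # non-differentiating branch (id 2) stalls at the branch-point stage
        ts <- ifelse(branch[pool] == 2L, pmin(t, tr$branch_point), t)
        gidx <- findInterval(ts, bounds, left.open = TRUE) + 1L
        gidx <- pmin(gidx, length(traj_groups))
        group[pool] <- traj_groups[gidx]
        ptime[pool] <- t
        stage_t[pool] <- ts
        lo_b <- c(0, bounds[-length(bounds)])
        for (gi in seq_along(traj_groups)) {
            tg <- traj_groups[gi]
            take <- which(gidx == gi)
            if (!length(take)) next
            kcl <- cluster_names[cluster_group == tg]
            u <- (ts[take] - lo_b[gi]) / (bounds[gi] - lo_b[gi])
            sub <- pmin(pmax(ceiling(u * length(kcl)), 1L), length(kcl))
            cluster[pool[take]] <- kcl[sub]
        }
    }

    batch <- sample(rep_len(paste0("b", seq_len(cfg$n_batches)), n_true))
    sf <- stats::rlnorm(n_true, 0, cfg$size_factor_log_sd)
    sf <- sf / mean(sf)
    n_lowq <- round(cfg$lowq_frac * n_true)
    lowq_idx <- sample(n_true, n_lowq)
    is_lowq <- seq_len(n_true) %in% lowq_idx
    mito_target <- rep(NA_real_, n_true)
    mito_target[lowq_idx] <- stats::runif(n_lowq, 0.2, 0.6)

    batch_fac <- matrix(stats::rlnorm(cfg$n_genes * cfg$n_batches, 0,
                                      cfg$batch_log_sd),
                        nrow = cfg$n_genes)
    batch_fac <- sweep(batch_fac, 2, colMeans(batch_fac), "/")

    ## ---- expected means --------------------------------------------------
    mu <- matrix(p0 * cfg$mean_umi, nrow = cfg$n_genes, ncol = n_true)
    # trajectory stages form a continuum: stage (cluster) markers ramp up and
    # down triangularly around the stage center, group markers plateau over
    # the group's pseudotime interval with a short linear ramp, so maturation
    # is smooth in expression space. Non-trajectory clusters (the AFEC niche,
    # immune cells) switch their markers on discretely.
    lo_b <- c(0, bounds[-length(bounds)])
    stage_center <- stage_width <- c()
    for (gi in seq_along(traj_groups)) {
        kcl <- cluster_names[cluster_group == traj_groups[gi]]
        bks <- seq(lo_b[gi], bounds[gi], length.out = length(kcl) + 1L)
        stage_center[kcl] <- (bks[-1] + bks[-length(bks)]) / 2
        stage_width[kcl] <- diff(bks)[1]
    }
    on_tr <- which(!is.na(stage_t))
    for (k in seq_len(n_clusters)) {
        ck <- cluster_names[k]
        gset <- lay$cluster_markers[[k]]
        if (ck %in% names(stage_center)) {
            w <- pmax(0, 1 - abs(stage_t[on_tr] - stage_center[ck]) /
                             stage_width[ck])
            mu[gset, on_tr] <- mu[gset, on_tr] *
                outer(rep(1, length(gset)), 2^(cfg$marker_effect * w))
        } else {
            cells <- which(cluster == ck)
            mu[gset, cells] <- mu[gset, cells] * 2^cfg$marker_effect
        }
    }
    for (gi in seq_len(nrow(gs))) {
        gname <- gs$group[gi]; gset <- lay$group_markers[[gi]]
        if (gname %in% traj_groups) {
            j <- match(gname, traj_groups)
            outside <- pmax(0, lo_b[j] - stage_t[on_tr]) +
                pmax(0, stage_t[on_tr] - bounds[j])
            w <- pmax(0, 1 - outside / 0.02)
            mu[gset, on_tr] <- mu[gset, on_tr] *
                outer(rep(1, length(gset)), 2^(cfg$group_marker_effect * w))
        } else {
            cells <- which(group == gname)
            mu[gset, cells] <- mu[gset, cells] * 2^cfg$group_marker_effect
        }
    }
    imm <- which(is_immune)
    mu[lay$immune, imm] <- mu[lay$immune, imm] * 2^cfg$immune_marker_effect

    shape <- tr
    on_traj <- which(!is.na(ptime))
    if (length(on_traj)) {
        t <- ptime[on_traj]
        mu[lay$early, on_traj] <- outer(rep(1, length(lay$early)),
                            programCurve("early", t, shape)) *
            mu[lay$early, on_traj]
        mu[lay$middle, on_traj] <- outer(rep(1, length(lay$middle)),
                            programCurve("middle", t, shape)) *
            mu[lay$middle, on_traj]
        # late program rises only on the differentiating branch; the
        # alternative branch carries its own late block
        b <- branch[on_traj]
        t_late <- ifelse(b == 2L, shape$branch_point, t)
        t_alt <- ifelse(b %in% c(0L, 1L), pmin(t, shape$branch_point), t)
        bif <- cfg$conditions[cell_condition[on_traj]] == "bifurcating"
        t_alt[!bif] <- 0
        mu[lay$late, on_traj] <- outer(rep(1, length(lay$late)),
                            programCurve("late", t_late, shape)) *
            mu[lay$late, on_traj]
        shape_alt <- shape
        shape_alt$amplitude <- shape$amplitude_alt
        mu[lay$late_alt, on_traj] <- outer(rep(1, length(lay$late_alt)),
                            programCurve("late", t_alt, shape_alt)) *
            mu[lay$late_alt, on_traj]
    }

    # low-quality cells: inflate mitochondrial means to the target share
    if (length(lay$mito) && n_lowq) {
        share <- colSums(mu[lay$mito, lowq_idx, drop = FALSE]) /
            colSums(mu[, lowq_idx, drop = FALSE])
        m <- mito_target[lowq_idx]
        f <- m * (1 - share) / (share * (1 - m))
        mu[lay$mito, lowq_idx] <- sweep(mu[lay$mito, lowq_idx, drop = FALSE],
                                        2, f, "*")
    }

    bi <- match(batch, paste0("b", seq_len(cfg$n_batches)))
    mu <- mu * batch_fac[, bi]
    mu <- sweep(mu, 2, sf, "*")

    counts_true <- matrix(stats::rnbinom(length(mu), mu = mu,
                                         size = 1 / cfg$nb_dispersion),
                          nrow = cfg$n_genes)

    ## ---- empty droplets --------------------------------------------------
    n_empty <- cfg$n_empty_droplets
    if (n_empty > 0) {
        ambient <- rowMeans(mu); ambient <- ambient / sum(ambient)
        tot_emp <- stats::rpois(n_empty,
                                cfg$ambient_scale * mean(colSums(mu)))
        draws <- sample.int(cfg$n_genes, sum(tot_emp), replace = TRUE,
                            prob = ambient)
        counts_empty <- Matrix::sparseMatrix(
            i = draws, j = rep.int(seq_len(n_empty), tot_emp), x = 1,
            dims = c(cfg$n_genes, n_empty))
    } else {
        counts_empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0),
                                             dims = c(cfg$n_genes, 0L))
    }

    counts <- cbind(as(counts_true, "CsparseMatrix"), counts_empty)
    n_all <- ncol(counts)
    perm <- sample(n_all)   # interleave true cells and empties
    counts <- counts[, perm, drop = FALSE]
    barcodes <- sprintf("BC%06d", seq_len(n_all))

    emp_cond <- rep_len(conds, n_empty)
    emp_batch <- rep_len(paste0("b", seq_len(cfg$n_batches)), n_empty)
    truth_bc <- S4Vectors::DataFrame(
        barcode = barcodes,
        is_empty = c(rep(FALSE, n_true), rep(TRUE, n_empty))[perm],
        is_lowq = c(is_lowq, rep(FALSE, n_empty))[perm],
        is_immune = c(is_immune, rep(NA, n_empty))[perm],
        cluster = c(cluster, rep(NA_character_, n_empty))[perm],
        group = c(group, rep(NA_character_, n_empty))[perm],
        condition = c(cell_condition, emp_cond)[perm],
        batch = c(batch, emp_batch)[perm],
        size_factor = c(sf, rep(NA_real_, n_empty))[perm],
        pseudotime = c(ptime, rep(NA_real_, n_empty))[perm],
        branch = c(branch, rep(NA_integer_, n_empty))[perm],
        mito_target = c(mito_target, rep(NA_real_, n_empty))[perm],
        row.names = barcodes)

    marker_of <- rep("", cfg$n_genes)
    add_marker <- function(genes, label) {
        marker_of[genes] <<- ifelse(nzchar(marker_of[genes]),
                                    paste(marker_of[genes], label, sep = ","),
                                    label)
    }
    for (k in seq_len(n_clusters))
        add_marker(lay$cluster_markers[[k]], cluster_names[k])
    for (gi in seq_len(nrow(gs)))
        add_marker(lay$group_markers[[gi]],
                   paste(cluster_names[cluster_group == gs$group[gi]],
                         collapse = ","))
    add_marker(lay$immune, "Immune")

    program <- rep("none", cfg$n_genes)
    program[lay$early] <- "early"; program[lay$middle] <- "middle"
    program[c(lay$late, lay$late_alt)] <- "late"
    program_paths <- rep("", cfg$n_genes)
    program_paths[c(lay$early, lay$middle)] <- "1,2,3"
    program_paths[lay$late] <- "1,2"
    program_paths[lay$late_alt] <- "3"

    truth_gn <- S4Vectors::DataFrame(
        gene_id = gene_ids, symbol = symbols,
        is_mito = seq_len(cfg$n_genes) %in% lay$mito,
        marker_of = marker_of, program = program,
        program_paths = program_paths, row.names = gene_ids)

    sce <- makeUMIMatrix(counts, gene_ids = gene_ids, gene_symbols = symbols,
                         barcode_ids = barcodes,
                         is_mito = truth_gn$is_mito,
                         condition = truth_bc$condition,
                         batch = truth_bc$batch)
    truth <- new("SimTruth", barcodes = truth_bc, genes = truth_gn,
                 params = unclass(cfg)[setdiff(names(cfg), "group_spec")])
    list(sce = sce, truth = truth)
}

#' Write simulation ground truth to JSON
#'
#' The truth round-trips losslessly through \code{\link{readTruth}}; missing
#' values (e.g. the cluster of an empty droplet) serialize as JSON null.
#'
#' @param truth a \code{SimTruth}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeTruth <- function(truth, path) {
    stopifnot(is(truth, "SimTruth"))
    bc <- as.data.frame(truth@barcodes); rownames(bc) <- NULL
    gn <- as.data.frame(truth@genes); rownames(gn) <- NULL
    obj <- list(barcodes = bc, genes = gn, params = truth@params)
    jsonlite::write_json(obj, path, dataframe = "columns", na = "null",
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    bc <- obj$barcodes
    for (col in c("is_empty", "is_lowq", "is_immune"))
        bc[[col]] <- as.logical(bc[[col]])
    for (col in c("barcode", "cluster", "group", "condition", "batch"))
        bc[[col]] <- as.character(bc[[col]])
    for (col in c("size_factor", "pseudotime", "mito_target"))
        bc[[col]] <- as.numeric(bc[[col]])
    bc$branch <- as.integer(bc$branch)
    gn <- obj$genes
    gn$is_mito <- as.logical(gn$is_mito)
    for (col in c("gene_id", "symbol", "marker_of", "program",
                  "program_paths"))
        gn[[col]] <- as.character(gn[[col]])
    new("SimTruth",
        barcodes = S4Vectors::DataFrame(bc, row.names = bc$barcode),
        genes = S4Vectors::DataFrame(gn, row.names = gn$gene_id),
        params = obj$params)
}
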
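#' Specification for a synthetic droplet scRNA-seq dataset
#'
#' Describes the generative model used by
#' \code{\link{generateClusteredCounts}}: UMI counts for cell c and gene g
#' are Poisson with mean
#' \code{s_c * theta_g * F(g, cluster(c)) * B(g, run(c)) * C(g, c)}, where
#' \code{s_c} is a log-normal library size, \code{theta_g} a log-normal
#' baseline relative abundance normalized to sum 1, \code{F} the marker
#' fold change of the cell's cluster (1 for non-markers), \code{B} a run
#' batch factor on a random subset of genes, and
#' \code{C = exp(effect * phase_score)} for cell-cycle module genes.
#' Mitochondrial pseudo-genes (prefix \code{MT-}) absorb a Beta-distributed
#' per-cell fraction of the expression budget. Defaults reflect a typical
#' multi-run droplet experiment with well-separated subpopulations:
#' 8 clusters of 150 cells with 20 markers each at natural-log fold change
#' 2, median library size 8000 UMIs (within the 4000--13000 QC window),
#' two runs with a mild batch effect on 10\% of genes, and a mean
#' mitochondrial fraction of 5\%.
#'
#' @param n_genes number of non-mitochondrial genes.
#' @param clusters data.frame with columns \code{name}, \code{n_cells},
#'   \code{marker_genes} (count), \code{marker_log_fc} (natural-log fold
#'   change), and optionally \code{marker_ids} (list column of explicit
#'   gene indices; must be disjoint across clusters).
#' @param library_size c(median, sdlog) of the log-normal library size.
#' @param baseline c(meanlog, sdlog) of the log-normal gene abundance.
#' @param cc list with \code{n_s}, \code{n_g2m} (module gene counts),
#'   \code{effect} (log-scale effect per unit phase score),
#'   \code{phase_prob} (mixture weights of the G1/S-high/G2M-high states),
#'   \code{amplitude} (mean phase-score in the S-high and G2M-high states;
#'   mitotic signatures swing harder than S-phase ones, which also keeps
#'   the two module directions separable by PCA) and \code{abundance_boost}
#'   (log-scale baseline abundance bonus for module genes, reflecting the
#'   robust expression of cycle machinery).
#' @param runs data.frame with columns \code{run_id}, \code{fraction},
#'   \code{batch_log_fc}, \code{affected_frac}, \code{alignment_rate}.
#' @param mito list with \code{n_genes} and \code{beta} (shape1, shape2 of
#'   the per-cell mitochondrial fraction).
#' @param overdispersion gene-by-cell Gamma overdispersion; 0 (default)
#'   gives pure Poisson noise, matching near-Poisson UMI-level variation.
#' @param seed integer; fixed seed makes every generator bit-reproducible.
#' @return A validated \code{SyntheticSpec} list.
#' @export
syntheticSpec <- function(n_genes = 2000,
                          clusters = data.frame(name = paste0("C", 1:8),
                                                n_cells = 150,
                                                marker_genes = 20,
                                                marker_log_fc = 2),
                          library_size = c(median = 8000, sdlog = 0.15),
                          baseline = c(meanlog = 0, sdlog = 1),
                          cc = list(n_s = 43, n_g2m = 54, effect = 1,
                                    phase_prob = c(g1 = 0.6, s = 0.2, g2m = 0.2),
                                    amplitude = c(s = 1, g2m = 1.4),
                                    abundance_boost = 1),
                          runs = data.frame(run_id = c("run1", "run2"),
                                            fraction = c(0.5, 0.5),
                                            batch_log_fc = c(0, 0.3),
                                            affected_frac = c(0, 0.1),
                                            alignment_rate = c(0.85, 0.8)),
                          mito = list(n_genes = 10, beta = c(20, 380)),
                          overdispersion = 0,
                          seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), clusters = clusters,
               library_size = library_size, baseline = baseline, cc = cc,
               runs = runs, mito = mito, overdispersion = overdispersion,
               seed = as.integer(seed))
  class(spec) <- "SyntheticSpec"
  validateSyntheticSpec(spec)
  spec
}

validateSyntheticSpec <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  cl <- spec$clusters
  if (any(cl$n_cells <= 0)) stop("cluster cell counts must be > 0")
  if (anyDuplicated(cl$name)) stop("cluster names must be unique")
  if (any(cl$marker_genes < 0)) stop("marker gene counts must be >= 0")
  if (!is.null(cl$marker_ids)) {
    ids <- unlist(cl$marker_ids)
    if (anyDuplicated(ids)) {
      stop("marker gene sets overlap across clusters: gene ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
  }
  n_reserved <- spec$cc$n_s + spec$cc$n_g2m
  if (n_reserved + sum(cl$marker_genes) > spec$n_genes) {
    stop("n_genes too small for the requested cell-cycle modules and markers")
  }
  r <- spec$runs
  if (any(r$fraction < 0 | r$fraction > 1) || abs(sum(r$fraction) - 1) > 1e-8) {
    stop("run fractions must lie in [0, 1] and sum to 1")
  }
  if (any(r$affected_frac < 0 | r$affected_frac > 1)) {
    stop("affected gene fractions must lie in [0, 1]")
  }
  if (any(r$alignment_rate < 0 | r$alignment_rate > 1)) {
    stop("alignment rates must lie in [0, 1]")
  }
  if (spec$library_size[[1]] <= 0 || spec$library_size[[2]] < 0) {
    stop("library size parameters invalid")
  }
  if (spec$overdispersion < 0) stop("overdispersion must be >= 0")
  if (abs(sum(spec$cc$phase_prob) - 1) > 1e-8) {
    stop("cell-cycle phase probabilities must sum to 1")
  }
  invisible(spec)
}

#' Generate a clustered multi-run UMI matrix with ground truth
#'
#' Draws a synthetic dataset from the generative model described in
#' \code{\link{syntheticSpec}}. Ground truth (cluster labels, phase
#' scores, run assignment, realized library composition, marker
#' annotations) is stored in \code{colData}/\code{rowData} and
#' \code{metadata(sce)$truth}.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return A \link[SingleCellExperiment]{SingleCellExperiment} with a
#'   sparse \code{counts} assay. \code{colData} columns:
#'   \code{true_cluster}, \code{run_id}, \code{alignment_rate},
#'   \code{true_s_score}, \code{true_g2m_score}, \code{true_libsize},
#'   \code{true_mito_fraction}. \code{rowData} columns: \code{marker_of},
#'   \code{cc_module}.
#' @export
generateClusteredCounts <- function(spec = syntheticSpec()) {
  validateSyntheticSpec(spec)
  withSeed(spec$seed, {
    cl <- spec$clusters
    n_cells <- sum(cl$n_cells)
    n_genes <- spec$n_genes
    cluster_of <- rep(as.character(cl$name), cl$n_cells)
    barcodes <- sprintf("BC%05d", seq_len(n_cells))

    # gene roles: cell-cycle modules first, then marker blocks
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    cc_s_idx <- seq_len(spec$cc$n_s)
    cc_g2m_idx <- spec$cc$n_s + seq_len(spec$cc$n_g2m)
    marker_of <- rep(NA_character_, n_genes)
    if (is.null(cl$marker_ids)) {
      nxt <- spec$cc$n_s + spec$cc$n_g2m
      marker_idx <- vector("list", nrow(cl))
      for (k in seq_len(nrow(cl))) {
        marker_idx[[k]] <- nxt + seq_len(cl$marker_genes[k])
        nxt <- nxt + cl$marker_genes[k]
      }
    } else {
      marker_idx <- cl$marker_ids
    }
    for (k in seq_len(nrow(cl))) marker_of[marker_idx[[k]]] <- as.character(cl$name[k])

    theta <- rlnorm(n_genes, spec$baseline[[1]], spec$baseline[[2]])
    # cycle-machinery genes are well expressed in real data; without this
    # boost their per-cell counts are too noisy to carry a phase signal
    boost <- spec$cc$abundance_boost
    if (is.null(boost)) boost <- 0
    theta[c(cc_s_idx, cc_g2m_idx)] <- theta[c(cc_s_idx, cc_g2m_idx)] * exp(boost)
    theta <- theta / sum(theta)

    run_id <- sample(as.character(spec$runs$run_id), n_cells, replace = TRUE,
                     prob = spec$runs$fraction)
    align <- rbeta(n_cells, spec$runs$alignment_rate[match(run_id, spec$runs$run_id)] * 200,
                   (1 - spec$runs$alignment_rate[match(run_id, spec$runs$run_id)]) * 200)
    batch_genes <- lapply(seq_len(nrow(spec$runs)), function(r) {
      n_aff <- round(spec$runs$affected_frac[r] * n_genes)
      if (n_aff > 0) sample.int(n_genes, n_aff) else integer(0)
    })

    # phase scores: 3-state mixture (G1 near zero, S-high, G2M-high)
    phase <- sample(c("g1", "s", "g2m"), n_cells, replace = TRUE,
                    prob = spec$cc$phase_prob)
    amp <- spec$cc$amplitude
    if (is.null(amp)) amp <- c(s = 1, g2m = 1)
    s_score <- rnorm(n_cells, 0, 0.1) +
      ifelse(phase == "s", rnorm(n_cells, amp[["s"]], 0.2), 0)
    g2m_score <- rnorm(n_cells, 0, 0.1) +
      ifelse(phase == "g2m", rnorm(n_cells, amp[["g2m"]], 0.2), 0)

    libsize <- rlnorm(n_cells, log(spec$library_size[[1]]), spec$library_size[[2]])
    mito_frac <- rbeta(n_cells, spec$mito$beta[1], spec$mito$beta[2])

    # per-gene x per-cell log rate, assembled cluster/run blockwise
    loglam <- matrix(log(theta), n_genes, n_cells)
    for (k in seq_len(nrow(cl))) {
      idx <- marker_idx[[k]]
      if (length(idx)) {
        cols <- cluster_of == as.character(cl$name[k])
        loglam[idx, cols] <- loglam[idx, cols] + cl$marker_log_fc[k]
      }
    }
    for (r in seq_len(nrow(spec$runs))) {
      idx <- batch_genes[[r]]
      if (length(idx)) {
        cols <- run_id == as.character(spec$runs$run_id[r])
        loglam[idx, cols] <- loglam[idx, cols] + spec$runs$batch_log_fc[r]
      }
    }
    loglam[cc_s_idx, ] <- loglam[cc_s_idx, ] +
      rep(spec$cc$effect * s_score, each = length(cc_s_idx))
    loglam[cc_g2m_idx, ] <- loglam[cc_g2m_idx, ] +
      rep(spec$cc$effect * g2m_score, each = length(cc_g2m_idx))

    lam <- exp(loglam)
    lam <- sweep(lam, 2L, libsize * (1 - mito_frac) / colSums(lam), `*`)
    if (spec$overdispersion > 0) {
      lam <- lam * rgamma(length(lam), shape = 1 / spec$overdispersion,
                          scale = spec$overdispersion)
    }
    counts <- matrix(rpois(length(lam), lam), n_genes, n_cells)

    # mitochondrial pseudo-genes absorb the remaining budget
    n_mt <- spec$mito$n_genes
    if (n_mt > 0) {
      q <- rlnorm(n_mt, 0, 0.5)
      q <- q / sum(q)
      lam_mt <- outer(q, libsize * mito_frac)
      counts <- rbind(counts, matrix(rpois(length(lam_mt), lam_mt), n_mt, n_cells))
      gene_ids <- c(gene_ids, sprintf("MT-%02d", seq_len(n_mt)))
      marker_of <- c(marker_of, rep(NA_character_, n_mt))
    }

    cc_module <- rep(NA_character_, length(gene_ids))
    cc_module[cc_s_idx] <- "S"
    cc_module[cc_g2m_idx] <- "G2M"

    sce <- umiExperiment(counts, gene_ids, barcodes,
                         rowData = S4Vectors::DataFrame(marker_of = marker_of,
                                                        cc_module = cc_module))
    SummarizedExperiment::colData(sce) <- S4Vectors::DataFrame(
      true_cluster = cluster_of, run_id = run_id, alignment_rate = align,
      true_s_score = s_score, true_g2m_score = g2m_score, true_libsize = libsize,
      true_mito_fraction = mito_frac, row.names = barcodes)
    S4Vectors::metadata(sce)$truth <- list(
      spec = spec, theta = stats::setNames(theta, gene_ids[seq_len(n_genes)]),
      batch_genes = lapply(batch_genes, function(i) gene_ids[i]),
      s_genes = gene_ids[cc_s_idx], g2m_genes = gene_ids[cc_g2m_idx],
      phase = phase)
    S4Vectors::metadata(sce)$generator <- list(
      name = "generateClusteredCounts", version = "1",
      package = as.character(packageVersion("scDropletKit")), seed = spec$seed)
    sce
  })
}

#' Split one true cluster into two random halves
#'
#' Produces an artificially over-partitioned labeling: the chosen
#' cluster's cells are split uniformly at random into two new labels of
#' near-equal size, all other labels unchanged. By construction the two
#' halves are statistically exchangeable, so a cluster-merge procedure
#' should reunite them.
#'
#' @param labels named vector of cluster labels (names are barcodes).
#' @param cluster label to split; must have at least 20 cells.
#' @param seed integer RNG seed.
#' @return Named character labels with the chosen cluster replaced by
#'   \code{<cluster>_split1} and \code{<cluster>_split2}.
#' @export
generateOversplit <- function(labels, cluster, seed = 1L) {
  labels <- stats::setNames(as.character(labels), names(labels))
  idx <- which(labels == as.character(cluster))
  if (!length(idx)) stop("cluster '", cluster, "' not present in labels")
  if (length(idx) < 20L) {
    stop("cluster '", cluster, "' has ", length(idx),
         " cells; at least 20 required to split")
  }
  withSeed(seed, {
    half <- sample(idx, floor(length(idx) / 2))
    labels[idx] <- paste0(cluster, "_split2")
    labels[half] <- paste0(cluster, "_split1")
  })
  labels
}

#' Simulate Poisson co-encapsulation of cells and beads into droplets
#'
#' Independent Poisson draws of cell and bead occupancy per droplet, the
#' stochastic loading model of droplet microfluidics.
#'
#' @param lambda_cells,lambda_beads mean occupancy per droplet (>= 0).
#' @param n_droplets number of droplets (> 0).
#' @param seed integer RNG seed.
#' @return A list with \code{droplets} (data.frame of per-droplet
#'   \code{n_cells}, \code{n_beads}), \code{cell_hist} and
#'   \code{bead_hist} (occupancy histograms named by occupancy), and the
#'   simulation parameters.
#' @export
simulateEncapsulation <- function(lambda_cells, lambda_beads, n_droplets,
                                  seed = 1L) {
  if (lambda_cells < 0 || lambda_beads < 0) stop("lambda must be >= 0")
  if (n_droplets <= 0) stop("n_droplets must be > 0")
  withSeed(seed, {
    nc <- rpois(n_droplets, lambda_cells)
    nb <- rpois(n_droplets, lambda_beads)
    histOf <- function(x) {
      tab <- tabulate(x + 1L, nbins = max(x) + 1L)
      stats::setNames(as.numeric(tab), as.character(seq_along(tab) - 1L))
    }
    list(droplets = data.frame(n_cells = nc, n_beads = nb),
         cell_hist = histOf(nc), bead_hist = histOf(nb),
         lambda_cells = lambda_cells, lambda_beads = lambda_beads,
         n_droplets = as.integer(n_droplets), seed = as.integer(seed))
  })
}

#' Generate a two-species (barnyard) mixed UMI matrix
#'
#' Emulates a species-mixing run: a barcode exists only where a bead and
#' at least one cell co-occur, so per-barcode occupancy is zero-truncated
#' Poisson. Each occupant is human with probability \code{species_mix};
#' the barcode's transcripts are allocated to species proportionally to
#' its occupants, each UMI switching species with probability
#' \code{purity_noise} (cross-contamination). Gene rows carry
#' \code{hg_}/\code{mm_} prefixes.
#'
#' @param n_barcodes number of occupied barcodes to emit.
#' @param lambda_cells mean cell occupancy per droplet (> 0).
#' @param species_mix human fraction among loaded cells, in [0, 1].
#' @param purity_noise per-UMI cross-species contamination probability.
#' @param seed integer RNG seed.
#' @param genes_per_species number of gene rows per species.
#' @param mean_umi,umi_sdlog log-normal per-occupant UMI yield.
#' @return A SingleCellExperiment with species-prefixed rows; colData
#'   records the true occupant composition (\code{n_human}, \code{n_mouse},
#'   \code{true_mixed}).
#' @export
generateBarnyard <- function(n_barcodes, lambda_cells, species_mix = 0.5,
                             purity_noise = 0.01, seed = 1L,
                             genes_per_species = 50, mean_umi = 2000,
                             umi_sdlog = 0.3) {
  if (species_mix < 0 || species_mix > 1) stop("species_mix must lie in [0, 1]")
  if (purity_noise < 0 || purity_noise > 0.5) stop("purity_noise must lie in [0, 0.5]")
  if (lambda_cells <= 0) stop("lambda_cells must be > 0 to produce occupied droplets")
  if (n_barcodes <= 0) stop("n_barcodes must be > 0")
  withSeed(seed, {
    # zero-truncated Poisson occupancy via inverse transform
    u <- runif(n_barcodes, dpois(0, lambda_cells), 1)
    k <- qpois(u, lambda_cells)
    n_h <- rbinom(n_barcodes, k, species_mix)
    n_m <- k - n_h
    total <- round(k * rlnorm(n_barcodes, log(mean_umi), umi_sdlog))
    total <- pmax(total, 1L)
    frac_h <- n_h / k
    p_h <- frac_h * (1 - purity_noise) + (1 - frac_h) * purity_noise
    human_umi <- rbinom(n_barcodes, total, p_h)
    mouse_umi <- total - human_umi

    gene_w_h <- rlnorm(genes_per_species, 0, 1)
    gene_w_m <- rlnorm(genes_per_species, 0, 1)
    counts_h <- vapply(seq_len(n_barcodes), function(i)
      rmultinom(1L, human_umi[i], gene_w_h)[, 1L], numeric(genes_per_species))
    counts_m <- vapply(seq_len(n_barcodes), function(i)
      rmultinom(1L, mouse_umi[i], gene_w_m)[, 1L], numeric(genes_per_species))
    counts <- rbind(counts_h, counts_m)
    gene_ids <- c(sprintf("hg_GENE%03d", seq_len(genes_per_species)),
                  sprintf("mm_GENE%03d", seq_len(genes_per_species)))
    barcodes <- sprintf("BY%05d", seq_len(n_barcodes))
    sce <- umiExperiment(counts, gene_ids, barcodes)
    SummarizedExperiment::colData(sce) <- S4Vectors::DataFrame(
      n_human = n_h, n_mouse = n_m, n_cells = k,
      true_mixed = n_h > 0L & n_m > 0L, row.names = barcodes)
    S4Vectors::metadata(sce)$generator <- list(
      name = "generateBarnyard", version = "1", lambda_cells = lambda_cells,
      species_mix = species_mix, purity_noise = purity_noise, seed = as.integer(seed))
    sce
  })
}

#' Generate ERCC spike-in counts under binomial capture
#'
#' For every barcode and ERCC species, the detected molecule count is
#' Binomial(expected molecules per droplet, capture_rate); expectations
#' are rounded to the nearest molecule. This is the binomial-thinning
#' model under which detected abundance ratios track input ratios and
#' mean sensitivity is capture_rate times the total expected input.
#'
#' @param ref an \code{\linkS4class{ErccReference}}.
#' @param capture_rate per-molecule capture probability in (0, 1].
#' @param n_barcodes number of bead barcodes.
#' @param seed integer RNG seed.
#' @return A SingleCellExperiment of ERCC rows by barcodes; the capture
#'   rate per barcode is recorded in colData.
#' @export
generateErcc <- function(ref, capture_rate, n_barcodes, seed = 1L) {
  stopifnot(methods::is(ref, "ErccReference"))
  if (any(capture_rate <= 0) || any(capture_rate > 1)) {
    stop("capture_rate must lie in (0, 1]")
  }
  if (n_barcodes <= 0) stop("n_barcodes must be > 0")
  capture_rate <- rep_len(capture_rate, n_barcodes)
  withSeed(seed, {
    expected <- round(expectedMolecules(ref))
    counts <- vapply(seq_len(n_barcodes), function(b)
      rbinom(length(expected), expected, capture_rate[b]),
      numeric(length(expected)))
    counts <- matrix(counts, nrow = length(expected))  # 1-species refs
    barcodes <- sprintf("EB%05d", seq_len(n_barcodes))
    sce <- umiExperiment(counts, erccIds(ref), barcodes)
    SummarizedExperiment::colData(sce) <- S4Vectors::DataFrame(
      capture_rate = capture_rate, row.names = barcodes)
    S4Vectors::metadata(sce)$generator <- list(
      name = "generateErcc", version = "1", seed = as.integer(seed),
      expected_total = sum(expected))
    sce
  })
}
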
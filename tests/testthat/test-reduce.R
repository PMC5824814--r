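normalizedSmall <- function(seed = 1L, n_clusters = 2, n_cells = 80,
                            n_genes = 300, marker_log_fc = 2) {
  sce <- generateClusteredCounts(smallSpec(n_clusters = n_clusters,
                                           n_cells = n_cells,
                                           n_genes = n_genes,
                                           marker_log_fc = marker_log_fc,
                                           seed = seed))
  sce <- logNormalize(computeCellCovariates(sce))
  regressCovariates(sce, covariates = c("n_umi", "mito_fraction"))
}

test_that("variable-gene statistics match brute force on a toy matrix", {
  set.seed(3)
  m <- matrix(rpois(30 * 40, 5), 30, 40,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:40)))
  m[1, ] <- 7                      # constant nonzero: dispersion 0 -> excluded
  m[30, ] <- max(colSums(m)) - colSums(m[-30, ])   # equalize library sizes
  sce <- logNormalize(scDropletKit:::umiExperiment(m))
  out <- selectVariableGenes(sce, mean_low = 0, mean_high = 100,
                             disp_low = 0.5, disp_high = 30)
  norm <- expm1(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
  mu <- rowMeans(norm)
  disp <- apply(norm, 1, var) / mu
  brute <- rownames(m)[disp >= 0.5 & disp <= 30 &
                         log1p(mu) >= 0 & log1p(mu) <= 100]
  expect_setequal(out$genes, brute)
  expect_false("g01" %in% out$genes)
  expect_equal(unname(out$table$dispersion), unname(disp), tolerance = 1e-12)

  # mean bound excludes a low-expression gene
  low <- rownames(m)[log1p(mu) < 0.05]
  out2 <- selectVariableGenes(sce, mean_low = 0.05, mean_high = 100,
                              disp_low = 0, disp_high = Inf)
  expect_true(!any(low %in% out2$genes))
  expect_error(selectVariableGenes(sce, mean_low = 50, mean_high = 60),
               "no genes")
})

test_that("PCA matches an eigendecomposition oracle and fixes signs", {
  sce <- normalizedSmall(seed = 5L, n_genes = 120, n_cells = 30)
  genes <- rownames(sce)[1:60]
  out <- runPca(sce, genes, k = 5)
  scores <- SingleCellExperiment::reducedDim(out, "PCA")
  meta <- S4Vectors::metadata(out)$pca

  X <- t(as.matrix(SummarizedExperiment::assay(sce, "residuals")[genes, ]))
  ev <- eigen(crossprod(X), symmetric = TRUE)
  for (j in 1:5) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(meta$loadings[, j]), v, tolerance = 1e-8)
    expect_equal(unname(scores[, j]), unname(as.numeric(X %*% v)),
                 tolerance = 1e-8)
  }
  expect_true(all(diff(meta$var_explained) <= 1e-12))
  expect_equal(unname(apply(meta$loadings, 2, function(v) sqrt(sum(v^2)))),
               rep(1, 5), tolerance = 1e-10)
})

test_that("PCA reconstructs exact low-rank data and checks rank", {
  # rank-2 residual matrix: k = 2 reconstructs exactly
  set.seed(8)
  u <- matrix(rnorm(40 * 2), 40, 2)
  v <- matrix(rnorm(25 * 2), 2, 25)
  R <- u %*% v
  R <- t(scale(t(R)))   # per-gene standardized, still rank <= 2
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(matrix(1, 40, 25), sparse = TRUE),
                  residuals = R))
  rownames(sce) <- sprintf("g%02d", 1:40)
  colnames(sce) <- sprintf("c%02d", 1:25)
  out <- runPca(sce, rownames(sce), k = 2)
  sc <- SingleCellExperiment::reducedDim(out, "PCA")
  lo <- S4Vectors::metadata(out)$pca$loadings
  Rm <- as.matrix(SummarizedExperiment::assay(out, "residuals"))
  Rm <- matrix(Rm, nrow(Rm))
  expect_equal(t(Rm), unname(sc %*% t(lo)), tolerance = 1e-8)
  expect_error(runPca(sce, rownames(sce), k = 10), "rank")
})

test_that("neighbor graph has forced topology and brute-force Jaccard weights", {
  pts <- matrix(c(0, 0, 1, 0, 10, 0), 3, 2, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  g <- buildNeighborGraph(pts, n_neighbors = 1)
  el <- igraph::as_edgelist(g)
  expect_true(all(apply(el, 1, paste, collapse = "-") %in%
                    c("a-b", "b-a", "b-c", "c-b")))

  # duplicated coordinates are mutual nearest neighbors
  pts2 <- rbind(pts, d = c(10, 0))
  g2 <- buildNeighborGraph(pts2, n_neighbors = 1)
  expect_true(igraph::are_adjacent(g2, "c", "d"))

  # Jaccard weights vs set computation on random points
  set.seed(13)
  P <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(sprintf("p%02d", 1:50), NULL))
  k <- 6
  g3 <- buildNeighborGraph(P, n_neighbors = k)
  d <- as.matrix(dist(P))
  sets <- lapply(1:50, function(i) c(i, order(d[i, ])[2:(k + 1)]))
  el3 <- igraph::as_edgelist(g3, names = FALSE)
  w3 <- igraph::E(g3)$weight
  for (e in seq_len(nrow(el3))) {
    i <- el3[e, 1]; j <- el3[e, 2]
    jac <- length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
    expect_equal(w3[e], jac, tolerance = 1e-12)
  }
  expect_error(buildNeighborGraph(pts, n_neighbors = 5), "smaller")
})

test_that("Louvain separates two cliques and is seed-reproducible", {
  g <- igraph::make_full_graph(8)
  g2 <- igraph::make_full_graph(8)
  gg <- igraph::disjoint_union(g, g2)
  gg <- igraph::add_edges(gg, c(1, 9))
  igraph::E(gg)$weight <- 1
  igraph::V(gg)$name <- sprintf("v%02d", 1:16)
  lab <- louvainCluster(gg, resolution = 1, seed = 3L)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:8])), 1)
  expect_equal(length(unique(lab[9:16])), 1)
  expect_identical(louvainCluster(gg, resolution = 1, seed = 3L), lab)
  expect_error(louvainCluster(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("clustering recovers planted subpopulations on synthetic data", {
  sce <- normalizedSmall(seed = 17L, n_clusters = 4, n_cells = 60,
                         n_genes = 400)
  vg <- selectVariableGenes(sce)
  sce <- runPca(sce, vg$genes, k = 8)
  g <- buildNeighborGraph(sce, n_neighbors = 15)
  lab <- louvainCluster(g, seed = 1L)
  ari <- adjustedRand(lab, colDataOf(sce)$true_cluster)
  expect_gte(ari, 0.9)
})

test_that("rfMerge reunites an artificial oversplit and keeps real structure", {
  sce <- normalizedSmall(seed = 23L, n_clusters = 2, n_cells = 100,
                         n_genes = 400)
  vg <- selectVariableGenes(sce)
  truth <- setNames(colDataOf(sce)$true_cluster, colnames(sce))

  # split one true cluster at random: exchangeable halves, OOB ~ 0.5
  split_lab <- generateOversplit(truth, "C1", seed = 2L)
  out <- rfMerge(sce, split_lab, vg$genes, threshold = 0.11, seed = 7L)
  expect_equal(length(unique(out$labels)), 2)
  expect_equal(adjustedRand(out$labels, truth), 1)
  merged_row <- out$merge_history[out$merge_history$action == "merged", ]
  expect_equal(nrow(merged_row), 1)
  expect_gt(merged_row$oob_error, 0.3)

  # two genuinely distinct clusters stay apart
  out2 <- rfMerge(sce, truth, vg$genes, threshold = 0.11, seed = 7L)
  expect_equal(length(unique(out2$labels)), 2)
  expect_true(all(out2$merge_history$action == "retained"))
  expect_true(all(out2$merge_history$oob_error < 0.11))
})

test_that("merge threshold boundaries behave as the rule dictates", {
  sce <- normalizedSmall(seed = 29L, n_clusters = 2, n_cells = 60,
                         n_genes = 300)
  vg <- selectVariableGenes(sce)
  truth <- setNames(colDataOf(sce)$true_cluster, colnames(sce))
  # threshold >= 1: no pair can exceed it, nothing merges
  hi <- rfMerge(sce, truth, vg$genes, threshold = 1, seed = 1L)
  expect_equal(length(unique(hi$labels)), 2)
  # threshold 0 with indistinguishable halves: everything collapses
  split_lab <- generateOversplit(
    setNames(rep("C1", ncol(sce)), colnames(sce)), "C1", seed = 3L)
  lo <- rfMerge(sce, split_lab, vg$genes, threshold = 0, seed = 1L)
  expect_equal(length(unique(lo$labels)), 1)
  # single cluster: returned unchanged with empty history
  one <- rfMerge(sce, setNames(rep("A", ncol(sce)), colnames(sce)), vg$genes)
  expect_equal(length(unique(one$labels)), 1)
  expect_equal(nrow(one$merge_history), 0)
})

test_that("merge history reconstructs the final labeling and terminates", {
  sce <- normalizedSmall(seed = 31L, n_clusters = 3, n_cells = 60,
                         n_genes = 300)
  vg <- selectVariableGenes(sce)
  truth <- setNames(colDataOf(sce)$true_cluster, colnames(sce))
  lab <- generateOversplit(truth, "C2", seed = 5L)
  out <- rfMerge(sce, lab, vg$genes, seed = 9L)
  n_merges <- sum(out$merge_history$action == "merged")
  expect_lte(n_merges, length(unique(lab)) - 1)
  # replay the history over the initial labels
  replay <- setNames(as.character(lab), names(lab))
  for (i in seq_len(nrow(out$merge_history))) {
    row <- out$merge_history[i, ]
    if (row$action == "merged") {
      replay[replay == row$cluster_b] <- row$cluster_a
    }
  }
  expect_equal(adjustedRand(replay, out$labels), 1)
  expect_identical(rfMerge(sce, lab, vg$genes, seed = 9L)$labels, out$labels)
})

test_that("subclustering exposes planted substructure and namespaces labels", {
  # global structure: two well-separated clusters; one hides two sub-states
  spec <- syntheticSpec(
    n_genes = 400,
    clusters = data.frame(name = c("A1", "A2", "B"),
                          n_cells = c(60, 60, 80),
                          marker_genes = c(12, 12, 25),
                          marker_log_fc = c(1.5, 1.5, 4)),
    library_size = c(median = 6000, sdlog = 0.15),
    cc = smallCc(0), runs = oneRun(),
    mito = list(n_genes = 5, beta = c(20, 380)),
    seed = 37L)
  sce <- generateClusteredCounts(spec)
  sce <- regressCovariates(logNormalize(computeCellCovariates(sce)),
                           covariates = c("n_umi", "mito_fraction"))
  cd <- colDataOf(sce)
  coarse <- setNames(ifelse(cd$true_cluster == "B", "B", "A"), colnames(sce))
  sub <- subcluster(sce, coarse, "A", k_pcs = 6, n_neighbors = 10, seed = 1L)
  expect_true(all(startsWith(sub, "A.")))
  expect_setequal(names(sub), colnames(sce)[cd$true_cluster != "B"])
  ari <- adjustedRand(sub, cd$true_cluster[match(names(sub), colnames(sce))])
  expect_gte(ari, 0.8)
  # running on everything reproduces the global procedure's granularity
  expect_error(subcluster(sce, coarse, "missing"), "at least 50")
})

test_that("t-SNE embedding has the right shape and is deterministic", {
  sce <- normalizedSmall(seed = 41L, n_clusters = 2, n_cells = 50,
                         n_genes = 300)
  vg <- selectVariableGenes(sce)
  sce <- runPca(sce, vg$genes, k = 5)
  xy <- embed2d(sce, seed = 4L)
  expect_identical(dim(xy), c(100L, 2L))
  expect_identical(rownames(xy), colnames(sce))
  expect_identical(embed2d(sce, seed = 4L), xy)
  # well-separated clusters keep positive silhouette in 2-D
  truth <- colDataOf(sce)$true_cluster
  d <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- mean(d[i, truth == truth[i] & seq_len(nrow(xy)) != i])
    oth <- mean(d[i, truth != truth[i]])
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})
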
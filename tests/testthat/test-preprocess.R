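# 6-cell toy matrix realizing exact (n_gene, n_umi) covariate pairs
toyQcSce <- function() {
  pairs <- list(c(500, 4000), c(499, 9000), c(2000, 3999),
                c(600, 4000), c(700, 13001), c(900, 12000))
  n_genes <- 2000
  m <- matrix(0, n_genes, length(pairs),
              dimnames = list(sprintf("G%04d", 1:n_genes),
                              sprintf("cell%d", seq_along(pairs))))
  for (j in seq_along(pairs)) {
    ng <- pairs[[j]][1]; nu <- pairs[[j]][2]
    m[seq_len(ng), j] <- 1
    m[1, j] <- nu - (ng - 1)
  }
  sce <- scDropletKit:::umiExperiment(m)
  computeCellCovariates(sce,
                        run_map = setNames(rep("r1", 6), colnames(m)),
                        align_map = setNames(rep(0.9, 6), colnames(m)))
}

test_that("covariates follow forced arithmetic on a tiny example", {
  m <- matrix(c(3, 1), 2, 1, dimnames = list(c("GAPDH", "MT-CO1"), "cellA"))
  sce <- scDropletKit:::umiExperiment(m)
  sce <- computeCellCovariates(sce, run_map = c(cellA = "r1"),
                               align_map = c(cellA = 0.8))
  cd <- colDataOf(sce)
  expect_equal(cd$n_umi, 4)
  expect_equal(cd$n_gene, 2)
  expect_equal(cd$mito_fraction, 0.25)

  # no MT- genes: mito fraction identically zero
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("c1", "c2")))
  sce2 <- computeCellCovariates(scDropletKit:::umiExperiment(m2),
                                run_map = c(c1 = "r", c2 = "r"),
                                align_map = c(c1 = 1, c2 = 1))
  expect_equal(colDataOf(sce2)$mito_fraction, c(0, 0))
})

test_that("covariates match generator truth and error on incomplete maps", {
  sce <- generateClusteredCounts(smallSpec(seed = 11L))
  out <- computeCellCovariates(sce)
  expect_equal(colDataOf(out)$n_umi,
               unname(Matrix::colSums(SummarizedExperiment::assay(sce, "counts"))))
  expect_error(
    computeCellCovariates(sce, run_map = c(BC00001 = "r1")),
    "missing from run_map")
  expect_warning(
    computeCellCovariates(
      SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = SummarizedExperiment::assay(sce, "counts"))),
      run_map = setNames(rep("r1", ncol(sce)), colnames(sce))),
    "defaulting to 1.0")
})

test_that("cell filtering applies the 500/4000/13000 rules with kept boundaries", {
  sce <- toyQcSce()
  out <- filterCells(sce)
  expect_identical(colnames(out), c("cell1", "cell4", "cell6"))
  qc <- S4Vectors::metadata(out)$qc_cell_filter
  expect_equal(qc$n_kept, 3)
  expect_equal(qc$removed_low_gene, 1)   # cell2 (499 genes)
  expect_equal(qc$removed_low_umi, 1)    # cell3 (3999 UMIs)
  expect_equal(qc$removed_high_umi, 1)   # cell5 (13001 UMIs)

  # filtering is idempotent
  again <- filterCells(out)
  expect_identical(colnames(again), colnames(out))

  expect_error(filterCells(sce, min_umi = 20000, max_umi = 30000), "all cells")
  expect_error(filterCells(sce, min_umi = 5000, max_umi = 4000), "min_umi")
})

test_that("gene filtering keeps genes detected in >= min_cells cells", {
  m <- matrix(0, 4, 5, dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  m[1, 1:3] <- 1   # exactly 3 cells -> kept
  m[2, 1:2] <- 5   # 2 cells -> dropped
  m[3, ] <- 2      # all cells -> kept
  sce <- filterGenes(scDropletKit:::umiExperiment(m))
  expect_identical(rownames(sce), c("g1", "g3"))

  # brute-force recount oracle on a random sparse matrix
  r <- randomCountsSce(60, 30, density = 0.08, seed = 12)
  kept <- rownames(filterGenes(r, min_cells = 3))
  brute <- rownames(r)[apply(countsOf(r) > 0, 1, sum) >= 3]
  expect_identical(kept, brute)
})

test_that("normalization matches the closed form and conserves totals", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  sce <- logNormalize(scDropletKit:::umiExperiment(m))
  v <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  expect_equal(as.numeric(v), log(c(2501, 2501, 5001)))

  syn <- logNormalize(generateClusteredCounts(smallSpec(seed = 2L)))
  lc <- SummarizedExperiment::assay(syn, "logcounts")
  sums <- Matrix::colSums(expm1(as.matrix(lc)))
  expect_true(all(abs(sums - 10000) / 10000 < 1e-6))
  # zero counts stay exactly zero
  zero_at <- which(countsOf(syn) == 0)[1]
  expect_identical(as.numeric(as.matrix(lc)[zero_at]), 0)

  z <- matrix(c(1, 0), 1, 2, dimnames = list("g", c("ok", "empty")))
  expect_error(logNormalize(scDropletKit:::umiExperiment(z)), "zero-total")
})

ccFixture <- function(n_cells = 1200, seed = 21L, n_genes = 1500) {
  spec <- syntheticSpec(
    n_genes = n_genes,
    clusters = data.frame(name = "C1", n_cells = n_cells, marker_genes = 0,
                          marker_log_fc = 0),
    seed = seed)
  sce <- generateClusteredCounts(spec)
  sce <- logNormalize(computeCellCovariates(sce))
  sce
}

test_that("cell-cycle scores recover the planted phase structure", {
  sce <- ccFixture(n_cells = 2000, seed = 11L, n_genes = 2000)
  truth <- S4Vectors::metadata(sce)$truth
  sce <- scoreCellCycle(sce, truth$s_genes, truth$g2m_genes)
  cd <- colDataOf(sce)
  expect_gte(cor(cd$s_score, cd$true_s_score), 0.8)
  expect_gte(cor(cd$g2m_score, cd$true_g2m_score), 0.8)
  # positive orientation against own module mean is guaranteed by construction
  lc <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  expect_gt(cor(cd$s_score, colMeans(lc[truth$s_genes, ])), 0)
  expect_gt(cor(cd$g2m_score, colMeans(lc[truth$g2m_genes, ])), 0)
})

test_that("cell-cycle scoring is equivariant under cell permutation", {
  sce <- ccFixture(n_cells = 300, seed = 31L)
  truth <- S4Vectors::metadata(sce)$truth
  a <- scoreCellCycle(sce, truth$s_genes, truth$g2m_genes)
  perm <- sample(ncol(sce))
  b <- scoreCellCycle(sce[, perm], truth$s_genes, truth$g2m_genes)
  expect_equal(colDataOf(b)$s_score, colDataOf(a)$s_score[perm], tolerance = 1e-6)
  expect_equal(colDataOf(b)$g2m_score, colDataOf(a)$g2m_score[perm], tolerance = 1e-6)
})

test_that("cell-cycle scoring flags degenerate inputs", {
  m <- matrix(5, 12, 30, dimnames = list(sprintf("cc%02d", 1:12),
                                         sprintf("c%02d", 1:30)))
  sce <- logNormalize(scDropletKit:::umiExperiment(m))
  expect_error(suppressWarnings(scoreCellCycle(sce, rownames(m)[1:6], rownames(m)[7:12])),
               "degenerate|constant")
  expect_error(scoreCellCycle(sce, rownames(m)[1:3], rownames(m)[7:12]),
               ">= 5")
})

test_that("regression removes planted covariate effects and standardizes", {
  sce <- ccFixture(n_cells = 800, seed = 41L)
  truth <- S4Vectors::metadata(sce)$truth
  sce <- scoreCellCycle(sce, truth$s_genes, truth$g2m_genes)
  sce <- regressCovariates(sce)
  res <- SummarizedExperiment::assay(sce, "residuals")
  # per-gene standardization (zero-variance rows all-zero)
  rm_ <- rowMeans(res); rs <- apply(res, 1, sd)
  nz <- rs > 0
  expect_true(all(abs(rm_[nz]) < 1e-6))
  expect_true(all(abs(rs[nz] - 1) < 1e-6))
  # planted cycle effect is removed on average
  cd <- colDataOf(sce)
  cS <- apply(res[truth$s_genes, ], 1, cor, y = cd$true_s_score)
  expect_lt(mean(abs(cS)), 0.05)
})

test_that("a gene exactly linear in n_umi leaves an all-zero residual row", {
  sce <- ccFixture(n_cells = 200, seed = 51L)
  truth <- S4Vectors::metadata(sce)$truth
  sce <- scoreCellCycle(sce, truth$s_genes, truth$g2m_genes)
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  lc <- as.matrix(lc)
  lc[1, ] <- 0.5 + 2e-4 * colDataOf(sce)$n_umi
  SummarizedExperiment::assay(sce, "logcounts") <- lc
  sce <- regressCovariates(sce)
  expect_true(all(SummarizedExperiment::assay(sce, "residuals")[1, ] == 0))
})

test_that("intercept-only regression reduces to per-gene z-scores", {
  sce <- ccFixture(n_cells = 150, seed = 61L)
  sce <- regressCovariates(sce, covariates = character(0))
  res <- SummarizedExperiment::assay(sce, "residuals")
  lc <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  z <- t(scale(t(lc)))
  z[!is.finite(z)] <- 0
  z <- matrix(z, nrow(z))
  expect_equal(matrix(res, nrow(res)), z, tolerance = 1e-10)
})

test_that("collinear or constant design columns are dropped with a warning", {
  spec <- smallSpec(n_clusters = 1, n_cells = 150, n_genes = 300,
                    marker_genes = 0, seed = 71L)
  sce <- logNormalize(computeCellCovariates(generateClusteredCounts(spec)))
  # single run: the run indicator is constant and dropped, never silently
  expect_warning(regressCovariates(sce, covariates = c("n_umi", "run_id")),
                 "constant")
  cd <- colDataOf(sce)
  cd$dup <- cd$n_umi * 2
  SummarizedExperiment::colData(sce) <- cd
  expect_warning(regressCovariates(sce, covariates = c("n_umi", "dup")),
                 "collinear")
})
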
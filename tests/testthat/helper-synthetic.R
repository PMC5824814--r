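# Small, fast synthetic specs used across the unit tests.

smallCc <- function(effect = 1) {
  list(n_s = 10, n_g2m = 10, effect = effect,
       phase_prob = c(g1 = 0.6, s = 0.2, g2m = 0.2),
       amplitude = c(s = 1, g2m = 1.4), abundance_boost = 1)
}

oneRun <- function() {
  data.frame(run_id = "run1", fraction = 1, batch_log_fc = 0,
             affected_frac = 0, alignment_rate = 0.85)
}

smallSpec <- function(n_clusters = 2, n_cells = 60, n_genes = 400,
                      marker_genes = 15, marker_log_fc = 2, seed = 1L,
                      cc_effect = 0, runs = oneRun(), library_median = 6000) {
  syntheticSpec(
    n_genes = n_genes,
    clusters = data.frame(name = paste0("C", seq_len(n_clusters)),
                          n_cells = n_cells, marker_genes = marker_genes,
                          marker_log_fc = marker_log_fc),
    library_size = c(median = library_median, sdlog = 0.15),
    cc = smallCc(cc_effect),
    runs = runs,
    mito = list(n_genes = 5, beta = c(20, 380)),
    seed = seed)
}

# random sparse nonnegative-integer count matrix for I/O round-trip tests
randomCountsSce <- function(n_genes, n_cells, density = 0.3, max_count = 20,
                            seed = 1L) {
  set.seed(seed)
  nnz <- max(1L, round(n_genes * n_cells * density))
  idx <- sample.int(n_genes * n_cells, nnz)
  m <- matrix(0, n_genes, n_cells)
  m[idx] <- sample.int(max_count, nnz, replace = TRUE)
  rownames(m) <- sprintf("G%03d", seq_len(n_genes))
  colnames(m) <- sprintf("BC%03d", seq_len(n_cells))
  scDropletKit:::umiExperiment(m)
}

countsOf <- function(sce) as.matrix(SummarizedExperiment::assay(sce, "counts"))

colDataOf <- function(sce) SummarizedExperiment::colData(sce)

# toy ERCC reference with explicit concentrations (amol/uL)
toyErccRef <- function(conc, ids = sprintf("ERCC-T%02d", seq_along(conc)),
                       volume_nl = 1, dilution = 1) {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(id = ids, conc = conc), f, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  on.exit(unlink(f))
  readErccReference(f, volume_nl = volume_nl, dilution = dilution)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
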
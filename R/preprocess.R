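#' Compute per-cell technical covariates
#'
#' Populates the per-barcode covariates used for QC filtering and
#' covariate regression: total UMIs, genes detected, mitochondrial UMI
#' fraction (genes prefixed \code{MT-}), run identity and transcriptome
#' alignment rate.
#'
#' @param sce a SingleCellExperiment with a \code{counts} assay.
#' @param run_map named character vector mapping every barcode to a run
#'   id; may be NULL when colData already carries \code{run_id}.
#' @param align_map named numeric vector mapping barcodes to alignment
#'   rates in [0, 1]; defaults to 1.0 with a warning when absent.
#' @return \code{sce} with colData columns \code{n_umi}, \code{n_gene},
#'   \code{mito_fraction}, \code{run_id}, \code{alignment_rate}.
#' @export
computeCellCovariates <- function(sce, run_map = NULL, align_map = NULL) {
  counts <- getCounts(sce)
  barcodes <- colnames(counts)
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(run_map)) {
    if (!"run_id" %in% names(cd)) {
      stop("no run_map supplied and colData has no 'run_id' column")
    }
    run <- as.character(cd$run_id)
  } else {
    missing <- setdiff(barcodes, names(run_map))
    if (length(missing)) {
      stop("barcodes missing from run_map: ",
           paste(head(missing, 10L), collapse = ", "),
           if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L))
    }
    run <- as.character(run_map[barcodes])
  }
  if (is.null(align_map)) {
    if ("alignment_rate" %in% names(cd)) {
      align <- as.numeric(cd$alignment_rate)
    } else {
      warning("no alignment rates supplied; defaulting to 1.0 for all barcodes")
      align <- rep(1, length(barcodes))
    }
  } else {
    missing <- setdiff(barcodes, names(align_map))
    if (length(missing)) {
      stop("barcodes missing from align_map: ",
           paste(head(missing, 10L), collapse = ", "))
    }
    align <- as.numeric(align_map[barcodes])
  }
  n_umi <- Matrix::colSums(counts)
  n_gene <- Matrix::colSums(counts > 0)
  mt <- grepl("^MT-", rownames(counts))
  mito <- if (any(mt)) {
    mumi <- Matrix::colSums(counts[mt, , drop = FALSE])
    ifelse(n_umi > 0, mumi / n_umi, 0)
  } else {
    rep(0, length(barcodes))
  }
  cd$n_umi <- as.numeric(n_umi)
  cd$n_gene <- as.numeric(n_gene)
  cd$mito_fraction <- as.numeric(mito)
  cd$run_id <- run
  cd$alignment_rate <- align
  SummarizedExperiment::colData(sce) <- cd
  sce
}

#' Filter low-quality cells and likely doublets
#'
#' Keeps a barcode iff it has at least \code{min_genes} detected genes and
#' a UMI total inside \code{[min_umi, max_umi]} (boundaries kept: the
#' rules remove strictly-fewer and strictly-greater cells). The UMI
#' ceiling targets droplet doublets. Counts removed per rule are recorded
#' in \code{metadata(sce)$qc_cell_filter}.
#'
#' @param sce SingleCellExperiment with covariates from
#'   \code{\link{computeCellCovariates}}.
#' @param min_genes,min_umi,max_umi QC thresholds; defaults 500 genes and
#'   a 4000--13000 UMI window.
#' @return The filtered SingleCellExperiment, column order preserved.
#' @export
filterCells <- function(sce, min_genes = 500, min_umi = 4000, max_umi = 13000) {
  stopifnot(min_genes >= 0, min_umi >= 0)
  if (min_umi > max_umi) stop("min_umi must be <= max_umi")
  cd <- SummarizedExperiment::colData(sce)
  if (!all(c("n_umi", "n_gene") %in% names(cd))) {
    stop("run computeCellCovariates() before filterCells()")
  }
  low_gene <- cd$n_gene < min_genes
  low_umi <- cd$n_umi < min_umi
  high_umi <- cd$n_umi > max_umi
  keep <- !(low_gene | low_umi | high_umi)
  if (!any(keep)) {
    stop("all cells removed by QC filtering; review thresholds (min_genes=",
         min_genes, ", min_umi=", min_umi, ", max_umi=", max_umi, ")")
  }
  out <- sce[, keep]
  S4Vectors::metadata(out)$qc_cell_filter <- list(
    n_input = ncol(sce), n_kept = sum(keep),
    removed_low_gene = sum(low_gene), removed_low_umi = sum(low_umi),
    removed_high_umi = sum(high_umi),
    thresholds = c(min_genes = min_genes, min_umi = min_umi, max_umi = max_umi))
  out
}

#' Filter rarely detected genes
#'
#' Keeps a gene iff its count is nonzero in at least \code{min_cells}
#' barcodes. Intended to run after \code{\link{filterCells}} so detection
#' is assessed on QC-passing cells only.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay.
#' @param min_cells minimum number of expressing cells (default 3).
#' @return The gene-filtered SingleCellExperiment, row order preserved.
#' @export
filterGenes <- function(sce, min_cells = 3) {
  stopifnot(min_cells >= 1)
  counts <- getCounts(sce)
  keep <- Matrix::rowSums(counts > 0) >= min_cells
  out <- sce[keep, ]
  S4Vectors::metadata(out)$qc_gene_filter <- list(
    n_input = nrow(sce), n_kept = sum(keep), min_cells = min_cells)
  out
}

#' Library-size normalize and log-transform
#'
#' value(g, c) = log1p(count(g, c) * scale_factor / n_umi(c)): counts are
#' scaled by the cell's total transcripts, multiplied by
#' \code{scale_factor}, and natural-log transformed with log1p. The
#' per-cell sum of expm1(value) therefore equals \code{scale_factor}.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay and no
#'   zero-total barcode (guaranteed after \code{\link{filterCells}}).
#' @param scale_factor library-size scale (default 10000).
#' @return \code{sce} with a sparse \code{logcounts} assay and
#'   normalization provenance in metadata.
#' @export
logNormalize <- function(sce, scale_factor = 10000) {
  counts <- getCounts(sce)
  n_umi <- Matrix::colSums(counts)
  if (any(n_umi == 0)) {
    stop("zero-total barcode(s): ",
         paste(head(colnames(counts)[n_umi == 0], 5L), collapse = ", "))
  }
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / n_umi)
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  S4Vectors::metadata(sce)$normalization <- list(scale_factor = scale_factor,
                                                 transform = "log1p")
  sce
}

#' Score cell-cycle phase activity by PCA on annotated cycle genes
#'
#' Performs PCA restricted to the union of the S-phase and G2/M module
#' genes (per-gene centered, unscaled) and assigns the two leading
#' component scores to the S and G2/M phases by maximal absolute Pearson
#' correlation with each module's mean expression, then orients each
#' score to correlate positively with its own module. The correlation
#' table is kept as orientation metadata.
#'
#' @param sce SingleCellExperiment with \code{logcounts}.
#' @param s_genes,g2m_genes character vectors of module gene symbols; at
#'   least 5 of each must be present in the matrix (a warning is issued
#'   below 20).
#' @return \code{sce} with colData columns \code{s_score} and
#'   \code{g2m_score} (overwriting any previous values) and
#'   \code{metadata(sce)$cell_cycle} holding the correlation table.
#' @export
scoreCellCycle <- function(sce, s_genes, g2m_genes) {
  expr <- getLogcounts(sce)
  s_in <- intersect(s_genes, rownames(expr))
  g2m_in <- intersect(g2m_genes, rownames(expr))
  for (nm in list(c("S", length(s_in)), c("G2M", length(g2m_in)))) {
    n <- as.integer(nm[2])
    if (n < 5L) stop("only ", n, " ", nm[1], "-phase genes present; >= 5 required")
    if (n < 20L) warning("only ", n, " ", nm[1], "-phase genes present")
  }
  genes <- union(s_in, g2m_in)
  x <- t(as.matrix(expr[genes, , drop = FALSE]))   # cells x genes
  x <- sweep(x, 2L, colMeans(x))
  if (all(abs(x) < 1e-12)) {
    stop("degenerate cell-cycle structure: all module genes are constant")
  }
  sv <- svd(x, nu = 2L, nv = 2L)
  scores <- sv$u %*% diag(sv$d[1:2], 2L, 2L)
  mean_s <- colMeans(t(x)[match(s_in, genes), , drop = FALSE])
  mean_g2m <- colMeans(t(x)[match(g2m_in, genes), , drop = FALSE])
  ct <- rbind(S = c(cor(scores[, 1L], mean_s), cor(scores[, 2L], mean_s)),
              G2M = c(cor(scores[, 1L], mean_g2m), cor(scores[, 2L], mean_g2m)))
  colnames(ct) <- c("PC1", "PC2")
  best <- apply(abs(ct), 2L, which.max)   # per PC, which module wins
  if (best[1L] == best[2L]) {
    stop("degenerate cell-cycle structure: both components best match the ",
         c("S", "G2M")[best[1L]], " module; correlations: ",
         paste(capture.output(print(round(ct, 3)))[-1], collapse = " | "))
  }
  pc_s <- which(best == 1L)
  pc_g2m <- which(best == 2L)
  s_score <- scores[, pc_s] * sign(ct["S", pc_s])
  g2m_score <- scores[, pc_g2m] * sign(ct["G2M", pc_g2m])
  cd <- SummarizedExperiment::colData(sce)
  cd$s_score <- as.numeric(s_score)
  cd$g2m_score <- as.numeric(g2m_score)
  SummarizedExperiment::colData(sce) <- cd
  S4Vectors::metadata(sce)$cell_cycle <- list(
    correlations = ct, s_component = unname(pc_s), g2m_component = unname(pc_g2m),
    n_s_genes = length(s_in), n_g2m_genes = length(g2m_in))
  sce
}

#' Regress technical covariates out of log-normalized expression
#'
#' Fits an ordinary least-squares model per gene predicting
#' log-normalized expression from the cell-cycle scores, total UMIs,
#' mitochondrial fraction, run indicator contrasts and alignment rate
#' (the available subset of \code{covariates}), and returns the per-gene
#' z-scored residuals as corrected expression. Collinear design columns
#' are dropped with a warning, never silently. Genes with zero residual
#' variance are carried as all-zero rows.
#'
#' @param sce SingleCellExperiment with \code{logcounts} and colData
#'   covariates.
#' @param covariates colData columns to regress on; character run ids are
#'   expanded to indicator contrasts.
#' @return \code{sce} with a dense \code{residuals} assay (rows mean 0,
#'   sd 1) and the model description in \code{metadata(sce)$regression}.
#' @export
regressCovariates <- function(sce,
                              covariates = c("s_score", "g2m_score", "n_umi",
                                             "mito_fraction", "run_id",
                                             "alignment_rate")) {
  expr <- getLogcounts(sce)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  missing <- setdiff(covariates, names(cd))
  if (length(missing)) {
    stop("covariates absent from colData: ", paste(missing, collapse = ", "))
  }
  if (length(covariates)) {
    df <- cd[, covariates, drop = FALSE]
    for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    # single-level factors carry no information; drop with notice
    const <- vapply(df, function(v) length(unique(v)) <= 1L, logical(1))
    if (any(const)) {
      warning("dropping constant covariate(s): ",
              paste(names(df)[const], collapse = ", "))
      df <- df[, !const, drop = FALSE]
    }
    X <- if (ncol(df)) stats::model.matrix(~ ., df) else
      matrix(1, nrow(cd), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- matrix(1, nrow(cd), 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (ncol(expr) < ncol(X) + 2L) {
    stop("need at least ", ncol(X) + 2L, " cells for ", ncol(X), " predictors")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning("rank-deficient design; dropping collinear column(s): ",
            paste(drop_cols, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  Y <- t(as.matrix(expr))                 # cells x genes
  R <- qr.resid(qrX, Y)
  sds <- apply(R, 2L, sd)
  zero <- sds < 1e-12
  R[, !zero] <- scale(R[, !zero, drop = FALSE], center = TRUE, scale = TRUE)
  R[, zero] <- 0
  SummarizedExperiment::assay(sce, "residuals") <- t(R)
  S4Vectors::metadata(sce)$regression <- list(
    covariates = covariates, design_columns = colnames(X),
    n_zero_variance = sum(zero))
  sce
}
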
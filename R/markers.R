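# Vectorized two-sided Wilcoxon rank-sum test (normal approximation with
# tie correction, no continuity correction) of each row of `expr` between
# the cells in `in_idx` and everything else in `out_idx`.
rankSumTest <- function(expr, in_idx, out_idx) {
  n1 <- length(in_idx)
  n2 <- length(out_idx)
  n <- n1 + n2
  cols <- c(in_idx, out_idx)
  p <- apply(expr[, cols, drop = FALSE], 1L, function(x) {
    r <- rank(x)
    R1 <- sum(r[seq_len(n1)])
    U <- R1 - n1 * (n1 + 1) / 2
    ties <- table(x)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  })
  p
}

#' One-vs-rest Wilcoxon marker detection for a cluster
#'
#' Tests every gene (passing the detection filter) for differential
#' expression between the chosen cluster and all remaining cells, using a
#' two-sided Wilcoxon rank-sum test with normal approximation and tie
#' correction. P-values are Bonferroni-adjusted over the number of genes
#' actually tested. The log fold change is the difference of mean
#' log-normalized expression (cluster minus rest).
#'
#' @param sce SingleCellExperiment with \code{logcounts}.
#' @param labels named cluster labels.
#' @param cluster label to test (one-vs-rest); needs >= 3 cells in and out.
#' @param min_pct detection filter: a gene is tested only when detected
#'   in at least this fraction of cells on either side (default 0.1).
#' @param genes optional restriction of the testing universe.
#' @return A \link[S4Vectors]{DataFrame} sorted by adjusted p then
#'   decreasing |avg_log_fc|, with columns gene, cluster, p_value, p_adj,
#'   avg_log_fc, pct_in, pct_out; the number of genes tested and the
#'   filter are in its metadata.
#' @export
wilcoxonMarkers <- function(sce, labels, cluster, min_pct = 0.1, genes = NULL) {
  expr <- getLogcounts(sce)
  labels <- stats::setNames(as.character(labels),
                            if (is.null(names(labels))) colnames(expr) else names(labels))
  in_idx <- match(names(labels)[labels == as.character(cluster)], colnames(expr))
  out_idx <- match(names(labels)[labels != as.character(cluster)], colnames(expr))
  if (!length(in_idx)) stop("cluster '", cluster, "' not present in labels")
  if (length(in_idx) < 3L || length(out_idx) < 3L) {
    stop("need at least 3 cells in and out of the cluster")
  }
  if (is.null(genes)) genes <- rownames(expr)
  expr <- expr[genes, , drop = FALSE]
  pct_in <- Matrix::rowMeans(expr[, in_idx, drop = FALSE] > 0)
  pct_out <- Matrix::rowMeans(expr[, out_idx, drop = FALSE] > 0)
  tested <- pmax(pct_in, pct_out) >= min_pct
  if (!any(tested)) stop("no genes pass the min_pct detection filter")
  sub <- as.matrix(expr[tested, , drop = FALSE])
  p <- rankSumTest(sub, in_idx, out_idx)
  lfc <- rowMeans(sub[, in_idx, drop = FALSE]) - rowMeans(sub[, out_idx, drop = FALSE])
  n_tested <- sum(tested)
  res <- S4Vectors::DataFrame(
    gene = rownames(sub), cluster = as.character(cluster),
    p_value = unname(p), p_adj = pmin(1, unname(p) * n_tested),
    avg_log_fc = unname(lfc),
    pct_in = unname(pct_in[tested]), pct_out = unname(pct_out[tested]))
  res <- res[order(res$p_adj, -abs(res$avg_log_fc)), ]
  S4Vectors::metadata(res) <- list(n_tested = n_tested, min_pct = min_pct,
                                   n_in = length(in_idx), n_out = length(out_idx),
                                   lfc_definition = "difference of mean log1p-normalized expression (cluster - rest)")
  res
}

#' Pseudobulk ("in silico average") expression profiles
#'
#' Per-gene arithmetic mean of log-normalized expression within each
#' group of cells, the single-cell substitute for bulk RNA-seq of sorted
#' populations.
#'
#' @param sce SingleCellExperiment with \code{logcounts}.
#' @param grouping named group labels (names = barcodes), or the name of
#'   a colData column.
#' @return genes x groups matrix of mean expression with an
#'   \code{n_cells} attribute (named integer vector).
#' @export
pseudobulk <- function(sce, grouping) {
  expr <- getLogcounts(sce)
  if (length(grouping) == 1L && is.character(grouping) &&
      grouping %in% names(SummarizedExperiment::colData(sce))) {
    grouping <- stats::setNames(
      as.character(SummarizedExperiment::colData(sce)[[grouping]]), colnames(sce))
  }
  grouping <- stats::setNames(as.character(grouping),
                              if (is.null(names(grouping))) colnames(expr) else names(grouping))
  f <- factor(grouping[colnames(expr)])
  if (anyNA(f)) stop("grouping does not cover every barcode")
  sizes <- table(f)
  if (any(sizes == 0)) stop("empty group(s): ",
                            paste(names(sizes)[sizes == 0], collapse = ", "))
  prof <- vapply(levels(f), function(g)
    Matrix::rowMeans(expr[, f == g, drop = FALSE]), numeric(nrow(expr)))
  rownames(prof) <- rownames(expr)
  attr(prof, "n_cells") <- stats::setNames(as.integer(sizes), levels(f))
  prof
}

#' Pearson correlation between two pseudobulk profiles
#'
#' @param a,b named per-gene mean expression vectors (columns of a
#'   \code{\link{pseudobulk}} matrix).
#' @param gene_subset optional genes to use; defaults to the genes shared
#'   by both profiles (at least 10 required).
#' @return list with \code{r} (Pearson correlation) and \code{n_genes}.
#' @export
pseudobulkCorrelation <- function(a, b, gene_subset = NULL) {
  shared <- intersect(names(a), names(b))
  if (!is.null(gene_subset)) shared <- intersect(shared, gene_subset)
  if (length(shared) < 10L) {
    stop("need at least 10 shared genes; got ", length(shared))
  }
  x <- a[shared]; y <- b[shared]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: constant expression vector")
  }
  list(r = cor(x, y), n_genes = length(shared))
}

#' Immunoglobulin kappa/lambda ratio among plasma cells
#'
#' Calls each plasma cell kappa or lambda by whichever light-chain gene
#' set has the larger summed log-normalized expression; exact ties
#' (including all-zero cells) are left unassigned and excluded. The
#' ratio is the kappa call count over the lambda call count, a standard
#' clonality indicator. Refuses to report when the plasma cluster has
#' fewer than \code{min_cells} cells, since the ratio is unstable in
#' small samples.
#'
#' @param sce SingleCellExperiment with \code{logcounts}.
#' @param labels named cluster labels.
#' @param plasma_label label of the plasma-cell cluster.
#' @param kappa_genes,lambda_genes light-chain gene sets; defaults are
#'   the constant-region symbols (kappa IGKC; lambda IGLC1/2/3/7).
#' @param min_cells minimum plasma cells required (default 25).
#' @return list with \code{ratio}, \code{n_kappa}, \code{n_lambda},
#'   \code{n_unassigned} and per-cell \code{calls}.
#' @export
kappaLambdaRatio <- function(sce, labels, plasma_label,
                             kappa_genes = c("IGKC"),
                             lambda_genes = c("IGLC1", "IGLC2", "IGLC3", "IGLC7"),
                             min_cells = 25) {
  expr <- getLogcounts(sce)
  labels <- stats::setNames(as.character(labels),
                            if (is.null(names(labels))) colnames(expr) else names(labels))
  cells <- names(labels)[labels == as.character(plasma_label)]
  if (length(cells) < min_cells) {
    stop("only ", length(cells), " plasma cells; at least ", min_cells,
         " required for a stable kappa/lambda ratio")
  }
  kg <- intersect(kappa_genes, rownames(expr))
  lg <- intersect(lambda_genes, rownames(expr))
  if (!length(kg)) stop("none of the kappa genes are in the matrix")
  if (!length(lg)) stop("none of the lambda genes are in the matrix")
  ksum <- Matrix::colSums(expr[kg, cells, drop = FALSE])
  lsum <- Matrix::colSums(expr[lg, cells, drop = FALSE])
  call <- ifelse(ksum > lsum, "kappa", ifelse(lsum > ksum, "lambda", "unassigned"))
  n_k <- sum(call == "kappa")
  n_l <- sum(call == "lambda")
  if (n_l == 0L) {
    warning("no lambda-called plasma cells; ratio reported as Inf")
    ratio <- Inf
  } else {
    ratio <- n_k / n_l
  }
  list(ratio = ratio, n_kappa = n_k, n_lambda = n_l,
       n_unassigned = sum(call == "unassigned"),
       calls = stats::setNames(call, cells))
}
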
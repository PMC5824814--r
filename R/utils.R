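#' @import methods
#' @importFrom stats cor dpois pchisq pnorm ppois prcomp qpois rbeta rbinom
#'   rgamma rlnorm rmultinom rpois runif sd var rnorm
#' @importFrom utils head read.delim write.table packageVersion capture.output
#' @importFrom tools md5sum
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# counts may be a base matrix or any Matrix class; returns dgCMatrix after
# validating the UMI-matrix contract (nonnegative integral entries, unique
# dimension names matching the stated ids).
validateUmiCounts <- function(counts, gene_ids = rownames(counts),
                              barcode_ids = colnames(counts)) {
  if (is.null(gene_ids) && nrow(counts) == 0L) gene_ids <- character(0)
  if (is.null(barcode_ids) && ncol(counts) == 0L) barcode_ids <- character(0)
  if (is.null(gene_ids) || is.null(barcode_ids)) {
    stop("UMI matrix requires gene and barcode identifiers")
  }
  if (length(gene_ids) != nrow(counts) || length(barcode_ids) != ncol(counts)) {
    stop("id list lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(head(unique(gene_ids[duplicated(gene_ids)]), 5L), collapse = ", "))
  }
  if (anyDuplicated(barcode_ids)) {
    stop("duplicate barcode identifiers: ",
         paste(head(unique(barcode_ids[duplicated(barcode_ids)]), 5L), collapse = ", "))
  }
  m <- if (is.matrix(counts)) Matrix::Matrix(counts, sparse = TRUE) else counts
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (anyNA(m@x)) stop("UMI matrix contains missing values")
  x <- m@x
  bad <- which(x < 0 | x != round(x))
  if (length(bad)) {
    b <- bad[1L]
    # recover (row, col) of the first offending entry from CSC slots
    row <- m@i[b] + 1L
    col <- sum(m@p < b)
    stop(sprintf(
      "invalid UMI count %g at gene '%s' (row %d), barcode '%s' (column %d): entries must be nonnegative integers",
      x[b], gene_ids[row], row, barcode_ids[col], col))
  }
  dimnames(m) <- list(as.character(gene_ids), as.character(barcode_ids))
  m
}

# Wrap a validated count matrix into a SingleCellExperiment.
umiExperiment <- function(counts, gene_ids = rownames(counts),
                          barcode_ids = colnames(counts), rowData = NULL) {
  m <- validateUmiCounts(counts, gene_ids, barcode_ids)
  sce <- SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
  if (!is.null(rowData)) {
    SummarizedExperiment::rowData(sce) <- rowData
  }
  sce
}

getCounts <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else {
    x
  }
}

getLogcounts <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x)) {
      stop("no 'logcounts' assay: run logNormalize() first")
    }
    SummarizedExperiment::assay(x, "logcounts")
  } else {
    x
  }
}
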
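#' Select highly variable genes by mean/dispersion bounds
#'
#' Computes, per gene, the log-mean expression log1p(mean normalized
#' count) and the dispersion (variance/mean of normalized counts, where
#' normalized counts are expm1 of the logcounts), and keeps genes whose
#' log-mean lies in [mean_low, mean_high] and dispersion in
#' [disp_low, disp_high] (bounds inclusive). Genes with zero mean have
#' undefined dispersion and are excluded.
#'
#' @param sce SingleCellExperiment with \code{logcounts}.
#' @param mean_low,mean_high log-mean expression bounds (defaults 0.05, 8).
#' @param disp_low,disp_high dispersion bounds (defaults 0.5, 30).
#' @return list with \code{genes} (character vector of selected genes)
#'   and \code{table} (DataFrame of log_mean, dispersion, selected per
#'   gene, for audit).
#' @export
selectVariableGenes <- function(sce, mean_low = 0.05, mean_high = 8,
                                disp_low = 0.5, disp_high = 30) {
  expr <- getLogcounts(sce)
  norm <- expr
  if (methods::is(norm, "sparseMatrix")) {
    norm <- methods::as(norm, "CsparseMatrix")
    norm@x <- expm1(norm@x)
  } else {
    norm <- expm1(norm)
  }
  n <- ncol(norm)
  m <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- (ex2 - m^2) * n / (n - 1)
  log_mean <- log1p(m)
  dispersion <- ifelse(m > 0, v / m, NA_real_)
  selected <- !is.na(dispersion) &
    log_mean >= mean_low & log_mean <= mean_high &
    dispersion >= disp_low & dispersion <= disp_high
  tab <- S4Vectors::DataFrame(log_mean = log_mean, dispersion = dispersion,
                              selected = selected, row.names = rownames(expr))
  if (!any(selected)) {
    stop("no genes pass the variable-gene bounds; consider relaxing ",
         "mean [", mean_low, ", ", mean_high, "] or dispersion [",
         disp_low, ", ", disp_high, "]")
  }
  list(genes = rownames(expr)[selected], table = tab)
}

#' Principal component analysis of corrected expression
#'
#' PCA of the variable-gene-restricted residual matrix with cells as
#' observations, computed by singular value decomposition (deterministic;
#' residual rows are already centered). Component signs are fixed by
#' making the largest-magnitude entry of each loading vector positive.
#'
#' @param sce SingleCellExperiment with a \code{residuals} assay.
#' @param genes variable genes (subset of rownames).
#' @param k number of components (default 13).
#' @return \code{sce} with \code{reducedDim(sce, "PCA")} holding the
#'   cells x k score matrix, and \code{metadata(sce)$pca} holding the
#'   unit-norm loadings and the variance explained per component.
#' @export
runPca <- function(sce, genes, k = 13) {
  if (k < 2) stop("k must be >= 2")
  if (!"residuals" %in% SummarizedExperiment::assayNames(sce)) {
    stop("no 'residuals' assay: run regressCovariates() first")
  }
  bad <- setdiff(genes, rownames(sce))
  if (length(bad)) stop("genes absent from matrix: ", paste(head(bad, 5L), collapse = ", "))
  X <- t(as.matrix(SummarizedExperiment::assay(sce, "residuals")[genes, , drop = FALSE]))
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (k > rank) {
    stop("k = ", k, " exceeds the attained rank ", rank, " of the residual matrix")
  }
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(sce)
  rownames(loadings) <- genes
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  SingleCellExperiment::reducedDim(sce, "PCA") <- scores
  S4Vectors::metadata(sce)$pca <- list(
    loadings = loadings, k = k,
    var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
  sce
}

#' Build a shared-nearest-neighbor graph in PC space
#'
#' Connects each cell to its \code{n_neighbors} Euclidean nearest
#' neighbors in PC space and weights each edge by the Jaccard overlap of
#' the two cells' neighbor sets (each set including the cell itself).
#' The graph is undirected; zero-weight edges are pruned.
#'
#' @param x a cells x k PC score matrix, or a SingleCellExperiment with a
#'   "PCA" reducedDim.
#' @param n_neighbors neighbors per cell (default 30); must be smaller
#'   than the number of cells.
#' @return A weighted undirected \link[igraph]{igraph} graph with one
#'   vertex per cell, named by barcode.
#' @export
buildNeighborGraph <- function(x, n_neighbors = 30) {
  scores <- if (methods::is(x, "SingleCellExperiment")) {
    SingleCellExperiment::reducedDim(x, "PCA")
  } else {
    as.matrix(x)
  }
  n <- nrow(scores)
  if (n <= n_neighbors) {
    stop("n_neighbors (", n_neighbors, ") must be smaller than the number of cells (", n, ")")
  }
  d <- as.matrix(stats::dist(scores))
  nn <- matrix(0L, n, n_neighbors)
  for (i in seq_len(n)) {
    nn[i, ] <- order(d[i, ])[2:(n_neighbors + 1L)]   # skip self; stable ties
  }
  # neighbor sets include self: adjacency A is n x n, row i marks {i} U nn(i)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = n_neighbors + 1L),
                            j = as.integer(t(cbind(seq_len(n), nn))),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  # candidate edges: kNN pairs, symmetrized
  ei <- rep(seq_len(n), each = n_neighbors)
  ej <- as.integer(t(nn))
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  keyed <- !duplicated(lo * (n + 1) + hi)
  lo <- lo[keyed]; hi <- hi[keyed]
  s <- shared[cbind(lo, hi)]
  w <- s / (2 * (n_neighbors + 1L) - s)
  keep <- w > 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[keep], to = hi[keep], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(id = seq_len(n), name = seq_len(n)))
  igraph::V(g)$name <- if (!is.null(rownames(scores))) rownames(scores) else
    as.character(seq_len(n))
  g
}

#' Louvain modularity clustering of the cell graph
#'
#' Runs the Louvain community-detection algorithm on the weighted
#' shared-nearest-neighbor graph at the given modularity resolution.
#'
#' @param g graph from \code{\link{buildNeighborGraph}}.
#' @param resolution modularity resolution (default 1).
#' @param seed integer RNG seed (Louvain's vertex sweep order is random).
#' @return Named integer vector of cluster labels, contiguous from 1,
#'   with attributes \code{modularity} and \code{provenance}.
#' @export
louvainCluster <- function(g, resolution = 1, seed = 1L) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  cl <- withSeed(seed, igraph::cluster_louvain(g, resolution = resolution))
  labels <- as.integer(igraph::membership(cl))
  labels <- match(labels, unique(labels))   # contiguous, first-appearance order
  names(labels) <- igraph::V(g)$name
  attr(labels, "modularity") <- max(igraph::modularity(cl))
  attr(labels, "provenance") <- list(resolution = resolution, seed = as.integer(seed),
                                     n_neighbors_graph = igraph::vcount(g))
  labels
}

# Balanced out-of-bag error of a random forest separating two clusters.
pairOobError <- function(features, idx_a, idx_b, num_trees, seed) {
  m <- min(length(idx_a), length(idx_b))
  withSeed(seed, {
    sa <- if (length(idx_a) > m) sample(idx_a, m) else idx_a
    sb <- if (length(idx_b) > m) sample(idx_b, m) else idx_b
  })
  dat <- data.frame(features[c(sa, sb), , drop = FALSE], check.names = FALSE)
  dat$.cls <- factor(rep(c("a", "b"), c(length(sa), length(sb))))
  fit <- ranger::ranger(dependent.variable.name = ".cls", data = dat,
                        num.trees = num_trees, seed = seed,
                        num.threads = 1L, verbose = FALSE)
  unname(fit$prediction.error)
}

#' Merge statistically indistinguishable clusters by random-forest OOB error
#'
#' Post-hoc validation of a modularity clustering: for every pair of
#' clusters a random forest is trained to tell the two apart from the
#' log-normalized expression of the variable genes (classes balanced by
#' downsampling the larger cluster), and the pair's out-of-bag prediction
#' error is recorded. While any pair's OOB error exceeds
#' \code{threshold}, the single worst (highest-error, i.e. least
#' separable) pair is merged and errors involving the merged cluster are
#' recomputed. Random label halves of one population have OOB error near
#' 0.5 and merge immediately; genuinely distinct populations separate
#' almost perfectly and are retained.
#'
#' @param sce SingleCellExperiment with \code{logcounts}.
#' @param labels named cluster labels (names = barcodes).
#' @param variable_genes feature genes for the classifier.
#' @param threshold OOB error above which a pair is merged (default 0.11).
#' @param seed integer RNG seed (downsampling and forest bootstraps).
#' @param num_trees trees per forest (default 500).
#' @param min_cells clusters below this size are skipped with a warning
#'   (default 10).
#' @return list with \code{labels} (integer labels contiguous from 1,
#'   named by barcode), \code{merge_history} (data.frame: iteration,
#'   cluster_a, cluster_b, oob_error, action) and \code{label_map}
#'   (original label -> final integer label).
#' @export
rfMerge <- function(sce, labels, variable_genes, threshold = 0.11, seed = 1L,
                    num_trees = 500, min_cells = 10) {
  expr <- getLogcounts(sce)
  labels <- stats::setNames(as.character(labels),
                            if (is.null(names(labels))) colnames(expr) else names(labels))
  stopifnot(all(names(labels) %in% colnames(expr)))
  features <- t(as.matrix(expr[variable_genes, names(labels), drop = FALSE]))
  history <- data.frame(iteration = integer(), cluster_a = character(),
                        cluster_b = character(), oob_error = numeric(),
                        action = character(), stringsAsFactors = FALSE)
  current <- labels
  sizes <- table(current)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warning("cluster(s) below ", min_cells, " cells skipped in merge evaluation: ",
            paste(small, collapse = ", "))
  }
  if (length(setdiff(names(sizes), small)) >= 2L) {
    oob <- list()   # cache keyed by "a||b" (sorted)
    it <- 0L
    eval_id <- 0L
    repeat {
      it <- it + 1L
      sizes <- table(current)
      elig <- sort(names(sizes)[sizes >= min_cells])
      if (length(elig) < 2L) break
      pairs <- utils::combn(elig, 2L)
      for (p in seq_len(ncol(pairs))) {
        key <- paste(pairs[, p], collapse = "||")
        if (is.null(oob[[key]])) {
          eval_id <- eval_id + 1L
          oob[[key]] <- pairOobError(features,
                                     which(current == pairs[1L, p]),
                                     which(current == pairs[2L, p]),
                                     num_trees, seed + eval_id)
          history <- rbind(history, data.frame(
            iteration = it, cluster_a = pairs[1L, p], cluster_b = pairs[2L, p],
            oob_error = oob[[key]], action = "retained",
            stringsAsFactors = FALSE))
        }
      }
      keys <- apply(pairs, 2L, paste, collapse = "||")
      errs <- unlist(oob[keys])
      if (max(errs) <= threshold) break
      worst <- pairs[, which.max(errs)]
      # absorb b into a, invalidate cached errors touching either
      current[current == worst[2L]] <- worst[1L]
      touched <- vapply(strsplit(names(oob), "||", fixed = TRUE),
                        function(k) any(k %in% worst), logical(1))
      oob[touched] <- NULL
      history$action[history$cluster_a == worst[1L] & history$cluster_b == worst[2L]] <- "merged"
    }
  }
  final_names <- unique(current)
  final <- stats::setNames(match(current, final_names), names(current))
  label_map <- stats::setNames(final[match(unique(labels), labels)], unique(labels))
  list(labels = final, merge_history = history, label_map = label_map,
       provenance = list(threshold = threshold, seed = as.integer(seed),
                         num_trees = num_trees, min_cells = min_cells,
                         n_variable_genes = length(variable_genes)))
}

#' Re-cluster a subset of cells to expose finer heterogeneity
#'
#' Repeats the clustering procedure (variable-gene selection, PCA on the
#' residuals, shared-neighbor graph, Louvain, random-forest merging) on
#' the cells of the chosen parent cluster(s) only, exposing structure
#' that the global resolution absorbs. Returned labels are namespaced
#' under the parent label so they can never collide with other parents'
#' labels.
#'
#' @param sce SingleCellExperiment with \code{logcounts} and
#'   \code{residuals} assays.
#' @param labels named cluster labels over all cells.
#' @param target_labels parent label(s) whose cells are re-clustered;
#'   together at least 50 cells.
#' @param k_pcs,n_neighbors,resolution,merge_threshold,seed tuning
#'   parameters for the sub-analysis (defaults scaled down for subsets).
#' @param mean_low,mean_high,disp_low,disp_high variable-gene bounds.
#' @param num_trees trees per forest in the merge step.
#' @return Named character vector of labels for the subset cells, of the
#'   form \code{"<parent>.<sub>"}.
#' @export
subcluster <- function(sce, labels, target_labels, k_pcs = 10, n_neighbors = 20,
                       resolution = 1, merge_threshold = 0.11, seed = 1L,
                       mean_low = 0.05, mean_high = 8, disp_low = 0.5,
                       disp_high = 30, num_trees = 500) {
  labels <- stats::setNames(as.character(labels),
                            if (is.null(names(labels))) colnames(sce) else names(labels))
  cells <- names(labels)[labels %in% as.character(target_labels)]
  if (length(cells) < 50L) {
    stop("sub-clustering requires at least 50 cells; got ", length(cells))
  }
  sub <- sce[, cells]
  vg <- selectVariableGenes(sub, mean_low, mean_high, disp_low, disp_high)
  k <- min(k_pcs, length(vg$genes) - 1L, length(cells) - 1L)
  sub <- runPca(sub, vg$genes, k = k)
  g <- buildNeighborGraph(sub, n_neighbors = min(n_neighbors, length(cells) - 1L))
  lab <- louvainCluster(g, resolution = resolution, seed = seed)
  merged <- rfMerge(sub, lab, vg$genes, threshold = merge_threshold,
                    seed = seed, num_trees = num_trees)
  prefix <- paste(sort(unique(as.character(target_labels))), collapse = "+")
  stats::setNames(paste0(prefix, ".", merged$labels), names(merged$labels))
}

#' Two-dimensional t-SNE embedding of the PC scores
#'
#' Visualization-only coordinates from Barnes-Hut t-SNE run on the PC
#' score matrix. Deterministic under a fixed seed. Coordinates carry no
#' downstream semantics.
#'
#' @param x cells x k PC score matrix, or a SingleCellExperiment with a
#'   "PCA" reducedDim.
#' @param seed integer RNG seed.
#' @param perplexity t-SNE perplexity; reduced automatically for small n.
#' @return cells x 2 coordinate matrix, rownames = barcodes.
#' @export
embed2d <- function(x, seed = 1L, perplexity = 30) {
  scores <- if (methods::is(x, "SingleCellExperiment")) {
    SingleCellExperiment::reducedDim(x, "PCA")
  } else {
    as.matrix(x)
  }
  n <- nrow(scores)
  if (n < 10L) stop("at least 10 cells required for embedding")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  out <- withSeed(seed, Rtsne::Rtsne(scores, dims = 2L, perplexity = perplexity,
                                     pca = FALSE, check_duplicates = FALSE,
                                     verbose = FALSE))
  coords <- out$Y
  rownames(coords) <- rownames(scores)
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}
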
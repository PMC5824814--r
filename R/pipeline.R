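pipelineDefaults <- function() {
  list(
    seed = 1L,
    input = list(path = NULL, format = "mtx_triplet", covariates = NULL),
    cell_cycle = list(s_genes = NULL, g2m_genes = NULL),
    preprocess = list(min_genes = 500, min_umi = 4000, max_umi = 13000,
                      min_cells = 3, scale_factor = 10000,
                      covariates = c("s_score", "g2m_score", "n_umi",
                                     "mito_fraction", "run_id", "alignment_rate")),
    variable_genes = list(mean_low = 0.05, mean_high = 8,
                          disp_low = 0.5, disp_high = 30),
    cluster = list(k_pcs = 13, n_neighbors = 30, resolution = 1,
                   merge_threshold = 0.11, num_trees = 500,
                   manual_merges = list()),
    markers = list(min_pct = 0.1),
    output = list(dir = NULL))
}

mergeConfig <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]])) {
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]],
                                    paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings (an in-memory list and/or a YAML file; explicit
#' settings override the file, the file overrides defaults) onto the
#' default configuration, rejecting unknown keys and inconsistent
#' thresholds before any computation. Defaults are the standard droplet
#' pipeline parameters: 500-gene / 4000--13000-UMI cell filters, 3-cell
#' gene filter, scale factor 10000, variable-gene mean bounds 0.05--8 and
#' dispersion bounds 0.5--30, 13 PCs, Louvain resolution 1, and an 11\%
#' OOB merge threshold.
#'
#' @param path optional YAML configuration file.
#' @param overrides optional named list of settings.
#' @return Validated configuration list (class \code{pipeline_config}).
#' @export
pipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- pipelineDefaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config file must contain a YAML mapping")
    cfg <- mergeConfig(cfg, user)
  }
  cfg <- mergeConfig(cfg, overrides)
  with(cfg$preprocess, {
    if (min_umi > max_umi) stop("invalid config: max_umi (", max_umi,
                                ") < min_umi (", min_umi, ")")
    if (min_genes < 0 || min_umi < 0) stop("invalid config: negative QC threshold")
    if (min_cells < 1) stop("invalid config: min_cells must be >= 1")
  })
  if (cfg$variable_genes$mean_low > cfg$variable_genes$mean_high ||
      cfg$variable_genes$disp_low > cfg$variable_genes$disp_high) {
    stop("invalid config: variable-gene bounds out of order")
  }
  if (cfg$cluster$k_pcs < 2) stop("invalid config: k_pcs must be >= 2")
  if (cfg$cluster$merge_threshold < 0 || cfg$cluster$merge_threshold > 1) {
    stop("invalid config: merge_threshold must lie in [0, 1]")
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full clustering pipeline
#'
#' Executes preprocessing (covariates, cell and gene filters,
#' normalization, cell-cycle scoring when gene lists are configured,
#' covariate regression), dimensionality reduction and clustering
#' (variable genes, PCA, shared-neighbor graph, Louvain, random-forest
#' merging, optional configured manual merges), marker detection for
#' every final cluster, and a 2-D embedding. All stage outputs plus a
#' provenance manifest (configuration echo, seed, package version, file
#' checksums) are written under \code{config$output$dir}.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param sce optional in-memory SingleCellExperiment; when NULL the
#'   matrix is read from \code{config$input}.
#' @return Invisibly, a list with the final SingleCellExperiment,
#'   labels, marker table, merge history and output file paths.
#' @export
runPipeline <- function(config, sce = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output$dir
  if (is.null(out_dir)) stop("config$output$dir must be set")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stage <- "input"
  res <- tryCatch({
    if (is.null(sce)) {
      sce <- readUmiMatrix(config$input$path, config$input$format)
      if (!is.null(config$input$covariates)) {
        cov <- read.delim(config$input$covariates, stringsAsFactors = FALSE)
        run_map <- stats::setNames(as.character(cov$run_id), cov$barcode)
        align_map <- if ("alignment_rate" %in% names(cov)) {
          stats::setNames(as.numeric(cov$alignment_rate), cov$barcode)
        } else NULL
        sce <- computeCellCovariates(sce, run_map, align_map)
      } else {
        sce <- computeCellCovariates(sce)
      }
    } else if (!all(c("n_umi", "n_gene") %in%
                    names(SummarizedExperiment::colData(sce)))) {
      sce <- computeCellCovariates(sce)
    }

    stage <- "preprocess"
    pp <- config$preprocess
    sce <- filterCells(sce, pp$min_genes, pp$min_umi, pp$max_umi)
    sce <- filterGenes(sce, pp$min_cells)
    sce <- logNormalize(sce, pp$scale_factor)
    covs <- pp$covariates
    if (!is.null(config$cell_cycle$s_genes) &&
        !is.null(config$cell_cycle$g2m_genes)) {
      s_genes <- if (length(config$cell_cycle$s_genes) == 1L &&
                     file.exists(config$cell_cycle$s_genes)) {
        readGeneList(config$cell_cycle$s_genes)
      } else config$cell_cycle$s_genes
      g2m_genes <- if (length(config$cell_cycle$g2m_genes) == 1L &&
                       file.exists(config$cell_cycle$g2m_genes)) {
        readGeneList(config$cell_cycle$g2m_genes)
      } else config$cell_cycle$g2m_genes
      sce <- scoreCellCycle(sce, s_genes, g2m_genes)
    } else {
      covs <- setdiff(covs, c("s_score", "g2m_score"))
    }
    covs <- intersect(covs, names(SummarizedExperiment::colData(sce)))
    sce <- regressCovariates(sce, covs)

    stage <- "cluster"
    vg <- selectVariableGenes(sce, config$variable_genes$mean_low,
                              config$variable_genes$mean_high,
                              config$variable_genes$disp_low,
                              config$variable_genes$disp_high)
    sce <- runPca(sce, vg$genes, k = config$cluster$k_pcs)
    g <- buildNeighborGraph(sce, config$cluster$n_neighbors)
    lab0 <- louvainCluster(g, config$cluster$resolution, seed = config$seed)
    merged <- rfMerge(sce, lab0, vg$genes,
                      threshold = config$cluster$merge_threshold,
                      seed = config$seed, num_trees = config$cluster$num_trees)
    labels <- merged$labels
    # configured judgment-call merges, applied after the automatic pass
    for (grp in config$cluster$manual_merges) {
      grp <- as.integer(grp)
      labels[labels %in% grp] <- min(grp)
    }
    labels <- stats::setNames(match(labels, sort(unique(labels))), names(labels))
    cd <- SummarizedExperiment::colData(sce)
    cd$cluster <- as.integer(labels[colnames(sce)])
    SummarizedExperiment::colData(sce) <- cd

    stage <- "markers"
    marker_list <- lapply(sort(unique(labels)), function(cl)
      as.data.frame(wilcoxonMarkers(sce, labels, cl,
                                    min_pct = config$markers$min_pct)))
    markers <- do.call(rbind, marker_list)

    stage <- "embed"
    coords <- embed2d(sce, seed = config$seed)
    SingleCellExperiment::reducedDim(sce, "TSNE") <- coords

    list(sce = sce, labels = labels, markers = markers,
         merge_history = merged$merge_history, variable_genes = vg$genes)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  files <- c(
    labels = writeTsv(data.frame(barcode = names(res$labels),
                                 cluster = as.integer(res$labels)),
                      file.path(out_dir, "labels.tsv")),
    markers = writeTsv(res$markers, file.path(out_dir, "markers.tsv")),
    embedding = writeTsv(data.frame(
      barcode = rownames(SingleCellExperiment::reducedDim(res$sce, "TSNE")),
      SingleCellExperiment::reducedDim(res$sce, "TSNE")),
      file.path(out_dir, "embedding.tsv")))
  jsonlite::write_json(S4Vectors::metadata(res$sce)$qc_cell_filter,
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(res$merge_history, file.path(out_dir, "merge_history.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  files <- c(files, qc_report = file.path(out_dir, "qc_report.json"),
             merge_history = file.path(out_dir, "merge_history.json"))
  manifest <- list(
    config = unclass(config), seed = config$seed,
    package_version = as.character(packageVersion("scDropletKit")),
    n_cells = ncol(res$sce), n_genes = nrow(res$sce),
    n_clusters = length(unique(res$labels)),
    checksums = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(files = c(files, manifest = file.path(out_dir, "manifest.json")))))
}

#' Generate a synthetic fixture bundle on disk
#'
#' Writes a synthetic UMI matrix (via the io module), the per-barcode
#' covariate table, the ground-truth table and a JSON echo of the
#' generating specification, so the bundle can be fed straight back into
#' \code{\link{runPipeline}}.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param out_dir output directory (created if needed).
#' @param format matrix format, \code{"mtx_triplet"} or \code{"dense_tsv"}.
#' @return Invisibly, a list of the generated SingleCellExperiment and
#'   the file paths written.
#' @export
runSimulate <- function(spec = syntheticSpec(), out_dir, format = "mtx_triplet") {
  validateSyntheticSpec(spec)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sce <- generateClusteredCounts(spec)
  if (format == "mtx_triplet") {
    mat_path <- file.path(out_dir, "matrix")
    writeUmiMatrix(sce, mat_path, "mtx_triplet")
  } else {
    mat_path <- file.path(out_dir, "matrix.tsv")
    writeUmiMatrix(sce, mat_path, "dense_tsv")
  }
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cov_path <- writeTsv(data.frame(barcode = colnames(sce),
                                  run_id = cd$run_id,
                                  alignment_rate = cd$alignment_rate),
                       file.path(out_dir, "covariates.tsv"))
  truth <- S4Vectors::metadata(sce)$truth
  writeLines(truth$s_genes, file.path(out_dir, "s_genes.txt"))
  writeLines(truth$g2m_genes, file.path(out_dir, "g2m_genes.txt"))
  truth_path <- writeTsv(data.frame(barcode = colnames(sce), cd),
                         file.path(out_dir, "truth.tsv"))
  spec_echo <- file.path(out_dir, "spec.json")
  jsonlite::write_json(unclass(spec), spec_echo, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(list(sce = sce, matrix = mat_path, covariates = cov_path,
                 truth = truth_path, spec = spec_echo,
                 s_genes = file.path(out_dir, "s_genes.txt"),
                 g2m_genes = file.path(out_dir, "g2m_genes.txt")))
}
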
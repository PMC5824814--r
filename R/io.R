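#' Read a UMI count matrix
#'
#' Reads a genes x barcodes UMI count matrix either from a Matrix Market
#' triplet file with plain-text sidecars, or from a dense TSV. Both
#' representations carry the same information and round-trip exactly
#' through \code{\link{writeUmiMatrix}}.
#'
#' For \code{mtx_triplet}, \code{path} is either a directory containing
#' \code{matrix.mtx}, \code{genes.tsv} and \code{barcodes.tsv}, or the
#' \code{.mtx} file itself with the two sidecars alongside it.
#' \code{genes.tsv} has one or two tab-separated columns (gene id, optional
#' symbol); \code{barcodes.tsv} has one barcode per line. Coordinates are
#' 1-based with genes as rows. For \code{dense_tsv}, \code{path} is a
#' single TSV with a header row of barcodes and the gene identifier in the
#' first column.
#'
#' @param path file or directory, see Details.
#' @param format \code{"mtx_triplet"} or \code{"dense_tsv"}.
#' @return A \link[SingleCellExperiment]{SingleCellExperiment} with a
#'   \code{counts} assay (sparse, nonnegative integer), gene ids as row
#'   names and barcodes as column names. A gene \code{symbol} column is
#'   placed in \code{rowData} when the sidecar provides one.
#' @seealso \code{\link{writeUmiMatrix}}
#' @export
readUmiMatrix <- function(path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    if (dir.exists(path)) {
      mtx <- file.path(path, "matrix.mtx")
      gfile <- file.path(path, "genes.tsv")
      bfile <- file.path(path, "barcodes.tsv")
    } else {
      mtx <- path
      gfile <- file.path(dirname(path), "genes.tsv")
      bfile <- file.path(dirname(path), "barcodes.tsv")
    }
    if (!file.exists(mtx)) stop("matrix file not found: ", mtx)
    for (f in c(gfile, bfile)) {
      if (!file.exists(f)) {
        stop("format error: missing sidecar file '", f,
             "' required for mtx_triplet input")
      }
    }
    m <- Matrix::readMM(mtx)
    glines <- readLines(gfile, encoding = "UTF-8")
    barcodes <- readLines(bfile, encoding = "UTF-8")
    gsplit <- strsplit(glines, "\t", fixed = TRUE)
    gene_ids <- vapply(gsplit, `[`, character(1), 1L)
    symbols <- vapply(gsplit, function(x) if (length(x) >= 2L) x[2L] else NA_character_,
                      character(1))
    rd <- if (all(is.na(symbols))) NULL else S4Vectors::DataFrame(symbol = symbols)
    umiExperiment(m, gene_ids, barcodes, rowData = rd)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                      quote = "")
    if (ncol(tab) < 1L) stop("format error: dense TSV has no columns")
    gene_ids <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (length(vals) && !is.numeric(vals)) {
      stop("validation error: non-numeric entries in dense TSV")
    }
    storage.mode(vals) <- "double"
    umiExperiment(vals, gene_ids, colnames(tab)[-1L])
  }
}

#' Write a UMI count matrix
#'
#' Inverse of \code{\link{readUmiMatrix}}: writing then reading reproduces
#' the matrix exactly (values, identifiers, order). For \code{mtx_triplet},
#' \code{path} is a directory (created if needed) receiving
#' \code{matrix.mtx}, \code{genes.tsv} and \code{barcodes.tsv}; for
#' \code{dense_tsv} it is the output file. The dense dialect is unquoted,
#' so identifiers containing a tab or newline are rejected.
#'
#' @param x a SingleCellExperiment with a \code{counts} assay, or a matrix
#'   with gene/barcode dimnames.
#' @param path output directory (mtx_triplet) or file (dense_tsv).
#' @param format \code{"mtx_triplet"} or \code{"dense_tsv"}.
#' @return Invisibly, the path written.
#' @export
writeUmiMatrix <- function(x, path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  counts <- validateUmiCounts(getCounts(x))
  gene_ids <- as.character(rownames(counts))   # NULL -> character(0)
  barcodes <- as.character(colnames(counts))
  symbols <- NULL
  if (methods::is(x, "SummarizedExperiment") &&
      "symbol" %in% names(SummarizedExperiment::rowData(x))) {
    symbols <- as.character(SummarizedExperiment::rowData(x)$symbol)
  }
  if (format == "mtx_triplet") {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("I/O error: cannot create directory ", path)
    }
    Matrix::writeMM(counts, file.path(path, "matrix.mtx"))
    glines <- if (is.null(symbols)) gene_ids else paste(gene_ids, symbols, sep = "\t")
    writeLines(glines, file.path(path, "genes.tsv"), useBytes = TRUE)
    writeLines(barcodes, file.path(path, "barcodes.tsv"), useBytes = TRUE)
  } else {
    bad <- grepl("[\t\n]", c(gene_ids, barcodes))
    if (any(bad)) {
      stop("dense_tsv dialect is unquoted: identifiers must not contain ",
           "tab or newline characters")
    }
    dense <- as.matrix(counts)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("gene", barcodes), collapse = "\t"), con)
    if (nrow(dense)) {
      body <- apply(dense, 1L, function(r) paste(format(r, scientific = FALSE,
                                                        trim = TRUE),
                                                 collapse = "\t"))
      if (ncol(dense) == 0L) body <- rep("", nrow(dense))
      writeLines(paste(gene_ids, body, sep = if (ncol(dense)) "\t" else ""), con)
    }
  }
  invisible(path)
}

#' Read an annotated gene list
#'
#' One gene symbol per line; blank lines and lines starting with \code{#}
#' are ignored, and trailing \code{# comments} on a line are stripped.
#' Duplicates are removed with a warning, preserving first-occurrence
#' order. An empty result is an error, since an empty module is unusable.
#'
#' @param path text file of gene symbols.
#' @return Character vector of unique gene symbols in file order.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (anyDuplicated(lines)) {
    dup <- unique(lines[duplicated(lines)])
    warning("duplicate gene symbols removed: ", paste(dup, collapse = ", "))
    lines <- lines[!duplicated(lines)]
  }
  if (!length(lines)) stop("gene list '", path, "' is empty")
  lines
}

#' Read an ERCC reference table
#'
#' Parses a tab-separated table of ERCC identifiers and input
#' concentrations (attomoles per microlitre of the loaded mix) and derives
#' the expected number of molecules per droplet for a caller-supplied
#' droplet volume, optionally after diluting the stock mix. A header row
#' is detected automatically.
#'
#' @param path TSV with identifier and concentration columns (first two
#'   columns are used).
#' @param volume_nl droplet volume in nanolitres (default 1, the volume of
#'   a standard Drop-seq droplet).
#' @param dilution fold-dilution of the stock mix before loading
#'   (default 1 = undiluted).
#' @return An \code{\linkS4class{ErccReference}}.
#' @export
readErccReference <- function(path, volume_nl = 1, dilution = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(volume_nl) || length(volume_nl) != 1L || volume_nl <= 0) {
    stop("volume_nl must be a single positive number")
  }
  if (!is.numeric(dilution) || length(dilution) != 1L || dilution <= 0) {
    stop("dilution must be a single positive number")
  }
  tab <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("format error: expected at least two columns")
  # drop a header row if the second field of the first row is non-numeric
  if (is.na(suppressWarnings(as.numeric(tab[1L, 2L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  ids <- as.character(tab[[1L]])
  conc <- suppressWarnings(as.numeric(tab[[2L]]))
  if (any(is.na(conc))) {
    stop("validation error: non-numeric concentration for ",
         paste(head(ids[is.na(conc)], 5L), collapse = ", "))
  }
  if (any(conc <= 0)) {
    stop("validation error: nonpositive concentration for ",
         paste(head(ids[conc <= 0], 5L), collapse = ", "))
  }
  methods::new("ErccReference", ids = ids, concentration = conc,
               expected_molecules = conc * 602214.076 * volume_nl * 1e-3 / dilution,
               volume_nl = volume_nl, dilution = dilution)
}

reportPayload <- function(obj) {
  if (methods::is(obj, "OccupancySummary")) {
    list(type = "OccupancySummary",
         data = list(histogram = as.list(obj@histogram),
                     lambda_hat = obj@lambda_hat, gof_stat = obj@gof_stat,
                     gof_df = obj@gof_df, gof_p = obj@gof_p,
                     degenerate = obj@degenerate))
  } else if (methods::is(obj, "SpeciesCalls")) {
    list(type = "SpeciesCalls",
         data = list(calls = obj@calls, mixed_fraction = obj@mixed_fraction,
                     collision_rate = obj@collision_rate,
                     purity_threshold = obj@purity_threshold,
                     min_umi = obj@min_umi, mix_fraction = obj@mix_fraction))
  } else if (methods::is(obj, "ErccMetrics")) {
    list(type = "ErccMetrics",
         data = list(per_barcode = obj@per_barcode,
                     mean_sensitivity = obj@mean_sensitivity,
                     sd_sensitivity = obj@sd_sensitivity,
                     mean_accuracy = obj@mean_accuracy,
                     sd_accuracy = obj@sd_accuracy,
                     min_umi = obj@min_umi, n_filtered = obj@n_filtered))
  } else if (methods::is(obj, "DataFrame") || is.data.frame(obj)) {
    df <- as.data.frame(obj)
    if (all(c("p_adj", "p_value") %in% names(df))) {
      df <- df[order(df$p_adj, df$p_value), , drop = FALSE]
    }
    list(type = "table", data = df)
  } else if (is.list(obj) && !is.null(names(obj))) {
    list(type = "summary", data = obj)
  } else {
    stop("writeReport: unsupported object of class ", paste(class(obj), collapse = "/"))
  }
}

#' Write a pipeline result report as JSON
#'
#' Serializes a supported result object (occupancy summary, species calls,
#' ERCC metrics, a marker table, or a named list) to a versioned JSON
#' document with full numeric precision. Marker tables are emitted sorted
#' by adjusted then raw p-value. \code{\link{readReport}} restores the
#' payload losslessly for all numeric fields.
#'
#' @param obj result object to serialize.
#' @param path output JSON file.
#' @return Invisibly, \code{path}.
#' @export
writeReport <- function(obj, path) {
  payload <- reportPayload(obj)
  doc <- c(list(schema_version = "1.0"), payload)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
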
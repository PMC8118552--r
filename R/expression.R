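# Expression-matrix container and preprocessing.
#
# The pipeline's working unit is a dense cells x genes matrix carrying a
# normalization tag so that each step can refuse inputs on the wrong scale
# (e.g. double log-normalization). Matrices at the scale this package targets
# (10^3-10^4 cells, ~6-7x10^3 genes) fit comfortably in memory as base R
# doubles.

#' Immunoglobulin heavy-chain isotype transcripts
#'
#' The eight IgH constant-region transcripts whose relative expression serves
#' as the default adjacent (supervision/conditioning) signal for modelling
#' class switch recombination in mouse B cells.
#' @export
IGH_CHANNELS <- c("Ighm", "Ighg1", "Ighg2b", "Ighg2c", "Ighg3",
                  "Igha", "Ighd", "Ighe")

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, cells in rows and genes in columns.
#' @param gene_ids,cell_ids identifiers; taken from dimnames when missing.
#' @param normalization_tag one of "raw_counts", "tpm", "log2_tpm1".
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              cell_ids = rownames(values),
                              normalization_tag = c("raw_counts", "tpm",
                                                    "log2_tpm1")) {
  normalization_tag <- match.arg(normalization_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length does not match the number of columns")
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length does not match the number of rows")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(utils::head(dup, 10), collapse = ", "))
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup))
    stop("duplicate cell ids: ", paste(utils::head(dup, 10), collapse = ", "))
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 normalization_tag = normalization_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$normalization_tag))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Load an expression matrix from disk
#'
#' Supported formats: MatrixMarket MTX with 10x-style companion files
#' (`features.tsv`/`genes.tsv` and `barcodes.tsv` next to the matrix, genes in
#' rows, cells in columns) and dense CSV/TSV (header row of gene ids; an
#' initial non-numeric column is taken as cell ids). HDF5 input is not
#' supported by this build.
#'
#' @param path file path (for MTX, the `matrix.mtx` file).
#' @param format "mtx", "csv", "tsv" or "auto" (from the file extension).
#' @param orientation of dense files; MTX is always genes x cells (10x).
#' @param normalization_tag scale of the stored values.
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path,
                            format = c("auto", "mtx", "csv", "tsv", "h5"),
                            orientation = c("cells_by_genes",
                                            "genes_by_cells"),
                            normalization_tag = "raw_counts") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     h5 = "h5",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "h5")
    stop("HDF5 input is not supported; use MTX or CSV/TSV")
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    dir <- dirname(path)
    feat <- c(file.path(dir, "features.tsv"), file.path(dir, "genes.tsv"))
    feat <- feat[file.exists(feat)][1]
    bc <- file.path(dir, "barcodes.tsv")
    if (is.na(feat) || !file.exists(bc))
      stop("MTX companion files missing: expected features.tsv (or ",
           "genes.tsv) and barcodes.tsv alongside ", path)
    m <- as.matrix(Matrix::readMM(path))          # genes x cells (10x)
    features <- data.table::fread(feat, header = FALSE, sep = "\t")
    barcodes <- data.table::fread(bc, header = FALSE, sep = "\t")
    if (nrow(features) != nrow(m))
      stop("features.tsv has ", nrow(features), " rows but matrix has ",
           nrow(m), " gene rows")
    if (nrow(barcodes) != ncol(m))
      stop("barcodes.tsv has ", nrow(barcodes), " rows but matrix has ",
           ncol(m), " cell columns")
    gene_ids <- as.character(features[[min(2, ncol(features))]])
    expression_matrix(t(m), gene_ids = gene_ids,
                      cell_ids = as.character(barcodes[[1]]),
                      normalization_tag = normalization_tag)
  } else {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE)
    cell_ids <- NULL
    if (ncol(dt) > 0 && !is.numeric(dt[[1]])) {
      cell_ids <- as.character(dt[[1]])
      dt <- dt[, -1]
    }
    m <- as.matrix(dt)
    if (orientation == "genes_by_cells") {
      m <- t(m)
      tmp <- cell_ids        # ids in the first column were gene ids
      gene_ids <- tmp
      if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(m)))
      expression_matrix(m, gene_ids = gene_ids, cell_ids = rownames(m),
                        normalization_tag = normalization_tag)
    } else {
      expression_matrix(m, gene_ids = colnames(m), cell_ids = cell_ids,
                        normalization_tag = normalization_tag)
    }
  }
}

#' Write an expression matrix as MTX + companion TSVs (10x convention)
#'
#' @param expr an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(expr, dir) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(expr$values), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  data.table::fwrite(data.table::data.table(id = expr$gene_ids,
                                            name = expr$gene_ids),
                     file.path(dir, "features.tsv"),
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::data.table(expr$cell_ids),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", col.names = FALSE)
  invisible(dir)
}

#' Drop genes with no counts in any cell
#'
#' Genes with zero expression across every cell carry no information and are
#' removed before normalization. Idempotent; cell set and the relative order
#' of retained genes are unchanged.
#'
#' @param expr an [expression_matrix()] on the raw_counts or tpm scale.
#' @return filtered [expression_matrix()].
#' @export
filter_zero_genes <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$normalization_tag == "log2_tpm1")
    stop("filter_zero_genes expects raw_counts or tpm input")
  keep <- colSums(expr$values) > 0
  if (!any(keep)) stop("all genes have zero counts; empty matrix")
  expression_matrix(expr$values[, keep, drop = FALSE],
                    gene_ids = expr$gene_ids[keep], cell_ids = expr$cell_ids,
                    normalization_tag = expr$normalization_tag)
}

#' Normalize to log2(TPM + 1)
#'
#' TPM input is log-transformed directly. For raw counts without gene-length
#' information (droplet/UMI data), counts-per-million is used as the TPM
#' surrogate; a message records this choice.
#'
#' @param expr an [expression_matrix()]; must not already be log-scale.
#' @return [expression_matrix()] with tag "log2_tpm1".
#' @export
normalize_log2_tpm1 <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$normalization_tag == "log2_tpm1")
    stop("input is already on the log2(TPM+1) scale (double-normalization)")
  v <- expr$values
  if (expr$normalization_tag == "raw_counts") {
    lib <- rowSums(v)
    if (any(lib == 0)) stop("cells with zero total counts: ",
                            paste(expr$cell_ids[lib == 0], collapse = ", "))
    message("raw counts: using counts-per-million as the TPM surrogate")
    v <- v / lib * 1e6
  }
  expression_matrix(log2(v + 1), gene_ids = expr$gene_ids,
                    cell_ids = expr$cell_ids, normalization_tag = "log2_tpm1")
}

#' Per-cell relative isotype (adjacent) profiles
#'
#' Divides each cell's log2(TPM+1) expression of every condition-channel gene
#' by the summed expression over all channels, yielding one simplex vector
#' per cell. Cells with zero total channel expression receive the uniform
#' profile 1/K with a warning (rather than NaN or silent removal).
#'
#' @param expr an [expression_matrix()] on the log2_tpm1 scale.
#' @param channel_ids condition-gene identifiers (default the 8 IgH isotype
#'   transcripts, [IGH_CHANNELS]).
#' @param case_insensitive match channel ids to gene ids ignoring case.
#' @return numeric matrix, cells x channels, rows summing to one.
#' @export
compute_adjacent_profiles <- function(expr, channel_ids = IGH_CHANNELS,
                                      case_insensitive = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$normalization_tag != "log2_tpm1")
    stop("adjacent profiles are defined on the log2(TPM+1) scale; ",
         "call normalize_log2_tpm1() first")
  ids <- expr$gene_ids
  if (case_insensitive) {
    pos <- match(tolower(channel_ids), tolower(ids))
  } else {
    pos <- match(channel_ids, ids)
  }
  if (anyNA(pos))
    stop("channel genes not found: ",
         paste(channel_ids[is.na(pos)], collapse = ", "))
  ch <- expr$values[, pos, drop = FALSE]
  total <- rowSums(ch)
  zero <- total == 0
  if (any(zero)) {
    warning("zero total channel expression; assigning uniform profile to: ",
            paste(utils::head(expr$cell_ids[zero], 10), collapse = ", "),
            if (sum(zero) > 10) sprintf(" (and %d more)", sum(zero) - 10))
    ch[zero, ] <- 1
    total[zero] <- length(channel_ids)
  }
  p <- ch / total
  dimnames(p) <- list(expr$cell_ids, channel_ids)
  p
}

#' Keep the most variable genes
#'
#' Ranks genes by variance across cells on the current scale (plain variance
#' on log2(TPM+1) by default) and retains the top `k`, preserving original
#' gene order among those selected.
#'
#' @param expr an [expression_matrix()].
#' @param k number of genes to keep (the heatmap analyses in this package use
#'   6500 at full scale).
#' @param metric "variance" or "cv2" (squared coefficient of variation).
#' @return filtered [expression_matrix()].
#' @export
select_variable_genes <- function(expr, k = 6500,
                                  metric = c("variance", "cv2")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  metric <- match.arg(metric)
  g <- ncol(expr$values)
  if (k > g) stop("k = ", k, " exceeds the number of genes (", g, ")")
  mu <- colMeans(expr$values)
  v <- colMeans(expr$values^2) - mu^2
  score <- switch(metric, variance = v, cv2 = v / pmax(mu^2, 1e-12))
  keep <- sort(order(score, decreasing = TRUE)[seq_len(k)])
  expression_matrix(expr$values[, keep, drop = FALSE],
                    gene_ids = expr$gene_ids[keep], cell_ids = expr$cell_ids,
                    normalization_tag = expr$normalization_tag)
}

#' Hierarchical clustering of adjacent profiles
#'
#' Agglomerative clustering (Euclidean distance, average linkage by default)
#' of per-cell relative-isotype profiles, returning flat labels at a
#' configurable cut together with the dendrogram leaf order.
#'
#' @param profiles cells x channels matrix from [compute_adjacent_profiles()].
#' @param k number of flat clusters to cut the tree into.
#' @param method linkage passed to [stats::hclust()].
#' @return list with `labels` (named integer vector), `order` (leaf order)
#'   and `hclust` (the tree).
#' @export
cluster_adjacent_profiles <- function(profiles, k = 7, method = "average") {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 cells to cluster")
  k <- min(k, nrow(profiles))
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = method)
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(profiles)
  list(labels = labels, order = hc$order, hclust = hc)
}
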
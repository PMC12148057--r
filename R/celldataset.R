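#' Construct a CellDataset
#'
#' The shared single-cell container used by every assistant stage. Counts are
#' stored cells x genes (cells as rows); 10x on-disk convention (genes as
#' rows) is transposed on load. Per-cell QC columns `total_counts` and
#' `n_genes_detected` are always present and recomputable from the counts.
#'
#' @param counts cells x genes matrix of non-negative integers (base matrix
#'   or a `Matrix` sparse matrix). Rows are cells, columns genes.
#' @param gene_names character vector of unique gene identifiers; defaults to
#'   `colnames(counts)`.
#' @param cell_names character vector of cell barcodes; defaults to
#'   `rownames(counts)` or `cell_1..n`.
#' @param cell_meta optional data.frame of extra per-cell columns (e.g.
#'   `percent_mito`, in percent units 0-100).
#' @return an object of class `CellDataset`: a list with `counts`,
#'   `cell_meta`, `gene_names` and a `layers` list for derived results
#'   (lognorm, hvg_flags, pc_embedding, pc_variance, pc_loadings,
#'   cluster_labels, cell_type_labels).
#' @export
CellDataset <- function(counts, gene_names = NULL, cell_names = NULL,
                        cell_meta = NULL) {
  if (!inherits(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(gene_names)) gene_names <- colnames(counts)
  if (is.null(gene_names)) {
    stop("gene_names must be supplied when counts has no column names")
  }
  if (is.null(cell_names)) cell_names <- rownames(counts)
  if (is.null(cell_names)) cell_names <- paste0("cell_", seq_len(nrow(counts)))
  gene_names <- as.character(gene_names)
  dup <- unique(gene_names[duplicated(gene_names)])
  if (length(dup) > 0) {
    stop("duplicated gene names: ", paste(dup, collapse = ", "))
  }
  vals <- counts@x
  if (any(vals < 0)) stop("counts must be non-negative")
  if (any(vals != round(vals))) stop("counts must be integral")
  dimnames(counts) <- list(cell_names, gene_names)

  meta <- data.frame(
    total_counts = as.numeric(Matrix::rowSums(counts)),
    n_genes_detected = as.integer(Matrix::rowSums(counts > 0)),
    row.names = cell_names, check.names = FALSE
  )
  if (!is.null(cell_meta)) {
    if (nrow(cell_meta) != nrow(counts)) {
      stop("cell_meta has ", nrow(cell_meta), " rows but counts has ",
           nrow(counts), " cells")
    }
    for (cn in setdiff(colnames(cell_meta), colnames(meta))) {
      col <- cell_meta[[cn]]
      if (grepl("^percent", cn) && is.numeric(col) &&
          any(col < 0 | col > 100, na.rm = TRUE)) {
        stop("percent column '", cn, "' outside [0,100]")
      }
      meta[[cn]] <- col
    }
  }
  structure(
    list(counts = counts, cell_meta = meta,
         gene_names = gene_names, layers = list()),
    class = "CellDataset"
  )
}

#' @export
print.CellDataset <- function(x, ...) {
  cat(sprintf("CellDataset: %d cells x %d genes\n",
              n_cells(x), length(x$gene_names)))
  cat("  cell_meta columns:", paste(colnames(x$cell_meta), collapse = ", "),
      "\n")
  if (length(x$layers) > 0) {
    cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cells in a CellDataset
#' @param ds a CellDataset
#' @return integer cell count
#' @export
n_cells <- function(ds) nrow(ds$counts)

#' Validate CellDataset invariants
#'
#' Checks that counts are non-negative integers, per-cell structures agree in
#' length, the stored QC columns equal their recomputation from counts, and
#' percent columns lie in [0,100].
#'
#' @param ds a CellDataset
#' @return invisibly TRUE; stops on violation
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "CellDataset"))
  if (nrow(ds$cell_meta) != n_cells(ds)) stop("cell_meta/counts cell mismatch")
  tc <- as.numeric(Matrix::rowSums(ds$counts))
  ng <- as.integer(Matrix::rowSums(ds$counts > 0))
  if (!isTRUE(all.equal(tc, ds$cell_meta$total_counts))) {
    stop("stored total_counts differ from recomputation")
  }
  if (!identical(ng, as.integer(ds$cell_meta$n_genes_detected))) {
    stop("stored n_genes_detected differ from recomputation")
  }
  for (cn in grep("^percent", colnames(ds$cell_meta), value = TRUE)) {
    col <- ds$cell_meta[[cn]]
    if (any(col < 0 | col > 100, na.rm = TRUE)) {
      stop("percent column '", cn, "' outside [0,100]")
    }
  }
  cl <- ds$layers$cluster_labels
  if (!is.null(cl)) {
    if (length(cl) != n_cells(ds)) stop("cluster_labels length mismatch")
    if (anyNA(cl)) stop("cluster_labels must be assigned for every cell")
  }
  for (lyr in c("lognorm")) {
    m <- ds$layers[[lyr]]
    if (!is.null(m) && !identical(dim(m), dim(ds$counts))) {
      stop(lyr, " layer shape differs from counts")
    }
  }
  invisible(TRUE)
}

#' Attach per-cell labels derived from cluster assignments
#'
#' Maps each cell's cluster to a label (e.g. a predicted cell type) and
#' stores the result as a new per-cell metadata column, mirroring how
#' annotations are appended to the dataset as metadata.
#'
#' @param ds CellDataset with a `cluster_labels` layer
#' @param column name of the metadata column to create
#' @param mapping named character vector or list, cluster id -> label; must
#'   cover every observed cluster
#' @param overwrite overwrite an existing column of that name (default FALSE)
#' @return the modified CellDataset
#' @export
attach_labels <- function(ds, column, mapping, overwrite = FALSE) {
  cl <- ds$layers$cluster_labels
  if (is.null(cl)) stop("dataset has no cluster_labels layer")
  cl <- as.character(cl)
  mapping <- unlist(mapping)
  names(mapping) <- as.character(names(mapping))
  missing <- setdiff(unique(cl), names(mapping))
  if (length(missing) > 0) {
    stop("mapping missing clusters; missing: ",
         paste(sort(missing), collapse = ", "))
  }
  if (column %in% colnames(ds$cell_meta) && !overwrite) {
    stop("column '", column, "' exists; set overwrite = TRUE to replace")
  }
  ds$cell_meta[[column]] <- unname(mapping[cl])
  if (column == "cell_type_labels") {
    ds$layers$cell_type_labels <- unname(mapping[cl])
  }
  ds
}
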
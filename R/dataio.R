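#' Load a count matrix into a CellDataset
#'
#' Supported formats: a 10x-style MTX triplet directory (`matrix.mtx` plus
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`; genes as rows on disk,
#' transposed to cells x genes on load), an H5AD file (read natively via
#' HDF5; the main `X` matrix or a named layer), or a dense CSV with cells as
#' rows and a header of gene names.
#'
#' @param path file or directory path
#' @param format one of `"mtx_dir"`, `"h5ad"`, `"csv"`
#' @param allow_float if TRUE, non-integer matrices are rounded with a
#'   warning instead of rejected
#' @param h5ad_layer optional layer name inside the H5AD file holding raw
#'   counts; defaults to the main matrix `X`
#' @return a CellDataset with QC columns computed
#' @export
load_counts <- function(path, format = c("mtx_dir", "h5ad", "csv"),
                        allow_float = FALSE, h5ad_layer = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  m <- switch(format,
    mtx_dir = read_mtx_dir(path),
    h5ad    = read_h5ad_counts(path, h5ad_layer),
    csv     = read_csv_counts(path)
  )
  m$counts <- check_integral(m$counts, allow_float)
  CellDataset(m$counts, gene_names = m$gene_names, cell_names = m$cell_names)
}

check_integral <- function(counts, allow_float) {
  vals <- if (inherits(counts, "Matrix")) counts@x else as.numeric(counts)
  bad <- which(vals != round(vals))
  if (length(bad) > 0) {
    if (!allow_float) {
      # report the first offender by position for actionable errors
      if (inherits(counts, "sparseMatrix")) {
        tm <- Matrix::mat2triplet(counts)
        off <- which(tm$x != round(tm$x))[1]
        stop(sprintf(
          "non-integer count %g at cell row %d, gene column %d; use allow_float to round",
          tm$x[off], tm$i[off], tm$j[off]))
      }
      idx <- arrayInd(bad[1], dim(counts))
      stop(sprintf(
        "non-integer count %g at row %d, column %d; use allow_float to round",
        vals[bad[1]], idx[1], idx[2]))
    }
    warning("non-integer counts rounded to nearest integer")
    counts <- round(counts)
  }
  counts
}

read_mtx_dir <- function(dir) {
  if (!dir.exists(dir)) stop("MTX directory does not exist: ", dir)
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(dir, "genes.tsv")
  bar <- file.path(dir, "barcodes.tsv")
  missing <- c(mtx, feat, bar)[!file.exists(c(mtx, feat, bar))]
  if (length(missing) > 0) {
    stop("missing files in MTX triplet: ",
         paste(basename(missing), collapse = ", "))
  }
  m <- Matrix::readMM(mtx)              # genes x cells on disk
  feats <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  bars <- utils::read.delim(bar, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m)) stop("features file length != matrix rows")
  if (nrow(bars) != ncol(m)) stop("barcodes file length != matrix columns")
  gene_col <- if (ncol(feats) >= 2) 2L else 1L  # 10x: id, symbol, type
  list(counts = Matrix::t(m),
       gene_names = make.unique(as.character(feats[[gene_col]]), sep = "."),
       cell_names = as.character(bars[[1]]))
}

read_csv_counts <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "numeric"
  bad <- which(m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer entry %g at row '%s', column '%s'",
                 m[bad[1, 1], bad[1, 2]],
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  list(counts = m, gene_names = colnames(m), cell_names = rownames(m))
}

read_h5ad_counts <- function(path, layer = NULL) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("reading H5AD requires the rhdf5 package")
  }
  xpath <- if (is.null(layer)) "X" else file.path("layers", layer)
  info <- rhdf5::h5ls(path)
  grp_attrs <- tryCatch(rhdf5::h5readAttributes(path, xpath),
                        error = function(e) list())
  obs_names <- as.character(rhdf5::h5read(path, "obs/_index"))
  var_names <- as.character(rhdf5::h5read(path, "var/_index"))
  is_group <- any(info$group == paste0("/", xpath))
  if (is_group) {
    # sparse encoding: csr (obs-major) or csc
    enc <- grp_attrs[["encoding-type"]]
    data <- as.numeric(rhdf5::h5read(path, file.path(xpath, "data")))
    indices <- as.integer(rhdf5::h5read(path, file.path(xpath, "indices")))
    indptr <- as.integer(rhdf5::h5read(path, file.path(xpath, "indptr")))
    shape <- as.integer(grp_attrs[["shape"]])  # (n_obs, n_var)
    if (identical(enc, "csr_matrix") || is.null(enc)) {
      # CSR over obs rows == CSC of the var x obs transpose
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = c(shape[2], shape[1]),
                                repr = "C", index1 = TRUE)
      m <- Matrix::t(m)                  # -> obs x var
    } else if (identical(enc, "csc_matrix")) {
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = c(shape[1], shape[2]),
                                repr = "C", index1 = TRUE)
    } else {
      stop("unsupported H5AD matrix encoding: ", enc)
    }
  } else {
    m <- rhdf5::h5read(path, xpath)      # h5py writes row-major; rhdf5
    m <- t(m)                            # returns transposed -> fix to obs x var
  }
  rhdf5::h5closeAll()
  list(counts = m, gene_names = var_names, cell_names = obs_names)
}

#' Write a CellDataset as an MTX triplet directory
#'
#' Inverse of [load_counts()] for the `mtx_dir` format (genes as rows on
#' disk). When true population labels are present they are written alongside
#' as `labels.tsv`.
#'
#' @param ds CellDataset
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_counts <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = ds$gene_names, symbol = ds$gene_names, type = "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(bc = rownames(ds$counts)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  cl <- ds$layers$cluster_labels
  if (!is.null(cl)) {
    utils::write.table(data.frame(barcode = rownames(ds$counts), label = cl),
                       file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated member genes.
#' Members are deduplicated within a line; duplicate set names are an error.
#'
#' @param path GMT file path
#' @return a `GeneSetCollection`: named list of character vectors with a
#'   `descriptions` attribute
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0),
                     class = "GeneSetCollection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) stop("duplicate set name(s): ", paste(dup, collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(lengths(sets) == 0)) {
    stop("empty gene set(s): ",
         paste(nm[lengths(sets) == 0], collapse = ", "))
  }
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, descriptions = desc, class = "GeneSetCollection")
}

#' Create a recommendation record
#'
#' The provenance unit for one assistant run: the rendered prompt, the raw
#' LLM response, the parsed payload, and backend identity, serialisable to
#' JSON so runs can be displayed, saved and audited later.
#'
#' @param task_id registered task id
#' @param rendered_prompt the augmented prompt text sent to the backend
#' @param raw_response verbatim response text
#' @param parsed_payload task-dependent parsed structure (may be NULL)
#' @param model_id,backend_name backend identity strings
#' @param parsed_ok logical; FALSE when the parser failed and only raw text
#'   is preserved
#' @param provenance optional named list of run metadata
#' @param timestamp time string; defaults to now
#' @return object of class `RecommendationRecord`
#' @export
recommendation_record <- function(task_id, rendered_prompt, raw_response,
                                  parsed_payload = NULL, model_id = "",
                                  backend_name = "", parsed_ok = TRUE,
                                  provenance = list(),
                                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  stopifnot(is.character(task_id), nzchar(task_id))
  structure(
    list(task_id = task_id, rendered_prompt = rendered_prompt,
         raw_response = raw_response, parsed_payload = parsed_payload,
         parsed_ok = isTRUE(parsed_ok), model_id = model_id,
         backend_name = backend_name, provenance = provenance,
         timestamp = timestamp),
    class = "RecommendationRecord"
  )
}

#' @export
print.RecommendationRecord <- function(x, ...) {
  cat(sprintf("RecommendationRecord [%s] via %s/%s\n", x$task_id,
              x$backend_name, x$model_id))
  cat(x$raw_response, "\n")
  invisible(x)
}

# drop bespoke S3 classes so any parsed payload serializes to plain JSON
strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, strip_classes))
  if (!is.null(attr(x, "class"))) attr(x, "class") <- NULL
  x
}

#' Write / read a RecommendationRecord as JSON
#'
#' Lossless round-trip of all fields, including multi-line responses that
#' contain arbitrary delimiter characters.
#'
#' @param record a RecommendationRecord
#' @param path output file
#' @return `path` invisibly (write); the record (read)
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "RecommendationRecord"))
  json <- jsonlite::toJSON(strip_classes(unclass(record)), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write record to: ", path)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("no such record file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupt record file: ", path,
                                           " (", conditionMessage(e), ")"))
  required <- c("task_id", "rendered_prompt", "raw_response")
  if (!all(required %in% names(obj))) {
    stop("corrupt record file: ", path, " (missing fields)")
  }
  do.call(recommendation_record, obj[intersect(names(obj), names(formals(recommendation_record)))])
}
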
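#' Quality-control summary statistics for prompt injection
#'
#' For each named per-cell metric, computes the summary statistics and
#' quantile grid that the quality-analysis prompt consumes: mean, median,
#' sample sd, min, max, and quantiles at 1, 5, 10, 25, 50, 75, 90, 95, 99
#' percent (linear interpolation between order statistics, the R default).
#'
#' @param ds CellDataset
#' @param metric_names character vector of `cell_meta` column names
#' @return a `QCMetricBundle`: list with `n_cells` and a per-metric list of
#'   stats
#' @export
summarize_qc <- function(ds, metric_names = c("total_counts", "n_genes_detected")) {
  unknown <- setdiff(metric_names, colnames(ds$cell_meta))
  if (length(unknown) > 0) {
    stop("unknown metric name(s): ", paste(unknown, collapse = ", "))
  }
  probs <- c(1, 5, 10, 25, 50, 75, 90, 95, 99) / 100
  metrics <- lapply(metric_names, function(mn) {
    v <- as.numeric(ds$cell_meta[[mn]])
    q <- stats::quantile(v, probs = probs, type = 7, names = FALSE)
    names(q) <- paste0("q", probs * 100)
    list(mean = mean(v), median = stats::median(v), sd = stats::sd(v),
         min = min(v), max = max(v), quantiles = q)
  })
  names(metrics) <- metric_names
  structure(list(n_cells = n_cells(ds), metrics = metrics),
            class = "QCMetricBundle")
}

#' Library-size and expression-distribution statistics
#'
#' Feeds the normalization-recommendation prompt: number of cells,
#' library-size mean/median/CV (sample sd over mean), the fraction of zero
#' entries in the count matrix, and quantiles of per-gene mean expression.
#'
#' @param ds CellDataset with counts
#' @return a `NormalizationMetrics` list
#' @export
library_size_stats <- function(ds) {
  tot <- ds$cell_meta$total_counts
  if (all(tot == 0)) stop("all-zero count matrix: nothing to normalize")
  gene_means <- as.numeric(Matrix::colMeans(ds$counts))
  nz <- Matrix::nnzero(ds$counts)
  structure(list(
    n_cells = n_cells(ds),
    libsize_mean = mean(tot),
    libsize_median = stats::median(tot),
    libsize_cv = stats::sd(tot) / mean(tot),
    zero_fraction = 1 - nz / prod(dim(ds$counts)),
    gene_mean_quantiles = stats::quantile(
      gene_means, probs = c(.1, .25, .5, .75, .9), type = 7)
  ), class = "NormalizationMetrics")
}

#' Variance explained per principal component
#'
#' Fractions are per-PC variance over the total variance across the stored
#' PCs, with the cumulative sum alongside.
#'
#' @param ds CellDataset with a `pc_variance` layer (or a `pc_embedding`
#'   layer from which per-PC column variances are taken)
#' @return a `PCVarianceProfile` list with `fractions` and `cumulative`
#' @export
variance_explained <- function(ds) {
  v <- ds$layers$pc_variance
  if (is.null(v)) {
    emb <- ds$layers$pc_embedding
    if (is.null(emb)) stop("no PCs: run compute_pca() first")
    v <- apply(emb, 2, stats::var)
  }
  if (length(v) == 0) stop("no PCs stored")
  frac <- v / sum(v)
  structure(list(fractions = frac, cumulative = cumsum(frac)),
            class = "PCVarianceProfile")
}

#' Top contributing genes per principal component
#'
#' For each of the first `n_pcs` components, the `n_genes` genes with the
#' highest positive loadings and the `n_genes` with the most negative
#' loadings, each list sorted by |loading| descending with gene-name
#' lexicographic tie-break.
#'
#' @param ds CellDataset with a `pc_loadings` layer (genes x PCs)
#' @param n_pcs,n_genes table dimensions
#' @return a `PCGeneTable`: per-PC list of `positive` and `negative`
#'   data.frames (gene, loading)
#' @export
top_pc_genes <- function(ds, n_pcs = 5, n_genes = 10) {
  L <- ds$layers$pc_loadings
  if (is.null(L)) stop("no pc_loadings layer: run compute_pca() first")
  if (n_pcs > ncol(L)) stop("n_pcs exceeds stored PCs (", ncol(L), ")")
  if (n_genes > nrow(L)) stop("n_genes exceeds gene count (", nrow(L), ")")
  per_pc <- lapply(seq_len(n_pcs), function(j) {
    lo <- L[, j]
    nm <- rownames(L)
    take <- function(idx) {
      # |loading| descending, ties by gene name
      o <- order(-abs(lo[idx]), nm[idx])
      sel <- idx[o][seq_len(min(n_genes, length(idx)))]
      data.frame(gene = nm[sel], loading = unname(lo[sel]),
                 stringsAsFactors = FALSE)
    }
    list(positive = take(which(lo >= 0)), negative = take(which(lo < 0)))
  })
  names(per_pc) <- paste0("PC", seq_len(n_pcs))
  structure(per_pc, class = "PCGeneTable")
}

#' Mean expression variability across highly variable genes
#'
#' A scale-free heterogeneity summary used by the resolution-recommendation
#' prompt: the mean, over flagged HVGs, of per-gene dispersion defined as
#' sample variance divided by mean of the log-normalized values; genes with
#' zero mean contribute 0.
#'
#' @param ds CellDataset with `lognorm` and `hvg_flags` layers
#' @return non-negative scalar
#' @export
expression_variability <- function(ds) {
  ln <- ds$layers$lognorm
  hvg <- ds$layers$hvg_flags
  if (is.null(ln) || is.null(hvg)) {
    stop("lognorm and hvg_flags layers required: run prepare_layers() first")
  }
  idx <- which(hvg)
  if (length(idx) == 0) stop("no HVGs flagged")
  sub <- ln[, idx, drop = FALSE]
  mu <- as.numeric(Matrix::colMeans(sub))
  # E[x^2] route keeps sparse matrices sparse; ddof = 1
  n <- nrow(sub)
  ex2 <- as.numeric(Matrix::colMeans(sub^2))
  v <- (ex2 - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  mean(disp)
}

#' Median distance to the k nearest neighbors in PC space
#'
#' The median over all cells x k of Euclidean distances from each cell to
#' its k nearest neighbors (self excluded) in the first `n_pcs` principal
#' components. Exact: brute-force pairwise distances below 5,000 cells,
#' kd-tree search above.
#'
#' @param ds CellDataset with a `pc_embedding` layer
#' @param k number of neighbors (default 20); must be < number of cells
#' @param n_pcs number of leading PCs to use (default 10, capped at stored)
#' @return non-negative scalar
#' @export
median_neighbor_distance <- function(ds, k = 20, n_pcs = 10) {
  emb <- ds$layers$pc_embedding
  if (is.null(emb)) stop("no pc_embedding layer: run compute_pca() first")
  n <- nrow(emb)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (", n, ")")
  if (k < 1) stop("k must be >= 1")
  n_pcs <- min(n_pcs, ncol(emb))
  x <- emb[, seq_len(n_pcs), drop = FALSE]
  if (n <= 5000) {
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    knn <- apply(d, 1, function(row) sort(row, partial = k)[seq_len(k)])
  } else {
    knn <- FNN::get.knn(x, k = k)$nn.dist
  }
  stats::median(as.numeric(knn))
}

#' Top markers per cluster from a marker table
#'
#' Keeps, per cluster, the top `n` genes by descending effect size among
#' rows passing the adjusted-p threshold; ties broken by gene name.
#'
#' @param marker_table data.frame with columns `cluster`, `gene`,
#'   `avg_log2FC`, `p_val_adj`
#' @param n markers kept per cluster
#' @param max_padj adjusted-p cutoff (default 0.05)
#' @return a `ClusterMarkerBundle`: named list (cluster id as string) of
#'   data.frames (gene, avg_log2FC, p_val_adj)
#' @export
top_markers <- function(marker_table, n = 10, max_padj = 0.05) {
  required <- c("cluster", "gene", "avg_log2FC", "p_val_adj")
  miss <- setdiff(required, colnames(marker_table))
  if (length(miss) > 0) {
    stop("marker table missing column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(n >= 1)
  cl <- as.character(marker_table$cluster)
  out <- lapply(split(seq_len(nrow(marker_table)), cl), function(idx) {
    sub <- marker_table[idx, , drop = FALSE]
    sub <- sub[sub$p_val_adj <= max_padj, , drop = FALSE]
    if (nrow(sub) == 0) return(sub[, required])
    o <- order(-sub$avg_log2FC, sub$gene)
    sub[o[seq_len(min(n, nrow(sub)))], required]
  })
  empty <- names(out)[vapply(out, nrow, 0L) == 0]
  if (length(empty) > 0) {
    warning("no significant markers for cluster(s): ",
            paste(empty, collapse = ", "))
  }
  structure(out, class = "ClusterMarkerBundle")
}

#' Compute the derived layers the assistant tasks rely on
#'
#' Fills any missing derived layers using workflow defaults: per-cell
#' scaling to 10,000 counts followed by log1p for the lognorm layer; the
#' `n_hvg` genes with the highest dispersion (variance/mean of lognorm) as
#' HVGs; PCA (centered, on HVG lognorm values) for embedding, loadings and
#' per-PC variance. Layers already present are left untouched, so upstream
#' results are honored.
#'
#' @param ds CellDataset
#' @param n_hvg number of highly variable genes to flag (default 2000,
#'   capped at gene count)
#' @param n_pcs number of PCs to compute (default 10)
#' @return the CellDataset with layers filled
#' @export
prepare_layers <- function(ds, n_hvg = 2000, n_pcs = 10) {
  if (is.null(ds$layers$lognorm)) {
    sf <- ds$cell_meta$total_counts
    sf[sf == 0] <- 1
    ln <- Matrix::Diagonal(x = 10000 / sf) %*% ds$counts
    ds$layers$lognorm <- log1p(methods::as(ln, "CsparseMatrix"))
  }
  ln <- ds$layers$lognorm
  if (is.null(ds$layers$hvg_flags)) {
    mu <- as.numeric(Matrix::colMeans(ln))
    n <- nrow(ln)
    v <- (as.numeric(Matrix::colMeans(ln^2)) - mu^2) * n / (n - 1)
    disp <- ifelse(mu > 0, v / mu, 0)
    n_hvg <- min(n_hvg, ncol(ln))
    flags <- logical(ncol(ln))
    flags[order(-disp, ds$gene_names)[seq_len(n_hvg)]] <- TRUE
    ds$layers$hvg_flags <- flags
  }
  if (is.null(ds$layers$pc_embedding)) {
    idx <- which(ds$layers$hvg_flags)
    x <- as.matrix(ln[, idx, drop = FALSE])
    n_pcs <- min(n_pcs, ncol(x) - 1, nrow(x) - 1)
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
    ds$layers$pc_embedding <- p$x
    ds$layers$pc_variance <- p$sdev[seq_len(n_pcs)]^2
    rot <- p$rotation
    rownames(rot) <- ds$gene_names[idx]
    ds$layers$pc_loadings <- rot
  }
  ds
}
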
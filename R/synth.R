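# Seed-reproducible synthetic single-cell data and canned LLM responses so
# every assistant stage is testable offline.

#' Synthetic dataset configuration
#'
#' Defaults describe the standard offline test world: 500 cells, 1,000
#' genes, 3 populations each carrying 20 planted marker genes up-regulated
#' 8-fold, negative-binomial counts (mean 0.3, dispersion size 2) with
#' log-normal library-size factors (sdlog 0.35).
#'
#' @param n_cells,n_genes matrix dimensions
#' @param n_populations number of cell populations (<= n_cells)
#' @param markers_per_pop planted marker genes per population
#' @param marker_fold fold-change applied to a population's markers
#' @param nb_mean baseline negative-binomial mean per gene scale
#' @param nb_size negative-binomial size (inverse dispersion)
#' @param libsize_sdlog sdlog of the log-normal per-cell library factor
#' @param seed RNG seed
#' @return a `SynthConfig` list
#' @export
synth_config <- function(n_cells = 500, n_genes = 1000, n_populations = 3,
                         markers_per_pop = 20, marker_fold = 8,
                         nb_mean = 0.3, nb_size = 2, libsize_sdlog = 0.35,
                         seed = 1) {
  stopifnot(n_cells > 0, n_genes > 0, n_populations > 0,
            n_populations <= n_cells, markers_per_pop > 0, marker_fold > 0,
            nb_mean > 0, nb_size > 0, libsize_sdlog > 0,
            markers_per_pop * n_populations <= n_genes)
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 n_populations = n_populations,
                 markers_per_pop = markers_per_pop,
                 marker_fold = marker_fold, nb_mean = nb_mean,
                 nb_size = nb_size, libsize_sdlog = libsize_sdlog,
                 seed = seed),
            class = "SynthConfig")
}

#' Generate a synthetic CellDataset
#'
#' Negative-binomial counts with per-gene gamma-distributed baseline means,
#' log-normal per-cell library factors, and each population's planted
#' marker genes up-regulated by the configured fold-change. True population
#' labels are stored as the `cluster_labels` layer (strings "0", "1", ...)
#' and in `cell_meta$true_labels`. Fully reproducible from the seed.
#'
#' @param cfg a `SynthConfig`
#' @return a CellDataset
#' @export
generate_counts <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  pops <- as.character(rep_len(seq_len(cfg$n_populations) - 1L, cfg$n_cells))
  pops <- sort(pops)
  base_mu <- cfg$nb_mean * stats::rgamma(cfg$n_genes, shape = 0.7, rate = 0.7)
  libf <- stats::rlnorm(cfg$n_cells, meanlog = 0, sdlog = cfg$libsize_sdlog)

  marker_idx <- matrix(seq_len(cfg$markers_per_pop * cfg$n_populations),
                       nrow = cfg$n_populations, byrow = TRUE)
  counts <- matrix(0L, cfg$n_cells, cfg$n_genes)
  for (p in seq_len(cfg$n_populations)) {
    cells <- which(pops == as.character(p - 1L))
    mu_p <- base_mu
    mu_p[marker_idx[p, ]] <- mu_p[marker_idx[p, ]] * cfg$marker_fold
    mu_mat <- outer(libf[cells], mu_p)
    counts[cells, ] <- stats::rnbinom(length(mu_mat), mu = mu_mat,
                                      size = cfg$nb_size)
  }
  dimnames(counts) <- list(sprintf("cell_%04d", seq_len(cfg$n_cells)), genes)
  ds <- CellDataset(counts)
  ds$cell_meta$true_labels <- pops
  ds$cell_meta$percent_mito <- round(stats::runif(cfg$n_cells, 0.5, 15), 3)
  ds$layers$cluster_labels <- pops
  attr(ds, "planted_markers") <- lapply(seq_len(cfg$n_populations),
                                        function(p) genes[marker_idx[p, ]])
  ds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Differential-expression marker table from true labels
#'
#' For each population versus the rest: average log2 fold change of
#' expm1(lognorm) means (pseudocount 1) and Wilcoxon rank-sum p-values,
#' BH-adjusted across all tests, in the TSV schema consumed by
#' [top_markers()]. Genes detected in fewer than `min_cells` cells are
#' skipped.
#'
#' @param ds CellDataset with true labels in `cluster_labels`
#' @param min_cells detection floor per gene (default 5)
#' @return data.frame(cluster, gene, avg_log2FC, p_val_adj)
#' @export
generate_marker_table <- function(ds, min_cells = 5) {
  labels <- as.character(ds$layers$cluster_labels)
  if (is.null(labels)) stop("dataset has no cluster_labels layer")
  pops <- sort(unique(labels))
  if (length(pops) < 2) stop("marker table needs at least two populations")
  if (is.null(ds$layers$lognorm)) ds <- prepare_layers(ds)
  ln <- ds$layers$lognorm
  detected <- which(as.numeric(Matrix::colSums(ds$counts > 0)) >= min_cells)

  rows <- list()
  for (p in pops) {
    inp <- labels == p
    sub <- as.matrix(ln[, detected, drop = FALSE])
    mu_in <- colMeans(expm1(sub[inp, , drop = FALSE]))
    mu_out <- colMeans(expm1(sub[!inp, , drop = FALSE]))
    lfc <- log2((mu_in + 1) / (mu_out + 1))
    pv <- vapply(seq_along(detected), function(j) {
      suppressWarnings(stats::wilcox.test(sub[inp, j], sub[!inp, j],
                                          exact = FALSE)$p.value)
    }, 1.0)
    pv[is.na(pv)] <- 1
    rows[[p]] <- data.frame(cluster = p, gene = ds$gene_names[detected],
                            avg_log2FC = lfc, p_val = pv,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$p_val_adj <- stats::p.adjust(tab$p_val, method = "BH")
  rownames(tab) <- NULL
  tab[, c("cluster", "gene", "avg_log2FC", "p_val_adj")]
}

#' Default canned responses for every task
#'
#' One deterministic response text per task id, shaped so each task's
#' parser succeeds on synthetic 3-population data. The recommend_res
#' default reproduces a published tutorial-style output block (resolution
#' range with metric-citing reasoning) so the range/metric parsers have a
#' realistic fixture.
#'
#' @param clusters cluster ids the annotation fixture must cover
#' @return named list task_id -> response text
#' @export
default_fixture_responses <- function(clusters = c("0", "1", "2")) {
  ann <- paste(vapply(seq_along(clusters), function(i) {
    types <- c("NK cells", "CD8 T cells", "B cells", "Monocytes",
               "Dendritic cells")
    sprintf("Cluster %s: %s - strong expression of population marker genes.",
            clusters[i], types[((i - 1) %% length(types)) + 1])
  }, character(1)), collapse = "\n")
  list(
    analyze_quality = paste(
      "Recommended filtering cutoffs:",
      "Keep cells with nFeature_RNA > 200 and < 5000.",
      "Keep cells with percent_mito below 10.",
      "Reasoning: the lower tail of the n_genes_detected distribution",
      "suggests empty droplets below 200 detected genes, while the upper",
      "tail above 5000 is consistent with doublets.", sep = "\n"),
    recommend_normalization = paste(
      "Recommended method: LogNormalize",
      "Reasoning: the moderate library-size coefficient of variation and",
      "the high zero fraction are well served by global scaling followed",
      "by log transformation.", sep = "\n"),
    analyze_variable_features = paste(
      "The most variable genes are dominated by the planted population",
      "markers, suggesting programs that separate the cell populations",
      "rather than cell-cycle or stress signatures.", sep = "\n"),
    recommend_pcs = paste(
      "Recommended number of PCs: 10",
      "Reasoning: the variance-explained profile flattens after the first",
      "few components; ten components capture the dominant structure",
      "while avoiding noise dimensions.", sep = "\n"),
    analyze_pcs = paste(
      "PC1 separates the largest population from the rest, driven by its",
      "planted marker genes; subsequent components capture the remaining",
      "population contrasts.", sep = "\n"),
    recommend_k = paste(
      "Recommended k.param: 10 to 30",
      "Reasoning: with a few hundred cells, small neighborhoods preserve",
      "rare populations while 30 keeps the graph connected.", sep = "\n"),
    recommend_res = paste(
      "## Based on the data characteristics, I recommend: ",
      "## **Recommended Resolution:** seq(0.2, 1.2, 0.1) ",
      "## ",
      "## **Reasoning:** ",
      "## The mean expression variability of 0.868717336264306 suggests a moderate level of heterogeneity in your dataset. This indicates that there are likely distinct cell populations, but they may not be drastically different from each other. The median neighbor distance of 2.50502443313599 in the k-nearest neighbor graph further supports this notion, as it implies a moderate level of separation between cells. ",
      "## Therefore, a resolution range of 0.2 to 1.2 with increments of 0.1 is recommended. This range allows for the identification of both distinct and subtle cell populations. Lower resolutions (closer to 0.2) will capture broader, more general cell types, while higher resolutions (closer to 1.2) will reveal finer distinctions within those populations. By exploring this range, you can effectively identify the optimal resolution for your specific analysis goals.",
      sep = "\n"),
    analyze_and_annotate = ann,
    analyze_enrichment = paste(
      "The over-represented sets point to a coordinated program: PATHWAY_A",
      "is the dominant signal, its overlapping genes acting downstream of",
      "the regulator implied by PATHWAY_B. Key genes from the table are",
      "the population markers with the largest fold changes.", sep = "\n"),
    summary_network = paste(
      "PATHWAY_A|involves|GENE0001",
      "PATHWAY_A|involves|GENE0002",
      "PATHWAY_B|regulates|PATHWAY_A", sep = "\n")
  )
}

#' Build (and optionally write) a replay fixture store
#'
#' The store is the JSON mapping consumed by [make_replay_backend()]:
#' per task a `default` response plus optional prompt-fingerprint-keyed
#' `variants`. Ships the defaults for all ten tasks.
#'
#' @param responses named list task_id -> response text (defaults provided
#'   for missing tasks)
#' @param path optional JSON output path
#' @return the store list (invisibly the path when written)
#' @export
build_fixture_store <- function(responses = list(), path = NULL) {
  unknown <- setdiff(names(responses), task_ids())
  if (length(unknown) > 0) {
    stop("unknown task key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- default_fixture_responses()
  store <- lapply(task_ids(), function(tid) {
    list(default = responses[[tid]] %||% defaults[[tid]],
         variants = stats::setNames(list(), character(0)))
  })
  names(store) <- task_ids()
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(store, auto_unbox = TRUE, pretty = TRUE),
               path)
    return(invisible(path))
  }
  store
}
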
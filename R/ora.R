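#' Over-representation analysis of a gene list against gene sets
#'
#' One-sided hypergeometric test per set: with universe size N, set size K
#' (after intersecting the set with the universe), query size n and overlap
#' k, p = P[X >= k] under Hypergeometric(N, K, n). P-values are adjusted
#' across all tested sets with Benjamini-Hochberg. Gene matching is
#' case-insensitive (identifiers are case-preserved for display).
#'
#' @param query_genes character vector of query gene symbols; members not in
#'   the universe are dropped with a warning
#' @param universe_genes character vector defining the universe (typically
#'   all genes detected in at least one cell)
#' @param sets a `GeneSetCollection` from [read_gene_sets()] or a named list
#'   of character vectors
#' @param max_q keep rows with BH q <= max_q; `Inf` keeps everything
#' @return an `EnrichmentTable` data.frame with columns set, k, K, n, N, p,
#'   q, genes (overlap, "/"-separated), sorted by q then p then set name
#' @export
run_ora <- function(query_genes, universe_genes, sets, max_q = 0.05) {
  uni <- unique(universe_genes)
  uni_key <- tolower(uni)
  if (anyDuplicated(uni_key)) uni <- uni[!duplicated(uni_key)]
  uni_key <- tolower(uni)

  q_in <- unique(query_genes)
  keep <- tolower(q_in) %in% uni_key
  if (any(!keep)) {
    warning(sum(!keep), " query gene(s) not in universe dropped: ",
            paste(utils::head(q_in[!keep], 5), collapse = ", "))
  }
  query <- q_in[keep]
  if (length(query) == 0) stop("empty query after universe filtering")
  qkey <- tolower(query)

  N <- length(uni)
  n <- length(query)
  rows <- lapply(names(sets), function(sn) {
    skey <- unique(tolower(sets[[sn]]))
    skey <- skey[skey %in% uni_key]
    K <- length(skey)
    if (K == 0) return(NULL)
    ov <- query[qkey %in% skey]
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = sn, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(ov), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    stop("no gene set overlaps the universe")
  }
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows <- rows[rows$q <= max_q, , drop = FALSE]
  rows <- rows[order(rows$q, rows$p, rows$set), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows[, c("set", "k", "K", "n", "N", "p", "q", "genes")],
            class = c("EnrichmentTable", "data.frame"))
}

#' Write an EnrichmentTable as TSV
#' @param tab EnrichmentTable; @param path output file
#' @return path invisibly
#' @export
write_enrichment_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
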
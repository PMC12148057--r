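# Groundedness scoring and chunked-embedding semantic similarity for
# auditing LLM responses against data-derived ground truth.

default_stopwords <- c(
  "a", "an", "and", "are", "as", "at", "be", "by", "for", "from", "has",
  "in", "is", "it", "its", "of", "on", "or", "that", "the", "this", "to",
  "was", "were", "which", "will", "with", "we", "our", "your", "you",
  "these", "those", "their", "they", "not", "but", "can", "may", "also")

#' Tokenize text into a normalized term set
#'
#' Splits on any character that is not alphanumeric, hyphen or underscore
#' (so gene-style tokens like `NF-kB` survive intact), case-folds, strips
#' leading/trailing hyphens, drops stopwords and tokens shorter than 2
#' characters, and deduplicates.
#'
#' @param text input text ("" gives the empty set)
#' @param stopwords words to drop (a small default list)
#' @return a `TokenSet`: character vector with set semantics
#' @export
tokenize_terms <- function(text, stopwords = default_stopwords) {
  if (is.null(text) || !nzchar(text)) {
    return(structure(character(0), class = "TokenSet"))
  }
  toks <- strsplit(tolower(text), "[^a-z0-9_-]+")[[1]]
  toks <- gsub("^[-_]+|[-_]+$", "", toks)
  toks <- toks[nchar(toks) >= 2]
  toks <- setdiff(unique(toks), stopwords)
  structure(toks, class = "TokenSet")
}

#' Groundedness of a response against ground truth
#'
#' G = |GT intersect LLM| / |LLM|: the fraction of the response's terms that
#' appear in the ground-truth term set; an indirect hallucination measure
#' (1 means every response term is grounded).
#'
#' @param gt ground-truth TokenSet (or character vector)
#' @param resp response TokenSet (or character vector); must be non-empty
#' @return a `GroundednessScore`: list(G, intersection, response_size)
#' @export
groundedness <- function(gt, resp) {
  gt <- unique(as.character(gt)); resp <- unique(as.character(resp))
  if (length(resp) == 0) stop("groundedness undefined for an empty response")
  inter <- length(intersect(gt, resp))
  structure(list(G = inter / length(resp), intersection = inter,
                 response_size = length(resp)),
            class = "GroundednessScore")
}

#' Deterministic bag-of-words embedder over a fixed vocabulary
#'
#' A test/reference embedder: maps a chunk of tokens to its term-count
#' vector over `vocab`. Token-disjoint documents embed to orthogonal
#' vectors, and results are exactly reproducible across runs — the
#' transformer embedder it stands in for is pluggable via the same
#' function contract (tokens -> fixed-length numeric vector).
#'
#' @param vocab character vector defining the embedding dimensions
#' @return a function(tokens) -> numeric vector of length `length(vocab)`
#' @export
bow_embedder <- function(vocab) {
  vocab <- unique(vocab)
  function(tokens) {
    v <- table(factor(tokens, levels = vocab))
    as.numeric(v)
  }
}

#' Embed a document by chunking and mean pooling
#'
#' Tokenizes the text (simple word tokenizer, order preserved), splits the
#' token stream into ceiling(L / (chunk_limit - 2)) consecutive
#' non-overlapping chunks — two slots per chunk are reserved for the
#' start/end special markers a transformer adds — embeds each chunk, and
#' mean-pools the chunk vectors.
#'
#' @param text document text; must be non-empty
#' @param embedder function(tokens) -> numeric vector
#' @param chunk_limit model input length including the 2 special tokens
#'   (default 512)
#' @return a `DocumentEmbedding`: list(vector, n_chunks, pooling)
#' @export
embed_document <- function(text, embedder, chunk_limit = 512) {
  if (is.null(text) || !nzchar(trimws(text))) stop("empty document")
  toks <- strsplit(tolower(text), "[^a-z0-9_-]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) stop("document has no tokens")
  usable <- chunk_limit - 2
  stopifnot(usable >= 1)
  n_chunks <- ceiling(length(toks) / usable)
  idx <- split(seq_along(toks), ceiling(seq_along(toks) / usable))
  mats <- vapply(idx, function(i) embedder(toks[i]),
                 numeric(length(embedder(toks[idx[[1]]]))))
  vec <- if (is.null(dim(mats))) mats else rowMeans(mats)
  structure(list(vector = as.numeric(vec), n_chunks = n_chunks,
                 pooling = "mean"),
            class = "DocumentEmbedding")
}

#' Cosine semantic similarity of two documents
#'
#' Both documents are chunk-embedded with the same embedder and the cosine
#' of the pooled vectors is returned.
#'
#' @param doc_a,doc_b document texts
#' @param embedder function(tokens) -> numeric vector
#' @param chunk_limit as in [embed_document()]
#' @return value in [-1, 1]
#' @export
semantic_similarity <- function(doc_a, doc_b, embedder, chunk_limit = 512) {
  a <- embed_document(doc_a, embedder, chunk_limit)$vector
  b <- embed_document(doc_b, embedder, chunk_limit)$vector
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm embedding")
  sum(a * b) / (na * nb)
}

#' Assemble ground truth from a run directory
#'
#' Collects the term sets a run actually supplied to the LLM — the metric
#' values and gene lists embedded in each saved RecommendationRecord's
#' rendered prompt — as the ground truth for groundedness audits.
#'
#' @param run_dir directory containing `*.json` RecommendationRecords
#' @return a TokenSet
#' @export
collect_ground_truth <- function(run_dir) {
  files <- list.files(run_dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0) stop("no record files in ", run_dir)
  toks <- unlist(lapply(files, function(f) {
    rec <- read_record(f)
    tokenize_terms(rec$rendered_prompt)
  }))
  structure(unique(toks), class = "TokenSet")
}
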
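# Parsers turning free-text LLM responses into structured payloads. Each is
# total on the packaged fixture corpus; on unrecognized input they stop()
# and run_task() preserves the raw text flagged unparsed.

num_re <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"

#' Parse a resolution range from response text
#'
#' Recognizes the `seq(a, b, s)` dialect and the prose dialect
#' "a to b ... (steps|increments) of s"; the first match wins.
#'
#' @param text response text
#' @return a `ResolutionRange`: list(start, stop, step, reasoning)
#' @export
parse_seq_range <- function(text) {
  stopifnot(nzchar(text))
  seq_pat <- paste0("seq\\(\\s*(", num_re, ")\\s*,\\s*(", num_re,
                    ")\\s*,\\s*(", num_re, ")\\s*\\)")
  m <- regexec(seq_pat, text)
  hit <- regmatches(text, m)[[1]]
  if (length(hit) == 0) {
    prose_pat <- paste0("(", num_re, ")\\s+to\\s+(", num_re,
                        ")[^.]*?(?:steps|increments)\\s+of\\s+(", num_re, ")")
    m <- regexec(prose_pat, text)
    hit <- regmatches(text, m)[[1]]
  }
  if (length(hit) == 0) stop("no recognizable resolution range in response")
  vals <- as.numeric(hit[2:4])
  resolution_range(vals[1], vals[2], vals[3], reasoning = text)
}

#' @rdname parse_seq_range
#' @param start,stop,step positive reals with start <= stop, step > 0
#' @param reasoning free text carried alongside
#' @export
resolution_range <- function(start, stop, step, reasoning = "") {
  if (start > stop) stop("invalid range: start > stop")
  if (step <= 0) stop("invalid range: step must be positive")
  if (start < stop && step > stop - start) {
    stop("invalid range: step exceeds stop - start")
  }
  structure(list(start = start, stop = stop, step = step,
                 reasoning = reasoning),
            class = "ResolutionRange")
}

#' Parse filtering cutoffs from response text
#'
#' Numbers are bound to metrics via the nearest preceding metric mention;
#' direction words decide the side: "min"/"above"/">" give a lower bound,
#' "max"/"below"/"<" an upper bound. Common aliases (nFeature_RNA,
#' nCount_RNA) map onto the container's column names.
#'
#' @param text response text
#' @param metric_names metrics to look for
#' @return a `FilterCutoffs`: per-metric list(lower, upper), plus reasoning
#' @export
parse_cutoffs <- function(text, metric_names) {
  stopifnot(length(metric_names) > 0)
  aliases <- list(
    n_genes_detected = c("n_genes_detected", "nFeature_RNA", "nFeature"),
    total_counts = c("total_counts", "nCount_RNA", "nCount"))
  patterns <- lapply(metric_names, function(mn) {
    al <- if (mn %in% names(aliases)) aliases[[mn]] else mn
    paste0("(?i)(", paste(al, collapse = "|"), ")")
  })
  names(patterns) <- metric_names

  # locate every metric mention and every number; bind each number to the
  # nearest preceding mention, then classify direction from local context
  mention_pos <- integer(0); mention_metric <- character(0)
  for (mn in metric_names) {
    g <- gregexpr(patterns[[mn]], text, perl = TRUE)[[1]]
    if (g[1] != -1) {
      mention_pos <- c(mention_pos, as.integer(g))
      mention_metric <- c(mention_metric, rep(mn, length(g)))
    }
  }
  if (length(mention_pos) == 0) stop("no metric mention found in response")
  o <- order(mention_pos)
  mention_pos <- mention_pos[o]; mention_metric <- mention_metric[o]

  g <- gregexpr(num_re, text)[[1]]
  if (g[1] == -1) stop("no numbers found in response")
  num_pos <- as.integer(g)
  num_val <- as.numeric(regmatches(text, gregexpr(num_re, text))[[1]])

  out <- stats::setNames(
    rep(list(list(lower = NULL, upper = NULL)), length(metric_names)),
    metric_names)
  for (i in seq_along(num_pos)) {
    prev <- which(mention_pos < num_pos[i])
    if (length(prev) == 0) next
    mn <- mention_metric[max(prev)]
    ctx <- substr(text, max(1, num_pos[i] - 40), num_pos[i] - 1)
    lower <- grepl("(?i)min|above|greater|more than|at least|>", ctx, perl = TRUE)
    upper <- grepl("(?i)max|below|less than|under|at most|<", ctx, perl = TRUE)
    # the word nearest the number wins when both directions appear
    if (lower && upper) {
      lp <- max(unlist(gregexpr("(?i)min|above|greater|>", ctx, perl = TRUE)))
      up <- max(unlist(gregexpr("(?i)max|below|less|under|<", ctx, perl = TRUE)))
      if (lp > up) upper <- FALSE else lower <- FALSE
    }
    # first assignment per side wins: the recommendation precedes the
    # reasoning, which may re-mention the numbers in other directions
    if (lower && is.null(out[[mn]]$lower)) out[[mn]]$lower <- num_val[i]
    else if (upper && is.null(out[[mn]]$upper)) out[[mn]]$upper <- num_val[i]
  }
  got <- vapply(out, function(b) !is.null(b$lower) || !is.null(b$upper),
                TRUE)
  if (!any(got)) stop("no metric mention with a bound number found")
  for (mn in names(out)) {
    b <- out[[mn]]
    if (!is.null(b$lower) && !is.null(b$upper) && b$lower >= b$upper) {
      stop("invalid cutoffs for ", mn, ": lower (", b$lower,
           ") must be below upper (", b$upper, ")")
    }
  }
  structure(list(cutoffs = out, reasoning = text), class = "FilterCutoffs")
}

#' Parse per-cluster cell-type annotations
#'
#' Expects one entry per cluster of the form
#' `Cluster <id>: <label> - <reasoning>`; reasoning is optional. Labels for
#' clusters that were not asked about are ignored with a warning; any
#' requested cluster missing from the text is an error (listing them), so
#' dataset write-back stays atomic.
#'
#' @param text response text
#' @param clusters character vector of cluster ids that must be covered
#' @return an `AnnotationTable`: data.frame(cluster, label, reasoning)
#' @export
parse_annotations <- function(text, clusters) {
  stopifnot(length(clusters) > 0)
  clusters <- as.character(clusters)
  pat <- "(?im)^[^A-Za-z0-9]*cluster[[:space:]]*([A-Za-z0-9_.-]+)[[:space:]]*[:\\-][[:space:]]*(.+)$"
  g <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (g[1] == -1) stop("no 'Cluster <id>: <label>' entries found")
  lines <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  ids <- character(0); labels <- character(0); reasons <- character(0)
  for (ln in lines) {
    m <- regexec(pat, ln, perl = TRUE)
    parts <- regmatches(ln, m)[[1]]
    id <- parts[2]
    rest <- trimws(parts[3])
    split <- regexpr("\\s+[-—–]\\s+|\\s*—\\s*", rest)
    if (split > 0) {
      lab <- trimws(substr(rest, 1, split - 1))
      rea <- trimws(substr(rest, split + attr(split, "match.length"),
                           nchar(rest)))
    } else {
      lab <- trimws(sub("[.]\\s*$", "", rest)); rea <- ""
    }
    ids <- c(ids, id); labels <- c(labels, lab); reasons <- c(reasons, rea)
  }
  extra <- setdiff(ids, clusters)
  if (length(extra) > 0) {
    warning("ignoring annotations for unknown cluster(s): ",
            paste(extra, collapse = ", "))
  }
  keep <- ids %in% clusters
  ids <- ids[keep]; labels <- labels[keep]; reasons <- reasons[keep]
  keep <- !duplicated(ids)
  ids <- ids[keep]; labels <- labels[keep]; reasons <- reasons[keep]
  missing <- setdiff(clusters, ids)
  if (length(missing) > 0) {
    stop("annotation missing cluster(s); missing: ",
         paste(sort(missing), collapse = ", "))
  }
  o <- order(match(ids, clusters))
  structure(data.frame(cluster = ids[o], label = labels[o],
                       reasoning = reasons[o], stringsAsFactors = FALSE),
            class = c("AnnotationTable", "data.frame"))
}

#' Extract the numeric metric values echoed in a response
#'
#' Metric-echo parsing: pulls every number the LLM's reasoning cites so it
#' can be audited against the values actually supplied in the prompt.
#'
#' @param text response text
#' @return numeric vector (possibly empty)
#' @export
echoed_numbers <- function(text) {
  hits <- regmatches(text, gregexpr(num_re, text))[[1]]
  as.numeric(hits)
}

#' Parse a recommended PC count
#' @param text response text
#' @return integer
#' @export
parse_pc_count <- function(text) {
  m <- regexec(paste0("(?i)recommended number of PCs[^0-9]*([0-9]+)"), text,
               perl = TRUE)
  hit <- regmatches(text, m)[[1]]
  if (length(hit) == 0) {
    m <- regexec("(?i)([0-9]+)\\s*(?:principal components|PCs)", text,
                 perl = TRUE)
    hit <- regmatches(text, m)[[1]]
  }
  if (length(hit) == 0) stop("no PC count found in response")
  as.integer(hit[2])
}

#' Parse a recommended k.param range
#' @param text response text
#' @return list(low, high)
#' @export
parse_k_range <- function(text) {
  m <- regexec("(?i)k\\.?param[^0-9]*([0-9]+)\\s*(?:to|-|–)\\s*([0-9]+)",
               text, perl = TRUE)
  hit <- regmatches(text, m)[[1]]
  if (length(hit) == 0) {
    m <- regexec("(?i)([0-9]+)\\s*(?:to|-|–)\\s*([0-9]+)", text,
                 perl = TRUE)
    hit <- regmatches(text, m)[[1]]
  }
  if (length(hit) == 0) stop("no k.param range found in response")
  lo <- as.integer(hit[2]); hi <- as.integer(hit[3])
  if (lo > hi) stop("invalid k range: low > high")
  list(low = lo, high = hi)
}

#' Parse a normalization method choice from a menu
#' @param text response text
#' @param menu candidate method names
#' @return the chosen method name
#' @export
parse_method_choice <- function(text, menu) {
  pos <- vapply(menu, function(m) {
    p <- regexpr(paste0("(?i)", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", m)),
                 text, perl = TRUE)
    if (p == -1) NA_integer_ else as.integer(p)
  }, 1L)
  if (all(is.na(pos))) {
    stop("no method from the menu mentioned in response")
  }
  menu[which.min(pos)]
}

#' Parse network edges from "source|relation|target" lines
#'
#' Malformed lines are skipped with a warning; duplicate edges are removed;
#' self-loops are dropped. Zero parsable edges is an error with the raw text
#' preserved in the condition message.
#'
#' @param text response text
#' @return data.frame(source, relation, target)
#' @export
parse_network_edges <- function(text) {
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "|", fixed = TRUE)
  ok <- lengths(parts) == 3
  if (any(!ok) && any(ok)) {
    warning("skipped ", sum(!ok), " malformed network line(s)")
  }
  parts <- parts[ok]
  parts <- lapply(parts, trimws)
  edges <- do.call(rbind, lapply(parts, function(p) {
    data.frame(source = p[1], relation = p[2], target = p[3],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(edges)) {
    edges <- edges[nzchar(edges$source) & nzchar(edges$target) &
                     edges$source != edges$target, , drop = FALSE]
    edges <- edges[!duplicated(edges), , drop = FALSE]
  }
  if (is.null(edges) || nrow(edges) == 0) {
    stop("zero parsable network edges in response; raw text: ", text)
  }
  rownames(edges) <- NULL
  edges
}
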
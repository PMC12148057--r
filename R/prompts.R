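#' Task ids known to the assistant
#' @return character vector of the ten registered task ids
#' @export
task_ids <- function() {
  c("analyze_quality", "recommend_normalization", "analyze_variable_features",
    "recommend_pcs", "analyze_pcs", "recommend_k", "recommend_res",
    "analyze_and_annotate", "analyze_enrichment", "summary_network")
}

#' Fetch the prompt template for a task
#'
#' Templates are plain-text package resources (one file per task) so users
#' can edit them; a file named `<task_id>.txt` in `template_dir` overrides
#' the packaged version. Placeholders use single braces `{name}`; literal
#' braces are written doubled (`{{`, `}}`).
#'
#' @param task_id one of [task_ids()]
#' @param template_dir optional user override directory
#' @return a `PromptTemplate`: list with `task_id`, `text`,
#'   `required_placeholders`
#' @export
get_template <- function(task_id, template_dir = NULL) {
  if (!task_id %in% task_ids()) {
    stop("unknown task id '", task_id, "'; valid: ",
         paste(task_ids(), collapse = ", "))
  }
  path <- NULL
  if (!is.null(template_dir)) {
    cand <- file.path(template_dir, paste0(task_id, ".txt"))
    if (file.exists(cand)) path <- cand
  }
  if (is.null(path)) {
    path <- system.file("templates", paste0(task_id, ".txt"),
                        package = "scadvisor")
    if (!nzchar(path)) stop("packaged template missing for ", task_id)
  }
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  structure(list(task_id = task_id, text = text,
                 required_placeholders = template_placeholders(text)),
            class = "PromptTemplate")
}

# placeholder names in a template, ignoring doubled-brace escapes
template_placeholders <- function(text) {
  scrubbed <- gsub("\\{\\{|\\}\\}", "", text)
  m <- gregexpr("\\{([A-Za-z0-9_]+)\\}", scrubbed)
  hits <- regmatches(scrubbed, m)[[1]]
  unique(gsub("[{}]", "", hits))
}

#' Render an augmented prompt
#'
#' Substitutes every placeholder in the template with the supplied value,
#' injecting the free-text experiment description at its placeholder.
#' Substituted values are treated as literal text: brace sequences inside a
#' value are never re-expanded. Numbers should be pre-formatted at full
#' precision by the caller ([format_full()] does this).
#'
#' @param template a `PromptTemplate` from [get_template()]
#' @param values named list/character of placeholder substitutions
#' @param experiment_description optional free text; when absent the
#'   placeholder resolves to a fixed "not provided" sentence
#' @return an `AugmentedPrompt`: list with `task_id`, `text`, `values`
#' @export
render_prompt <- function(template, values = list(),
                          experiment_description = NULL) {
  stopifnot(inherits(template, "PromptTemplate"))
  values <- lapply(values, as.character)
  if ("experiment_description" %in% template$required_placeholders &&
      is.null(values$experiment_description)) {
    values$experiment_description <-
      if (is.null(experiment_description) || !nzchar(experiment_description))
        "No experiment description was provided."
      else experiment_description
  }
  missing <- setdiff(template$required_placeholders, names(values))
  if (length(missing) > 0) {
    stop("unfilled: ", paste(missing, collapse = ", "))
  }
  # tokenize template on escapes and placeholders, then substitute: values
  # are inserted verbatim so they can never be re-expanded
  text <- template$text
  out <- character(0)
  i <- 1L
  nc <- nchar(text)
  while (i <= nc) {
    rest <- substr(text, i, nc)
    if (startsWith(rest, "{{")) { out <- c(out, "{"); i <- i + 2L; next }
    if (startsWith(rest, "}}")) { out <- c(out, "}"); i <- i + 2L; next }
    m <- regexpr("^\\{([A-Za-z0-9_]+)\\}", rest)
    if (m == 1L) {
      len <- attr(m, "match.length")
      key <- substr(rest, 2, len - 1)
      out <- c(out, values[[key]])
      i <- i + len
      next
    }
    nxt <- regexpr("[{}]", substr(rest, 2, nchar(rest)))
    take <- if (nxt == -1L) nchar(rest) else nxt
    out <- c(out, substr(rest, 1, take))
    i <- i + take
  }
  structure(list(task_id = template$task_id,
                 text = paste(out, collapse = ""),
                 values = values),
            class = "AugmentedPrompt")
}

#' Format a number at full precision for prompt injection
#'
#' The LLM sees exactly what was computed: up to 15 significant digits, no
#' scientific notation for the magnitudes that occur in these metrics.
#'
#' @param x numeric vector
#' @return character vector
#' @export
format_full <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE),
         character(1))
}
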
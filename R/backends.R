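#' Configure an LLM backend
#'
#' Supported servers: `"google"` (default model gemini-1.5-flash-latest),
#' `"openai"` (gpt-4o-mini), `"ollama"` (llama3, local HTTP server), and
#' `"replay"` — a deterministic offline store of canned responses used by
#' the entire test suite so no network I/O ever happens.
#'
#' @param server one of google, openai, ollama, replay
#' @param model model id; per-server default when NULL
#' @param api_key_file path to a file whose first line is the API key
#'   (required for google/openai)
#' @param base_url base URL for the ollama server
#' @param fixtures path to a replay fixture store (JSON), or the store
#'   itself as a list (required for replay)
#' @param temperature sampling temperature; 0 by default so parameter
#'   advice is reproducible
#' @param timeout per-request timeout, seconds
#' @param max_retries attempts on 5xx/timeout failures (exponential
#'   backoff); 4xx fails fast
#' @return a `BackendConfig`
#' @export
backend_config <- function(server, model = NULL, api_key_file = NULL,
                           base_url = "http://localhost:11434",
                           fixtures = NULL, temperature = 0,
                           timeout = 120, max_retries = 3) {
  supported <- c("google", "openai", "ollama", "replay")
  if (!server %in% supported) {
    stop("unknown server '", server, "'; supported: ",
         paste(supported, collapse = ", "))
  }
  if (is.null(model)) {
    model <- switch(server,
                    google = "gemini-1.5-flash-latest",
                    openai = "gpt-4o-mini",
                    ollama = "llama3",
                    replay = "replay-fixture")
  }
  if (server %in% c("google", "openai")) {
    if (is.null(api_key_file)) {
      stop("server '", server, "' requires api_key_file")
    }
    if (!file.exists(api_key_file)) {
      stop("api_key_file does not exist: ", api_key_file)
    }
  }
  if (server == "replay") {
    if (is.null(fixtures)) stop("replay backend requires a fixture store")
    if (is.character(fixtures)) {
      if (!file.exists(fixtures)) {
        stop("fixture store does not exist: ", fixtures)
      }
      fixtures <- jsonlite::fromJSON(fixtures, simplifyVector = FALSE)
    }
  }
  structure(list(server = server, model = model,
                 api_key_file = api_key_file, base_url = base_url,
                 fixtures = fixtures, temperature = temperature,
                 timeout = timeout, max_retries = max_retries),
            class = "BackendConfig")
}

#' Replay backend from a fixture store
#'
#' Convenience wrapper: a [backend_config()] whose `complete()` is pure —
#' the same prompt always yields the same stored response. Fixtures are
#' keyed by task id plus a stable hash of the rendered prompt; unmatched
#' prompts fall back to the task's default fixture so metric jitter does not
#' break replay.
#'
#' @param fixture_store_path JSON store path or in-memory store list
#' @return a `BackendConfig` with server = "replay"
#' @export
make_replay_backend <- function(fixture_store_path) {
  backend_config("replay", fixtures = fixture_store_path)
}

#' Read an API key file
#'
#' Returns the whitespace-stripped first line. The key is never echoed in
#' logs or error messages.
#'
#' @param path key file path
#' @return the key string
#' @export
read_api_key <- function(path) {
  if (!file.exists(path)) stop("api key file does not exist: ", path)
  lines <- readLines(path, n = 1, warn = FALSE)
  key <- if (length(lines) == 0) "" else trimws(lines[1])
  if (!nzchar(key)) stop("api key file is empty")
  key
}

#' Stable fingerprint of a rendered prompt (replay fixture key)
#' @param text prompt text
#' @return 12-hex-character string
#' @export
prompt_fingerprint <- function(text) {
  substr(digest::digest(text, algo = "sha256", serialize = FALSE), 1, 12)
}

#' Send an augmented prompt to the configured backend
#'
#' For remote servers performs the HTTP call with retries on transient
#' failures; for the replay backend looks up the stored fixture. Request and
#' response metadata (never the API key) are carried in the returned object
#' for provenance.
#'
#' @param cfg a `BackendConfig`
#' @param prompt an `AugmentedPrompt` (or plain string with a `task_id`
#'   attribute for the replay store)
#' @return an `LLMResponse`: list with `text`, `model_id`, `finish_reason`,
#'   `usage`
#' @export
complete <- function(cfg, prompt) {
  stopifnot(inherits(cfg, "BackendConfig"))
  if (cfg$server == "replay") return(replay_complete(cfg, prompt))
  key <- if (cfg$server %in% c("google", "openai")) {
    read_api_key(cfg$api_key_file)
  } else NULL
  req <- build_request(cfg, prompt, key)
  resp <- http_post_with_retries(cfg, req)
  text <- extract_completion_text(cfg$server, resp)
  if (!nzchar(text)) stop("backend returned an empty completion")
  llm_response(text, cfg$model)
}

llm_response <- function(text, model_id, finish_reason = "stop",
                         usage = NULL) {
  structure(list(text = text, model_id = model_id,
                 finish_reason = finish_reason, usage = usage),
            class = "LLMResponse")
}

replay_complete <- function(cfg, prompt) {
  task_id <- if (inherits(prompt, "AugmentedPrompt")) prompt$task_id
             else attr(prompt, "task_id")
  text <- if (inherits(prompt, "AugmentedPrompt")) prompt$text
          else as.character(prompt)
  if (is.null(task_id)) stop("replay backend needs a task id on the prompt")
  entry <- cfg$fixtures[[task_id]]
  if (is.null(entry)) {
    stop("fixture store has no entry for task '", task_id, "'")
  }
  fp <- prompt_fingerprint(text)
  hit <- entry$variants[[fp]]
  if (is.null(hit)) hit <- entry$default
  if (is.null(hit)) {
    stop("fixture store has no default for task '", task_id, "'")
  }
  llm_response(as.character(hit), cfg$model, finish_reason = "replay")
}

# --- remote request construction (pure; unit-testable offline) -----------

#' Build the HTTP request for a remote backend
#'
#' Pure function mapping (config, prompt, key) to url/body/headers, so the
#' wire contracts can be tested without any network I/O.
#'
#' @param cfg BackendConfig; @param prompt AugmentedPrompt or string;
#' @param key API key string (google/openai)
#' @return list(url, body, headers)
#' @keywords internal
build_request <- function(cfg, prompt, key = NULL) {
  text <- if (inherits(prompt, "AugmentedPrompt")) prompt$text
          else as.character(prompt)
  switch(cfg$server,
    google = list(
      url = paste0("https://generativelanguage.googleapis.com/v1beta/models/",
                   cfg$model, ":generateContent?key=", key),
      body = list(contents = list(list(parts = list(list(text = text)))),
                  generationConfig = list(temperature = cfg$temperature)),
      headers = c("Content-Type" = "application/json")),
    openai = list(
      url = "https://api.openai.com/v1/chat/completions",
      body = list(model = cfg$model,
                  messages = list(list(role = "user", content = text)),
                  temperature = cfg$temperature),
      headers = c("Content-Type" = "application/json",
                  Authorization = paste("Bearer", key))),
    ollama = list(
      url = paste0(sub("/$", "", cfg$base_url), "/api/generate"),
      body = list(model = cfg$model, prompt = text, stream = FALSE,
                  options = list(temperature = cfg$temperature)),
      headers = c("Content-Type" = "application/json")),
    stop("no remote contract for server ", cfg$server)
  )
}

http_post_with_retries <- function(cfg, req) {
  if (!requireNamespace("httr", quietly = TRUE)) {
    stop("remote backends require the httr package")
  }
  attempt <- 0
  repeat {
    attempt <- attempt + 1
    out <- tryCatch({
      r <- httr::POST(req$url, body = req$body, encode = "json",
                      httr::add_headers(.headers = req$headers),
                      httr::timeout(cfg$timeout))
      code <- httr::status_code(r)
      if (code %in% c(401, 403)) {
        stop("authentication failed (HTTP ", code,
             "): check the API key file contents")
      }
      if (code >= 400 && code < 500) {
        stop("request rejected (HTTP ", code, ")")
      }
      if (code >= 500) stop("transient:server error (HTTP ", code, ")")
      httr::content(r, as = "parsed", type = "application/json")
    }, error = function(e) e)
    if (!inherits(out, "error")) return(out)
    transient <- grepl("transient:|Timeout|timed out", conditionMessage(out))
    if (!transient || attempt > cfg$max_retries) stop(out)
    Sys.sleep(2^(attempt - 1))
  }
}

extract_completion_text <- function(server, parsed) {
  switch(server,
    google = parsed$candidates[[1]]$content$parts[[1]]$text,
    openai = parsed$choices[[1]]$message$content,
    ollama = parsed$response,
    stop("unknown server"))
}
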
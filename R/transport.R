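# Transport layer: every remote Rfam interaction goes through fetch() on a
# connection object. Two backends exist -- a live HTTP client and a
# deterministic on-disk replay store. Replay mode performs no network I/O at
# all: an unrecorded request is a loud replay-miss error, never a silent
# download. Requests are canonicalized (endpoint kind + sorted parameters +
# uppercase sequence digest) so the same logical request always maps to the
# same recorded entry.

ENDPOINT_KINDS <- c("summary", "secondary_structure", "structure_image",
                    "seed_alignment", "seed_tree", "seed_tree_image",
                    "covariance_model", "regions", "pdb_mapping",
                    "text_search", "search_submit", "search_poll", "id_lookup")

RFAM_SEARCH_WINDOW <- 10000L  # server-side length limit per query

#' Open a connection to the Rfam service or a replay store
#'
#' @param backend `"replay"` (deterministic, offline; reads a recorded store)
#'   or `"http"` (live service; requires network and the \pkg{curl} package).
#' @param replay_dir Directory holding a recorded replay store (required for
#'   the replay backend).
#' @param base_url Base URL of the live service.
#' @param max_retries Retry cap for transient failures.
#' @param backoff_initial,backoff_multiplier,backoff_cap Exponential backoff
#'   schedule (seconds) used both for retries and for search-job polling.
#' @param poll_timeout Overall per-fragment polling budget in seconds.
#' @param submit_spacing Minimum spacing between live job submissions (s).
#' @param sleep_fn Sleeping function; injectable for tests.
#' @return An object of class `rfam_connection`.
#' @export
rfam_connection <- function(backend = c("replay", "http"), replay_dir = NULL,
                            base_url = "https://rfam.org",
                            max_retries = 3L, backoff_initial = 5,
                            backoff_multiplier = 1.5, backoff_cap = 60,
                            poll_timeout = 600, submit_spacing = 1,
                            sleep_fn = Sys.sleep) {
  backend <- match.arg(backend)
  if (backend == "replay") {
    if (is.null(replay_dir) || !dir.exists(replay_dir)) {
      stop_rfam("bad_config", "replay backend requires an existing replay_dir")
    }
  }
  structure(list(backend = backend, replay_dir = replay_dir,
                 base_url = base_url, max_retries = as.integer(max_retries),
                 backoff_initial = backoff_initial,
                 backoff_multiplier = backoff_multiplier,
                 backoff_cap = backoff_cap, poll_timeout = poll_timeout,
                 submit_spacing = submit_spacing, sleep_fn = sleep_fn,
                 state = new.env(parent = emptyenv())),
            class = c(paste0("rfam_", backend, "_connection"), "rfam_connection"))
}

#' @export
print.rfam_connection <- function(x, ...) {
  cat(sprintf("<rfam_connection> backend=%s %s\n", x$backend,
              if (x$backend == "replay") x$replay_dir else x$base_url))
  invisible(x)
}

#' Build an endpoint request
#'
#' @param kind One of the endpoint kinds (`summary`, `seed_alignment`,
#'   `search_submit`, ...).
#' @param accession_or_id Family accession/ID where the endpoint takes one.
#' @param params Named list of additional parameters (plot type, alignment
#'   format, sequence digest, job identifier, ...).
#' @return An object of class `endpoint_request`.
#' @export
endpoint_request <- function(kind, accession_or_id = NULL, params = list()) {
  if (!(kind %in% ENDPOINT_KINDS)) {
    stop_rfam("bad_request", sprintf("unknown endpoint kind '%s'", kind))
  }
  structure(list(kind = kind, accession_or_id = accession_or_id,
                 params = params),
            class = "endpoint_request")
}

# Canonical replay key: kind | accession | sorted k=v params. Long keys (e.g.
# with sequence digests) are already fixed-length because sequences enter only
# through their md5 digest.
canonical_request_key <- function(request) {
  params <- request$params
  if (length(params)) params <- params[order(names(params))]
  kv <- if (length(params)) {
    paste(names(params), vapply(params, as.character, ""), sep = "=", collapse = "&")
  } else ""
  paste(request$kind, request$accession_or_id %||% "", kv, sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(x, f, eos = NULL, useBytes = TRUE)
  unname(tools::md5sum(f))
}

request_entry_id <- function(request) md5_string(canonical_request_key(request))

#' Record a response into a replay store
#'
#' Each entry is a JSON envelope (`<id>.json` holding the canonical request,
#' HTTP-like status and declared content kind) plus a raw body file
#' (`<id>.body`).
#'
#' @param replay_dir Store directory (created if missing).
#' @param request An [endpoint_request()].
#' @param body Response body (character scalar).
#' @param status Integer status (200 success, 404 not found, 503 transient).
#' @param content_kind Declared kind (`"json"`, `"stockholm"`, `"nhx"`,
#'   `"cm"`, `"svg"`, `"text"`).
#' @return The entry identifier, invisibly.
#' @export
record_response <- function(replay_dir, request, body, status = 200L,
                            content_kind = "json") {
  dir.create(replay_dir, recursive = TRUE, showWarnings = FALSE)
  id <- request_entry_id(request)
  envelope <- list(request = list(kind = request$kind,
                                  accession_or_id = request$accession_or_id,
                                  params = request$params),
                   status = as.integer(status), content_kind = content_kind)
  jsonlite::write_json(envelope, file.path(replay_dir, paste0(id, ".json")),
                       auto_unbox = TRUE, null = "null")
  writeChar(body, file.path(replay_dir, paste0(id, ".body")), eos = NULL,
            useBytes = TRUE)
  invisible(id)
}

read_replay_entry <- function(replay_dir, request) {
  id <- request_entry_id(request)
  env_path <- file.path(replay_dir, paste0(id, ".json"))
  if (!file.exists(env_path)) return(NULL)
  envelope <- jsonlite::read_json(env_path)
  body_path <- file.path(replay_dir, paste0(id, ".body"))
  body <- readChar(body_path, file.info(body_path)$size, useBytes = TRUE)
  list(status = envelope$status, content_kind = envelope$content_kind, body = body)
}

# Monotone non-decreasing exponential backoff schedule, capped.
backoff_delays <- function(n, initial, multiplier, cap) {
  if (n <= 0L) return(numeric(0))
  pmin(initial * multiplier^(seq_len(n) - 1L), cap)
}

#' Fetch a response for an endpoint request
#'
#' Returns the body verbatim together with its declared content kind; payload
#' parsing happens in the format layer. Transient failures are retried up to
#' the connection's cap with exponential backoff.
#'
#' @param conn An [rfam_connection()].
#' @param request An [endpoint_request()].
#' @return A list with elements `body`, `content_kind`, `status`.
#' @export
fetch <- function(conn, request) {
  stopifnot(inherits(conn, "rfam_connection"), inherits(request, "endpoint_request"))
  delays <- backoff_delays(conn$max_retries, conn$backoff_initial,
                           conn$backoff_multiplier, conn$backoff_cap)
  attempt <- 0L
  repeat {
    res <- tryCatch(fetch_once(conn, request), rfamtools_service_unavailable = identity)
    if (!inherits(res, "condition")) return(res)
    attempt <- attempt + 1L
    if (attempt > length(delays)) stop(res)
    conn$sleep_fn(delays[attempt])
  }
}

fetch_once <- function(conn, request) UseMethod("fetch_once")

#' @export
fetch_once.rfam_replay_connection <- function(conn, request) {
  entry <- read_replay_entry(conn$replay_dir, request)
  if (is.null(entry)) {
    stop_rfam("replay_miss",
              sprintf("no recorded response for request '%s'",
                      canonical_request_key(request)),
              key = canonical_request_key(request))
  }
  if (entry$status == 404L) {
    stop_rfam("family_not_found",
              sprintf("not found: %s", request$accession_or_id %||% request$kind))
  }
  if (entry$status >= 500L) {
    stop_rfam("service_unavailable",
              sprintf("recorded status %d for %s", entry$status, request$kind))
  }
  list(body = entry$body, content_kind = entry$content_kind, status = entry$status)
}

# Live HTTP backend. Exercised only with network access; every offline code
# path uses the replay backend instead.
#' @export
fetch_once.rfam_http_connection <- function(conn, request) {
  if (!requireNamespace("curl", quietly = TRUE)) {
    stop_rfam("bad_config", "the live backend requires the 'curl' package")
  }
  url <- live_url(conn, request)
  h <- curl::new_handle()
  curl::handle_setheaders(h, Accept = "application/json")
  res <- tryCatch(curl::curl_fetch_memory(url, handle = h),
                  error = function(e) NULL)
  if (is.null(res)) stop_rfam("service_unavailable", sprintf("request to %s failed", url))
  if (res$status_code == 404L) {
    stop_rfam("family_not_found", sprintf("not found: %s", url))
  }
  if (res$status_code >= 500L) {
    stop_rfam("service_unavailable", sprintf("status %d from %s", res$status_code, url))
  }
  list(body = rawToChar(res$content), content_kind = "text",
       status = res$status_code)
}

live_url <- function(conn, request) {
  acc <- request$accession_or_id
  p <- request$params
  base <- conn$base_url
  switch(request$kind,
    summary = sprintf("%s/family/%s?content-type=application/json", base, acc),
    secondary_structure = sprintf("%s/family/%s/structure?content-type=application/json", base, acc),
    structure_image = sprintf("%s/family/%s/image/%s", base, acc, p$plot_type %||% "norm"),
    seed_alignment = sprintf("%s/family/%s/alignment?format=stockholm", base, acc),
    seed_tree = sprintf("%s/family/%s/tree/", base, acc),
    seed_tree_image = sprintf("%s/family/%s/tree/label/%s/image", base, acc, p$label %||% "species"),
    covariance_model = sprintf("%s/family/%s/cm", base, acc),
    regions = sprintf("%s/family/%s/regions?content-type=application/json", base, acc),
    pdb_mapping = sprintf("%s/family/%s/structures?content-type=application/json", base, acc),
    text_search = sprintf("%s/search?q=%s&content-type=application/json", base,
                          utils::URLencode(p$q %||% "", reserved = TRUE)),
    id_lookup = sprintf("%s/family/%s?content-type=application/json", base, acc),
    search_submit = sprintf("%s/search/sequence", base),
    search_poll = sprintf("%s/search/sequence/%s", base, p$job_id %||% ""))
}

#' Submit one sequence fragment for a remote family search
#'
#' Never blocks on job completion: returns a handle to poll with
#' [poll_search()]. Fragments longer than the service's 10,000-nt limit are
#' rejected locally.
#'
#' @param conn An [rfam_connection()].
#' @param fragment A `sequence_fragment` (see [extract_fragments()]).
#' @return A list of class `job_handle` with `job_id` and `fragment`.
#' @export
submit_search <- function(conn, fragment) {
  stopifnot(inherits(fragment, "sequence_fragment"))
  if (nchar(fragment$residues) > RFAM_SEARCH_WINDOW) {
    stop_rfam("fragment_too_long",
              sprintf("fragment of %d nt exceeds the %d-nt search limit",
                      nchar(fragment$residues), RFAM_SEARCH_WINDOW))
  }
  request <- endpoint_request("search_submit",
                              params = list(seq_digest = md5_string(toupper(fragment$residues))))
  if (conn$backend == "http") {
    last <- conn$state$last_submit %||% -Inf
    wait <- conn$submit_spacing - (as.numeric(Sys.time()) - last)
    if (is.finite(wait) && wait > 0) conn$sleep_fn(wait)
    conn$state$last_submit <- as.numeric(Sys.time())
  }
  res <- fetch(conn, request)
  job_id <- jsonlite::fromJSON(res$body)$job_id
  if (is.null(job_id) || !nzchar(job_id)) {
    stop_rfam("service_unavailable", "submission response carried no job identifier")
  }
  structure(list(job_id = job_id, fragment = fragment), class = "job_handle")
}

#' Poll a submitted search job
#'
#' @param conn An [rfam_connection()].
#' @param handle A `job_handle` from [submit_search()].
#' @return A list with `status` (`"pending"` or `"done"`) and, when done,
#'   `hits`: the raw per-fragment hit records (fragment-local coordinates).
#' @export
poll_search <- function(conn, handle) {
  stopifnot(inherits(handle, "job_handle"))
  request <- endpoint_request("search_poll", params = list(job_id = handle$job_id))
  res <- tryCatch(fetch(conn, request), rfamtools_replay_miss = function(e) {
    stop_rfam("job_expired", sprintf("unknown or expired job '%s'", handle$job_id))
  })
  payload <- jsonlite::fromJSON(res$body, simplifyVector = FALSE)
  if (identical(payload$status, "pending")) {
    return(list(status = "pending"))
  }
  if (!identical(payload$status, "done")) {
    stop_rfam("service_unavailable",
              sprintf("unexpected job status '%s'", payload$status %||% "<none>"))
  }
  list(status = "done", hits = payload$hits %||% list())
}

# Poll until done, sleeping per the connection's backoff schedule.
await_search <- function(conn, handle) {
  deadline <- as.numeric(Sys.time()) + conn$poll_timeout
  delay <- conn$backoff_initial
  repeat {
    res <- poll_search(conn, handle)
    if (res$status == "done") return(res)
    if (as.numeric(Sys.time()) >= deadline) {
      stop_rfam("job_expired",
                sprintf("job '%s' did not complete within %gs",
                        handle$job_id, conn$poll_timeout))
    }
    conn$sleep_fn(delay)
    delay <- min(delay * conn$backoff_multiplier, conn$backoff_cap)
  }
}

#' Resolve a family accession/ID to its (accession, ID) pair
#'
#' The mapping is bijective: looking up either member of the pair returns the
#' same pair.
#'
#' @param conn An [rfam_connection()].
#' @param accession_or_id Family accession (`RFxxxxx`) or ID (e.g. `"tRNA"`).
#' @return A list with `accession` and `id`.
#' @export
lookup_id <- function(conn, accession_or_id) {
  validate_accession(accession_or_id)
  res <- fetch(conn, endpoint_request("id_lookup", accession_or_id))
  pair <- jsonlite::fromJSON(res$body)
  list(accession = pair$accession, id = pair$id)
}

#' Keyword search over family IDs, summaries and descriptions
#'
#' @param conn An [rfam_connection()].
#' @param query Non-empty keyword.
#' @return Character vector of matching family accessions, de-duplicated, in
#'   the server's stable order.
#' @export
text_search <- function(conn, query) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    stop_rfam("bad_request", "query must be a non-empty string")
  }
  res <- fetch(conn, endpoint_request("text_search", params = list(q = query)))
  accs <- unlist(jsonlite::fromJSON(res$body, simplifyVector = TRUE))
  unique(as.character(accs %||% character()))
}
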
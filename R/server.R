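# --- Beacon v2 response assembly for the mock ------------------------------

mock_meta <- function(granularity) {
  list(apiVersion = "v2.0", beaconId = "org.beaconcnv.mock",
       returnedGranularity = granularity)
}

mock_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
}

# Answer one request against the in-memory dataset; shared by the HTTP
# server and the in-process dataset transport, so endpoint answers are
# always reproducible by direct computation on the dataset.
mock_respond <- function(dataset, path, params = list()) {
  parts <- strsplit(sub("^/+", "", path), "/")[[1]]
  known <- c(BEACON_ENTITIES, "filtering_terms")
  hit <- which(parts %in% known)
  if (length(hit) == 0) {
    return(list(status = 404L, body = mock_json(list(
      error = list(errorCode = 404, errorMessage = paste0("No such endpoint: ", path))
    ))))
  }
  entity <- parts[hit[length(hit)]]
  trailing_id <- if (hit[length(hit)] < length(parts)) parts[length(parts)] else NULL

  if (identical(entity, "filtering_terms")) {
    terms <- lapply(seq_len(nrow(dataset$filtering_terms)), function(i) {
      as.list(dataset$filtering_terms[i, ])
    })
    body <- list(meta = mock_meta("record"),
                 response = list(filteringTerms = terms))
    return(list(status = 200L, body = mock_json(body)))
  }

  filters <- split_param(params$filters)
  bs_ids <- split_param(params$biosampleIds)
  ind_ids <- split_param(params$individualIds)
  if (!is.null(trailing_id)) {
    if (entity == "biosamples") bs_ids <- c(bs_ids, trailing_id)
    if (entity == "individuals") ind_ids <- c(ind_ids, trailing_id)
  }
  ids <- mock_matching_ids(dataset, entity, filters, bs_ids, ind_ids)
  total <- length(ids)
  granularity <- params$requestedGranularity %||% "record"

  if (identical(granularity, "count")) {
    body <- list(meta = mock_meta("count"),
                 responseSummary = list(exists = total > 0,
                                        numTotalResults = total))
    return(list(status = 200L, body = mock_json(body)))
  }
  if (identical(granularity, "boolean")) {
    body <- list(meta = mock_meta("boolean"),
                 responseSummary = list(exists = total > 0))
    return(list(status = 200L, body = mock_json(body)))
  }

  skip <- as.integer(params$skip %||% 0)
  limit <- as.integer(params$limit %||% 0)
  page <- ids
  if (skip > 0) page <- if (skip < length(page)) page[-seq_len(skip)] else character(0)
  if (limit > 0 && length(page) > limit) page <- page[seq_len(limit)]
  docs <- mock_entity_docs(dataset, entity, page)

  body <- list(
    meta = mock_meta("record"),
    responseSummary = list(exists = total > 0, numTotalResults = total),
    response = list(resultSets = list(list(
      id = "mock-dataset", setType = "dataset", exists = total > 0,
      resultsCount = length(docs), results = docs
    )))
  )
  list(status = 200L, body = mock_json(body))
}

split_param <- function(x) {
  if (is.null(x) || !nzchar(x)) return(character())
  strsplit(x, ",", fixed = TRUE)[[1]]
}

parse_query_string <- function(qs) {
  qs <- sub("^\\?", "", qs %||% "")
  if (!nzchar(qs)) return(list())
  pairs <- strsplit(strsplit(qs, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(pairs, function(p) utils::URLdecode(p[2] %||% ""))
  setNames(vals, vapply(pairs, `[[`, "", 1))
}

# fault = list(mode = "500" | "timeout" | "malformed", after = 0, times = Inf)
# applies to request numbers after < k <= after + times, making retry logic
# deterministically testable.
fault_active <- function(fault, k) {
  if (is.null(fault)) return(FALSE)
  after <- fault$after %||% 0
  times <- fault$times %||% Inf
  k > after && k <= after + times
}

#' In-process mock transport
#'
#' A [transports] function answering straight from a [generate_cohort()]
#' dataset — the client's full request/parse path runs, but no socket is
#' involved. Pass a single dataset (any hostname is answered) or a named
#' list of datasets keyed by `host` or `host:port` to emulate a federation;
#' requests for hosts not in the list fail like an unreachable domain.
#'
#' @param dataset a `mock_dataset`, or a named list of them.
#' @param fault optional fault injection: `list(mode = "500" | "timeout" |
#'   "malformed", after = 0, times = Inf)`, applied to the request counter.
#' @return a transport function.
#' @export
dataset_transport <- function(dataset, fault = NULL) {
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  function(url) {
    counter$k <- counter$k + 1L
    if (fault_active(fault, counter$k)) {
      switch(fault$mode,
        "500" = abort("HTTP 500 Internal Server Error (injected fault)"),
        timeout = abort("Timeout was reached (injected fault)"),
        malformed = return("{\"meta\": this is not json"),
        abort(paste0("Unknown fault mode ", sQuote(fault$mode)))
      )
    }
    u <- sub("^https?://", "", url)
    host <- sub("/.*$", "", u)
    rest <- sub("^[^/]*", "", u)
    path <- sub("\\?.*$", "", rest)
    params <- parse_query_string(sub("^[^?]*", "", rest))
    ds <- if (inherits(dataset, "mock_dataset")) {
      dataset
    } else {
      key <- if (host %in% names(dataset)) host else sub(":.*$", "", host)
      if (!key %in% names(dataset)) {
        abort(paste0("Could not resolve host ", sQuote(host), " (unreachable)"))
      }
      dataset[[key]]
    }
    resp <- mock_respond(ds, path, params)
    if (resp$status >= 400) {
      abort(paste0("HTTP ", resp$status, " from mock for ", url))
    }
    resp$body
  }
}

# --- real local HTTP server -------------------------------------------------

#' Serve a mock dataset over local HTTP
#'
#' Starts a Beacon-v2-shaped HTTP endpoint for a generated dataset in a
#' background R process (httpuv), answering
#' `/{entry_point}/{entity}`, `/{entry_point}/{entity}/{id}` and
#' `/{entry_point}/filtering_terms` with protocol envelopes (meta,
#' responseSummary, response.resultSets), honoring multi-filter AND
#' semantics, `limit`/`skip` paging and `requestedGranularity`. Faults
#' (HTTP 500, stalled response, malformed JSON) can be injected per request
#' count to exercise client retry and partial-failure paths.
#'
#' @param dataset a `mock_dataset` from [generate_cohort()].
#' @param port TCP port; default: a free port chosen by the OS range walk.
#' @param fault see [dataset_transport()].
#' @param startup_timeout seconds to wait for the server to come up.
#' @return a `mock_server` handle with `$domain` (e.g. `"localhost:8123"`),
#'   usable directly as a query domain. Stop it with [stop_mock_server()].
#' @export
serve_mock <- function(dataset, port = NULL, fault = NULL,
                       startup_timeout = 15) {
  for (pkg in c("callr", "httpuv")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(paste0("serve_mock() needs the ", pkg, " package."))
    }
  }
  stopifnot(inherits(dataset, "mock_dataset"))
  port <- port %||% httpuv::randomPort()
  rds <- tempfile(fileext = ".rds")
  saveRDS(list(dataset = dataset, fault = fault), rds)
  proc <- callr::r_bg(
    function(rds, port) {
      x <- readRDS(rds)
      beaconcnv:::serve_mock_blocking(x$dataset, port, x$fault)
    },
    args = list(rds = rds, port = port),
    supervise = TRUE
  )
  base <- sprintf("http://127.0.0.1:%d", port)
  deadline <- Sys.time() + startup_timeout
  repeat {
    if (!proc$is_alive()) {
      abort(paste0("Mock server failed to start (port ", port, " busy?): ",
                   paste(proc$read_all_error_lines(), collapse = " ")))
    }
    ok <- suppressWarnings(tryCatch({
      con <- url(paste0(base, "/ready"), open = "rb")
      on.exit(close(con), add = TRUE)
      length(readLines(con, warn = FALSE)) > 0
    }, error = function(e) FALSE))
    if (ok) break
    if (Sys.time() > deadline) {
      proc$kill()
      abort("Mock server did not become ready in time.")
    }
    Sys.sleep(0.1)
  }
  structure(list(process = proc, port = port,
                 domain = sprintf("localhost:%d", port), url = base),
            class = "mock_server")
}

# blocking server loop, run inside the background process
serve_mock_blocking <- function(dataset, port, fault = NULL) {
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  app <- list(call = function(req) {
    path <- req$PATH_INFO %||% "/"
    if (identical(path, "/ready")) {
      return(list(status = 200L, headers = list("Content-Type" = "text/plain"),
                  body = "ok"))
    }
    counter$k <- counter$k + 1L
    if (fault_active(fault, counter$k)) {
      switch(fault$mode,
        "500" = return(list(status = 500L,
                            headers = list("Content-Type" = "application/json"),
                            body = mock_json(list(error = list(
                              errorCode = 500,
                              errorMessage = "injected fault"))))),
        timeout = Sys.sleep(fault$sleep %||% 3600),
        malformed = return(list(status = 200L,
                                headers = list("Content-Type" = "application/json"),
                                body = "{\"meta\": this is not json"))
      )
    }
    params <- parse_query_string(req$QUERY_STRING %||% "")
    resp <- mock_respond(dataset, path, params)
    list(status = resp$status,
         headers = list("Content-Type" = "application/json"),
         body = resp$body)
  })
  httpuv::runServer("127.0.0.1", port, app)
}

#' @rdname serve_mock
#' @param server a `mock_server` handle.
#' @export
stop_mock_server <- function(server) {
  stopifnot(inherits(server, "mock_server"))
  if (server$process$is_alive()) server$process$kill()
  invisible(NULL)
}

#' @export
print.mock_server <- function(x, ...) {
  cat("<mock_server>", x$url,
      if (x$process$is_alive()) "(running)" else "(stopped)", "\n")
  invisible(x)
}
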
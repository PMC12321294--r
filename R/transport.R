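#' Transports: how requests reach a beacon
#'
#' A transport is a function taking a full request URL and returning the
#' response body as a single JSON string, or signalling an error on failure.
#' Three transports ship with the package:
#'
#' * `http_transport()` — live HTTP(S) GET with timeout and retry policy;
#' * `fixture_transport()` — canned responses from a directory of JSON files
#'   keyed by request URL (written by [export_fixture_files()]);
#' * [dataset_transport()] — in-process answers computed directly from a
#'   [generate_cohort()] dataset, no sockets involved.
#'
#' All query functions accept any of them through their `transport` argument,
#' so the same client code runs against live beacons, canned files, or an
#' in-memory mock.
#'
#' @param timeout seconds before a request is abandoned (default 30).
#' @param retries number of retry attempts after a failure (default 2).
#' @param backoff base of the exponential backoff between retries, in seconds;
#'   attempt k waits `backoff * 2^(k-1)`.
#' @return a transport function of one argument (the request URL).
#' @name transports
#' @export
http_transport <- function(timeout = 30, retries = 2, backoff = 0.5) {
  force(timeout); force(retries); force(backoff)
  function(url) {
    attempt <- 0L
    repeat {
      # base url() reports HTTP error statuses as a warning followed by a
      # bare "cannot open" error; treat the warning as the failure so the
      # status survives into the envelope's error message
      result <- tryCatch({
        withr::local_options(timeout = timeout)
        con <- url(url, open = "rb")
        on.exit(close(con), add = TRUE)
        paste(readLines(con, warn = FALSE), collapse = "\n")
      }, error = function(e) e, warning = function(w) {
        simpleError(conditionMessage(w))
      })
      if (!inherits(result, "error")) return(result)
      attempt <- attempt + 1L
      if (attempt > retries) {
        abort(paste0("Request failed after ", retries + 1L, " attempt(s): ",
                     conditionMessage(result)))
      }
      Sys.sleep(backoff * 2^(attempt - 1L))
    }
  }
}

#' @rdname transports
#' @param dir directory holding canned responses, one
#'   `<hash-of-url>.json` per request URL.
#' @export
fixture_transport <- function(dir) {
  force(dir)
  function(url) {
    path <- file.path(dir, paste0(url_fixture_key(url), ".json"))
    if (!file.exists(path)) {
      abort(paste0("No canned response for ", url, " (expected ", path, ")."))
    }
    paste(readLines(path, warn = FALSE), collapse = "\n")
  }
}
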
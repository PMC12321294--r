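#' Beacon response envelopes
#'
#' Every query function returns (or aggregates) `beacon_envelope` objects: a
#' faithful, lightly typed view of one domain's Beacon v2 response. Failures
#' along the federation path are captured in the `error` field — they never
#' propagate as R errors, so one unreachable domain cannot abort a
#' multi-domain query.
#'
#' @section Fields:
#' * `domain` — hostname answered (or queried, on failure);
#' * `granularity` — `"boolean"`, `"count"`, or `"record"`;
#' * `total_count` — server-reported `numTotalResults` (`NA` when absent;
#'   boolean granularity is represented as 0 / 1 with the granularity tag,
#'   not coerced into a real count);
#' * `records` — list of nested entity documents (empty unless record
#'   granularity);
#' * `error` — `NULL`, or one message describing what failed;
#' * `elapsed` — wall-clock seconds spent on the request (informational).
#' @name beacon_envelope
NULL

new_beacon_envelope <- function(domain, granularity = NA_character_,
                                total_count = NA_integer_, records = list(),
                                error = NULL, elapsed = NA_real_) {
  structure(
    list(domain = domain, granularity = granularity,
         total_count = total_count, records = records,
         error = error, elapsed = elapsed),
    class = "beacon_envelope"
  )
}

#' @export
print.beacon_envelope <- function(x, ...) {
  cat("<beacon_envelope>", x$domain, "\n")
  if (!is.null(x$error)) {
    cat("  error:", x$error, "\n")
  } else {
    cat("  granularity:", x$granularity,
        " records:", length(x$records),
        " total_count:", x$total_count, "\n")
  }
  invisible(x)
}

# Parse a Beacon v2 JSON body into an envelope. Handles record, count and
# boolean granularities plus the /filtering_terms response shape.
parse_beacon_body <- function(text, domain) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!is.null(doc$error)) {
    msg <- scalar_or(doc$error$errorMessage, "server-side error")
    return(new_beacon_envelope(domain, error = as.character(msg)))
  }
  granularity <- scalar_or(doc$meta$returnedGranularity, NA_character_)
  total <- doc$responseSummary$numTotalResults
  exists <- doc$responseSummary$exists

  records <- list()
  if (!is.null(doc$response$filteringTerms)) {
    records <- doc$response$filteringTerms
    granularity <- scalar_or(granularity, "record")
  } else if (!is.null(doc$response$resultSets)) {
    for (rs in doc$response$resultSets) {
      if (!is.null(rs$results)) records <- c(records, rs$results)
    }
  }

  if (is.na(granularity)) {
    granularity <- if (length(records)) "record"
      else if (!is.null(total)) "count"
      else "boolean"
  }
  total_count <- if (!is.null(total)) {
    as.integer(total)
  } else if (identical(granularity, "boolean") && !is.null(exists)) {
    as.integer(isTRUE(exists))
  } else if (identical(granularity, "record")) {
    length(records)
  } else {
    NA_integer_
  }
  if (!identical(granularity, "record")) records <- list()
  new_beacon_envelope(domain, granularity = granularity,
                      total_count = total_count, records = records)
}

#' Fetch one entity from one beacon domain
#'
#' Executes a single GET against `https://{domain}/{entry_point}/{endpoint}`
#' and parses the Beacon v2 envelope. Transport failures, HTTP errors and
#' malformed JSON are captured in the returned envelope's `error` field.
#'
#' @param query a [beacon_query()].
#' @param domain,entry_point target domain and API prefix; default to the
#'   first entries of `query$domains` / `query$entry_points`.
#' @param transport a transport function, see [transports].
#' @return a [beacon_envelope].
#' @export
fetch_entity <- function(query, domain = NULL, entry_point = NULL,
                         transport = http_transport()) {
  stopifnot(inherits(query, "beacon_query"))
  domain <- domain %||% query$domains[1]
  entry_point <- entry_point %||%
    (if (length(query$entry_points)) query$entry_points[1] else "beacon")
  if (is.null(domain) || is.na(domain)) {
    abort("No domain given: set `domains` in the query or pass `domain`.")
  }
  req <- build_request(query, domain, entry_point)
  t0 <- proc.time()[["elapsed"]]
  env <- tryCatch(
    parse_beacon_body(transport(req$full_url), domain),
    error = function(e) new_beacon_envelope(domain, error = conditionMessage(e))
  )
  env$elapsed <- proc.time()[["elapsed"]] - t0
  env
}

#' Count matching records across domains
#'
#' Issues a count-granularity query to every domain in the query and tabulates
#' the reported totals. A failing domain yields a row with `NA` count plus a
#' warning; if every domain fails the table still comes back (all `NA`) with
#' an aggregate warning — never an error.
#'
#' @param query a [beacon_query()]; needs at least one filter or id.
#' @param transport a transport function, see [transports].
#' @return a tibble with columns `domain`, `entity`, `count`, `error`.
#' @export
fetch_counts <- function(query, transport = http_transport()) {
  stopifnot(inherits(query, "beacon_query"))
  if (length(query$filters) + length(query$biosample_ids) +
      length(query$individual_ids) == 0) {
    abort("A counts query needs at least one filter or id.")
  }
  cq <- query
  cq$entity_type <- "counts"
  if (query$entity_type %in% BEACON_ENTITIES) cq$count_entity <- query$entity_type
  if (length(cq$domains) == 0) abort("No domains in query.")

  rows <- purrr::map2(cq$domains, cq$entry_points, function(d, ep) {
    env <- fetch_entity(cq, d, ep, transport = transport)
    tibble(domain = d, entity = cq$count_entity,
           count = if (is.null(env$error)) env$total_count else NA_integer_,
           error = env$error %||% NA_character_)
  })
  out <- bind_rows(rows)
  failed <- out$domain[!is.na(out$error)]
  if (length(failed) == length(cq$domains) && length(failed) > 0) {
    warn(paste0("All ", length(failed), " domain(s) failed; counts are NA."))
  } else if (length(failed) > 0) {
    warn(paste0("Count query failed for domain(s): ",
                paste(failed, collapse = ", ")))
  }
  out
}

#' List (and pattern-search) a beacon's filtering terms
#'
#' Retrieves the `/filtering_terms` informational endpoint — the inventory of
#' queryable fields and permissible values — optionally narrowed by keyword
#' patterns. A term is kept when its id or label contains ANY pattern,
#' case-insensitively (so `"male"` also matches `"Female"`); server order is
#' preserved.
#'
#' @param domain,entry_point beacon hostname and API prefix.
#' @param patterns character vector of keyword patterns; empty = all terms.
#' @param transport a transport function, see [transports].
#' @return a tibble with columns `id`, `label`, `scope`, `type`.
#' @export
fetch_filtering_terms <- function(domain, entry_point = "beacon",
                                  patterns = character(),
                                  transport = http_transport()) {
  q <- beacon_query("filtering_terms")
  env <- fetch_entity(q, domain, entry_point, transport = transport)
  if (!is.null(env$error)) {
    abort(paste0("Filtering terms unsupported or unreachable on ", domain,
                 ": ", env$error))
  }
  terms <- purrr::map(env$records, function(t) {
    tibble(id = scalar_or(t$id, NA_character_),
           label = as.character(scalar_or(t$label, NA_character_)),
           scope = as.character(scalar_or(t$scope, NA_character_)),
           type = as.character(scalar_or(t$type, NA_character_)))
  })
  out <- bind_rows(terms)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), label = character(),
                  scope = character(), type = character())
  }
  if (length(patterns) > 0 && nrow(out) > 0) {
    hit <- rep(FALSE, nrow(out))
    for (p in patterns) {
      hit <- hit |
        stringr::str_detect(out$id, stringr::fixed(p, ignore_case = TRUE)) |
        (!is.na(out$label) &
           stringr::str_detect(out$label, stringr::fixed(p, ignore_case = TRUE)))
    }
    out <- out[hit, , drop = FALSE]
  }
  out
}

#' Query several beacon domains and merge the answers
#'
#' Runs the same entity query against every domain in `query`, in parallel up
#' to `num_workers` processes, flattens each record-granularity response with
#' the entity's mapping configuration, and row-binds the per-domain tables
#' with a `domain` provenance column. Column sets are harmonized (union,
#' absent cells `NA`). Per-domain failures are isolated in their envelopes;
#' the merged table then simply lacks that domain's rows. The merged table is
#' identical whatever `num_workers` is.
#'
#' Identical records returned by two domains are NOT deduplicated: every row
#' keeps its provenance and it is the analyst's call whether they are the
#' same specimen.
#'
#' @param query a [beacon_query()] with nonempty `domains`.
#' @param num_workers parallel worker processes (>= 1).
#' @param transport a transport function, see [transports].
#' @param config a [load_mapping()] configuration; default: the packaged
#'   config for the query's entity.
#' @return list with class `beacon_federation`: `envelopes` (per-domain
#'   [beacon_envelope]s) and `table` (merged tibble, first column `domain`).
#' @export
fetch_multi_domain <- function(query, num_workers = 1,
                               transport = http_transport(),
                               config = NULL) {
  stopifnot(inherits(query, "beacon_query"))
  if (length(query$domains) == 0) abort("`query` has no domains.")
  if (num_workers < 1) abort("`num_workers` must be >= 1.")
  config <- config %||% default_mapping(query$entity_type)

  idx <- seq_along(query$domains)
  run_one <- function(i) {
    fetch_entity(query, query$domains[i], query$entry_points[i],
                 transport = transport)
  }
  envelopes <- if (num_workers == 1 || length(idx) == 1) {
    lapply(idx, run_one)
  } else {
    parallel::mclapply(idx, run_one,
                       mc.cores = min(num_workers, length(idx)))
  }
  # mclapply can surface worker-level failures as try-error objects
  envelopes <- lapply(idx, function(i) {
    e <- envelopes[[i]]
    if (inherits(e, "beacon_envelope")) e
    else new_beacon_envelope(query$domains[i],
                             error = paste("worker failure:",
                                           paste(as.character(e), collapse = " ")))
  })

  tables <- lapply(envelopes, function(env) {
    if (!is.null(env$error) || length(env$records) == 0) return(NULL)
    flatten_records(env$records, config, domain = env$domain)
  })
  merged <- harmonize_tables(purrr::compact(tables))
  structure(list(envelopes = envelopes, table = merged),
            class = "beacon_federation")
}

#' @export
print.beacon_federation <- function(x, ...) {
  ok <- sum(vapply(x$envelopes, function(e) is.null(e$error), logical(1)))
  cat("<beacon_federation> ", ok, "/", length(x$envelopes),
      " domain(s) answered, ", nrow(x$table), " merged row(s)\n", sep = "")
  invisible(x)
}
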
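BEACON_ENTITIES <- c("individuals", "biosamples", "analyses", "g_variants")
QUERY_TYPES <- c(BEACON_ENTITIES, "filtering_terms", "counts")

#' Describe one Beacon v2 request
#'
#' Bundles everything needed to query one or several Beacon v2 domains: the
#' target entity, CURIE filters (combined with AND by the Beacon protocol),
#' id constraints, target domains with their API entry points, and paging.
#'
#' @param entity_type one of `"individuals"`, `"biosamples"`, `"analyses"`,
#'   `"g_variants"`, `"filtering_terms"`, or `"counts"`. `"counts"` requests
#'   count granularity for an entity given in `count_entity`.
#' @param filters character vector of filter values, typically CURIEs such as
#'   `"NCIT:C3512"`. Multiple filters are combined with AND. Non-CURIE
#'   free-text filters are permitted but flagged with a warning.
#' @param biosample_ids,individual_ids character vectors of record identifiers
#'   to constrain the query.
#' @param domains character vector of beacon hostnames (a scheme prefix such
#'   as `http://localhost:8080` is honored; plain hostnames default to https,
#'   localhost addresses to http).
#' @param entry_points character vector of API path prefixes, parallel to
#'   `domains` (recycled if length 1). Default `"beacon"`.
#' @param count_entity entity counted when `entity_type = "counts"`.
#' @param limit,skip non-negative paging integers; `limit = 0` means
#'   "server default page size".
#' @return an object of class `beacon_query`.
#' @export
#' @examples
#' beacon_query("biosamples", filters = c("NCIT:C20197", "NCIT:C3512"),
#'              domains = "progenetix.org")
beacon_query <- function(entity_type,
                         filters = character(),
                         biosample_ids = character(),
                         individual_ids = character(),
                         domains = character(),
                         entry_points = "beacon",
                         count_entity = "biosamples",
                         limit = 0L,
                         skip = 0L) {
  entity_type <- match_entity_type(entity_type)
  count_entity <- match.arg(count_entity, BEACON_ENTITIES)
  filters <- as.character(filters)
  if (any(!nzchar(filters))) {
    abort("`filters` must be nonempty strings.")
  }
  free_text <- filters[!is_curie(filters)]
  if (length(free_text) > 0) {
    warn(paste0("Non-CURIE filter value(s): ",
                paste(sQuote(free_text), collapse = ", "),
                ". They are passed through verbatim."))
  }
  if (length(domains) > 0) {
    if (length(entry_points) == 1L) {
      entry_points <- rep(entry_points, length(domains))
    }
    if (length(entry_points) != length(domains)) {
      abort("`domains` and `entry_points` must have equal lengths (entry points pair with domains).")
    }
  }
  if (limit < 0 || skip < 0) abort("`limit` and `skip` must be non-negative.")
  if (identical(entity_type, "counts") &&
      length(filters) + length(biosample_ids) + length(individual_ids) == 0) {
    abort("A counts query needs at least one filter or id.")
  }
  structure(
    list(
      entity_type = entity_type,
      filters = filters,
      biosample_ids = as.character(biosample_ids),
      individual_ids = as.character(individual_ids),
      domains = as.character(domains),
      entry_points = as.character(entry_points),
      count_entity = count_entity,
      limit = as.integer(limit),
      skip = as.integer(skip)
    ),
    class = "beacon_query"
  )
}

match_entity_type <- function(entity_type) {
  if (length(entity_type) != 1L || !entity_type %in% QUERY_TYPES) {
    abort(paste0("Unknown entity_type ", sQuote(entity_type[1]),
                 ". Valid values: ", paste(QUERY_TYPES, collapse = ", "), "."))
  }
  entity_type
}

#' @export
print.beacon_query <- function(x, ...) {
  cat("<beacon_query>", x$entity_type, "\n")
  if (length(x$filters)) cat("  filters:", paste(x$filters, collapse = " AND "), "\n")
  if (length(x$domains)) cat("  domains:", paste(x$domains, collapse = ", "), "\n")
  invisible(x)
}

#' Build the request descriptor for one domain
#'
#' Maps a [beacon_query()] onto a concrete Beacon v2 GET request: the endpoint
#' URL `scheme://{domain}/{entry_point}/{endpoint}` plus a query-parameter
#' map. Filters are joined comma-separated, the Beacon v2 GET convention for
#' AND-combined filters; a counts query targets the counted entity's endpoint
#' with `requestedGranularity=count`.
#'
#' @param query a [beacon_query()].
#' @param domain beacon hostname (optionally with `http://`/`https://`).
#' @param entry_point API path prefix, e.g. `"beacon"` or `"api"`.
#' @return a `beacon_request`: list with `url` (endpoint without query
#'   string), `params` (named character), and `full_url`.
#' @export
#' @examples
#' q <- beacon_query("biosamples", filters = c("NCIT:C20197", "NCIT:C3512"))
#' build_request(q, "progenetix.org", "beacon")$full_url
build_request <- function(query, domain, entry_point = "beacon") {
  stopifnot(inherits(query, "beacon_query"))
  if (!nzchar(domain)) abort("`domain` must be nonempty.")
  endpoint <- if (identical(query$entity_type, "counts")) {
    query$count_entity
  } else {
    query$entity_type
  }
  base <- domain_base_url(domain)
  path <- paste(c(base, entry_point, endpoint), collapse = "/")

  params <- character()
  if (length(query$filters)) {
    params["filters"] <- paste(query$filters, collapse = ",")
  }
  if (length(query$biosample_ids)) {
    params["biosampleIds"] <- paste(query$biosample_ids, collapse = ",")
  }
  if (length(query$individual_ids)) {
    params["individualIds"] <- paste(query$individual_ids, collapse = ",")
  }
  if (identical(query$entity_type, "counts")) {
    params["requestedGranularity"] <- "count"
  }
  if (query$limit > 0) params["limit"] <- as.character(query$limit)
  if (query$skip > 0) params["skip"] <- as.character(query$skip)

  full <- if (length(params)) {
    paste0(path, "?", paste(paste0(names(params), "=",
                                   vapply(params, utils::URLencode, "", reserved = TRUE)),
                            collapse = "&"))
  } else {
    path
  }
  structure(list(url = path, params = params, full_url = full),
            class = "beacon_request")
}

# Hostnames default to https; loopback hosts to http (local mock servers).
domain_base_url <- function(domain) {
  if (grepl("^https?://", domain)) return(sub("/+$", "", domain))
  scheme <- if (grepl("^(localhost|127\\.0\\.0\\.1|\\[::1\\])([:/]|$)", domain)) {
    "http"
  } else {
    "https"
  }
  paste0(scheme, "://", sub("/+$", "", domain))
}
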
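#' Export canned fixtures for a mock dataset
#'
#' Writes offline artifacts for a generated cohort into `dir`:
#'
#' * canned Beacon JSON responses — one `<hash>.json` per endpoint/query
#'   combination (all four entities and `/filtering_terms`; unfiltered,
#'   per-term filtered, and count variants), readable through
#'   [fixture_transport()]; a `manifest.tsv` maps request URLs to files;
#' * `cohort.pgxseg` — the cohort's CNV segments with per-sample metadata;
#' * `truth_frequency.tsv` — the per-bin gain/loss frequencies computed from
#'   the generator's own segments by the per-base reference counter
#'   ([per_base_freq()]), for cross-module checks against [seg_to_freq()].
#'
#' @param dataset a `mock_dataset`.
#' @param dir output directory (created if needed).
#' @param domain,entry_point hostname and prefix under which the canned
#'   responses are keyed; query the fixtures with the same values.
#' @return invisibly, the manifest tibble (`url`, `file`).
#' @export
export_fixture_files <- function(dataset, dir, domain = "mock.local",
                                 entry_point = "beacon") {
  stopifnot(inherits(dataset, "mock_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  queries <- list(beacon_query("filtering_terms"))
  for (ent in BEACON_ENTITIES) {
    queries <- c(queries, list(beacon_query(ent)))
    for (term in dataset$filtering_terms$id) {
      queries <- c(queries,
                   list(beacon_query(ent, filters = term)),
                   list(beacon_query("counts", filters = term,
                                     count_entity = ent)))
    }
  }
  rows <- lapply(queries, function(q) {
    req <- build_request(q, domain, entry_point)
    resp <- mock_respond(dataset, sub("^https?://[^/]*", "", req$url),
                         as.list(req$params))
    file <- paste0(url_fixture_key(req$full_url), ".json")
    writeLines(resp$body, file.path(dir, file))
    tibble(url = req$full_url, file = file)
  })
  manifest <- bind_rows(rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_pgxseg(mock_segment_file(dataset), file.path(dir, "cohort.pgxseg"))

  segs <- dataset$segments
  if (nrow(segs) > 0) {
    bins <- make_bins(dataset$genome, dataset$truth$spec$bin_size)
    truth <- per_base_freq(segs, bins, group = "mock-cohort")
    write_freq_tsv(truth, file.path(dir, "truth_frequency.tsv"))
  }
  invisible(manifest)
}

# segment_file view of a dataset: truth segments + per-sample metadata
mock_segment_file <- function(dataset) {
  n <- length(dataset$ids$biosamples)
  diag <- vapply(dataset$biosamples, function(b) b$histologicalDiagnosis$id, "")
  metadata <- tibble(
    sample_id = dataset$ids$biosamples,
    individual_id = dataset$ids$individuals,
    histological_diagnosis_id = diag,
    group = dataset$survival$group,
    followup_time = as.character(dataset$survival$time),
    vital_status = ifelse(dataset$survival$event, "dead", "alive")
  )
  new_segment_file(order_segments(dataset$segments), metadata, "pgxseg")
}
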
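# Shared fixtures and independent oracles used across test files.

# random segment table on a small genome (for round-trip and property tests)
random_segments <- function(n, genome = beaconcnv::mock_genome(), seed = 1) {
  withr::with_seed(seed, {
    ci <- sample.int(nrow(genome), n, replace = TRUE)
    len <- genome$length[ci]
    start <- floor(runif(n, 0, len - 2))
    width <- pmax(1, floor(runif(n, 1, pmax(2, (len - start) / 4))))
    tibble::tibble(
      sample_id = sprintf("S%02d", sample.int(8, n, replace = TRUE)),
      chromosome = genome$chromosome[ci],
      start = as.integer(start),
      end = as.integer(pmin(start + width, len)),
      log2 = round(rnorm(n, 0, 0.5), 4),
      state = sample(c("gain", "loss", "neutral"), n, replace = TRUE),
      n_probes = NA_integer_
    )
  })
}

# independent per-base interval-union oracle for CNV fractions: materializes
# boolean coverage per sample/state/chromosome, no interval algebra
brute_fraction <- function(segments, genome) {
  total <- sum(genome$length)
  out <- lapply(unique(segments$sample_id), function(sm) {
    per_state <- vapply(c("gain", "loss"), function(st) {
      covered <- 0
      for (ci in seq_len(nrow(genome))) {
        sel <- segments[segments$sample_id == sm &
                          segments$chromosome == genome$chromosome[ci] &
                          segments$state == st, , drop = FALSE]
        if (nrow(sel) == 0) next
        v <- logical(genome$length[ci])
        for (i in seq_len(nrow(sel))) v[(sel$start[i] + 1):sel$end[i]] <- TRUE
        covered <- covered + sum(v)
      }
      covered / total
    }, 0)
    tibble::tibble(sample_id = sm, gain_fraction = per_state[["gain"]],
                   loss_fraction = per_state[["loss"]])
  })
  dplyr::bind_rows(out)
}

# random nested documents for flattening property tests
random_nested_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      n_refs <- sample(0:4, 1)
      doc <- list(id = sprintf("rec-%03d", i))
      if (runif(1) > 0.2) {
        doc$histologicalDiagnosis <- list(id = sprintf("NCIT:C%04d", sample(1000:9999, 1)))
      }
      if (n_refs > 0) {
        doc$externalReferences <- lapply(seq_len(n_refs), function(k) {
          list(id = sprintf("geo:GSM%05d", sample(1e4, 1)))
        })
      }
      doc
    })
  })
}

explode_config <- function() {
  beaconcnv::load_mapping(paste(
    "entity: test",
    "columns:",
    "  - name: id",
    "    path: id",
    "  - name: diagnosis",
    "    path: histologicalDiagnosis.id",
    "  - name: ref",
    "    path: externalReferences[].id",
    "    cardinality: explode",
    sep = "\n"))
}

# small cohort used by many client tests
test_cohort <- function(seed = 11, n = 20,
                        probs = c("NCIT:C3512" = 0.5, "NCIT:C20197" = 0.5)) {
  beaconcnv::generate_cohort(beaconcnv::cohort_spec(
    n_individuals = n, filter_probs = probs, seed = seed))
}

# direct AND-intersection of carrier sets on the dataset truth
truth_individuals <- function(dataset, filters) {
  ids <- dataset$ids$individuals
  for (f in filters) {
    ids <- intersect(ids, dataset$term_index$individual_id[
      dataset$term_index$term == f])
  }
  ids
}
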
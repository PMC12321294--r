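# Labels for CURIEs the generator knows about; anything else gets a
# generic label so filtering-term matching still works.
MOCK_TERM_LABELS <- c(
  "NCIT:C20197" = "Male",
  "NCIT:C16576" = "Female",
  "NCIT:C3512"  = "Lung Adenocarcinoma",
  "NCIT:C4349"  = "Colon Adenocarcinoma",
  "NCIT:C3262"  = "Neoplasm",
  "NCIT:C189227" = "Severe COVID-19 Infection"
)

mock_term_label <- function(id) {
  ifelse(id %in% names(MOCK_TERM_LABELS), MOCK_TERM_LABELS[id],
         paste("Term", id))
}

#' Default fixture genome for synthetic cohorts
#'
#' Five synthetic chromosomes (4.0, 3.5, 3.0, 2.5, 2.2 Mb). Small enough
#' that per-base brute-force frequency counting stays fast, yet with
#' non-multiple lengths so partial terminal bins are exercised.
#'
#' @return tibble with `chromosome`, `length`.
#' @export
mock_genome <- function() {
  tibble(chromosome = as.character(1:5),
         length = c(4e6, 3.5e6, 3e6, 2.5e6, 2.2e6))
}

#' Specify a synthetic Beacon cohort
#'
#' Declares the generating model for [generate_cohort()]: cohort size,
#' independent per-individual CURIE assignment probabilities, bin-wise CNV
#' gain/loss probabilities (per sample and bin, segments are maximal runs of
#' same-state bins), and a two-group exponential survival model. Everything
#' downstream is deterministic given `seed`.
#'
#' @param n_individuals cohort size (>= 1); one biosample and one analysis
#'   per individual.
#' @param filter_probs named numeric vector: CURIE -> inclusion probability
#'   in \[0, 1\], drawn independently per individual.
#' @param genome chromosome length table, default [mock_genome()].
#' @param bin_size CNV generation bin width (default 1e6).
#' @param per_bin_gain_prob,per_bin_loss_prob probability that a given bin of
#'   a given sample is in gain / loss state; their sum must be <= 1.
#' @param hazards named vector of exponential event hazards per survival
#'   group (`carrier` / `noncarrier` when `group_term` is set, else a single
#'   `all` hazard is used).
#' @param censor_hazard exponential hazard of the independent censoring time.
#' @param group_term optional CURIE; carriers and non-carriers form the two
#'   survival groups.
#' @param seed integer seed owned by the dataset; generation never touches
#'   the caller's RNG state.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 50,
                        filter_probs = c("NCIT:C3512" = 0.5,
                                         "NCIT:C20197" = 0.5),
                        genome = mock_genome(),
                        bin_size = 1e6,
                        per_bin_gain_prob = 0.1,
                        per_bin_loss_prob = 0.1,
                        hazards = c(all = 0.02),
                        censor_hazard = 0.01,
                        group_term = NULL,
                        seed = 1) {
  if (n_individuals < 1) abort("`n_individuals` must be >= 1.")
  if (length(filter_probs) > 0 &&
      (is.null(names(filter_probs)) || any(!nzchar(names(filter_probs))))) {
    abort("`filter_probs` must be a named vector (CURIE -> probability).")
  }
  if (any(filter_probs < 0 | filter_probs > 1)) {
    abort("Filter inclusion probabilities must lie in [0, 1].")
  }
  if (per_bin_gain_prob < 0 || per_bin_loss_prob < 0 ||
      per_bin_gain_prob + per_bin_loss_prob > 1) {
    abort("Per-bin gain/loss probabilities must be >= 0 and sum to <= 1.")
  }
  if (any(hazards <= 0) || censor_hazard < 0) {
    abort("Hazards must be positive (censoring hazard >= 0).")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         filter_probs = filter_probs,
         genome = as_length_table(genome),
         bin_size = as.numeric(bin_size),
         per_bin_gain_prob = per_bin_gain_prob,
         per_bin_loss_prob = per_bin_loss_prob,
         hazards = hazards, censor_hazard = censor_hazard,
         group_term = group_term, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic Beacon v2 cohort
#'
#' Draws a full, referentially consistent mock dataset from a
#' [cohort_spec()]: individuals (sex, vital status, follow-up time),
#' biosamples (one per individual, with histological diagnosis and external
#' references), analyses (one per biosample) and CNV variants (one per
#' generated segment, interbase coordinates, EFO state terms), plus the
#' filtering-term inventory and a `truth` block recording the generating
#' parameters. The caller's RNG state is untouched; identical specs give
#' identical datasets.
#'
#' @param spec a [cohort_spec()].
#' @return a `mock_dataset`: entity document lists (`individuals`,
#'   `biosamples`, `analyses`, `variants`), `filtering_terms`, the truth
#'   segment table (`segments`), `term_index`, `survival` table, `genome`,
#'   and `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_individuals
  ind_ids <- sprintf("pgxind-%04d", seq_len(n))
  bs_ids <- sprintf("pgxbs-%04d", seq_len(n))
  an_ids <- sprintf("pgxana-%04d", seq_len(n))

  # independent CURIE assignment
  curies <- names(spec$filter_probs)
  carrier <- vapply(curies, function(cu) {
    as.logical(rbinom(n, 1, spec$filter_probs[[cu]]))
  }, logical(n))
  if (n == 1) carrier <- matrix(carrier, nrow = 1, dimnames = list(NULL, curies))
  term_index <- bind_rows(lapply(seq_along(curies), function(j) {
    tibble(individual_id = ind_ids[carrier[, j]], term = curies[j])
  }))
  if (nrow(term_index) == 0) {
    term_index <- tibble(individual_id = character(), term = character())
  }

  has_term <- function(i, cu) cu %in% curies && carrier[i, cu]
  sex_term <- vapply(seq_len(n), function(i) {
    if (has_term(i, "NCIT:C20197")) "NCIT:C20197"
    else if (has_term(i, "NCIT:C16576")) "NCIT:C16576"
    else NA_character_
  }, "")
  diagnosis_pool <- setdiff(curies, c("NCIT:C20197", "NCIT:C16576"))
  diag_term <- vapply(seq_len(n), function(i) {
    hit <- diagnosis_pool[carrier[i, diagnosis_pool]]
    if (length(hit)) hit[1] else "NCIT:C3262"
  }, "")

  # survival: exponential event and censoring times
  group <- if (is.null(spec$group_term)) {
    rep(names(spec$hazards)[1], n)
  } else {
    in_grp <- if (spec$group_term %in% curies) carrier[, spec$group_term] else rep(FALSE, n)
    ifelse(in_grp, "carrier", "noncarrier")
  }
  hz <- spec$hazards[group]
  if (any(is.na(hz))) abort("`hazards` must name every survival group.")
  t_event <- rexp(n, rate = hz)
  t_cens <- if (spec$censor_hazard > 0) rexp(n, rate = spec$censor_hazard) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  survival <- tibble(individual_id = ind_ids, group = group,
                     time = round(time, 3), event = event)

  # CNV segments: bin-wise states merged into maximal runs
  segments <- bind_rows(lapply(seq_len(n), function(i) {
    draw_sample_segments(bs_ids[i], spec)
  }))
  if (nrow(segments) == 0) segments <- empty_segments()

  individuals <- lapply(seq_len(n), function(i) {
    doc <- list(
      id = ind_ids[i],
      sex = if (!is.na(sex_term[i])) {
        list(id = sex_term[i], label = unname(mock_term_label(sex_term[i])))
      } else {
        list(id = "NCIT:C17998", label = "Unknown")
      },
      vitalStatus = if (event[i]) list(id = "NCIT:C28554", label = "Dead")
                    else list(id = "NCIT:C37987", label = "Alive"),
      followupTime = round(time[i], 3),
      diseases = list(list(diseaseCode = list(
        id = diag_term[i], label = unname(mock_term_label(diag_term[i]))))
      )
    )
    doc
  })
  biosamples <- lapply(seq_len(n), function(i) {
    list(
      id = bs_ids[i],
      individualId = ind_ids[i],
      histologicalDiagnosis = list(id = diag_term[i],
                                   label = unname(mock_term_label(diag_term[i]))),
      biosampleStatus = list(id = "EFO:0009656",
                             label = "neoplastic sample"),
      externalReferences = list(
        list(id = sprintf("geo:GSM%06d", 100000 + i)),
        list(id = "pubmed:12345678")
      )
    )
  })
  analyses <- lapply(seq_len(n), function(i) {
    list(
      id = an_ids[i],
      biosampleId = bs_ids[i],
      individualId = ind_ids[i],
      platformModel = list(id = "geo:GPL6801",
                           label = "Genome-Wide Human SNP Array 6.0"),
      pipelineName = "progenetix"
    )
  })
  an_of_bs <- setNames(an_ids, bs_ids)
  variants <- if (nrow(segments) > 0) {
    lapply(seq_len(nrow(segments)), function(k) {
      s <- segments[k, ]
      st <- if (s$state == "gain") list(id = "EFO:0030070", label = "copy number gain")
            else list(id = "EFO:0030067", label = "copy number loss")
      list(
        variantInternalId = sprintf("pgxvar-%05d", k),
        analysisId = unname(an_of_bs[s$sample_id]),
        biosampleId = s$sample_id,
        variantState = st,
        location = list(referenceName = s$chromosome,
                        start = s$start, end = s$end),
        info = list(log2 = s$log2)
      )
    })
  } else {
    list()
  }

  filtering_terms <- tibble(
    id = curies,
    label = unname(mock_term_label(curies)),
    scope = ifelse(curies %in% c("NCIT:C20197", "NCIT:C16576"),
                   "individuals", "biosamples"),
    type = "ontologyTerm"
  )

  structure(
    list(individuals = individuals, biosamples = biosamples,
         analyses = analyses, variants = variants,
         filtering_terms = filtering_terms,
         segments = segments, term_index = term_index,
         survival = survival,
         genome = spec$genome,
         truth = list(spec = spec),
         ids = list(individuals = ind_ids, biosamples = bs_ids,
                    analyses = an_ids)),
    class = "mock_dataset"
  )
}

draw_sample_segments <- function(sample_id, spec) {
  pg <- spec$per_bin_gain_prob
  pl <- spec$per_bin_loss_prob
  out <- lapply(seq_len(nrow(spec$genome)), function(ci) {
    chrom <- spec$genome$chromosome[ci]
    len <- spec$genome$length[ci]
    starts <- seq(0, len - 1, by = spec$bin_size)
    ends <- pmin(starts + spec$bin_size, len)
    u <- runif(length(starts))
    state <- ifelse(u < pg, "gain", ifelse(u < pg + pl, "loss", "neutral"))
    runs <- rle(state)
    stop_idx <- cumsum(runs$lengths)
    start_idx <- stop_idx - runs$lengths + 1L
    keep <- runs$values != "neutral"
    if (!any(keep)) return(NULL)
    tibble(
      sample_id = sample_id,
      chromosome = chrom,
      start = as.integer(starts[start_idx[keep]]),
      end = as.integer(ends[stop_idx[keep]]),
      log2 = round(ifelse(runs$values[keep] == "gain",
                          rnorm(sum(keep), 0.35, 0.08),
                          rnorm(sum(keep), -0.45, 0.08)), 4),
      state = runs$values[keep],
      n_probes = NA_integer_
    )
  })
  bind_rows(purrr::compact(out))
}

#' @export
print.mock_dataset <- function(x, ...) {
  cat("<mock_dataset>", length(x$individuals), "individuals,",
      length(x$biosamples), "biosamples,", length(x$analyses), "analyses,",
      length(x$variants), "variants,", nrow(x$filtering_terms),
      "filtering terms\n")
  invisible(x)
}

# Entity ids matching a filter set (AND) within the dataset, used by the
# mock server and by the in-process transport. Terms attach to individuals;
# other entities match through their individual.
mock_matching_ids <- function(dataset, entity, filters = character(),
                              biosample_ids = character(),
                              individual_ids = character()) {
  ind <- dataset$ids$individuals
  if (length(filters) > 0) {
    for (f in filters) {
      ind <- intersect(ind, dataset$term_index$individual_id[
        dataset$term_index$term == f])
    }
  }
  bs <- dataset$ids$biosamples[match(ind, dataset$ids$individuals)]
  if (length(individual_ids) > 0) {
    ind <- intersect(ind, individual_ids)
    bs <- dataset$ids$biosamples[match(ind, dataset$ids$individuals)]
  }
  if (length(biosample_ids) > 0) {
    bs <- intersect(bs, biosample_ids)
    ind <- dataset$ids$individuals[match(bs, dataset$ids$biosamples)]
  }
  switch(entity,
    individuals = ind,
    biosamples = bs,
    analyses = dataset$ids$analyses[match(bs, dataset$ids$biosamples)],
    g_variants = {
      vb <- vapply(dataset$variants, function(v) v$biosampleId, "")
      which_v <- vb %in% bs
      vapply(dataset$variants[which_v], function(v) v$variantInternalId, "")
    },
    abort(paste0("Unknown entity ", sQuote(entity), "."))
  )
}

mock_entity_docs <- function(dataset, entity, ids) {
  docs <- switch(entity,
    individuals = dataset$individuals,
    biosamples = dataset$biosamples,
    analyses = dataset$analyses,
    g_variants = dataset$variants
  )
  key <- if (entity == "g_variants") "variantInternalId" else "id"
  all_ids <- vapply(docs, function(d) d[[key]], "")
  docs[match(ids, all_ids)]
}
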
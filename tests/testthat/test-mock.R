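test_that("cohort generation is deterministic and leaves the RNG alone", {
  spec <- cohort_spec(n_individuals = 30, seed = 12)
  d1 <- generate_cohort(spec)
  d2 <- generate_cohort(spec)
  expect_identical(d1$segments, d2$segments)
  expect_identical(d1$individuals, d2$individuals)
  expect_identical(d1$term_index, d2$term_index)
  expect_identical(d1$survival, d2$survival)

  set.seed(999); before <- runif(1)
  set.seed(999); invisible(generate_cohort(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("inclusion probabilities behave at the extremes and in the middle", {
  d_all <- generate_cohort(cohort_spec(
    n_individuals = 40, filter_probs = c("NCIT:C3512" = 1), seed = 1))
  expect_identical(sum(d_all$term_index$term == "NCIT:C3512"), 40L)
  d_none <- generate_cohort(cohort_spec(
    n_individuals = 40, filter_probs = c("NCIT:C3512" = 0), seed = 1))
  expect_identical(nrow(d_none$term_index), 0L)

  # n = 1000, p = 0.5: carrier count within the 99% binomial interval
  d_half <- generate_cohort(cohort_spec(
    n_individuals = 1000, filter_probs = c("NCIT:C16576" = 0.5),
    per_bin_gain_prob = 0, per_bin_loss_prob = 0, seed = 8))
  k <- sum(d_half$term_index$term == "NCIT:C16576")
  half_width <- qnorm(0.995) * sqrt(1000 * 0.25)
  expect_gt(k, 500 - half_width)
  expect_lt(k, 500 + half_width)

  expect_error(cohort_spec(filter_probs = c("NCIT:C3512" = 1.2)), "\\[0, 1\\]")
  expect_error(cohort_spec(per_bin_gain_prob = 0.7, per_bin_loss_prob = 0.6),
               "sum to <= 1")
  expect_error(cohort_spec(n_individuals = 0), ">= 1")
})

test_that("referential integrity holds across seeds", {
  for (seed in 1:10) {
    d <- generate_cohort(cohort_spec(n_individuals = 12, seed = seed))
    bs_ind <- vapply(d$biosamples, function(b) b$individualId, "")
    expect_true(all(bs_ind %in% d$ids$individuals))
    expect_false(anyDuplicated(bs_ind) > 0)     # one individual per biosample
    an_bs <- vapply(d$analyses, function(a) a$biosampleId, "")
    expect_true(all(an_bs %in% d$ids$biosamples))
    if (length(d$variants)) {
      v_bs <- vapply(d$variants, function(v) v$biosampleId, "")
      v_an <- vapply(d$variants, function(v) v$analysisId, "")
      expect_true(all(v_bs %in% d$ids$biosamples))
      expect_true(all(v_an %in% d$ids$analyses))
    }
    # segments and variants describe the same calls
    expect_identical(length(d$variants), nrow(d$segments))
  }
})

test_that("generated segments are valid, bin-aligned maximal runs", {
  spec <- cohort_spec(n_individuals = 15, seed = 6)
  d <- generate_cohort(spec)
  s <- d$segments
  expect_true(all(s$start < s$end))
  expect_true(all(s$start %% spec$bin_size == 0))
  expect_true(all(s$state %in% c("gain", "loss")))
  # maximal runs: same-sample same-state neighbors never touch
  by_key <- split(s, paste(s$sample_id, s$chromosome, s$state))
  gaps_ok <- vapply(by_key, function(x) {
    x <- x[order(x$start), ]
    nrow(x) < 2 || all(x$start[-1] > x$end[-nrow(x)])
  }, TRUE)
  expect_true(all(gaps_ok))
  # gains have positive log2, losses negative
  expect_true(all(s$log2[s$state == "gain"] > 0))
  expect_true(all(s$log2[s$state == "loss"] < 0))
})

test_that("survival truth follows the requested two-group model", {
  spec <- cohort_spec(n_individuals = 400,
                      filter_probs = c("NCIT:C3512" = 0.5),
                      hazards = c(carrier = 0.2, noncarrier = 0.05),
                      censor_hazard = 0.02,
                      group_term = "NCIT:C3512", seed = 3)
  d <- generate_cohort(spec)
  sv <- d$survival
  expect_setequal(unique(sv$group), c("carrier", "noncarrier"))
  carriers <- truth_individuals(d, "NCIT:C3512")
  expect_setequal(sv$individual_id[sv$group == "carrier"], carriers)
  # the high-hazard group dies faster on average
  expect_lt(mean(sv$time[sv$group == "carrier"]),
            mean(sv$time[sv$group == "noncarrier"]))
})

test_that("mock endpoint answers are reproducible from the dataset", {
  d <- test_cohort(seed = 19, n = 25,
                   probs = c("NCIT:C3512" = 0.5, "NCIT:C20197" = 0.5))
  tr <- dataset_transport(d)
  both <- c("NCIT:C3512", "NCIT:C20197")
  env <- fetch_entity(beacon_query("individuals", filters = both,
                                   domains = "mock.local"), transport = tr)
  expect_setequal(vapply(env$records, function(r) r$id, ""),
                  truth_individuals(d, both))
  counts <- fetch_counts(beacon_query("individuals", filters = both,
                                      domains = "mock.local"), transport = tr)
  expect_identical(counts$count, length(truth_individuals(d, both)))
})

test_that("fixture export is complete, truthful and byte-deterministic", {
  spec <- cohort_spec(n_individuals = 10, seed = 23)
  d <- generate_cohort(spec)
  dir1 <- withr::local_tempdir()
  manifest <- export_fixture_files(d, dir1)
  expect_true(all(file.exists(file.path(dir1, manifest$file))))

  # canned responses drive the client exactly like the live mock
  ftr <- fixture_transport(dir1)
  env <- fetch_entity(beacon_query("biosamples", filters = "NCIT:C3512",
                                   domains = "mock.local"), transport = ftr)
  expect_identical(length(env$records),
                   length(truth_individuals(d, "NCIT:C3512")))

  # the pgxseg round-trips the dataset's segments
  sf <- read_segfile(file.path(dir1, "cohort.pgxseg"))
  expect_identical(nrow(sf$segments), nrow(d$segments))
  expect_identical(nrow(sf$metadata), 10L)

  # truth TSV == seg_to_freq on the exported file (cross-module oracle)
  truth <- read.delim(file.path(dir1, "truth_frequency.tsv"))
  got <- seg_to_freq(classify_segments(sf),
                     make_bins(d$genome, spec$bin_size))
  expect_equal(truth$gain_percent, got$gain_percent)
  expect_equal(truth$loss_percent, got$loss_percent)
  expect_identical(unique(truth$n_samples), attr(got, "n_samples"))

  # byte-identical re-export from an identical spec
  dir2 <- withr::local_tempdir()
  export_fixture_files(generate_cohort(spec), dir2)
  for (f in c(manifest$file, "cohort.pgxseg", "truth_frequency.tsv")) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir1, f)), label = f)
  }

  # empty cohort still exports a valid fixture set
  d0 <- generate_cohort(cohort_spec(n_individuals = 2,
                                    per_bin_gain_prob = 0,
                                    per_bin_loss_prob = 0, seed = 1))
  dir3 <- withr::local_tempdir()
  export_fixture_files(d0, dir3)
  sf0 <- read_segfile(file.path(dir3, "cohort.pgxseg"))
  expect_identical(nrow(sf0$segments), 0L)
  expect_identical(nrow(sf0$metadata), 2L)
})
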
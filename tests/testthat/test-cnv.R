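test_that("state classification: explicit labels beat log2 thresholds", {
  segs <- tibble::tibble(
    sample_id = "S1", chromosome = "1",
    start = c(0L, 100L, 200L, 300L, 400L, 500L),
    end = c(50L, 150L, 250L, 350L, 450L, 550L),
    log2 = c(0.5, 0, 0.4, -0.2, NA, NA),
    state = c("unknown", "unknown", "EFO:0030067", "unknown", "DUP", "unknown"),
    n_probes = NA_integer_
  )
  out <- classify_segments(segs)
  expect_identical(out$state,
                   c("gain",        # 0.5 >= 0.15
                     "neutral",     # 0 inside the band
                     "loss",        # explicit loss CURIE wins over log2 +0.4
                     "loss",        # -0.2 <= -0.15
                     "gain",        # DUP via vocabulary, no log2 needed
                     "unknown"))    # nothing to go on
  expect_error(classify_segments(segs, gain_threshold = -0.2,
                                 loss_threshold = 0.2), "greater")
  # boundary values are inclusive
  b <- classify_segments(tibble::tibble(sample_id = "S", chromosome = "1",
                                        start = 0L, end = 1L,
                                        log2 = c(0.15, -0.15),
                                        state = NA, n_probes = NA_integer_))
  expect_identical(b$state, c("gain", "loss"))
})

test_that("genome bins tile chromosomes exactly", {
  b <- make_bins(c("1" = 2500000), bin_size = 1e6)
  expect_identical(nrow(b), 3L)
  expect_identical(b$end - b$start, c(1e6, 1e6, 5e5))
  expect_identical(nrow(make_bins(c("1" = 500), bin_size = 1e6)), 1L)
  expect_error(make_bins(tibble::tibble(chromosome = character(),
                                        length = numeric())), "empty")
  expect_error(make_bins(c("1" = 100), bin_size = 0), ">= 1")
  # conservation over the full default genome at 1 Mb
  hb <- make_bins()
  expect_equal(sum(hb$end - hb$start), sum(hg38_chromosome_lengths()$length))
  expect_false(any(hb$start >= hb$end))
  # per chromosome: contiguous, non-overlapping
  by_chrom <- split(hb, hb$chromosome)
  expect_true(all(vapply(by_chrom, function(x) {
    all(x$start[-1] == x$end[-nrow(x)])
  }, TRUE)))
})

test_that("seg_to_freq counts each sample once per bin per state", {
  bins <- make_bins(c("1" = 4e6), bin_size = 1e6)
  segs <- tibble::tibble(
    sample_id = c("A", "A", "B"),
    chromosome = "1",
    start = c(0L, 500000L, 0L),
    end = c(2000000L, 700000L, 1L),
    log2 = NA_real_,
    state = c("gain", "gain", "neutral"),
    n_probes = NA_integer_
  )
  tr <- seg_to_freq(segs, bins)
  expect_identical(attr(tr, "n_samples"), 2L)   # B counts in the denominator
  expect_equal(tr$gain_percent, c(50, 50, 0, 0))  # A once despite two segments
  expect_equal(tr$loss_percent, rep(0, 4))

  # saturation: every sample gains over a bin -> 100%
  segs2 <- tibble::tibble(sample_id = c("A", "B"), chromosome = "1",
                          start = 0L, end = 1000000L, log2 = NA_real_,
                          state = "gain", n_probes = NA_integer_)
  expect_equal(seg_to_freq(segs2, bins)$gain_percent[1], 100)
  expect_error(seg_to_freq(segs2[0, ], bins), "zero samples")
})

test_that("min_overlap gates bin membership", {
  bins <- make_bins(c("1" = 2e6), bin_size = 1e6)
  seg <- tibble::tibble(sample_id = "A", chromosome = "1",
                        start = 999900L, end = 1000100L, log2 = NA_real_,
                        state = "gain", n_probes = NA_integer_)
  # 100 bases in bin 1, 100 in bin 2
  expect_equal(seg_to_freq(seg, bins, min_overlap = 1)$gain_percent, c(100, 100))
  expect_equal(seg_to_freq(seg, bins, min_overlap = 101)$gain_percent, c(0, 0))
})

test_that("seg_to_freq equals the per-base reference counter on random cohorts", {
  bins <- make_bins(mock_genome(), 1e6)
  for (seed in c(31, 32, 33)) {
    d <- generate_cohort(cohort_spec(n_individuals = 20, seed = seed))
    fast <- seg_to_freq(d$segments, bins)
    slow <- per_base_freq(d$segments, bins)
    expect_identical(fast$gain_percent, slow$gain_percent)
    expect_identical(fast$loss_percent, slow$loss_percent)
    # quantization: every percentage is a multiple of 100 / n_samples
    n <- attr(fast, "n_samples")
    ks <- c(fast$gain_percent, fast$loss_percent) * n / 100
    expect_equal(ks, round(ks))
  }
})

test_that("frequencies are invariant to splitting segments into pieces", {
  bins <- make_bins(mock_genome(), 1e6)
  d <- generate_cohort(cohort_spec(n_individuals = 10, seed = 44))
  segs <- d$segments
  # split every segment at its midpoint
  mid <- floor((segs$start + segs$end) / 2)
  splittable <- mid > segs$start & mid < segs$end
  left <- segs; left$end[splittable] <- mid[splittable]
  right <- segs[splittable, ]; right$start <- mid[splittable]
  split_segs <- dplyr::bind_rows(left, right)
  expect_equal(seg_to_freq(split_segs, bins)$gain_percent,
               seg_to_freq(segs, bins)$gain_percent)
  # fractions are likewise split-invariant
  expect_equal(cnv_fraction(split_segs, mock_genome()),
               cnv_fraction(segs, mock_genome()))
})

test_that("CNV fractions merge overlapping intervals before summing", {
  genome <- c("1" = 1000)
  segs <- tibble::tibble(sample_id = "S", chromosome = "1",
                         start = c(0L, 50L), end = c(100L, 150L),
                         log2 = NA_real_, state = "gain",
                         n_probes = NA_integer_)
  fr <- cnv_fraction(segs, genome)
  expect_equal(fr$gain_fraction, 0.15)   # union [0,150), not 0.25
  expect_equal(fr$total_fraction, 0.15)

  # half the genome gained
  half <- tibble::tibble(sample_id = "S", chromosome = "1", start = 0L,
                         end = 500L, log2 = NA_real_, state = "gain",
                         n_probes = NA_integer_)
  expect_equal(cnv_fraction(half, genome)$gain_fraction, 0.5)

  # neutral-only sample: zero fractions but present in the output
  neut <- tibble::tibble(sample_id = "N", chromosome = "1", start = 0L,
                         end = 500L, log2 = NA_real_, state = "neutral",
                         n_probes = NA_integer_)
  fr0 <- cnv_fraction(neut, genome)
  expect_identical(fr0$sample_id, "N")
  expect_equal(fr0$total_fraction, 0)
})

test_that("fractions agree with an independent per-base union oracle", {
  genome <- tibble::tibble(chromosome = c("1", "2"), length = c(50000, 30000))
  for (seed in c(5, 6)) {
    segs <- random_segments(60, genome = genome, seed = seed)
    got <- cnv_fraction(segs, genome)
    want <- brute_fraction(segs, genome)
    merged <- dplyr::left_join(got, want, by = "sample_id")
    expect_equal(merged$gain_fraction.x, merged$gain_fraction.y)
    expect_equal(merged$loss_fraction.x, merged$loss_fraction.y)
    expect_true(all(got$total_fraction <=
                      got$gain_fraction + got$loss_fraction + 1e-12))
    expect_true(all(got$total_fraction <= 1))
  }
})

test_that("per-chromosome fractions denominate by chromosome length", {
  genome <- tibble::tibble(chromosome = c("1", "2"), length = c(1000, 500))
  segs <- tibble::tibble(sample_id = "S", chromosome = c("1", "2"),
                         start = c(0L, 0L), end = c(500L, 500L),
                         log2 = NA_real_, state = c("gain", "loss"),
                         n_probes = NA_integer_)
  fr <- cnv_fraction(segs, genome, scope = "chromosome")
  expect_equal(fr$gain_fraction[fr$chromosome == "1"], 0.5)
  expect_equal(fr$loss_fraction[fr$chromosome == "2"], 1)
  expect_equal(fr$loss_fraction[fr$chromosome == "1"], 0)
})

test_that("frequency TSV export carries cohort size and group", {
  bins <- make_bins(c("1" = 2e6), 1e6)
  segs <- tibble::tibble(sample_id = c("A", "B"), chromosome = "1",
                         start = 0L, end = 1500000L, log2 = NA_real_,
                         state = c("gain", "loss"), n_probes = NA_integer_)
  tr <- seg_to_freq(segs, bins, group = "cohortX")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_freq_tsv(tr, path)
  back <- read.delim(path)
  expect_identical(names(back),
                   c("chromosome", "start", "end", "gain_percent",
                     "loss_percent", "n_samples", "group"))
  expect_identical(unique(back$n_samples), 2L)
  expect_identical(unique(back$group), "cohortX")
})
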
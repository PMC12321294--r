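#' Default CNV state vocabulary
#'
#' Maps the ontology terms and shorthand labels commonly attached to
#' copy-number calls (EFO copy-number concepts used by Beacon CNV exchanges,
#' Sequence Ontology terms, `DUP`/`DEL`) onto the package's three-state model
#' `gain` / `loss` / `neutral`. A convention, not a protocol constant —
#' override via the `state_vocab` argument of [classify_segments()].
#'
#' @return named character vector: term -> state.
#' @export
default_state_vocab <- function() {
  c(
    "EFO:0030070" = "gain",   # copy number gain
    "EFO:0030071" = "gain",   # low-level copy number gain
    "EFO:0030072" = "gain",   # high-level copy number gain / amplification
    "EFO:0030067" = "loss",   # copy number loss
    "EFO:0030068" = "loss",   # low-level copy number loss
    "EFO:0030069" = "loss",   # complete genomic deletion
    "EFO:0030066" = "neutral",
    "SO:0001742"  = "gain",   # copy_number_gain
    "SO:0001743"  = "loss",   # copy_number_loss
    "DUP" = "gain", "DEL" = "loss",
    "+" = "gain", "-" = "loss"
  )
}

#' Classify segments into gain / loss / neutral
#'
#' Fills the `state` column of a segment table. Precedence: an explicit
#' canonical state (`gain`/`loss`/`neutral`) or a label found in
#' `state_vocab` wins over the log2 value; otherwise `log2 >= gain_threshold`
#' is a gain, `log2 <= loss_threshold` a loss, anything between neutral; a
#' segment with neither a recognizable label nor a log2 value stays
#' `unknown`.
#'
#' @param segments a segments data frame (as from [read_segfile()]) or a
#'   `segment_file`.
#' @param gain_threshold,loss_threshold log2-ratio cutoffs, defaults
#'   +0.15 / -0.15 (a common convention for array-resolution CNV calls).
#' @param state_vocab named vector mapping state labels/CURIEs to states,
#'   default [default_state_vocab()].
#' @return the input with `state` filled (same type as the input).
#' @export
classify_segments <- function(segments, gain_threshold = 0.15,
                              loss_threshold = -0.15,
                              state_vocab = default_state_vocab()) {
  if (gain_threshold <= loss_threshold) {
    abort("`gain_threshold` must be greater than `loss_threshold`.")
  }
  if (inherits(segments, "segment_file")) {
    segments$segments <- classify_segments(segments$segments, gain_threshold,
                                           loss_threshold, state_vocab)
    return(segments)
  }
  segs <- as_tibble(segments)
  if (!"state" %in% names(segs)) segs$state <- NA_character_
  if (!"log2" %in% names(segs)) segs$log2 <- NA_real_

  raw <- as.character(segs$state)
  canonical <- !is.na(raw) & tolower(raw) %in% c("gain", "loss", "neutral")
  vocab_hit <- !is.na(raw) & raw %in% names(state_vocab)

  out <- rep("unknown", nrow(segs))
  out[canonical] <- tolower(raw[canonical])
  out[!canonical & vocab_hit] <- unname(state_vocab[raw[!canonical & vocab_hit]])

  open <- !(canonical | vocab_hit)
  has_log2 <- open & !is.na(segs$log2)
  out[has_log2 & segs$log2 >= gain_threshold] <- "gain"
  out[has_log2 & segs$log2 <= loss_threshold] <- "loss"
  out[has_log2 & segs$log2 > loss_threshold & segs$log2 < gain_threshold] <- "neutral"

  segs$state <- out
  segs
}

seg_to_iranges <- function(segs) {
  # interbase [start, end) -> IRanges 1-based inclusive [start+1, end]
  IRanges::IRanges(start = segs$start + 1L, end = segs$end)
}

#' Cohort CNV frequency over genome bins
#'
#' For every genome bin and each state (gain, loss), computes the percentage
#' of cohort samples having at least one segment of that state overlapping
#' the bin by at least `min_overlap` bases. A sample counts at most once per
#' bin per state, however many of its segments hit the bin; a sample carrying
#' both a gain and a loss in one bin counts toward both frequencies. Samples
#' present in the input but without any gain/loss segment still count in the
#' denominator.
#'
#' @param segments classified segments (see [classify_segments()]), a data
#'   frame or `segment_file`.
#' @param bins a [make_bins()] tiling.
#' @param min_overlap minimum overlap in bases for a segment to hit a bin
#'   (default 1: any overlap).
#' @param n_samples cohort size for the denominator; default: number of
#'   distinct `sample_id` values in `segments`.
#' @param group cohort label carried into plots and exports.
#' @return a `cnv_freq_track` tibble: chromosome, start, end, gain_percent,
#'   loss_percent, with attributes `n_samples` and `group`.
#' @export
seg_to_freq <- function(segments, bins = make_bins(), min_overlap = 1,
                        n_samples = NULL, group = "all") {
  if (inherits(segments, "segment_file")) segments <- segments$segments
  segs <- as_tibble(segments)
  samples <- unique(segs$sample_id)
  n_samples <- n_samples %||% length(samples)
  if (is.null(n_samples) || n_samples < 1) {
    abort("Cohort has zero samples; supply segments from >= 1 sample or set `n_samples`.")
  }
  if (!"state" %in% names(segs)) {
    abort("Segments carry no `state` column; run classify_segments() first.")
  }
  bins_tbl <- as_tibble(bins)[, c("chromosome", "start", "end")]
  counts <- matrix(0L, nrow = nrow(bins_tbl), ncol = 2,
                   dimnames = list(NULL, c("gain", "loss")))
  for (chrom in unique(bins_tbl$chromosome)) {
    bidx <- which(bins_tbl$chromosome == chrom)
    bir <- seg_to_iranges(bins_tbl[bidx, ])
    for (st in c("gain", "loss")) {
      sel <- segs[segs$chromosome == chrom & segs$state == st, , drop = FALSE]
      if (nrow(sel) == 0) next
      hits <- IRanges::findOverlaps(bir, seg_to_iranges(sel),
                                    minoverlap = min_overlap)
      if (length(hits) == 0) next
      pair <- unique(data.frame(bin = S4Vectors::queryHits(hits),
                                sample = sel$sample_id[S4Vectors::subjectHits(hits)]))
      tab <- table(pair$bin)
      counts[bidx[as.integer(names(tab))], st] <-
        counts[bidx[as.integer(names(tab))], st] + as.integer(tab)
    }
  }
  out <- bins_tbl
  out$gain_percent <- 100 * counts[, "gain"] / n_samples
  out$loss_percent <- 100 * counts[, "loss"] / n_samples
  structure(out, n_samples = as.integer(n_samples), group = group,
            bin_size = attr(bins, "bin_size"),
            class = c("cnv_freq_track", class(out)))
}

#' Reference per-base CNV frequency counter
#'
#' Independent brute-force computation of the same quantity as
#' [seg_to_freq()]: per chromosome it materializes a per-base coverage vector
#' for every sample and state, then counts, for each bin, the samples whose
#' covered bases inside the bin reach `min_overlap`. No interval algebra is
#' involved, which makes it a slow but transparent cross-check; use it on
#' small (fixture-scale) genomes only.
#'
#' @inheritParams seg_to_freq
#' @return a tibble with the same columns as [seg_to_freq()].
#' @export
per_base_freq <- function(segments, bins, min_overlap = 1,
                          n_samples = NULL, group = "all") {
  if (inherits(segments, "segment_file")) segments <- segments$segments
  segs <- as_tibble(segments)
  samples <- unique(segs$sample_id)
  n_samples <- n_samples %||% length(samples)
  bins_tbl <- as_tibble(bins)[, c("chromosome", "start", "end")]
  gain <- loss <- integer(nrow(bins_tbl))
  for (chrom in unique(bins_tbl$chromosome)) {
    bidx <- which(bins_tbl$chromosome == chrom)
    chrom_len <- max(bins_tbl$end[bidx])
    for (st in c("gain", "loss")) {
      acc <- integer(length(bidx))
      for (sm in samples) {
        sel <- segs[segs$chromosome == chrom & segs$state == st &
                      segs$sample_id == sm, , drop = FALSE]
        if (nrow(sel) == 0) next
        covered <- logical(chrom_len)
        for (i in seq_len(nrow(sel))) {
          covered[(sel$start[i] + 1):min(sel$end[i], chrom_len)] <- TRUE
        }
        # covered bases inside each bin, via one cumulative pass
        cs <- c(0, cumsum(covered))
        in_bin <- cs[bins_tbl$end[bidx] + 1] - cs[bins_tbl$start[bidx] + 1]
        acc <- acc + as.integer(in_bin >= min_overlap)
      }
      if (st == "gain") gain[bidx] <- acc else loss[bidx] <- acc
    }
  }
  out <- bins_tbl
  out$gain_percent <- 100 * gain / n_samples
  out$loss_percent <- 100 * loss / n_samples
  structure(out, n_samples = as.integer(n_samples), group = group,
            class = c("cnv_freq_track", class(out)))
}

#' Per-sample CNV genome fractions
#'
#' For each sample, the fraction of the genome (or of each chromosome)
#' covered by gain segments and by loss segments. Overlapping same-state
#' intervals are merged before summation, so the fractions are invariant to
#' how a call is split into adjacent or overlapping pieces.
#' `total_fraction` is the covered fraction of the union of gain and loss
#' intervals; it equals `gain_fraction + loss_fraction` whenever the two sets
#' are disjoint within a sample.
#'
#' @param segments classified segments (data frame or `segment_file`).
#' @param lengths chromosome lengths (data frame or named vector), default
#'   [hg38_chromosome_lengths()].
#' @param scope `"genome"` (one row per sample) or `"chromosome"` (one row
#'   per sample x chromosome).
#' @return tibble: sample_id, (chromosome,) gain_fraction, loss_fraction,
#'   total_fraction.
#' @export
cnv_fraction <- function(segments, lengths = hg38_chromosome_lengths(),
                         scope = c("genome", "chromosome")) {
  scope <- match.arg(scope)
  if (inherits(segments, "segment_file")) segments <- segments$segments
  segs <- as_tibble(segments)
  if (!"state" %in% names(segs)) {
    abort("Segments carry no `state` column; run classify_segments() first.")
  }
  lens <- as_length_table(lengths)
  genome_len <- sum(lens$length)
  samples <- unique(segs$sample_id)

  covered_bases <- function(sel) {
    # per chromosome union length
    vapply(split(sel, sel$chromosome), function(s) {
      sum(IRanges::width(IRanges::reduce(seg_to_iranges(s))))
    }, 0)
  }

  rows <- lapply(samples, function(sm) {
    per_chrom <- tibble(chromosome = lens$chromosome,
                        gain = 0, loss = 0, total = 0)
    for (st in c("gain", "loss")) {
      sel <- segs[segs$sample_id == sm & segs$state == st, , drop = FALSE]
      if (nrow(sel) == 0) next
      cb <- covered_bases(sel)
      per_chrom[[st]][match(names(cb), per_chrom$chromosome)] <- cb
    }
    both <- segs[segs$sample_id == sm & segs$state %in% c("gain", "loss"), ,
                 drop = FALSE]
    if (nrow(both) > 0) {
      cb <- covered_bases(both)
      per_chrom$total[match(names(cb), per_chrom$chromosome)] <- cb
    }
    if (scope == "genome") {
      tibble(sample_id = sm,
             gain_fraction = sum(per_chrom$gain) / genome_len,
             loss_fraction = sum(per_chrom$loss) / genome_len,
             total_fraction = sum(per_chrom$total) / genome_len)
    } else {
      tibble(sample_id = sm, chromosome = per_chrom$chromosome,
             gain_fraction = per_chrom$gain / lens$length,
             loss_fraction = per_chrom$loss / lens$length,
             total_fraction = per_chrom$total / lens$length)
    }
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(sample_id = character(), gain_fraction = double(),
                  loss_fraction = double(), total_fraction = double())
  }
  out
}

#' Export a CNV frequency track as TSV
#'
#' Columns: chromosome, start, end, gain_percent, loss_percent, n_samples,
#' group.
#'
#' @param track a `cnv_freq_track` from [seg_to_freq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freq_tsv <- function(track, path) {
  stopifnot(inherits(track, "cnv_freq_track"))
  out <- as_tibble(track)
  out$n_samples <- attr(track, "n_samples")
  out$group <- attr(track, "group")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
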
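#' GRCh38 chromosome lengths
#'
#' Base lengths of the 24 canonical human chromosomes (GRCh38/hg38 primary
#' assembly), the default reference for genome binning and CNV fractions.
#' Any assembly can be used instead by supplying a `chromosome`/`length`
#' table to [make_bins()] or [cnv_fraction()].
#'
#' @return tibble with columns `chromosome`, `length`.
#' @export
hg38_chromosome_lengths <- function() {
  tibble(
    chromosome = CANONICAL_CHROMOSOMES,
    length = c(
      248956422L, 242193529L, 198295559L, 190214555L, 181538259L, 170805979L,
      159345973L, 145138636L, 138394717L, 133797422L, 135086622L, 133275309L,
      114364328L, 107043718L, 101991189L, 90338345L, 83257441L, 80373285L,
      58617616L, 64444167L, 46709983L, 50818468L, 156040895L, 57227415L
    )
  )
}

as_length_table <- function(lengths) {
  if (is.data.frame(lengths)) {
    if (!all(c("chromosome", "length") %in% names(lengths))) {
      abort("Chromosome length table needs `chromosome` and `length` columns.")
    }
    out <- tibble(chromosome = strip_chr_prefix(as.character(lengths$chromosome)),
                  length = as.numeric(lengths$length))
  } else if (is.numeric(lengths) && !is.null(names(lengths))) {
    out <- tibble(chromosome = strip_chr_prefix(names(lengths)),
                  length = as.numeric(lengths))
  } else {
    abort("`lengths` must be a chromosome/length data frame or a named numeric vector.")
  }
  if (nrow(out) == 0) abort("Chromosome length table is empty.")
  if (any(out$length <= 0) || any(is.na(out$length))) {
    abort("Chromosome lengths must be positive.")
  }
  if (anyDuplicated(out$chromosome)) abort("Duplicate chromosome in length table.")
  out[order(chromosome_factor(out$chromosome)), , drop = FALSE]
}

#' Tile a genome into fixed-size bins
#'
#' Partitions each chromosome into consecutive half-open bins of `bin_size`
#' bases; the last bin of a chromosome is shorter when the length is not a
#' multiple, so the bins tile the genome exactly (no gaps, no overlap, bin
#' lengths sum to the chromosome length).
#'
#' @param lengths chromosome lengths: a `chromosome`/`length` data frame or a
#'   named numeric vector. Default [hg38_chromosome_lengths()].
#' @param bin_size bin width in bases (default 1e6, the Progenetix-style
#'   1 Mb convention).
#' @return a `genome_bins` tibble with columns `chromosome`, `start`, `end`
#'   (0-based half-open) and attributes `bin_size`, `lengths`.
#' @export
#' @examples
#' make_bins(c("1" = 2500000), bin_size = 1e6)  # 3 bins, last 0.5 Mb
make_bins <- function(lengths = hg38_chromosome_lengths(), bin_size = 1e6) {
  if (length(bin_size) != 1 || is.na(bin_size) || bin_size < 1) {
    abort("`bin_size` must be a single integer >= 1.")
  }
  bin_size <- as.numeric(bin_size)
  lens <- as_length_table(lengths)
  bins <- purrr::map2(lens$chromosome, lens$length, function(chrom, len) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble(chromosome = chrom, start = starts,
           end = pmin(starts + bin_size, len))
  })
  out <- bind_rows(bins)
  structure(out, bin_size = bin_size, lengths = lens,
            class = c("genome_bins", class(out)))
}
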
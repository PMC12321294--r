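SEGMENT_COLUMNS <- c("sample_id", "chromosome", "start", "end", "log2",
                     "state", "n_probes")

# accepted header spellings (case-insensitive) per canonical column
SEG_HEADER_SYNONYMS <- list(
  sample_id  = c("sample_id", "biosample_id", "sample", "id"),
  chromosome = c("chromosome", "chro", "chrom", "reference_name"),
  start      = c("start", "loc.start", "start_position"),
  end        = c("end", "loc.end", "end_position"),
  log2       = c("log2", "value", "seg.mean", "mean", "segment_mean"),
  state      = c("state", "variant_type", "variant_state"),
  n_probes   = c("n_probes", "num.mark", "probes", "num_probes")
)

new_segment_file <- function(segments, metadata = tibble(sample_id = character()),
                             dialect = "pgxseg", comments = character()) {
  structure(list(segments = segments, metadata = metadata,
                 dialect = dialect, comments = comments),
            class = "segment_file")
}

#' @export
print.segment_file <- function(x, ...) {
  cat("<segment_file> dialect:", x$dialect, "\n",
      " ", nrow(x$segments), "segment(s),",
      nrow(x$metadata), "metadata row(s)\n")
  invisible(x)
}

empty_segments <- function() {
  tibble(sample_id = character(), chromosome = character(),
         start = integer(), end = integer(), log2 = double(),
         state = character(), n_probes = integer())
}

#' Read a `.seg` or `.pgxseg` CNV segment file
#'
#' Both dialects are TAB-separated segment tables with a header row. The
#' `.pgxseg` dialect additionally carries `#`-prefixed per-sample metadata
#' lines (`#key=value;key=value`, with a mandatory sample identifier key)
#' before the table; other `#` lines are kept verbatim as file comments.
#'
#' Coordinates are normalized on read: `.seg` files use 1-based inclusive
#' positions (the circular-binary-segmentation output convention) and are
#' shifted to the package-internal 0-based half-open ("interbase")
#' convention; `.pgxseg` files are interbase already. `chr` prefixes are
#' stripped. Header spellings vary across exporters, so `sample_id` /
#' `biosample_id`, `log2` / `value` / `seg.mean`, etc. are all accepted.
#'
#' @param path file to read.
#' @param dialect `"auto"` (default: `.pgxseg` when `#` metadata lines or a
#'   `.pgxseg` extension are present), `"pgxseg"`, or `"seg"`.
#' @return a `segment_file`: list with `segments` (tibble: sample_id,
#'   chromosome, start, end, log2, state, n_probes), `metadata` (tibble, one
#'   row per annotated sample), `dialect`, `comments`.
#' @export
read_segfile <- function(path, dialect = c("auto", "pgxseg", "seg")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)

  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (dialect == "auto") {
    dialect <- if (length(meta_lines) > 0 ||
                   grepl("\\.pgxseg$", path, ignore.case = TRUE)) "pgxseg" else "seg"
  }

  md <- parse_pgxseg_metadata(meta_lines)
  if (dialect == "seg" && nrow(md$metadata) > 0) {
    warn("`#` metadata lines found in a file read as .seg; kept as metadata anyway.")
  }

  if (length(body) == 0) {
    sf <- new_segment_file(empty_segments(), md$metadata, dialect, md$comments)
    return(sf)
  }

  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  colmap <- match_seg_header(header)
  for (req in c("sample_id", "chromosome", "start", "end")) {
    if (is.na(colmap[[req]])) {
      abort(paste0("Missing mandatory column ", sQuote(req),
                   " (accepted spellings: ",
                   paste(SEG_HEADER_SYNONYMS[[req]], collapse = "/"),
                   ") in header: ", body[1]))
    }
  }

  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  if (length(rows) == 0) {
    sf <- new_segment_file(empty_segments(), md$metadata, dialect, md$comments)
    return(sf)
  }
  get <- function(fields, idx) if (is.na(idx) || idx > length(fields)) NA else fields[idx]
  segs <- purrr::imap(rows, function(fields, i) {
    line_no <- i + 1L  # 1 = header
    s_chr <- get(fields, colmap$start); e_chr <- get(fields, colmap$end)
    s <- suppressWarnings(as.numeric(s_chr)); e <- suppressWarnings(as.numeric(e_chr))
    if (is.na(s) || is.na(e)) {
      abort(paste0("Non-numeric coordinates at segment line ", line_no,
                   ": start=", s_chr, " end=", e_chr))
    }
    lg <- suppressWarnings(as.numeric(get(fields, colmap$log2)))
    np <- suppressWarnings(as.integer(get(fields, colmap$n_probes)))
    tibble(
      sample_id = as.character(get(fields, colmap$sample_id)),
      chromosome = strip_chr_prefix(as.character(get(fields, colmap$chromosome))),
      start = s, end = e, log2 = lg,
      state = as.character(get(fields, colmap$state)),
      n_probes = np, line = line_no
    )
  })
  segs <- bind_rows(segs)
  if (dialect == "seg") {
    segs$start <- segs$start - 1  # 1-based inclusive -> 0-based half-open
  }
  bad <- segs$line[segs$start < 0 | segs$start >= segs$end]
  if (length(bad)) {
    abort(paste0("Invalid interval (need 0 <= start < end) at segment line(s): ",
                 paste(bad, collapse = ", ")))
  }
  segs$state <- normalize_state(segs$state)
  segs$start <- as.integer(segs$start)
  segs$end <- as.integer(segs$end)
  segs$line <- NULL

  sf <- new_segment_file(order_segments(segs), md$metadata, dialect, md$comments)
  orphans <- setdiff(unique(sf$segments$sample_id), sf$metadata$sample_id)
  if (dialect == "pgxseg" && nrow(sf$metadata) > 0 && length(orphans) > 0) {
    warn(paste0("Segment sample(s) without metadata: ",
                paste(orphans, collapse = ", ")))
  }
  sf
}

# lower-case the three canonical labels; keep CURIEs/DUP/DEL etc. verbatim
# (mapping them to states is classify_segments' job, not the parser's)
normalize_state <- function(state) {
  raw <- as.character(state)
  low <- tolower(trimws(raw))
  out <- raw
  out[is.na(low) | !nzchar(low)] <- "unknown"
  canonical <- !is.na(low) & low %in% c("gain", "loss", "neutral", "unknown")
  out[canonical] <- low[canonical]
  out
}

order_segments <- function(segs) {
  if (nrow(segs) == 0) return(segs)
  segs[order(segs$sample_id, chromosome_factor(segs$chromosome), segs$start), ,
       drop = FALSE]
}

match_seg_header <- function(header) {
  h <- tolower(trimws(header))
  lapply(SEG_HEADER_SYNONYMS, function(syn) {
    hit <- which(h %in% syn)
    if (length(hit)) hit[1] else NA_integer_
  })
}

# "#sample_id=...;key=value" lines -> metadata tibble; others -> comments
parse_pgxseg_metadata <- function(meta_lines) {
  comments <- character()
  rows <- list()
  for (line in meta_lines) {
    body <- sub("^#+\\s*", "", line)
    pairs <- strsplit(body, ";", fixed = TRUE)[[1]]
    kv <- strsplit(pairs, "=", fixed = TRUE)
    if (any(vapply(kv, length, 0L) != 2)) {
      comments <- c(comments, line)
      next
    }
    vals <- setNames(vapply(kv, function(p) trimws(p[2]), ""),
                     vapply(kv, function(p) trimws(p[1]), ""))
    id_key <- intersect(c("sample_id", "biosample_id", "sample"), names(vals))
    if (length(id_key) == 0) {
      comments <- c(comments, line)
      next
    }
    vals <- c(sample_id = unname(vals[id_key[1]]),
              vals[setdiff(names(vals), id_key)])
    rows[[length(rows) + 1L]] <- tibble::as_tibble_row(as.list(vals))
  }
  metadata <- if (length(rows)) bind_rows(rows) else tibble(sample_id = character())
  if (anyDuplicated(metadata$sample_id)) {
    abort(paste0("Duplicate metadata sample_id: ",
                 paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
                       collapse = ", ")))
  }
  list(metadata = metadata, comments = comments)
}

#' Write a segment file in the `.pgxseg` dialect
#'
#' Emits file comments and per-sample metadata as `#` lines, then the
#' TAB-separated segment table in interbase coordinates. Reading the file
#' back with [read_segfile()] reproduces the object exactly (canonical
#' chromosome/start ordering, `NA` log2 as empty fields).
#'
#' @param x a `segment_file` (or a bare segments data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgxseg <- function(x, path) {
  x <- as_segment_file(x, dialect = "pgxseg")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in x$comments) writeLines(cm, con)
  if (nrow(x$metadata) > 0) {
    for (i in seq_len(nrow(x$metadata))) {
      row <- x$metadata[i, , drop = FALSE]
      keep <- !vapply(row, function(v) is.na(v), logical(1))
      writeLines(paste0("#", paste(paste0(names(row)[keep], "=",
                                          unlist(row[keep])), collapse = ";")),
                 con)
    }
  }
  segs <- order_segments(x$segments)
  writeLines(paste(SEGMENT_COLUMNS, collapse = "\t"), con)
  if (nrow(segs) > 0) {
    utils::write.table(segs[, SEGMENT_COLUMNS], con, sep = "\t", na = "",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a segment file in the standard `.seg` dialect
#'
#' Re-shifts interbase intervals to the 1-based inclusive convention of
#' `.seg` files; metadata (which `.seg` cannot carry) is dropped with a
#' warning when present.
#'
#' @inheritParams write_pgxseg
#' @export
write_seg <- function(x, path) {
  x <- as_segment_file(x, dialect = "seg")
  if (nrow(x$metadata) > 0) {
    warn("`.seg` cannot carry sample metadata; metadata rows dropped on write.")
  }
  segs <- order_segments(x$segments)
  out <- tibble(ID = segs$sample_id, chrom = segs$chromosome,
                loc.start = segs$start + 1L, loc.end = segs$end,
                num.mark = segs$n_probes, seg.mean = segs$log2)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0) {
    utils::write.table(out, con, sep = "\t", na = "", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

as_segment_file <- function(x, dialect = "pgxseg") {
  if (inherits(x, "segment_file")) return(x)
  if (is.data.frame(x)) {
    segs <- as_tibble(x)
    for (col in SEGMENT_COLUMNS) {
      if (!col %in% names(segs)) {
        segs[[col]] <- if (col %in% c("start", "end", "n_probes")) NA_integer_
          else if (col == "log2") NA_real_ else NA_character_
      }
    }
    if ("state" %in% names(segs)) segs$state <- normalize_state(segs$state)
    return(new_segment_file(segs[, SEGMENT_COLUMNS], dialect = dialect))
  }
  abort("Expected a `segment_file` or a segments data frame.")
}

#' Split a segment file into segment and metadata tables
#'
#' The segment table has the fixed column set (sample_id, chromosome, start,
#' end, log2, state); the metadata table passes through every annotation key
#' found in the file's `#` lines.
#'
#' @param x a `segment_file` from [read_segfile()].
#' @return list with tibbles `segments` and `metadata`.
#' @export
split_segmentfile <- function(x) {
  stopifnot(inherits(x, "segment_file"))
  list(
    segments = x$segments[, c("sample_id", "chromosome", "start", "end",
                              "log2", "state")],
    metadata = x$metadata
  )
}
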
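CARDINALITIES <- c("scalar", "first", "join", "explode")

#' Load a declarative JSON-to-table mapping configuration
#'
#' A mapping config describes how nested Beacon v2 entity documents become
#' columns of a rectangular table. It is a YAML document:
#'
#' ```yaml
#' entity: biosamples
#' columns:
#'   - name: biosample_id
#'     path: id
#'   - name: external_refs
#'     path: externalReferences[].id
#'     cardinality: join      # scalar | first | join | explode
#'     delimiter: ";"
#' ```
#'
#' Path expressions are dot-separated key paths; a `[]` marker collects a
#' value across the elements of a list (this tiny dialect — not full JSONPath
#' — keeps flattening auditable). Cardinality says what to do with list
#' values: `first` keeps the first element, `join` concatenates with the
#' delimiter (default `";"`), `explode` multiplies the record into one row
#' per element. At most one column may explode, so row multiplication stays
#' unambiguous. Paths without `[]` default to `scalar`, paths with it to
#' `join`.
#'
#' @param source path to a YAML file, or a YAML string.
#' @return a `mapping_config`: tibble(name, path, cardinality, delimiter)
#'   with the entity name as attribute.
#' @seealso [flatten_records()], [default_mapping()]
#' @export
load_mapping <- function(source) {
  doc <- if (length(source) == 1 && file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (!is.list(doc) || is.null(doc$columns)) {
    abort("Mapping config must be a YAML mapping with a `columns` list.")
  }
  cols <- purrr::imap(doc$columns, function(col, i) {
    if (is.null(col$name) || is.null(col$path)) {
      abort(paste0("Mapping column #", i, " lacks `name` or `path`."))
    }
    # YAML 1.1 coerces bare y/n/on/off to logical; paths must be strings
    if (!is.character(col$path) || length(col$path) != 1) {
      abort(paste0("Malformed path in column ", sQuote(col$name),
                   ": quote path values in the YAML."))
    }
    col$name <- as.character(col$name)
    if (!grepl("^[A-Za-z0-9_.$-]+(\\[\\])?([.][A-Za-z0-9_.$-]+(\\[\\])?)*$",
               gsub("\\[\\]", "", col$path)) || grepl("\\.\\.", col$path)) {
      abort(paste0("Malformed path ", sQuote(col$path),
                   " in column ", sQuote(col$name), "."))
    }
    card <- col$cardinality %||%
      (if (grepl("\\[\\]", col$path)) "join" else "scalar")
    if (!card %in% CARDINALITIES) {
      abort(paste0("Unknown cardinality ", sQuote(card), " in column ",
                   sQuote(col$name), "; valid: ",
                   paste(CARDINALITIES, collapse = ", "), "."))
    }
    tibble(name = col$name, path = col$path, cardinality = card,
           delimiter = col$delimiter %||% ";")
  })
  cfg <- bind_rows(cols)
  dup <- cfg$name[duplicated(cfg$name)]
  if (length(dup)) {
    abort(paste0("Duplicate column name(s): ", paste(unique(dup), collapse = ", "), "."))
  }
  if (sum(cfg$cardinality == "explode") > 1) {
    abort("At most one column may have cardinality `explode`.")
  }
  structure(cfg, entity = doc$entity %||% NA_character_,
            class = c("mapping_config", class(cfg)))
}

#' Packaged default mapping for a Beacon entity
#'
#' Loads the mapping configuration shipped under `inst/config/` for
#' individuals, biosamples, analyses or g_variants. These reflect the
#' Progenetix-style Beacon v2 default-model field names; they are best-effort
#' column inventories, and any beacon can be accommodated by supplying a
#' custom config to [fetch_multi_domain()] or [flatten_records()].
#'
#' @param entity entity name.
#' @return a `mapping_config`.
#' @export
default_mapping <- function(entity) {
  entity <- match.arg(entity, BEACON_ENTITIES)
  path <- system.file("config", paste0(entity, ".yaml"),
                      package = "beaconcnv", mustWork = TRUE)
  load_mapping(path)
}

#' Resolve a path expression inside a nested document
#'
#' Total function: missing keys at any depth yield `NULL`, never an error.
#' A `[]` marker maps the remaining path over the elements of a list and
#' concatenates the results.
#'
#' @param record a nested list (parsed JSON document).
#' @param path a path expression, e.g. `"histologicalDiagnosis.id"` or
#'   `"externalReferences[].id"`.
#' @return a scalar value, a list of values, or `NULL`.
#' @export
#' @examples
#' rec <- list(id = "PGX_1", histologicalDiagnosis = list(id = "NCIT:C3512"))
#' resolve_path(rec, "histologicalDiagnosis.id")
#' resolve_path(rec, "sampleOriginDetail.id")   # NULL
resolve_path <- function(record, path) {
  steps <- strsplit(path, ".", fixed = TRUE)[[1]]
  resolve_steps(record, steps)
}

resolve_steps <- function(node, steps) {
  if (is.null(node)) return(NULL)
  if (length(steps) == 0) return(node)
  step <- steps[1]
  rest <- steps[-1]
  if (grepl("\\[\\]$", step)) {
    key <- sub("\\[\\]$", "", step)
    child <- if (nzchar(key)) safe_pluck(node, key) else node
    if (is.null(child)) return(NULL)
    if (!is.list(child)) child <- list(child)
    vals <- purrr::compact(lapply(child, resolve_steps, steps = rest))
    # flatten one level so nested [] markers accumulate into a single list
    vals <- purrr::list_flatten(lapply(vals, function(v) if (is.list(v)) v else list(v)))
    if (length(vals) == 0) NULL else vals
  } else {
    resolve_steps(safe_pluck(node, step), rest)
  }
}

safe_pluck <- function(node, key) {
  if (!is.list(node)) return(NULL)
  node[[key]]
}

# Apply one config row's cardinality rule to a resolved value.
# Returns a length-1 vector for scalar/first/join; a list of scalars for explode.
apply_cardinality <- function(value, cardinality, delimiter) {
  if (is.null(value)) {
    return(if (cardinality == "explode") list() else NA)
  }
  vals <- if (is.list(value)) value else list(value)
  vals <- lapply(vals, function(v) if (is.null(v) || length(v) == 0) NA else v)
  switch(cardinality,
    scalar = if (length(vals) == 1) vals[[1]] else
      paste(vapply(vals, as.character, ""), collapse = delimiter),
    first = vals[[1]],
    join = paste(vapply(vals, as.character, ""), collapse = delimiter),
    explode = vals
  )
}

#' Flatten nested entity documents into a tibble
#'
#' One output row per record unless the config has an `explode` column, in
#' which case a record yields one row per list element (and a single all-null
#' row when the list is empty or absent). Values keep their native JSON
#' scalar types; columns where every value is scalar and type-consistent are
#' simplified, others stay list-columns.
#'
#' @param records list of nested documents (e.g. `envelope$records`).
#' @param config a `mapping_config` from [load_mapping()].
#' @param domain optional provenance label; adds a leading `domain` column.
#' @return a tibble with the config's columns (plus `domain` if given).
#' @export
flatten_records <- function(records, config, domain = NULL) {
  stopifnot(inherits(config, "mapping_config"))
  explode_col <- config$name[config$cardinality == "explode"]
  rows <- lapply(records, function(rec) {
    cells <- lapply(seq_len(nrow(config)), function(i) {
      apply_cardinality(resolve_path(rec, config$path[i]),
                        config$cardinality[i], config$delimiter[i])
    })
    names(cells) <- config$name
    if (length(explode_col) == 0) return(list(cells))
    ex <- cells[[explode_col]]
    n <- max(1L, length(ex))
    lapply(seq_len(n), function(k) {
      out <- cells
      out[[explode_col]] <- if (length(ex) >= k) ex[[k]] else NA
      out
    })
  })
  rows <- purrr::list_flatten(rows)
  out <- if (length(rows) == 0) {
    as_tibble(setNames(rep(list(logical(0)), nrow(config)), config$name))
  } else {
    bind_rows(lapply(rows, function(r) tibble::as_tibble_row(lapply(r, list))))
  }
  out <- simplify_list_columns(out)
  if (!is.null(domain) && nrow(out) > 0) {
    out <- mutate(out, domain = domain, .before = 1)
  } else if (!is.null(domain)) {
    out <- mutate(out, domain = character(0), .before = 1)
  }
  out
}

# Unwrap list-columns whose cells are all length-<=1 scalars of one base type.
simplify_list_columns <- function(tbl) {
  for (nm in names(tbl)) {
    col <- tbl[[nm]]
    if (!is.list(col)) next
    flat <- lapply(col, function(v) {
      if (is.list(v) && length(v) == 1) v <- v[[1]]
      v
    })
    ok <- all(vapply(flat, function(v) {
      is.null(v) || (is.atomic(v) && length(v) == 1)
    }, logical(1)))
    if (ok) {
      flat <- lapply(flat, function(v) if (is.null(v)) NA else v)
      types <- unique(vapply(flat[!is.na(flat)], function(v) class(v)[1], ""))
      if (length(types) <= 1 || all(types %in% c("integer", "numeric"))) {
        tbl[[nm]] <- unlist(lapply(flat, function(v) v %||% NA))
      } else {
        tbl[[nm]] <- vapply(flat, function(v) {
          if (length(v) == 1 && is.na(v)) NA_character_ else as.character(v)
        }, "")
      }
    }
  }
  tbl
}

#' Harmonize tables from heterogeneous beacons
#'
#' Row-binds flat tables whose column sets differ: the output columns are the
#' union in first-seen order, absent cells are `NA`, and any provenance
#' (`domain`) column passes through. Idempotent.
#'
#' @param tables a list of data frames (or a single data frame).
#' @return a tibble.
#' @export
harmonize_tables <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  tables <- purrr::compact(tables)
  if (length(tables) == 0) return(tibble())
  # guard against incompatible column types across beacons: a column that is
  # character anywhere is coerced to character everywhere before binding
  char_cols <- unique(unlist(lapply(tables, function(t) {
    names(t)[vapply(t, is.character, logical(1))]
  })))
  tables <- lapply(tables, function(t) {
    for (nm in intersect(char_cols, names(t))) t[[nm]] <- as.character(t[[nm]])
    as_tibble(t)
  })
  bind_rows(tables)
}

#' Write a flat table as TSV or CSV
#'
#' `NA` cells are written as empty strings, the convention of tabular
#' bioinformatics exports. Format chosen by file extension (`.csv` = comma,
#' anything else = TAB).
#'
#' @param table a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flat_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(table, path, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
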
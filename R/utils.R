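# Canonical chromosome ordering used throughout: autosomes 1..22 then X, Y.
CANONICAL_CHROMOSOMES <- c(as.character(1:22), "X", "Y")

#' Order chromosome labels canonically
#'
#' Returns a factor ordered 1..22, X, Y with any non-canonical labels appended
#' in first-appearance order (synthetic assemblies keep working).
#'
#' @param x character vector of chromosome labels (no "chr" prefix).
#' @return factor with canonical level order.
#' @keywords internal
chromosome_factor <- function(x) {
  extra <- setdiff(unique(x), CANONICAL_CHROMOSOMES)
  factor(x, levels = c(intersect(CANONICAL_CHROMOSOMES, unique(x)), extra))
}

strip_chr_prefix <- function(x) sub("^[Cc][Hh][Rr]", "", x)

#' Is a filter string CURIE-shaped?
#'
#' A CURIE is `prefix:suffix` with a non-empty alphanumeric prefix,
#' e.g. `NCIT:C3512`.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
#' @examples
#' is_curie(c("NCIT:C3512", "lung cancer"))
is_curie <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9._-]*:\\S+$", x)
}

# Collapse a scalar-or-NULL to a default.
scalar_or <- function(x, default = NA) {
  if (is.null(x) || length(x) == 0) default else x
}

# stable, filesystem-safe key for a request URL (used by fixture files)
url_fixture_key <- function(url) {
  rlang::hash(url)
}
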
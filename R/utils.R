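# shared helpers: identifier normalization and small validators

#' Normalize an identifier
#'
#' Trims leading/trailing whitespace and collapses internal whitespace runs to
#' a single space. Case is preserved: MeSH headings and gene symbols are
#' case-significant in practice.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_id(c("  lung   neoplasms ", "hsa_circ_0000140"))
normalize_id <- function(x) {
  x <- gsub("[[:space:]]+", " ", as.character(x))
  trimws(x)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}
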
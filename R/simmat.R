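#' Labeled similarity matrix
#'
#' A `simmat` is a square numeric matrix of pairwise similarity scores with
#' identical row and column labels. It is the common currency of the package:
#' the disease-derived (CDFS), ontology-derived (GOFS), sequence-derived
#' (SQFS), fused (FS), miRNA Jaccard (CMS) and expression similarity networks
#' are all `simmat` objects. Invariants enforced at construction:
#'
#' * symmetric within an absolute tolerance of 1e-9;
#' * all values in \[0, 1\] or `NA` (the missing-evidence sentinel);
#' * diagonal entries equal to 1 or `NA`.
#'
#' `NA` marks pairs for which a modality carries no evidence (for example a
#' circRNA with no known disease association); it is not a zero. Downstream
#' fusion renormalizes over the modalities that are present.
#'
#' @param values square numeric matrix.
#' @param labels character vector of entity labels; defaults to
#'   `rownames(values)`.
#' @return an object of class `simmat`.
#' @export
#' @examples
#' m <- diag(2)
#' m[1, 2] <- m[2, 1] <- 0.4
#' simmat(m, labels = c("circA", "circB"))
simmat <- function(values, labels = rownames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) {
    abort(sprintf("`values` must be square, got %d x %d", nrow(values), ncol(values)))
  }
  if (is.null(labels)) abort("`labels` must be supplied (or set as rownames)")
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    abort("length of `labels` must equal the matrix dimension")
  }
  if (anyDuplicated(labels) || any(!nzchar(labels))) {
    abort("labels must be unique and non-empty")
  }
  diffs <- abs(values - t(values))
  if (any(diffs > 1e-9, na.rm = TRUE) ||
      any(is.na(values) != is.na(t(values)))) {
    abort("similarity matrix must be symmetric within 1e-9")
  }
  rng <- range(values, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)) {
    abort(sprintf("similarity values must lie in [0, 1]; range is [%g, %g]",
                  rng[1], rng[2]))
  }
  d <- diag(values)
  if (any(!is.na(d) & abs(d - 1) > 1e-9)) {
    abort("diagonal entries must equal 1 (or NA for the missing sentinel)")
  }
  # clamp tiny numerical excursions introduced by symmetrization
  values[!is.na(values) & values < 0] <- 0
  values[!is.na(values) & values > 1] <- 1
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  class(values) <- c("simmat", class(matrix()))
  values
}

#' @rdname simmat
#' @param x object to test or tidy.
#' @export
is_simmat <- function(x) inherits(x, "simmat")

#' @export
print.simmat <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<simmat> %d x %d entities, %d missing off-diagonal entries\n",
              n, n, sum(is.na(x[upper.tri(x)])) * 2L))
  k <- min(n, 6L)
  print(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], digits = 3)
  if (n > k) cat(sprintf("... %d more entities\n", n - k))
  invisible(x)
}

#' Tidy a similarity matrix into pair rows
#'
#' Converts the strictly-upper triangle of a `simmat` into a tibble of pairs,
#' one row per unordered entity pair.
#'
#' @param x a `simmat`.
#' @param ... unused.
#' @return a tibble with columns `item1`, `item2`, `similarity`.
#' @export
tidy.simmat <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    item1 = labs[idx[, 1]],
    item2 = labs[idx[, 2]],
    similarity = unclass(x)[idx]
  )
}

#' Heatmap of a similarity matrix
#'
#' @param object a `simmat`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.simmat <- function(object, ...) {
  labs <- rownames(object)
  df <- expand.grid(item1 = labs, item2 = labs, stringsAsFactors = FALSE)
  df$similarity <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item1, y = .data$item2,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

# internal: build a simmat from an upper-triangle filler function
simmat_labels <- function(x) rownames(x)

check_same_labels <- function(a, b, name_a, name_b) {
  la <- rownames(a); lb <- rownames(b)
  if (length(la) != length(lb) || any(la != lb)) {
    bad <- which(la[seq_len(min(length(la), length(lb)))] !=
                 lb[seq_len(min(length(la), length(lb)))])
    detail <- if (length(bad)) {
      sprintf("first discrepancy at position %d: '%s' vs '%s'",
              bad[1], la[bad[1]], lb[bad[1]])
    } else {
      sprintf("label counts differ: %d vs %d", length(la), length(lb))
    }
    abort(sprintf("label sets of %s and %s must match exactly (%s)",
                  name_a, name_b, detail))
  }
  invisible(TRUE)
}
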
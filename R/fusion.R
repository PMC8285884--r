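# Weighted fusion of the three similarity networks, the miRNA Jaccard
# reference network, grid-search weight tuning, and evaluation utilities.

#' Fusion weights
#'
#' Convex weights on the three modality networks: `alpha` on the
#' disease-derived network (CDFS), `beta` on the ontology-derived network
#' (GOFS), `gamma` on the sequence-derived network (SQFS). They must sum to 1
#' within 1e-9.
#'
#' @param alpha,beta,gamma weights in \[0, 1\].
#' @return a list of class `fusion_weights`.
#' @export
#' @examples
#' fusion_weights(0.1, 0.3, 0.6)
fusion_weights <- function(alpha, beta, gamma) {
  check_scalar_number(alpha, "alpha", 0, 1)
  check_scalar_number(beta, "beta", 0, 1)
  check_scalar_number(gamma, "gamma", 0, 1)
  if (abs(alpha + beta + gamma - 1) > 1e-9) {
    abort(sprintf("weights must sum to 1 within 1e-9, got %g",
                  alpha + beta + gamma))
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("<fusion_weights> alpha = %g, beta = %g, gamma = %g\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Fuse the three similarity networks
#'
#' Entry-wise convex combination `FS = alpha * CDFS + beta * GOFS + gamma *
#' SQFS`. Where a modality carries the missing sentinel for a pair, the
#' remaining weights are renormalized over the modalities that are present,
#' so FS stays on the \[0, 1\] scale instead of being silently down-weighted;
#' `renormalize = FALSE` selects the strict mode in which any missing
#' modality makes the fused entry missing. The diagonal is 1.
#'
#' @param cdfs,gofs,sqfs [simmat()] objects over an identical label set and
#'   order.
#' @param weights a [fusion_weights()].
#' @param renormalize renormalize over available modalities (default TRUE).
#' @return a [simmat()] of fused functional similarity.
#' @export
fuse <- function(cdfs, gofs, sqfs, weights, renormalize = TRUE) {
  if (!inherits(weights, "fusion_weights")) {
    abort("`weights` must be a fusion_weights object")
  }
  for (m in list(cdfs, gofs, sqfs)) {
    if (!is_simmat(m)) abort("all inputs must be simmat objects")
  }
  check_same_labels(cdfs, gofs, "cdfs", "gofs")
  check_same_labels(cdfs, sqfs, "cdfs", "sqfs")
  w <- c(weights$alpha, weights$beta, weights$gamma)
  mats <- list(unclass(cdfs), unclass(gofs), unclass(sqfs))
  if (renormalize) {
    num <- matrix(0, nrow(cdfs), ncol(cdfs))
    den <- matrix(0, nrow(cdfs), ncol(cdfs))
    for (k in 1:3) {
      present <- !is.na(mats[[k]])
      num[present] <- num[present] + w[k] * mats[[k]][present]
      den[present] <- den[present] + w[k]
    }
    vals <- ifelse(den > 0, num / den, NA_real_)
  } else {
    vals <- w[1] * mats[[1]] + w[2] * mats[[2]] + w[3] * mats[[3]]
  }
  diag(vals) <- 1
  simmat(vals, labels = rownames(cdfs))
}

#' circRNA-miRNA Jaccard similarity (CMS)
#'
#' The reference signal for weight tuning: circRNAs acting as sponges for
#' overlapping miRNA sets are functionally related, so entry (i, j) is the
#' Jaccard index of the two miRNA sets. Pairs where both sets are empty get
#' the missing sentinel; the diagonal is 1.
#'
#' @param circ_mirna an `assoc_tbl` of kind `"circ-mirna"`.
#' @param circ_ids ordered character vector of circRNA labels.
#' @return a [simmat()] over `circ_ids`.
#' @export
cms_matrix <- function(circ_mirna, circ_ids) {
  check_assoc_kind(circ_mirna, "circ-mirna", "circ_mirna")
  if (!length(circ_ids)) abort("`circ_ids` must be non-empty")
  circ_ids <- as.character(circ_ids)
  msets <- lapply(circ_ids, function(cid) assoc_lookup(circ_mirna, cid))
  n <- length(circ_ids)
  vals <- matrix(NA_real_, n, n)
  diag(vals) <- 1
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        u <- length(union(msets[[i]], msets[[j]]))
        if (u == 0) next
        v <- length(intersect(msets[[i]], msets[[j]])) / u
        vals[i, j] <- v; vals[j, i] <- v
      }
    }
  }
  simmat(vals, labels = circ_ids)
}

#' Correlate two similarity networks
#'
#' Pearson correlation over the strictly-upper-triangle pairs where both
#' matrices carry a value (self-pairs are always 1 and would inflate the
#' correlation).
#'
#' @param a,b [simmat()] objects over the same labels.
#' @return a list of class `circ_eval`: `r`, `p`, `n_pairs`, `per_bin`
#'   (NULL here).
#' @export
correlate <- function(a, b) {
  if (!is_simmat(a) || !is_simmat(b)) abort("inputs must be simmat objects")
  check_same_labels(a, b, "a", "b")
  ut <- upper.tri(a)
  x <- unclass(a)[ut]; y <- unclass(b)[ut]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    abort(sprintf("need at least 3 usable pairs, got %d", length(x)))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant upper triangle: correlation undefined (zero variance)")
  }
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n_pairs = length(x), per_bin = NULL),
            class = "circ_eval")
}

#' @export
print.circ_eval <- function(x, ...) {
  cat(sprintf("<circ_eval> R = %.4g, P = %.3g, n_pairs = %d%s\n",
              x$r, x$p, x$n_pairs,
              if (!is.null(x$per_bin)) sprintf(" (%d bins)", nrow(x$per_bin)) else ""))
  invisible(x)
}

#' @export
tidy.circ_eval <- function(x, ...) {
  if (is.null(x$per_bin)) {
    tibble(r = x$r, p = x$p, n_pairs = x$n_pairs)
  } else {
    x$per_bin
  }
}

#' @export
glance.circ_eval <- function(x, ...) {
  tibble(r = x$r, p = x$p, n_pairs = x$n_pairs,
         n_bins = if (is.null(x$per_bin)) NA_integer_ else nrow(x$per_bin))
}

#' Grid search over fusion weights
#'
#' Enumerates all weight triples on a regular grid — `alpha` from 0 to
#' `alpha_max`, `beta` from 0 to 1, `gamma = 1 - alpha - beta >= 0` — fuses
#' the three networks at each triple and scores the fused network by Pearson
#' correlation against the miRNA Jaccard network. With step 0.1 and
#' `alpha_max` 0.2 this is exactly 30 combinations. The best triple maximizes
#' r; ties break by smaller p, then lexicographically by (alpha, beta).
#'
#' @param cdfs,gofs,sqfs modality networks, see [fuse()].
#' @param cms the reference [cms_matrix()].
#' @param step grid step; must divide 1 evenly.
#' @param alpha_max upper bound on alpha; must be a multiple of `step`.
#' @param renormalize passed to [fuse()].
#' @return a list of class `circ_grid`: `best` ([fusion_weights()]), `table`
#'   (tibble of all combinations with r, p, n_pairs).
#' @export
grid_search <- function(cdfs, gofs, sqfs, cms, step = 0.1, alpha_max = 0.2,
                        renormalize = TRUE) {
  check_scalar_number(step, "step", 1e-9, 1)
  check_scalar_number(alpha_max, "alpha_max", 0, 1)
  if (abs(1 / step - round(1 / step)) > 1e-9) {
    abort(sprintf("`step` must divide 1 evenly, got %g", step))
  }
  if (abs(alpha_max / step - round(alpha_max / step)) > 1e-9) {
    abort(sprintf("`alpha_max` must be a multiple of step, got %g", alpha_max))
  }
  alphas <- seq(0, alpha_max, by = step)
  betas <- seq(0, 1, by = step)
  grid <- expand.grid(beta = betas, alpha = alphas)[, c("alpha", "beta")]
  grid$gamma <- 1 - grid$alpha - grid$beta
  grid <- grid[grid$gamma >= -1e-9, , drop = FALSE]
  grid$gamma[grid$gamma < 0] <- 0
  grid <- grid[order(grid$alpha, grid$beta), ]
  if (!nrow(grid)) abort("no valid weight combination on the grid")
  res <- purrr::pmap(grid, function(alpha, beta, gamma) {
    w <- fusion_weights(alpha, beta, gamma)
    ev <- tryCatch(correlate(fuse(cdfs, gofs, sqfs, w, renormalize), cms),
                   error = function(e) NULL)
    if (is.null(ev)) {
      tibble(r = NA_real_, p = NA_real_, n_pairs = NA_integer_)
    } else {
      tibble(r = ev$r, p = ev$p, n_pairs = ev$n_pairs)
    }
  })
  table <- dplyr::bind_cols(as_tibble(grid), dplyr::bind_rows(res))
  usable <- dplyr::filter(table, is.finite(.data$r))
  if (!nrow(usable)) abort("correlation undefined for every weight combination")
  best <- dplyr::arrange(usable, dplyr::desc(.data$r), .data$p,
                         .data$alpha, .data$beta)[1, ]
  structure(list(best = fusion_weights(best$alpha, best$beta, best$gamma),
                 best_eval = tibble(r = best$r, p = best$p,
                                    n_pairs = best$n_pairs),
                 table = table),
            class = "circ_grid")
}

#' @export
print.circ_grid <- function(x, ...) {
  cat(sprintf("<circ_grid> %d combinations; best (alpha, beta, gamma) = (%g, %g, %g), R = %.4g\n",
              nrow(x$table), x$best$alpha, x$best$beta, x$best$gamma,
              x$best_eval$r))
  invisible(x)
}

#' @export
tidy.circ_grid <- function(x, ...) x$table

#' @export
glance.circ_grid <- function(x, ...) {
  tibble(alpha = x$best$alpha, beta = x$best$beta, gamma = x$best$gamma,
         r = x$best_eval$r, p = x$best_eval$p,
         n_combinations = nrow(x$table))
}

#' @export
autoplot.circ_grid <- function(object, ...) {
  tbl <- object$table
  tbl$label <- sprintf("(%g, %g, %g)", tbl$alpha, tbl$beta, tbl$gamma)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$beta, y = .data$r,
                                    colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "beta (weight on GOFS)", y = "Pearson R vs CMS",
                  colour = "alpha") +
    ggplot2::theme_minimal()
}

#' Binned correlation of functional and expression similarity
#'
#' Pairwise expression similarity is the absolute Pearson correlation of two
#' circRNAs' expression profiles. Pairs are bucketed by fused functional
#' similarity into bins of width `step`; per-bin mean functional and mean
#' expression similarity are computed, and the reported r/p is the Pearson
#' correlation over those bin means. `unbinned = TRUE` skips the binning and
#' correlates the raw pairs instead.
#'
#' @param fs a fused functional similarity [simmat()].
#' @param expr numeric matrix of expression profiles (rows = circRNAs,
#'   columns = samples, >= 2 samples).
#' @param step bin width on the functional-similarity axis.
#' @param unbinned return the raw pairwise correlation instead.
#' @return a `circ_eval` whose `per_bin` tibble has columns `bin_lower`,
#'   `mean_fs`, `mean_expr`, `n`.
#' @export
binned_expression_correlation <- function(fs, expr, step = 0.1,
                                          unbinned = FALSE) {
  if (!is_simmat(fs)) abort("`fs` must be a simmat")
  if (!is.matrix(expr) || ncol(expr) < 2L) {
    abort("`expr` must be a matrix with >= 2 sample columns")
  }
  check_scalar_number(step, "step", 1e-9, 1)
  shared <- intersect(rownames(fs), rownames(expr))
  if (length(shared) < 3L) abort("fewer than 3 circRNAs shared between fs and expr")
  f <- unclass(fs)[shared, shared]
  e <- suppressWarnings(abs(cor(t(expr[shared, , drop = FALSE]))))
  ut <- upper.tri(f)
  fx <- f[ut]; ex <- e[ut]
  ok <- !is.na(fx) & !is.na(ex)
  fx <- fx[ok]; ex <- ex[ok]
  if (length(fx) < 3L) abort("fewer than 3 usable pairs")
  if (unbinned) {
    if (sd(fx) == 0 || sd(ex) == 0) abort("zero variance in pairwise values")
    ct <- cor.test(fx, ex)
    return(structure(list(r = unname(ct$estimate), p = ct$p.value,
                          n_pairs = length(fx), per_bin = NULL),
                     class = "circ_eval"))
  }
  bin <- floor(fx / step + 1e-12)
  per_bin <- tibble(bin = bin, fs = fx, expr = ex) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(bin_lower = .data$bin[1] * step,
                     mean_fs = mean(.data$fs),
                     mean_expr = mean(.data$expr),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin_lower) |>
    dplyr::select(!"bin")
  if (nrow(per_bin) < 2L) {
    abort(sprintf("need at least 2 occupied bins, got %d", nrow(per_bin)))
  }
  r <- cor(per_bin$mean_fs, per_bin$mean_expr)
  p <- if (nrow(per_bin) >= 3L) {
    cor.test(per_bin$mean_fs, per_bin$mean_expr)$p.value
  } else {
    NA_real_
  }
  structure(list(r = r, p = p, n_pairs = length(fx), per_bin = per_bin),
            class = "circ_eval")
}

#' @export
autoplot.circ_eval <- function(object, ...) {
  if (is.null(object$per_bin)) {
    abort("autoplot is defined for binned evaluations (per_bin present)")
  }
  ggplot2::ggplot(object$per_bin,
                  ggplot2::aes(x = .data$mean_fs, y = .data$mean_expr)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "mean functional similarity (bin)",
                  y = "mean expression similarity (bin)", size = "pairs") +
    ggplot2::theme_minimal()
}

#' Threshold the fused network into an edge list
#'
#' All unordered circRNA pairs whose fused similarity meets the cutoff
#' (inclusive), diagonal and missing entries excluded, sorted by descending
#' score.
#'
#' @param fs a [simmat()].
#' @param cutoff similarity threshold in \[0, 1\]; the field's convention for
#'   a sparse functional network is 0.7.
#' @return a tibble with columns `circ_a`, `circ_b`, `score`.
#' @export
threshold_network <- function(fs, cutoff = 0.7) {
  if (!is_simmat(fs)) abort("`fs` must be a simmat")
  check_scalar_number(cutoff, "cutoff", 0, 1)
  edges <- tidy(fs)
  edges <- edges[!is.na(edges$similarity) & edges$similarity >= cutoff, ]
  edges <- dplyr::arrange(edges, dplyr::desc(.data$similarity),
                          .data$item1, .data$item2)
  dplyr::rename(edges, circ_a = "item1", circ_b = "item2",
                score = "similarity")
}
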
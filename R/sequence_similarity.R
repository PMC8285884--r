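# Chaos-game representation of circRNA sequences, FCGR grid features, and
# the sequence-derived circRNA functional similarity network (SQFS).

CGR_VERTICES <- matrix(c(0, 0,   # A
                         1, 0,   # C
                         1, 1,   # G
                         0, 1),  # U
                       ncol = 2, byrow = TRUE,
                       dimnames = list(c("A", "C", "G", "U"), c("x", "y")))

#' Chaos-game trajectory of a nucleotide sequence
#'
#' Iterated midpoint map on the unit square: starting from P0 = (0.5, 0.5),
#' each nucleotide moves the point halfway towards its vertex — A = (0,0),
#' C = (1,0), G = (1,1), U = (0,1). `T` is treated as `U`; any other symbol
#' (N, IUPAC ambiguity codes) is skipped without moving the point, keeping
#' the trajectory deterministic. The start point itself is not part of the
#' trajectory: it carries no sequence information.
#'
#' @param sequence a single nucleotide sequence string (or a one-row tibble
#'   from [read_fasta()]).
#' @return a list of class `cgr_trajectory`: `points` (n x 2 matrix of
#'   coordinates strictly inside the unit square), `skipped` (count of
#'   ignored symbols).
#' @export
#' @examples
#' cgr_trajectory("ACGU")$points
cgr_trajectory <- function(sequence) {
  if (is.data.frame(sequence)) {
    if (nrow(sequence) != 1L) abort("pass one sequence at a time")
    sequence <- sequence$sequence
  }
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars[chars == "T"] <- "U"
  usable <- chars %in% rownames(CGR_VERTICES)
  skipped <- sum(!usable)
  chars <- chars[usable]
  if (!length(chars)) {
    abort("sequence has no usable nucleotides (A/C/G/T/U)")
  }
  verts <- CGR_VERTICES[chars, , drop = FALSE]
  pts <- matrix(0, length(chars), 2, dimnames = list(NULL, c("x", "y")))
  prev <- c(0.5, 0.5)
  for (i in seq_along(chars)) {
    prev <- 0.5 * (prev + verts[i, ])
    pts[i, ] <- prev
  }
  structure(list(points = pts, skipped = skipped), class = "cgr_trajectory")
}

#' FCGR grid features of a chaos-game trajectory
#'
#' The unit square is subdivided into a 2^s x 2^s grid. Each cell i collects
#' three attributes: `X[i]` and `Y[i]`, the sums of the x- and y-coordinates
#' of the points falling in the cell, and `Z[i]`, the population z-score of
#' the cell's point count across all cells (all zero when every cell holds
#' the same count). Cells use half-open intervals with the top/right boundary
#' clamped inward and are ordered row-major by (y-cell, x-cell). The feature
#' vector concatenates (X, Y, Z) per cell: length 3 * 4^s, i.e. 192 at the
#' default s = 3.
#'
#' @param traj a [cgr_trajectory()].
#' @param s subdivision exponent, >= 1; default 3.
#' @return a list of class `fcgr`: `s`, `n_grid`, `num`, `X`, `Y`, `Z`,
#'   `vector`.
#' @export
fcgr_features <- function(traj, s = 3) {
  if (!inherits(traj, "cgr_trajectory")) abort("`traj` must be a cgr_trajectory")
  s <- check_count(s, "s", min = 1L)
  pts <- traj$points
  if (!nrow(pts)) abort("empty trajectory")
  side <- 2L^s
  n_grid <- side * side
  xcell <- pmin(floor(pts[, 1] * side), side - 1L)
  ycell <- pmin(floor(pts[, 2] * side), side - 1L)
  cell <- as.integer(ycell * side + xcell + 1L)
  num <- tabulate(cell, nbins = n_grid)
  X <- rep(0, n_grid); Y <- rep(0, n_grid)
  sx <- rowsum(pts[, 1], cell)
  sy <- rowsum(pts[, 2], cell)
  X[as.integer(rownames(sx))] <- sx
  Y[as.integer(rownames(sy))] <- sy
  mu <- mean(num)
  sigma <- sqrt(mean((num - mu)^2))
  Z <- if (sigma > 0) (num - mu) / sigma else rep(0, n_grid)
  structure(list(s = s, n_grid = n_grid, num = num, X = X, Y = Y, Z = Z,
                 vector = as.vector(rbind(X, Y, Z))),
            class = "fcgr")
}

#' @export
print.fcgr <- function(x, ...) {
  cat(sprintf("<fcgr> s = %d (%d cells), %d points, feature length %d\n",
              x$s, x$n_grid, sum(x$num), length(x$vector)))
  invisible(x)
}

#' Sequence-derived circRNA functional similarity (SQFS)
#'
#' Each sequence is mapped to its FCGR feature vector and pairwise similarity
#' is computed between vectors. The default metric is the absolute Pearson
#' correlation coefficient; `metric = "cosine"` uses the dot-product over
#' norms form instead, clamped at 0. A feature vector with zero variance
#' (only possible for degenerate sequences) cannot be Pearson-correlated; its
#' off-diagonal entries become the missing sentinel with a warning.
#'
#' @param records tibble with columns `id`, `sequence` (see [read_fasta()]).
#' @param s subdivision exponent passed to [fcgr_features()].
#' @param metric `"pearson"` (default) or `"cosine"`.
#' @return a [simmat()] over the record ids.
#' @export
sqfs_matrix <- function(records, s = 3, metric = c("pearson", "cosine")) {
  metric <- match.arg(metric)
  if (!is.data.frame(records) || !all(c("id", "sequence") %in% names(records))) {
    abort("`records` must have columns `id` and `sequence`")
  }
  if (nrow(records) < 2L) abort("need at least 2 sequence records")
  if (anyDuplicated(records$id)) abort("duplicate sequence ids")
  feats <- vapply(records$sequence,
                  function(sq) fcgr_features(cgr_trajectory(sq), s = s)$vector,
                  numeric(3 * 4^s))
  colnames(feats) <- records$id
  n <- ncol(feats)
  if (metric == "pearson") {
    sds <- apply(feats, 2, sd)
    vals <- suppressWarnings(abs(cor(feats)))
    if (any(sds == 0)) {
      warn(sprintf("zero-variance feature vector(s): %s; entries set to NA",
                   paste(records$id[sds == 0], collapse = ", ")))
      vals[sds == 0, ] <- NA_real_
      vals[, sds == 0] <- NA_real_
    }
  } else {
    norms <- sqrt(colSums(feats^2))
    vals <- crossprod(feats) / outer(norms, norms)
    vals[vals < 0] <- 0
    vals[norms == 0, ] <- NA_real_
    vals[, norms == 0] <- NA_real_
  }
  diag(vals) <- 1
  vals[!is.na(vals) & vals > 1] <- 1
  simmat(vals, labels = records$id)
}
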
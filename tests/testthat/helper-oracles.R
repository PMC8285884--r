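# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementations.

# Enumerate every upward path from D; the contribution of ancestor d is the
# max over paths of delta^path_length. Exponential, fine for <= 12 nodes.
oracle_profile <- function(dag, D) {
  contrib <- c()
  walk <- function(node, depth) {
    val <- dag$delta^depth
    if (is.null(contrib[node]) || is.na(contrib[node]) || val > contrib[node]) {
      contrib[node] <<- val
    }
    for (p in dag$parents[[node]]) walk(p, depth + 1)
  }
  walk(D, 0)
  list(contributions = contrib, dv = sum(contrib))
}

oracle_pair_similarity <- function(dag, M, N) {
  pm <- oracle_profile(dag, M)
  pn <- oracle_profile(dag, N)
  shared <- intersect(names(pm$contributions), names(pn$contributions))
  if (!length(shared)) return(0)
  (sum(pm$contributions[shared]) + sum(pn$contributions[shared])) /
    (pm$dv + pn$dv)
}

# Random DAG: node i may take parents only among nodes created before it,
# guaranteeing acyclicity; roughly a third of possible edges kept.
random_dag <- function(n, delta, p_edge = 0.35) {
  ids <- sprintf("d%02d", seq_len(n))
  child <- character(); parent <- character()
  for (i in seq_len(n)[-1]) {
    take <- which(runif(i - 1) < p_edge)
    child <- c(child, rep(ids[i], length(take)))
    parent <- c(parent, ids[take])
  }
  disease_dag(data.frame(child = child, parent = parent), nodes = ids,
              delta = delta)
}

# Per-point brute-force FCGR binning using explicit interval comparisons.
oracle_fcgr <- function(points, s) {
  side <- 2^s
  edges <- seq(0, 1, length.out = side + 1)
  num <- rep(0L, side * side); X <- rep(0, side * side); Y <- rep(0, side * side)
  for (r in seq_len(nrow(points))) {
    x <- points[r, 1]; y <- points[r, 2]
    cx <- max(which(edges <= x)); if (cx > side) cx <- side
    cy <- max(which(edges <= y)); if (cy > side) cy <- side
    i <- (cy - 1) * side + cx
    num[i] <- num[i] + 1L; X[i] <- X[i] + x; Y[i] <- Y[i] + y
  }
  mu <- mean(num); sig <- sqrt(mean((num - mu)^2))
  Z <- if (sig > 0) (num - mu) / sig else rep(0, length(num))
  list(num = num, X = X, Y = Y, Z = Z, vector = as.vector(rbind(X, Y, Z)))
}

# Explicit sum-based Pearson correlation (no stats::cor).
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - sum(a) * sum(b) / n
  den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  num / den
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# tiny in-memory fixtures used across test files
toy_dag <- function(delta = 0.5) {
  # root R with children P (parent of M, N) and Q
  disease_dag(data.frame(child = c("P", "Q", "M", "N"),
                         parent = c("R", "R", "P", "P")), delta = delta)
}

toy_assoc <- function(kind, ...) {
  pairs <- list(...)
  df <- if (length(pairs)) {
    data.frame(left = rep(names(pairs), lengths(pairs)),
               right = unlist(pairs, use.names = FALSE))
  } else {
    data.frame(left = character(), right = character())
  }
  association_table(df, kind = kind)
}
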
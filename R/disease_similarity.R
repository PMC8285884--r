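# Disease semantic similarity over a MeSH-style DAG, aggregated into the
# disease-derived circRNA functional similarity network (CDFS).

#' Disease DAG
#'
#' Diseases as nodes, child-to-parent edges (is-a / broader-than), plus the
#' semantic contribution factor delta used by the Wang-style semantic
#' similarity measure: a disease contributes 1 to itself and each step up the
#' ancestor hierarchy multiplies the contribution by delta (best path over
#' multiple parents). Acyclicity is verified at construction.
#'
#' @param edges data frame whose first two columns are child id and parent id.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes.
#' @param delta semantic contribution factor, strictly between 0 and 1.
#' @return an object of class `disease_dag` with fields `nodes`, `parents`
#'   (named list child -> parent ids), `children` (the reverse map) and
#'   `delta`.
#' @export
#' @examples
#' dag <- disease_dag(data.frame(child = c("d1", "d2"), parent = c("d2", "d3")))
#' semantic_profile(dag, "d1")
disease_dag <- function(edges, nodes = NULL, delta = 0.5) {
  check_scalar_number(delta, "delta")
  if (delta <= 0 || delta >= 1) {
    abort(sprintf("`delta` must be strictly between 0 and 1, got %s", delta))
  }
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0 && ncol(edges) < 2L) {
    abort("`edges` needs two columns: child, parent")
  }
  child <- if (nrow(edges)) normalize_id(edges[[1]]) else character()
  parent <- if (nrow(edges)) normalize_id(edges[[2]]) else character()
  if (any(!nzchar(child)) || any(!nzchar(parent))) {
    abort("DAG node ids must be non-empty")
  }
  if (length(child)) {
    keep <- !duplicated(paste0(child, "\r", parent))
    child <- child[keep]; parent <- parent[keep]
  }
  if (any(child == parent)) {
    abort(sprintf("self-loop at node '%s'", child[child == parent][1]))
  }
  all_nodes <- sort(unique(c(child, parent, normalize_id(nodes %||% character()))))
  parents <- split(parent, factor(child, levels = all_nodes))
  children <- split(child, factor(parent, levels = all_nodes))
  cyc <- find_cycle(all_nodes, parents)
  if (!is.null(cyc)) {
    abort(sprintf("cycle detected in disease DAG: %s",
                  paste(cyc, collapse = " -> ")))
  }
  structure(list(nodes = all_nodes, parents = parents, children = children,
                 delta = delta),
            class = "disease_dag")
}

# depth-first search for a directed cycle along child->parent edges;
# returns one cycle as a node sequence, or NULL
find_cycle <- function(nodes, parents) {
  state <- setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  for (start in nodes) {
    if (state[[start]] != 0L) next
    stack <- list(list(node = start, next_i = 1L))
    path <- start
    state[[start]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ps <- parents[[top$node]]
      if (top$next_i > length(ps)) {
        state[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
        next
      }
      stack[[length(stack)]]$next_i <- top$next_i + 1L
      nxt <- ps[top$next_i]
      if (state[[nxt]] == 1L) {
        i <- match(nxt, path)
        return(c(path[i:length(path)], nxt))
      }
      if (state[[nxt]] == 0L) {
        state[[nxt]] <- 1L
        stack[[length(stack) + 1L]] <- list(node = nxt, next_i = 1L)
        path <- c(path, nxt)
      }
    }
  }
  NULL
}

#' @export
print.disease_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  roots <- sum(lengths(x$parents) == 0L)
  cat(sprintf("<disease_dag> %d nodes, %d edges, %d root(s), delta = %g\n",
              length(x$nodes), n_edges, roots, x$delta))
  invisible(x)
}

check_in_dag <- function(dag, ids, arg) {
  missing <- setdiff(ids, dag$nodes)
  if (length(missing)) {
    abort(sprintf("disease(s) not in DAG (%s): %s", arg,
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# ancestor closure of d, including d itself
ancestor_closure <- function(dag, d) {
  seen <- d
  frontier <- d
  while (length(frontier)) {
    up <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(up, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Semantic profile of a disease
#'
#' Computes, for disease `D`, the contribution of every ancestor `d` in D's
#' ancestor DAG: the contribution of `D` to itself is 1 and each other
#' ancestor receives `delta` times the best (maximum) contribution among its
#' children inside the closure. With a single decay factor this equals
#' `delta^k` where `k` is the shortest ancestor-path hop count from `D` up to
#' `d`. The semantic value `dv` is the sum of all contributions.
#'
#' @param dag a [disease_dag()].
#' @param D a disease id present in the DAG.
#' @return a list of class `semantic_profile`: `disease`, `contributions`
#'   (named numeric over the ancestor closure), `dv`.
#' @export
semantic_profile <- function(dag, D) {
  check_in_dag(dag, D, "D")
  closure <- ancestor_closure(dag, D)
  contrib <- setNames(rep(NA_real_, length(closure)), closure)
  contrib[[D]] <- 1
  # children map restricted to the closure
  kids <- lapply(dag$children[closure], intersect, closure)
  names(kids) <- closure
  compute <- function(d) {
    if (!is.na(contrib[[d]])) return(contrib[[d]])
    vals <- vapply(kids[[d]], compute, numeric(1))
    contrib[[d]] <<- dag$delta * max(vals)
    contrib[[d]]
  }
  for (d in closure) compute(d)
  structure(list(disease = D, contributions = contrib, dv = sum(contrib)),
            class = "semantic_profile")
}

#' @export
print.semantic_profile <- function(x, ...) {
  cat(sprintf("<semantic_profile> %s: %d ancestors, DV = %g\n",
              x$disease, length(x$contributions), x$dv))
  invisible(x)
}

#' Semantic similarity of two diseases
#'
#' The shared-ancestor score: the sum over diseases in both ancestor closures
#' of the two contributions, divided by the sum of the two semantic values.
#' Symmetric, 1 for identical diseases, 0 for diseases with disjoint
#' ancestries.
#'
#' @param dag a [disease_dag()].
#' @param M,N disease ids.
#' @return similarity in \[0, 1\].
#' @export
disease_pair_similarity <- function(dag, M, N) {
  pm <- semantic_profile(dag, M)
  pn <- semantic_profile(dag, N)
  pair_similarity_from_profiles(pm, pn)
}

pair_similarity_from_profiles <- function(pm, pn) {
  shared <- intersect(names(pm$contributions), names(pn$contributions))
  if (!length(shared)) return(0)
  num <- sum(pm$contributions[shared]) + sum(pn$contributions[shared])
  min(num / (pm$dv + pn$dv), 1)
}

#' Similarity of a disease to a disease group
#'
#' Best match of `d` against the group `DT`: the maximum pairwise semantic
#' similarity between `d` and any member of `DT`.
#'
#' @param dag a [disease_dag()].
#' @param d a disease id.
#' @param DT non-empty character vector of disease ids.
#' @return similarity in \[0, 1\].
#' @export
disease_set_similarity <- function(dag, d, DT) {
  if (!length(DT)) abort("`DT` must be a non-empty set of diseases")
  max(vapply(DT, function(u) disease_pair_similarity(dag, d, u), numeric(1)))
}

#' Disease-derived circRNA functional similarity (CDFS)
#'
#' Best-match-average aggregation of disease semantic similarity over the
#' disease sets of two circRNAs: every disease of circRNA i is matched to its
#' most similar disease of circRNA j and vice versa, and the matched scores
#' are averaged over both sets. circRNAs with no disease association get the
#' missing sentinel (`NA`) off-diagonal — absence of evidence is not
#' dissimilarity — and 1 on the diagonal by the identity convention.
#'
#' @param dag a [disease_dag()].
#' @param circ_disease an `assoc_tbl` of kind `"circ-disease"`.
#' @param circ_ids ordered character vector of circRNA labels for the matrix.
#' @return a [simmat()] over `circ_ids`.
#' @export
cdfs_matrix <- function(dag, circ_disease, circ_ids) {
  check_assoc_kind(circ_disease, "circ-disease", "circ_disease")
  if (!length(circ_ids)) abort("`circ_ids` must be non-empty")
  circ_ids <- as.character(circ_ids)
  dsets <- lapply(circ_ids, function(cid) assoc_lookup(circ_disease, cid))
  names(dsets) <- circ_ids
  used <- sort(unique(unlist(dsets, use.names = FALSE)))
  check_in_dag(dag, used, "circ_disease")
  # all pairwise disease similarities among the used diseases, from cached
  # profiles
  profiles <- lapply(used, semantic_profile, dag = dag)
  names(profiles) <- used
  dsim <- matrix(1, length(used), length(used), dimnames = list(used, used))
  if (length(used) > 1) {
    for (i in seq_len(length(used) - 1)) {
      for (j in (i + 1):length(used)) {
        s <- pair_similarity_from_profiles(profiles[[i]], profiles[[j]])
        dsim[i, j] <- s; dsim[j, i] <- s
      }
    }
  }
  vals <- best_match_average_matrix(dsets, dsim)
  simmat(vals, labels = circ_ids)
}

# shared Eq.-style aggregation: given per-entity element sets and an
# element-level similarity matrix, compute the symmetric best-match average;
# empty sets give NA off-diagonal, the diagonal is 1
best_match_average_matrix <- function(sets, elem_sim) {
  n <- length(sets)
  vals <- matrix(NA_real_, n, n)
  diag(vals) <- 1
  if (n < 2) return(vals)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      si <- sets[[i]]; sj <- sets[[j]]
      if (!length(si) || !length(sj)) next
      block <- elem_sim[si, sj, drop = FALSE]
      v <- (sum(apply(block, 1, max)) + sum(apply(block, 2, max))) /
        (length(si) + length(sj))
      vals[i, j] <- v; vals[j, i] <- v
    }
  }
  vals
}
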
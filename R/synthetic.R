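# Synthetic datasets with planted cluster structure. The generator emulates
# the *shapes* of the real data sources — a MeSH-style disease hierarchy,
# a GO-style term hierarchy with gene annotations, circBase-style sequences,
# starBase-style miRNA links, an expression profile matrix — with circRNAs
# partitioned into functional clusters whose members share nearby diseases,
# same-subtree gene annotations, a common sequence ancestor, overlapping
# miRNA sets and correlated expression profiles.

#' Synthetic dataset configuration
#'
#' Defaults describe a desk-scale dataset: 24 circRNAs in 3 functional
#' clusters over a 30-disease hierarchy, a 40-term ontology annotated by 30
#' genes, 300-500 nt sequences, a 40-miRNA pool and 10 expression samples.
#' `noise` is the corruption probability applied per planted signal (an
#' association rewires, a nucleotide substitutes, a miRNA drops) so `noise =
#' 0` gives perfectly clean cluster structure.
#'
#' @param n_circ number of circRNAs.
#' @param n_disease,dag_depth,dag_branching disease hierarchy shape.
#' @param n_gene,n_go,go_depth ontology shape.
#' @param seq_len_range length-2 integer range of sequence lengths.
#' @param n_mirna miRNA pool size.
#' @param n_clusters number of planted functional clusters.
#' @param noise corruption probability in \[0, 1\].
#' @param n_samples expression samples per circRNA.
#' @param seed integer seed; identical config + seed reproduce the dataset
#'   byte for byte.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_circ = 24, n_disease = 30, dag_depth = 4,
                             dag_branching = 2, n_gene = 30, n_go = 40,
                             go_depth = 4, seq_len_range = c(300L, 500L),
                             n_mirna = 40, n_clusters = 3, noise = 0.1,
                             n_samples = 10, seed = 1L) {
  cfg <- list(
    n_circ = check_count(n_circ, "n_circ"),
    n_disease = check_count(n_disease, "n_disease", min = 2L),
    dag_depth = check_count(dag_depth, "dag_depth"),
    dag_branching = check_count(dag_branching, "dag_branching"),
    n_gene = check_count(n_gene, "n_gene"),
    n_go = check_count(n_go, "n_go", min = 3L),
    go_depth = check_count(go_depth, "go_depth"),
    seq_len_range = c(check_count(seq_len_range[1], "seq_len_range[1]", min = 10L),
                      check_count(seq_len_range[2], "seq_len_range[2]", min = 10L)),
    n_mirna = check_count(n_mirna, "n_mirna"),
    n_clusters = check_count(n_clusters, "n_clusters"),
    noise = check_scalar_number(noise, "noise", 0, 1),
    n_samples = check_count(n_samples, "n_samples", min = 2L),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$seq_len_range[1] > cfg$seq_len_range[2]) {
    abort("seq_len_range must be increasing")
  }
  if (cfg$n_clusters > cfg$n_circ) {
    abort("n_clusters cannot exceed n_circ")
  }
  structure(cfg, class = "synthetic_config")
}

# breadth-first b-ary tree with a depth cap; returns tibble(child, parent)
# plus node depths. Node 1 is the root.
bfs_tree <- function(n, branching, max_depth) {
  depth <- integer(n); depth[1] <- 0L
  parent <- integer(n); parent[1] <- NA_integer_
  open <- 1L  # next parent candidate
  kids <- integer(n)
  for (v in seq_len(n)[-1]) {
    while (kids[open] >= branching || depth[open] >= max_depth) {
      open <- open + 1L
      if (open >= v) { # depth cap saturated: recycle parents at the cap - 1
        open <- which(depth[seq_len(v - 1L)] == max_depth - 1L)[1]
        break
      }
    }
    parent[v] <- open
    depth[v] <- depth[open] + 1L
    kids[open] <- kids[open] + 1L
  }
  list(parent = parent, depth = depth)
}

sample_n_of <- function(x, k) {
  if (length(x) == 1L) return(rep(x, min(k, 1L)))
  sample(x, min(k, length(x)))
}

#' Generate a synthetic multi-source dataset
#'
#' See [synthetic_config()] for the planted structure. All randomness comes
#' from the config seed; the returned bundle re-serializes identically under
#' [write_dataset()].
#'
#' @param config a [synthetic_config()].
#' @return a list of class `circ_bundle` with elements `dag`
#'   ([disease_dag()]), `circ_disease`, `circ_gene`, `gene_go`, `circ_mirna`
#'   (assoc tibbles), `ontology`, `sequences` (tibble `id`, `sequence`),
#'   `expression` (matrix), `clusters` (tibble `id`, `cluster`), `config`.
#' @export
make_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  cfg <- config
  withr::with_seed(cfg$seed, {
    circ_ids <- sprintf("circ_%03d", seq_len(cfg$n_circ))
    cluster <- rep(seq_len(cfg$n_clusters), length.out = cfg$n_circ)

    ## disease hierarchy
    dtree <- bfs_tree(cfg$n_disease, cfg$dag_branching, cfg$dag_depth)
    dis_ids <- sprintf("disease_%03d", seq_len(cfg$n_disease))
    dedges <- tibble(child = dis_ids[-1], parent = dis_ids[dtree$parent[-1]])
    dag <- disease_dag(dedges, nodes = dis_ids, delta = 0.5)
    # cluster home subtrees: children of the root, cycled
    level1 <- which(dtree$depth == 1L)
    if (!length(level1)) level1 <- 1L
    subtree_of <- function(root_idx) {
      members <- root_idx
      repeat {
        more <- which(dtree$parent %in% members & !seq_along(dtree$parent) %in% members)
        if (!length(more)) break
        members <- c(members, more)
      }
      members
    }
    home <- level1[((seq_len(cfg$n_clusters) - 1L) %% length(level1)) + 1L]
    dis_pool <- lapply(home, subtree_of)

    ## circRNA-disease associations: 2-4 nearby diseases per circRNA
    cd <- purrr::map2(circ_ids, cluster, function(cid, cl) {
      k <- sample(2:4, 1)
      picks <- dis_ids[sample_n_of(dis_pool[[cl]], k)]
      rewire <- runif(length(picks)) < cfg$noise
      picks[rewire] <- dis_ids[sample.int(cfg$n_disease, sum(rewire))]
      tibble(left = cid, right = unique(picks))
    }) |> dplyr::bind_rows()
    circ_disease <- association_table(cd, "circ-disease")

    ## GO-style ontology: one shared root, one subtree per cluster
    go_ids <- sprintf("GO:%07d", seq_len(cfg$n_go))
    go_cluster <- c(0L, rep(seq_len(cfg$n_clusters),
                            length.out = cfg$n_go - 1L))
    go_parent <- integer(cfg$n_go)
    go_depth_v <- integer(cfg$n_go)
    for (cl in seq_len(cfg$n_clusters)) {
      members <- which(go_cluster == cl)
      for (i in seq_along(members)) {
        v <- members[i]
        if (i == 1L) {
          go_parent[v] <- 1L; go_depth_v[v] <- 1L
        } else {
          cand <- members[seq_len(i - 1L)]
          cand <- cand[go_depth_v[cand] < cfg$go_depth]
          if (!length(cand)) cand <- members[1L]
          p <- cand[sample.int(length(cand), 1L)]
          go_parent[v] <- p
          go_depth_v[v] <- go_depth_v[p] + 1L
        }
      }
    }
    axioms <- tibble(subject = go_ids[-1], relation = "is_a",
                     object = go_ids[go_parent[-1]])
    ontology <- structure(
      list(terms = go_ids, names = setNames(go_ids, go_ids), axioms = axioms),
      class = "ontology")

    ## genes: cluster-partitioned, 3-5 annotations from the cluster subtree
    gene_ids <- sprintf("gene_%03d", seq_len(cfg$n_gene))
    gene_cluster <- rep(seq_len(cfg$n_clusters), length.out = cfg$n_gene)
    gg <- purrr::map2(gene_ids, gene_cluster, function(gid, cl) {
      pool <- which(go_cluster == cl)
      k <- sample(3:5, 1)
      picks <- pool[sample_n_of(seq_along(pool), k)]
      rewire <- runif(length(picks)) < cfg$noise
      picks[rewire] <- 1L + sample.int(cfg$n_go - 1L, sum(rewire))
      tibble(left = gid, right = unique(go_ids[picks]))
    }) |> dplyr::bind_rows()
    gene_go <- association_table(gg, "gene-go")

    ## circRNA-gene links: 2-3 genes from the cluster
    cg <- purrr::map2(circ_ids, cluster, function(cid, cl) {
      pool <- which(gene_cluster == cl)
      k <- sample(2:3, 1)
      picks <- pool[sample_n_of(seq_along(pool), k)]
      rewire <- runif(length(picks)) < cfg$noise
      picks[rewire] <- sample.int(cfg$n_gene, sum(rewire))
      tibble(left = cid, right = unique(gene_ids[picks]))
    }) |> dplyr::bind_rows()
    circ_gene <- association_table(cg, "circ-gene")

    ## sequences: cluster ancestor + point substitutions at rate 0.3 * noise
    nts <- c("A", "C", "G", "T")
    anc <- lapply(seq_len(cfg$n_clusters), function(cl) {
      len <- sample(seq(cfg$seq_len_range[1], cfg$seq_len_range[2]), 1)
      sample(nts, len, replace = TRUE)
    })
    sub_rate <- 0.3 * cfg$noise
    seqs <- purrr::map2_chr(circ_ids, cluster, function(cid, cl) {
      sq <- anc[[cl]]
      hit <- runif(length(sq)) < sub_rate
      if (any(hit)) sq[hit] <- sample(nts, sum(hit), replace = TRUE)
      paste(sq, collapse = "")
    })
    sequences <- tibble(id = circ_ids, sequence = seqs)

    ## miRNA sets: disjoint cluster pools; at noise = 0 every member sponges
    ## the full pool, so within-cluster Jaccard is exactly 1
    mir_ids <- sprintf("mir_%03d", seq_len(cfg$n_mirna))
    mir_cluster <- rep(seq_len(cfg$n_clusters), length.out = cfg$n_mirna)
    cm <- purrr::map2(circ_ids, cluster, function(cid, cl) {
      pool <- mir_ids[mir_cluster == cl]
      keep <- pool[runif(length(pool)) >= cfg$noise]
      n_extra <- sum(runif(length(pool) - length(keep)) < 0.5)
      extra <- if (n_extra > 0) {
        outside <- setdiff(mir_ids, pool)
        outside[sample_n_of(seq_along(outside), n_extra)]
      } else character()
      picks <- unique(c(keep, extra))
      if (!length(picks)) picks <- pool[sample.int(length(pool), 1L)]
      tibble(left = cid, right = picks)
    }) |> dplyr::bind_rows()
    circ_mirna <- association_table(cm, "circ-mirna")

    ## expression: cluster mean + gaussian noise
    mu <- lapply(seq_len(cfg$n_clusters), function(cl) rnorm(cfg$n_samples))
    expr <- t(vapply(seq_len(cfg$n_circ), function(i) {
      mu[[cluster[i]]] + rnorm(cfg$n_samples, sd = 0.1 + cfg$noise)
    }, numeric(cfg$n_samples)))
    dimnames(expr) <- list(circ_ids, sprintf("sample_%02d", seq_len(cfg$n_samples)))

    structure(list(
      dag = dag, circ_disease = circ_disease, circ_gene = circ_gene,
      gene_go = gene_go, ontology = ontology, sequences = sequences,
      circ_mirna = circ_mirna, expression = expr,
      clusters = tibble(id = circ_ids, cluster = cluster),
      config = cfg
    ), class = "circ_bundle")
  })
}

#' @export
print.circ_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "<circ_bundle> %d circRNAs in %d clusters (noise %g, seed %d)\n",
    "  %d diseases, %d genes, %d GO terms, %d miRNAs, %d expression samples\n"),
    x$config$n_circ, x$config$n_clusters, x$config$noise, x$config$seed,
    x$config$n_disease, x$config$n_gene, x$config$n_go, x$config$n_mirna,
    ncol(x$expression)))
  invisible(x)
}

#' Serialize a synthetic bundle to disk
#'
#' Writes every component in the format its reader expects: `dag.tsv`
#' (edge list), `circ_disease.tsv`, `circ_gene.tsv`, `gene_go.tsv`,
#' `circ_mirna.tsv`, `ontology.obo`, `sequences.fasta`, `expression.tsv`,
#' `clusters.tsv`.
#'
#' @param bundle a [make_dataset()] bundle.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  if (!inherits(bundle, "circ_bundle")) abort("`bundle` must come from make_dataset()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  edges <- purrr::imap(bundle$dag$parents, function(ps, ch) {
    if (length(ps)) tibble(child = ch, parent = ps) else NULL
  }) |> dplyr::bind_rows() |> dplyr::arrange(.data$child, .data$parent)
  readr::write_tsv(edges, fp("dag.tsv"), col_names = FALSE, progress = FALSE)
  for (nm in c("circ_disease", "circ_gene", "gene_go", "circ_mirna")) {
    readr::write_tsv(as_tibble(bundle[[nm]]), fp(paste0(nm, ".tsv")),
                     col_names = FALSE, progress = FALSE)
  }
  onto <- bundle$ontology
  kids <- split(onto$axioms, onto$axioms$subject)
  stanzas <- vapply(onto$terms, function(tm) {
    ax <- kids[[tm]]
    lines <- c("[Term]", paste0("id: ", tm), paste0("name: ", onto$names[[tm]]))
    if (!is.null(ax)) {
      lines <- c(lines, ifelse(ax$relation == "is_a",
                               paste0("is_a: ", ax$object),
                               paste0("relationship: ", ax$relation, " ", ax$object)))
    }
    paste(c(lines, ""), collapse = "\n")
  }, "")
  writeLines(c("format-version: 1.2", "", stanzas), fp("ontology.obo"))
  writeLines(paste0(">", bundle$sequences$id, "\n", bundle$sequences$sequence),
             fp("sequences.fasta"))
  expr <- as.data.frame(bundle$expression)
  readr::write_tsv(dplyr::bind_cols(tibble(id = rownames(bundle$expression)),
                                    expr),
                   fp("expression.tsv"), progress = FALSE)
  readr::write_tsv(bundle$clusters, fp("clusters.tsv"), progress = FALSE)
  invisible(dir)
}

#' Planted fusion harness
#'
#' Builds three random symmetric \[0, 1\] networks with unit diagonal and a
#' reference network constructed as their weighted combination plus Gaussian
#' off-diagonal noise, clipped back to \[0, 1\]. Running [grid_search()] on
#' the output recovers the planted weights when the noise is small relative
#' to the grid step.
#'
#' @param config a [synthetic_config()] (only `n_circ` and `seed` are used).
#' @param weights the planted [fusion_weights()].
#' @param sigma standard deviation of the Gaussian noise, >= 0.
#' @return a list with `cdfs`, `gofs`, `sqfs`, `cms` [simmat()] objects.
#' @export
make_planted_fusion <- function(config = synthetic_config(),
                                weights = fusion_weights(0.1, 0.3, 0.6),
                                sigma = 0.01) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  if (!inherits(weights, "fusion_weights")) {
    abort("`weights` must be a fusion_weights object")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    abort("`sigma` must be a single number >= 0")
  }
  n <- config$n_circ
  labs <- sprintf("circ_%03d", seq_len(n))
  withr::with_seed(config$seed, {
    rand_sym <- function() {
      m <- matrix(runif(n * n), n, n)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- 1
      simmat(m, labels = labs)
    }
    cdfs <- rand_sym(); gofs <- rand_sym(); sqfs <- rand_sym()
    combo <- weights$alpha * unclass(cdfs) + weights$beta * unclass(gofs) +
      weights$gamma * unclass(sqfs)
    noise <- matrix(0, n, n)
    noise[upper.tri(noise)] <- rnorm(sum(upper.tri(noise)), sd = sigma)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    cms <- pmin(pmax(combo + noise, 0), 1)
    diag(cms) <- 1
    list(cdfs = cdfs, gofs = gofs, sqfs = sqfs,
         cms = simmat(cms, labels = labs))
  })
}

#' Mean within- and between-cluster similarity
#'
#' Summarises how strongly a similarity network separates the planted
#' clusters of a synthetic bundle.
#'
#' @param mat a [simmat()].
#' @param clusters tibble with columns `id`, `cluster` (as in a bundle).
#' @return a tibble with columns `within`, `between`, `gap`.
#' @export
cluster_signal <- function(mat, clusters) {
  if (!is_simmat(mat)) abort("`mat` must be a simmat")
  cl <- setNames(clusters$cluster, clusters$id)[rownames(mat)]
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  v <- unclass(mat)[upper.tri(mat)]
  same <- cl[ut[, 1]] == cl[ut[, 2]]
  tibble(within = mean(v[same], na.rm = TRUE),
         between = mean(v[!same], na.rm = TRUE),
         gap = mean(v[same], na.rm = TRUE) - mean(v[!same], na.rm = TRUE))
}
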
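# Ontology-corpus skip-gram embeddings and the ontology-derived circRNA
# functional similarity network (GOFS).
#
# The corpus treats every ontology axiom and every annotation as one short
# sentence of entity tokens: "GO:a is_a GO:b", "gene has-function GO:a",
# "circRNA has-function gene". Entities that share axioms or annotations
# co-occur with the same context tokens and end up with nearby vectors.

#' Build the axiom + annotation corpus
#'
#' One sentence per ontology axiom (subject, relation keyword, object), one
#' per gene-to-GO annotation (gene, `has-function`, term), one per
#' circRNA-to-gene link (circRNA, `has-function`, gene). Sentence order is
#' deterministic: axioms in file order, then annotations sorted
#' lexicographically.
#'
#' @param ontology an [read_ontology()] object.
#' @param gene_go an `assoc_tbl` of kind `"gene-go"`.
#' @param circ_gene an `assoc_tbl` of kind `"circ-gene"`.
#' @return an object of class `circ_corpus`: a list of character-vector
#'   sentences.
#' @export
build_corpus <- function(ontology, gene_go, circ_gene) {
  if (!inherits(ontology, "ontology")) abort("`ontology` must come from read_ontology()")
  check_assoc_kind(gene_go, "gene-go", "gene_go")
  check_assoc_kind(circ_gene, "circ-gene", "circ_gene")
  ax <- ontology$axioms
  sentences <- c(
    purrr::pmap(list(ax$subject, ax$relation, ax$object), c),
    purrr::map2(gene_go$left, gene_go$right,
                function(g, t) c(g, "has-function", t)),
    purrr::map2(circ_gene$left, circ_gene$right,
                function(ci, g) c(ci, "has-function", g))
  )
  missing_terms <- setdiff(gene_go$right, ontology$terms)
  if (length(missing_terms)) {
    warn(sprintf("annotation term(s) absent from the ontology (sentences kept): %s",
                 paste(head(missing_terms, 5), collapse = ", ")))
  }
  structure(sentences, class = "circ_corpus")
}

#' @export
print.circ_corpus <- function(x, ...) {
  vocab <- unique(unlist(x, use.names = FALSE))
  cat(sprintf("<circ_corpus> %d sentences, %d distinct tokens\n",
              length(x), length(vocab)))
  invisible(x)
}

#' Skip-gram training configuration
#'
#' Defaults follow the word2vec parameterisation conventionally used for
#' ontology-axiom corpora: skip-gram (`sg = 1`) with negative sampling,
#' 200-dimensional vectors, context window 10 (every token of a triple
#' sentence sees every other), 5 iterations, 4 noise words, and `min_count =
#' 1` so rare biological entities are never dropped.
#'
#' @param sg 1 for skip-gram (the only implemented mode; 0 selects CBOW,
#'   which is accepted as a key but not implemented).
#' @param min_count tokens with frequency below this are ignored.
#' @param size embedding dimension.
#' @param window maximum distance between the current and predicted token.
#' @param iter number of passes over the corpus.
#' @param negative number of noise words drawn per positive example.
#' @param alpha initial learning rate.
#' @return a named list of class `embedding_config`.
#' @export
embedding_config <- function(sg = 1, min_count = 1, size = 200, window = 10,
                             iter = 5, negative = 4, alpha = 0.025) {
  cfg <- list(
    sg = check_count(sg, "sg", min = 0L),
    min_count = check_count(min_count, "min_count", min = 1L),
    size = check_count(size, "size", min = 2L),
    window = check_count(window, "window", min = 1L),
    iter = check_count(iter, "iter", min = 1L),
    negative = check_count(negative, "negative", min = 0L),
    alpha = check_scalar_number(alpha, "alpha", lower = 1e-6, upper = 1)
  )
  structure(cfg, class = "embedding_config")
}

#' Train entity embeddings on a corpus
#'
#' Runs single-threaded skip-gram with negative sampling over the sentences.
#' All randomness (vector initialisation, noise-word draws) comes from R's
#' RNG, so a fixed `seed` with a fixed corpus reproduces the vectors exactly.
#'
#' @param corpus a [build_corpus()] object (or plain list of token vectors).
#' @param config an [embedding_config()].
#' @param seed integer seed.
#' @return an object of class `embedding_table`: `dim`, `vectors` (matrix,
#'   one row per token), `config`, `seed`.
#' @export
train_embeddings <- function(corpus, config = embedding_config(), seed = 42L) {
  if (!length(corpus)) abort("corpus is empty")
  if (!inherits(config, "embedding_config")) {
    config <- do.call(embedding_config, as.list(config))
  }
  if (config$sg != 1L) {
    abort("only skip-gram training (sg = 1) is implemented")
  }
  seed <- check_count(seed, "seed", min = 0L)
  tokens <- unlist(corpus, use.names = FALSE)
  if (any(!nzchar(tokens))) abort("corpus contains empty tokens")
  counts <- table(tokens)
  vocab <- names(counts)[counts >= config$min_count]
  if (!length(vocab)) abort("no token reaches min_count")
  vocab <- sort(vocab)
  counts <- as.numeric(counts[vocab])
  idx <- setNames(seq_along(vocab), vocab)
  sent_idx <- lapply(corpus, function(s) {
    v <- unname(idx[s[s %in% vocab]]) - 1L
    as.integer(v)
  })
  sent_idx <- sent_idx[lengths(sent_idx) > 0L]
  withr::with_seed(seed, {
    vecs <- sgns_train_cpp(sent_idx, length(vocab), counts,
                           config$size, config$window, config$iter,
                           config$negative, config$alpha)
  })
  rownames(vecs) <- vocab
  structure(list(dim = config$size, vectors = vecs, config = config,
                 seed = seed),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens x %d dims (seed %d)\n",
              nrow(x$vectors), x$dim, x$seed))
  invisible(x)
}

#' Write / read an embedding table as TSV
#'
#' One row per token: the token followed by its vector components.
#'
#' @param emb an `embedding_table`.
#' @param path output path.
#' @export
write_embedding_table <- function(emb, path) {
  df <- as.data.frame(emb$vectors)
  names(df) <- paste0("d", seq_len(ncol(df)))
  readr::write_tsv(dplyr::bind_cols(tibble(token = rownames(emb$vectors)), df),
                   path, progress = FALSE)
  invisible(path)
}

#' Cosine similarity of two entity vectors
#'
#' Clamped to \[0, 1\]: anti-correlated vectors score 0, preserving the
#' similarity contract.
#'
#' @param emb an `embedding_table`.
#' @param g1,g2 entity (gene) ids.
#' @return similarity in \[0, 1\].
#' @export
gene_similarity <- function(emb, g1, g2) {
  for (g in c(g1, g2)) {
    if (!g %in% rownames(emb$vectors)) {
      abort(sprintf("no vector for entity '%s'", g))
    }
  }
  v1 <- emb$vectors[g1, ]; v2 <- emb$vectors[g2, ]
  d <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
  if (d == 0) return(0)
  max(min(sum(v1 * v2) / d, 1), 0)
}

#' Ontology-derived circRNA functional similarity (GOFS)
#'
#' Best-match-average aggregation of embedding cosine similarity over the
#' gene sets of two circRNAs, mirroring the disease-side aggregation. Genes
#' without trained vectors are dropped from the sets with a warning; a
#' circRNA whose effective gene set is empty gets the missing sentinel
#' off-diagonal.
#'
#' @param emb an `embedding_table`.
#' @param circ_gene an `assoc_tbl` of kind `"circ-gene"`.
#' @param circ_ids ordered character vector of circRNA labels.
#' @param agg `"max"` (best match, default) or `"mean"` over the target set.
#' @return a [simmat()] over `circ_ids`.
#' @export
gofs_matrix <- function(emb, circ_gene, circ_ids, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  check_assoc_kind(circ_gene, "circ-gene", "circ_gene")
  if (!length(circ_ids)) abort("`circ_ids` must be non-empty")
  circ_ids <- as.character(circ_ids)
  gsets <- lapply(circ_ids, function(cid) assoc_lookup(circ_gene, cid))
  names(gsets) <- circ_ids
  known <- rownames(emb$vectors)
  dropped <- setdiff(unique(unlist(gsets, use.names = FALSE)), known)
  if (length(dropped)) {
    warn(sprintf("gene(s) without trained vectors dropped: %s",
                 paste(head(dropped, 5), collapse = ", ")))
    gsets <- lapply(gsets, intersect, known)
  }
  genes <- sort(unique(unlist(gsets, use.names = FALSE)))
  if (length(genes)) {
    V <- emb$vectors[genes, , drop = FALSE]
    norms <- sqrt(rowSums(V^2))
    norms[norms == 0] <- 1
    gsim <- tcrossprod(V / norms)
    gsim[gsim < 0] <- 0
    gsim[gsim > 1] <- 1
    dimnames(gsim) <- list(genes, genes)
  } else {
    gsim <- matrix(0, 0, 0)
  }
  n <- length(circ_ids)
  vals <- matrix(NA_real_, n, n)
  diag(vals) <- 1
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        si <- gsets[[i]]; sj <- gsets[[j]]
        if (!length(si) || !length(sj)) next
        block <- gsim[si, sj, drop = FALSE]
        f <- if (agg == "max") max else mean
        v <- (sum(apply(block, 1, f)) + sum(apply(block, 2, f))) /
          (length(si) + length(sj))
        vals[i, j] <- v; vals[j, i] <- v
      }
    }
  }
  simmat(vals, labels = circ_ids)
}
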
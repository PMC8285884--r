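# End-to-end pipeline: the three network builds, weight tuning or fixed-
# weight fusion, the miRNA reference network, optional expression evaluation,
# and the thresholded network export — with pre-flight input validation and
# atomic output publication (stage outputs land in a temp dir and are moved
# into place only on success).

#' Pipeline run configuration
#'
#' @param fasta,circ_disease,circ_gene,gene_go,obo,dag,circ_mirna input file
#'   paths; `expression` is optional (`NULL` skips the expression
#'   evaluation).
#' @param dag_format `"edges"` or `"treenum"`, see [read_disease_dag()].
#' @param out_dir output directory.
#' @param delta semantic contribution factor for the disease DAG.
#' @param s FCGR subdivision exponent.
#' @param metric sequence similarity metric, `"pearson"` or `"cosine"`.
#' @param embedding an [embedding_config()].
#' @param weights a [fusion_weights()], or `NULL` to tune by grid search.
#' @param tune_step,tune_alpha_max grid-search controls when tuning.
#' @param cutoff network threshold.
#' @param expression optional expression TSV path.
#' @param seed integer seed for embedding training.
#' @return a list of class `run_config`.
#' @export
run_config <- function(fasta, circ_disease, circ_gene, gene_go, obo, dag,
                       circ_mirna, out_dir, dag_format = "edges",
                       delta = 0.5, s = 3, metric = "pearson",
                       embedding = embedding_config(), weights = NULL,
                       tune_step = 0.1, tune_alpha_max = 0.2, cutoff = 0.7,
                       expression = NULL, seed = 42L) {
  cfg <- list(fasta = fasta, circ_disease = circ_disease,
              circ_gene = circ_gene, gene_go = gene_go, obo = obo, dag = dag,
              circ_mirna = circ_mirna, out_dir = out_dir,
              dag_format = match.arg(dag_format, c("edges", "treenum")),
              delta = delta, s = s,
              metric = match.arg(metric, c("pearson", "cosine")),
              embedding = embedding, weights = weights,
              tune_step = tune_step, tune_alpha_max = tune_alpha_max,
              cutoff = cutoff, expression = expression,
              seed = check_count(seed, "seed", min = 0L))
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; the `embedding` key is a
#' mapping of [embedding_config()] keys, `weights` a mapping of
#' alpha/beta/gamma. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(y$embedding)) y$embedding <- do.call(embedding_config, y$embedding)
  if (!is.null(y$weights)) y$weights <- do.call(fusion_weights, y$weights)
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Pre-flight checks every configured input, then builds the disease-,
#' ontology- and sequence-derived networks over the circRNA ids found in the
#' FASTA, fuses them at fixed weights or tunes weights against the miRNA
#' Jaccard network, thresholds the fused network into an edge list, and (if
#' an expression table is configured) evaluates the binned expression
#' correlation. Outputs are written to `out_dir`: the five matrices, the
#' tuning table, the edge list, the embedding table, the resolved config and
#' a JSON report. A stage failure aborts with a stage-named error and leaves
#' no partial outputs behind.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @return the report, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  inputs <- c(fasta = config$fasta, circ_disease = config$circ_disease,
              circ_gene = config$circ_gene, gene_go = config$gene_go,
              obo = config$obo, dag = config$dag,
              circ_mirna = config$circ_mirna)
  if (!is.null(config$expression)) inputs["expression"] <- config$expression
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    abort(sprintf("missing input file(s): %s",
                  paste(sprintf("%s (%s)", missing, names(missing)),
                        collapse = ", ")),
          class = "circfuse_validation")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "circfuse_compute", parent = e)
    })
  }
  tmp <- tempfile("circfuse_run_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)

  records <- stage("read-fasta", read_fasta(config$fasta))
  circ_ids <- records$id
  dag <- stage("read-dag", read_disease_dag(config$dag, delta = config$delta,
                                            format = config$dag_format))
  cd <- stage("read-circ-disease",
              read_association_table(config$circ_disease, "circ-disease",
                                     quiet = TRUE))
  cg <- stage("read-circ-gene",
              read_association_table(config$circ_gene, "circ-gene", quiet = TRUE))
  gg <- stage("read-gene-go",
              read_association_table(config$gene_go, "gene-go", quiet = TRUE))
  cm <- stage("read-circ-mirna",
              read_association_table(config$circ_mirna, "circ-mirna",
                                     quiet = TRUE))
  onto <- stage("read-ontology", read_ontology(config$obo))

  cdfs <- stage("cdfs", cdfs_matrix(dag, cd, circ_ids))
  corpus <- stage("corpus", build_corpus(onto, gg, cg))
  emb <- stage("embedding",
               train_embeddings(corpus, config$embedding, seed = config$seed))
  gofs <- stage("gofs", gofs_matrix(emb, cg, circ_ids))
  sqfs <- stage("sqfs", sqfs_matrix(records, s = config$s,
                                    metric = config$metric))
  cms <- stage("cms", cms_matrix(cm, circ_ids))

  tuning <- NULL
  if (is.null(config$weights)) {
    gs <- stage("tune", grid_search(cdfs, gofs, sqfs, cms,
                                    step = config$tune_step,
                                    alpha_max = config$tune_alpha_max))
    weights <- gs$best
    tuning <- gs$table
    tune_eval <- gs$best_eval
  } else {
    weights <- config$weights
    tune_eval <- NULL
  }
  fs <- stage("fuse", fuse(cdfs, gofs, sqfs, weights))
  mirna_eval <- stage("correlate-cms",
                      tryCatch(correlate(fs, cms), error = function(e) NULL))
  edges <- stage("network", threshold_network(fs, cutoff = config$cutoff))

  expr_eval <- NULL
  if (!is.null(config$expression)) {
    expr <- stage("read-expression", read_expression(config$expression))
    expr_eval <- stage("eval-expression",
                       binned_expression_correlation(fs, expr))
  }

  # publish
  for (nm in c("cdfs", "gofs", "sqfs", "cms", "fs")) {
    write_similarity_matrix(get(nm), file.path(tmp, paste0(nm, ".tsv")))
  }
  write_embedding_table(emb, file.path(tmp, "embedding.tsv"))
  if (!is.null(tuning)) {
    readr::write_tsv(tuning, file.path(tmp, "tuning.tsv"), progress = FALSE)
  }
  readr::write_tsv(edges, file.path(tmp, "network.tsv"), progress = FALSE)
  report <- list(
    n_circ = length(circ_ids),
    n_pairs = length(circ_ids) * (length(circ_ids) - 1L) / 2L,
    weights = list(alpha = weights$alpha, beta = weights$beta,
                   gamma = weights$gamma),
    tuned = is.null(config$weights),
    mirna_r = if (!is.null(mirna_eval)) mirna_eval$r,
    mirna_p = if (!is.null(mirna_eval)) mirna_eval$p,
    mirna_n_pairs = if (!is.null(mirna_eval)) mirna_eval$n_pairs,
    expression_binned_r = if (!is.null(expr_eval)) expr_eval$r,
    expression_binned_p = if (!is.null(expr_eval)) expr_eval$p,
    n_edges = nrow(edges),
    cutoff = config$cutoff,
    seed = config$seed
  )
  jsonlite::write_json(report, file.path(tmp, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  resolved <- config
  resolved$embedding <- unclass(resolved$embedding)
  if (!is.null(resolved$weights)) resolved$weights <- unclass(resolved$weights)
  yaml::write_yaml(unclass(resolved), file.path(tmp, "config.yaml"))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(tmp)) {
    ok <- file.rename(file.path(tmp, f), file.path(config$out_dir, f))
    if (!ok) file.copy(file.path(tmp, f), file.path(config$out_dir, f),
                       overwrite = TRUE)
  }
  invisible(report)
}
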
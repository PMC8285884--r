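# Readers and writers for every external format the pipeline touches.
# One TSV dialect throughout: tab-separated, UTF-8, '#'-prefixed comment
# lines skipped, no quoting. Missing matrix entries serialize as "NA".

IUPAC_NT <- "ACGTUNRYSWKMBDHV"

#' Read circRNA sequences from a FASTA file
#'
#' Parses a circBase-style FASTA file into a tibble of sequence records.
#' Sequences are upper-cased on load; `T` is preserved here (the chaos-game
#' layer maps `T` to `U`). Characters outside the IUPAC nucleotide alphabet
#' are rejected with the offending position named.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id` (character, unique) and `sequence`
#'   (character, uppercase).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">circA", "ACGU", ">circB", "AAGG"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("FASTA file contains no sequences: %s", path))
  ids <- normalize_id(sub("\\s.*$", "", names(set)))
  if (any(!nzchar(ids))) abort("FASTA header with empty identifier")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    abort(sprintf("duplicate sequence id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence for id(s): %s",
                  paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  bad <- regexpr(sprintf("[^%s]", IUPAC_NT), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf(
      "sequence '%s' has character '%s' outside the IUPAC nucleotide set at position %d",
      ids[i], substr(seqs[i], bad[i], bad[i]), bad[i]))
  }
  tibble(id = ids, sequence = unname(seqs))
}

ASSOC_KINDS <- c("circ-disease", "circ-gene", "circ-mirna", "gene-go")

#' Build an association table
#'
#' An association table is a deduplicated bipartite mapping, e.g. circRNA to
#' disease. It is stored as a two-column tibble (`left`, `right`) carrying its
#' `kind` as an attribute so downstream stages can verify they were handed the
#' intended mapping.
#'
#' @param pairs a data frame whose first two columns are left and right ids.
#' @param kind one of `"circ-disease"`, `"circ-gene"`, `"circ-mirna"`,
#'   `"gene-go"`.
#' @return a tibble of class `assoc_tbl` with columns `left`, `right`.
#' @export
association_table <- function(pairs, kind) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% ASSOC_KINDS) {
    abort(sprintf("unknown association kind '%s'; expected one of: %s",
                  paste(kind, collapse = ","), paste(ASSOC_KINDS, collapse = ", ")))
  }
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) abort("`pairs` needs at least two columns (left, right)")
  out <- tibble(
    left = normalize_id(pairs[[1]]),
    right = normalize_id(pairs[[2]])
  )
  if (any(!nzchar(out$left)) || any(!nzchar(out$right))) {
    abort("association ids must be non-empty after normalization")
  }
  out <- dplyr::distinct(out)
  out <- dplyr::arrange(out, .data$left, .data$right)
  structure(out, kind = kind, class = c("assoc_tbl", class(out)))
}

#' @rdname association_table
#' @param x an object.
#' @export
assoc_kind <- function(x) attr(x, "kind")

check_assoc_kind <- function(x, kind, arg) {
  if (!inherits(x, "assoc_tbl")) {
    abort(sprintf("`%s` must be an association table (see association_table())", arg))
  }
  if (!identical(assoc_kind(x), kind)) {
    abort(sprintf("`%s` must have kind '%s', got '%s'", arg, kind, assoc_kind(x)))
  }
  invisible(x)
}

#' Look up the right-hand set of a left id
#'
#' Absent left ids return the empty set, never an error: absence of evidence
#' is handled by the missing-value policy downstream.
#'
#' @param table an `assoc_tbl`.
#' @param left_id single left id.
#' @return character vector of associated right ids (possibly empty).
#' @export
assoc_lookup <- function(table, left_id) {
  table$right[table$left == left_id]
}

#' Read an association table from TSV
#'
#' @param path path to a TSV file; first column left id, second right id;
#'   lines starting with `#` are skipped.
#' @param kind association kind, see [association_table()].
#' @param header logical; does the file carry a header row?
#' @param quiet suppress the entity/pair count message.
#' @return an `assoc_tbl` tibble.
#' @export
read_association_table <- function(path, kind, header = FALSE, quiet = FALSE) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% ASSOC_KINDS) {
    abort(sprintf("unknown association kind '%s'; expected one of: %s",
                  paste(kind, collapse = ","), paste(ASSOC_KINDS, collapse = ", ")))
  }
  if (!file.exists(path)) abort(sprintf("association file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines)) abort(sprintf("no association rows in %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) sum(nzchar(trimws(f[1:2]))) == 2L &&
                 length(f) >= 2L, logical(1))
  if (any(!ok)) {
    abort(sprintf("line %d of %s has fewer than 2 non-empty fields",
                  lineno[which(!ok)[1]], path))
  }
  out <- association_table(
    data.frame(left = vapply(fields, `[`, "", 1L),
               right = vapply(fields, `[`, "", 2L)),
    kind = kind
  )
  if (!quiet) {
    message(sprintf("[%s] %d pairs, %d left entities, %d right entities",
                    kind, nrow(out), dplyr::n_distinct(out$left),
                    dplyr::n_distinct(out$right)))
  }
  out
}

#' Read a disease DAG
#'
#' Two on-disk renderings are supported. `format = "edges"` expects a TSV edge
#' list, child id then parent id. `format = "treenum"` expects MeSH-style
#' rows of disease id and dot-separated tree number (e.g. `C04.557`); an edge
#' is created from each tree number to the disease owning its longest proper
#' dotted prefix present in the file, and tree numbers with no parent prefix
#' become roots. Both renderings of the same DAG yield identical node and edge
#' sets.
#'
#' @param path path to the TSV file.
#' @param delta semantic contribution factor, strictly in (0, 1).
#' @param format `"edges"` or `"treenum"`.
#' @return a [disease_dag()] object.
#' @export
read_disease_dag <- function(path, delta = 0.5, format = c("edges", "treenum")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("disease DAG file not found: %s", path))
  df <- readr::read_tsv(path, col_names = c("a", "b"), comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  df$a <- normalize_id(df$a); df$b <- normalize_id(df$b)
  if (format == "edges") {
    return(disease_dag(edges = df[c("a", "b")], delta = delta))
  }
  # tree-number mode: a = disease id, b = tree number
  tn2id <- setNames(df$a, df$b)
  parent_of <- function(tn) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
    while (length(parts) > 1) {
      parts <- parts[-length(parts)]
      cand <- paste(parts, collapse = ".")
      if (cand %in% names(tn2id)) return(tn2id[[cand]])
    }
    NA_character_
  }
  parents <- vapply(df$b, parent_of, "")
  edges <- tibble(a = df$a, b = parents)
  edges <- edges[!is.na(edges$b) & edges$a != edges$b, ]
  disease_dag(edges = dplyr::distinct(edges), nodes = unique(df$a), delta = delta)
}

#' Read an ontology from an OBO-subset file
#'
#' Parses `[Term]` stanzas: `id`, `name`, `is_a` and `relationship` lines.
#' Each `is_a` and each `relationship` line yields one axiom triple
#' (subject, relation, object). Obsolete terms are dropped together with
#' their axioms. An axiom referencing an undeclared term is kept with a
#' warning.
#'
#' @param path path to an OBO file.
#' @return an object of class `ontology`: list with `terms` (character),
#'   `names` (named character) and `axioms` (tibble `subject`, `relation`,
#'   `object`).
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) abort(sprintf("ontology file not found: %s", path))
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  starts <- which(lines == "[Term]")
  if (!length(starts)) abort(sprintf("no [Term] stanzas in %s", path))
  bounds <- c(starts, length(lines) + 1L)
  terms <- character()
  term_names <- character()
  subj <- character(); rel <- character(); obj <- character()
  obsolete <- character()
  strip_comment <- function(x) trimws(sub("\\s*!.*$", "", x))
  for (k in seq_along(starts)) {
    stanza <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    stanza <- stanza[nzchar(stanza) & !grepl("^\\[", stanza)]
    idl <- grep("^id:", stanza, value = TRUE)
    if (!length(idl)) abort(sprintf("[Term] stanza #%d has no id line", k))
    id <- strip_comment(sub("^id:\\s*", "", idl[1]))
    if (any(grepl("^is_obsolete:\\s*true", stanza))) {
      obsolete <- c(obsolete, id)
      next
    }
    terms <- c(terms, id)
    nm <- grep("^name:", stanza, value = TRUE)
    term_names[id] <- if (length(nm)) strip_comment(sub("^name:\\s*", "", nm[1])) else id
    for (l in grep("^is_a:", stanza, value = TRUE)) {
      subj <- c(subj, id); rel <- c(rel, "is_a")
      obj <- c(obj, strip_comment(sub("^is_a:\\s*", "", l)))
    }
    for (l in grep("^relationship:", stanza, value = TRUE)) {
      rest <- strsplit(strip_comment(sub("^relationship:\\s*", "", l)), "\\s+")[[1]]
      if (length(rest) < 2) abort(sprintf("malformed relationship line in term %s", id))
      subj <- c(subj, id); rel <- c(rel, rest[1]); obj <- c(obj, rest[2])
    }
  }
  if (anyDuplicated(terms)) {
    abort(sprintf("duplicate term id(s): %s",
                  paste(unique(terms[duplicated(terms)]), collapse = ", ")))
  }
  axioms <- tibble(subject = subj, relation = rel, object = obj)
  # axioms whose subject became obsolete are gone with the stanza; drop those
  # pointing *at* obsolete terms too
  axioms <- axioms[!(axioms$object %in% obsolete), ]
  undeclared <- setdiff(axioms$object, terms)
  if (length(undeclared)) {
    warn(sprintf("axiom object(s) not declared as terms (kept): %s",
                 paste(head(undeclared, 5), collapse = ", ")))
  }
  structure(list(terms = terms, names = term_names, axioms = axioms),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d axioms (%s)\n", length(x$terms),
              nrow(x$axioms),
              paste(sprintf("%s: %d", names(table(x$axioms$relation)),
                            table(x$axioms$relation)), collapse = ", ")))
  invisible(x)
}

#' Write / read a similarity matrix as TSV
#'
#' The on-disk form is a TSV with a header row of labels and a leading label
#' column; missing entries serialize as `NA`. Values are written at 12
#' significant digits so a write/read round trip reproduces the matrix within
#' 1e-9.
#'
#' @param matrix a [simmat()].
#' @param path output path.
#' @return `write_similarity_matrix` returns `path` invisibly;
#'   `read_similarity_matrix` returns a `simmat`.
#' @export
write_similarity_matrix <- function(matrix, path) {
  if (!is_simmat(matrix)) matrix <- simmat(matrix)  # validates symmetry etc.
  labs <- rownames(matrix)
  body <- apply(unclass(matrix), 1, function(r) {
    paste(ifelse(is.na(r), "NA", sprintf("%.12g", r)), collapse = "\t")
  })
  writeLines(c(paste(c("id", labs), collapse = "\t"),
               paste(labs, body, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("matrix file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  col_labs <- fields[[1]][-1]
  n <- length(col_labs)
  rows <- fields[-1]
  if (length(rows) != n) {
    abort(sprintf("matrix is not square: %d columns but %d rows", n, length(rows)))
  }
  widths <- lengths(rows)
  if (any(widths != n + 1L)) {
    abort(sprintf("ragged row at line %d: %d fields, expected %d",
                  which(widths != n + 1L)[1] + 1L, widths[widths != n + 1L][1], n + 1L))
  }
  row_labs <- vapply(rows, `[`, "", 1L)
  if (!identical(row_labs, col_labs)) {
    abort("row labels differ from column labels")
  }
  vals <- t(vapply(rows, function(r) suppressWarnings(as.numeric(r[-1])),
                   numeric(n)))
  simmat(vals, labels = col_labs)
}

#' Read an expression profile matrix
#'
#' TSV with circRNA ids in the first column and one column per sample.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, rows = circRNAs, columns = samples.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(),
                        progress = FALSE)
  if (ncol(df) < 3L) abort("expression table needs an id column and >= 2 samples")
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- normalize_id(df[[1]])
  m
}
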
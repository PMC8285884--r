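test_that("read_fasta parses, concatenates and validates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "AC", "GU", ">c2", "AAAA"), fa)
  recs <- read_fasta(fa)
  expect_equal(recs$id, c("c1", "c2"))
  expect_equal(recs$sequence, c("ACGU", "AAAA"))

  # T preserved at the I/O layer, lowercase upper-cased
  writeLines(c(">c1", "acgt"), fa)
  expect_equal(read_fasta(fa)$sequence, "ACGT")

  writeLines(c(">c1", "ACGT", ">c1", "AAAA"), fa)
  expect_error(read_fasta(fa), "c1")

  writeLines(c(">c1", "ACXT"), fa)
  expect_error(read_fasta(fa), "position 3")

  writeLines(character(), fa)
  expect_error(read_fasta(fa), "no sequences")
})

test_that("association tables dedupe, index and validate kind", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\td1", "c1\td1", "# a comment", "c2\td2"), tsv)
  at <- read_association_table(tsv, "circ-disease", quiet = TRUE)
  expect_equal(nrow(at), 2)
  expect_equal(assoc_lookup(at, "c1"), "d1")
  expect_equal(assoc_lookup(at, "c3"), character())
  expect_identical(assoc_kind(at), "circ-disease")

  writeLines(c("c1\tg1", "c1\tg2", "c2\tg1"), tsv)
  at <- read_association_table(tsv, "circ-gene", quiet = TRUE)
  expect_equal(nrow(at), 3)
  expect_equal(dplyr::n_distinct(at$left), 2)

  writeLines(c("c1\t", "c2\tg1"), tsv)
  expect_error(read_association_table(tsv, "circ-gene", quiet = TRUE), "line 1")
  expect_error(read_association_table(tsv, "circ-rna", quiet = TRUE),
               "unknown association kind")
})

test_that("association reading is idempotent under duplication and reorder", {
  tsv1 <- withr::local_tempfile(); tsv2 <- withr::local_tempfile()
  rows <- c("c1\td1", "c2\td2", "c1\td2")
  writeLines(rows, tsv1)
  writeLines(rev(c(rows, rows)), tsv2)
  a1 <- read_association_table(tsv1, "circ-disease", quiet = TRUE)
  a2 <- read_association_table(tsv2, "circ-disease", quiet = TRUE)
  expect_equal(as.data.frame(a1), as.data.frame(a2))
})

test_that("disease DAG reads both renderings identically", {
  e <- withr::local_tempfile(); tn <- withr::local_tempfile()
  writeLines(c("D\tP", "P\tR"), e)
  writeLines(c("R\tC04", "P\tC04.557", "D\tC04.557.337"), tn)
  d1 <- read_disease_dag(e, format = "edges")
  d2 <- read_disease_dag(tn, format = "treenum")
  expect_setequal(d1$nodes, d2$nodes)
  expect_equal(d1$parents[d1$nodes], d2$parents[d1$nodes])
  # tree number with no parent prefix becomes a root, not an error
  expect_length(d2$parents[["R"]], 0)
})

test_that("tree-number mode skips gaps to the longest present prefix", {
  tn <- withr::local_tempfile()
  writeLines(c("d2\tC04", "d1\tC04.557.337"), tn)  # C04.557 absent
  dag <- read_disease_dag(tn, format = "treenum")
  expect_equal(dag$parents[["d1"]], "d2")
})

test_that("cycles are rejected with a named cycle", {
  expect_error(disease_dag(data.frame(c("A", "B"), c("B", "A"))),
               "cycle.*A|cycle.*B")
  expect_error(disease_dag(data.frame("A", "A")), "self-loop")
})

test_that("OBO reader extracts axiom triples and drops obsolete terms", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "",
    "[Term]", "id: GO:2", "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "relationship: part_of GO:1", "",
    "[Term]", "id: GO:4", "is_a: GO:1", "is_obsolete: true", ""
  ), obo)
  onto <- read_ontology(obo)
  expect_setequal(onto$terms, c("GO:1", "GO:2", "GO:3"))
  expect_equal(nrow(onto$axioms), 2)
  expect_equal(onto$axioms$relation, c("is_a", "part_of"))
  expect_equal(onto$axioms$object, c("GO:1", "GO:1"))

  writeLines(c("[Term]", "name: orphan"), obo)
  expect_error(read_ontology(obo), "no id")

  writeLines(c("[Term]", "id: GO:9", "is_a: GO:8"), obo)
  expect_warning(read_ontology(obo), "GO:8")
})

test_that("similarity matrices round-trip within 1e-9", {
  m <- matrix(c(1, 0.6500000001, NA,
                0.6500000001, 1, 0.25,
                NA, 0.25, 1), 3, 3)
  sm <- simmat(m, labels = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(sm, path)
  back <- read_similarity_matrix(path)
  expect_equal(rownames(back), rownames(sm))
  expect_true(all(abs(unclass(back) - unclass(sm)) < 1e-9, na.rm = TRUE))
  expect_identical(is.na(back), is.na(unclass(sm)))

  # label mismatch between rows and columns is an error
  lines <- readLines(path)
  lines[2] <- sub("^a\t", "zzz\t", lines[2])
  writeLines(lines, path)
  expect_error(read_similarity_matrix(path), "labels differ")
})

test_that("asymmetric matrices are rejected on write", {
  m <- matrix(c(1, 0.2, 0.8, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(write_similarity_matrix(m, tempfile()), "symmetric")
})

test_that("identifier normalization trims and collapses whitespace", {
  expect_equal(normalize_id("  lung   neoplasms "), "lung neoplasms")
  expect_equal(normalize_id("Gastric Cancer"), "Gastric Cancer")  # case kept
})
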
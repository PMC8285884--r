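toy_ontology <- function() {
  structure(list(
    terms = c("GO:1", "GO:2", "GO:3"),
    names = setNames(c("GO:1", "GO:2", "GO:3"), c("GO:1", "GO:2", "GO:3")),
    axioms = tibble::tibble(subject = c("GO:2", "GO:3"),
                            relation = c("is_a", "part_of"),
                            object = c("GO:1", "GO:1"))),
    class = "ontology")
}

test_that("corpus renders axioms and annotations as triple sentences", {
  onto <- toy_ontology()
  gg <- toy_assoc("gene-go", g1 = "GO:2", g2 = "GO:3")
  cg <- toy_assoc("circ-gene", c1 = "g1")
  corp <- build_corpus(onto, gg, cg)
  expect_length(corp, 5)  # 2 axioms + 2 annotations + 1 circ link
  expect_equal(corp[[1]], c("GO:2", "is_a", "GO:1"))
  expect_equal(corp[[2]], c("GO:3", "part_of", "GO:1"))
  expect_equal(corp[[3]], c("g1", "has-function", "GO:2"))
  expect_equal(corp[[4]], c("g2", "has-function", "GO:3"))
  expect_equal(corp[[5]], c("c1", "has-function", "g1"))
  expect_true(all(lengths(corp) >= 3))

  # dropping the circ links drops exactly their sentences
  corp2 <- build_corpus(onto, gg, toy_assoc("circ-gene"))
  expect_length(corp2, 4)

  gg_bad <- toy_assoc("gene-go", g1 = "GO:999")
  expect_warning(build_corpus(onto, gg_bad, cg), "GO:999")
})

test_that("training covers the vocabulary at the configured dimension", {
  onto <- toy_ontology()
  gg <- toy_assoc("gene-go", g1 = "GO:2", g2 = "GO:3")
  cg <- toy_assoc("circ-gene", c1 = "g1", c2 = "g2")
  corp <- build_corpus(onto, gg, cg)
  emb <- train_embeddings(corp, embedding_config(size = 16, iter = 2), seed = 3)
  expect_equal(emb$dim, 16)
  expect_equal(ncol(emb$vectors), 16)
  # min_count = 1: every token has a vector, including singletons like circ ids
  vocab <- unique(unlist(corp))
  expect_setequal(rownames(emb$vectors), vocab)
  # circRNA token vectors are trained and exposed for inspection
  expect_true(all(c("c1", "c2") %in% rownames(emb$vectors)))
})

test_that("default configuration produces 200-dimensional vectors", {
  corp <- build_corpus(toy_ontology(), toy_assoc("gene-go", g1 = "GO:2"),
                       toy_assoc("circ-gene", c1 = "g1"))
  emb <- train_embeddings(corp, seed = 1)
  expect_equal(unname(lengths(apply(emb$vectors, 1, identity, simplify = FALSE))),
               rep(200, nrow(emb$vectors)))
  cfg <- emb$config
  expect_equal(cfg[c("sg", "min_count", "size", "window", "iter", "negative")],
               list(sg = 1L, min_count = 1L, size = 200L, window = 10L,
                    iter = 5L, negative = 4L))
})

test_that("training is deterministic under a fixed seed", {
  corp <- build_corpus(toy_ontology(), toy_assoc("gene-go", g1 = "GO:2"),
                       toy_assoc("circ-gene", c1 = "g1"))
  e1 <- train_embeddings(corp, embedding_config(size = 32), seed = 9)
  e2 <- train_embeddings(corp, embedding_config(size = 32), seed = 9)
  expect_identical(e1$vectors, e2$vectors)
  e3 <- train_embeddings(corp, embedding_config(size = 32), seed = 10)
  expect_false(identical(e1$vectors, e3$vectors))
})

test_that("training rejects degenerate inputs", {
  expect_error(train_embeddings(list(), seed = 1), "empty")
  expect_error(embedding_config(size = 1), "size")
  corp <- list(c("a", "rel", "b"))
  expect_error(train_embeddings(corp, embedding_config(sg = 0), seed = 1),
               "skip-gram")
})

test_that("gene similarity is clamped cosine with named missing errors", {
  emb <- structure(list(
    dim = 2,
    vectors = rbind(g1 = c(1, 0), g2 = c(0, 1), g3 = c(-1, 0), g4 = c(2, 0)),
    config = embedding_config(size = 2), seed = 1), class = "embedding_table")
  expect_equal(gene_similarity(emb, "g1", "g1"), 1)
  expect_equal(gene_similarity(emb, "g1", "g4"), 1)   # parallel
  expect_equal(gene_similarity(emb, "g1", "g2"), 0)   # orthogonal
  expect_equal(gene_similarity(emb, "g1", "g3"), 0)   # anti-parallel, clamped
  expect_error(gene_similarity(emb, "g1", "gX"), "gX")
})

test_that("GOFS reduces to gene cosine for singleton sets", {
  emb <- structure(list(
    dim = 2,
    vectors = rbind(g1 = c(1, 0), g2 = c(1, 1), g3 = c(0, 1)),
    config = embedding_config(size = 2), seed = 1), class = "embedding_table")
  cg <- toy_assoc("circ-gene", c1 = "g1", c2 = "g2", c3 = "g1")
  m <- gofs_matrix(emb, cg, c("c1", "c2", "c3", "c4"))
  expect_equal(m["c1", "c2"], cos(pi / 4), tolerance = 1e-12)
  expect_equal(m["c1", "c3"], 1)            # same gene set
  expect_true(is.na(m["c1", "c4"]))         # no genes: sentinel
  expect_equal(m["c4", "c4"], 1)
  # symmetry and range
  expect_lt(max(abs(unclass(m) - t(unclass(m))), na.rm = TRUE), 1e-12)
  expect_true(all(unclass(m) >= 0 & unclass(m) <= 1, na.rm = TRUE))
})

test_that("GOFS drops unknown genes with a warning and is order-stable", {
  emb <- structure(list(
    dim = 2, vectors = rbind(g1 = c(1, 0), g2 = c(0.9, 0.1)),
    config = embedding_config(size = 2), seed = 1), class = "embedding_table")
  cg1 <- toy_assoc("circ-gene", c1 = c("g1", "g2", "ghost"), c2 = "g2")
  cg2 <- toy_assoc("circ-gene", c1 = c("g2", "g1", "ghost"), c2 = "g2")
  expect_warning(gofs_matrix(emb, cg1, c("c1", "c2")), "ghost")
  m1 <- suppressWarnings(gofs_matrix(emb, cg1, c("c1", "c2")))
  m2 <- suppressWarnings(gofs_matrix(emb, cg2, c("c1", "c2")))
  expect_equal(unclass(m1), unclass(m2))
})

test_that("genes sharing annotations embed closer than genes sharing none", {
  # two disjoint GO sub-hierarchies; g1, g2 annotated identically, g3 apart
  onto <- structure(list(
    terms = sprintf("GO:%d", 1:7),
    names = setNames(sprintf("GO:%d", 1:7), sprintf("GO:%d", 1:7)),
    axioms = tibble::tibble(
      subject = c("GO:2", "GO:3", "GO:4", "GO:5", "GO:6", "GO:7"),
      relation = "is_a",
      object = c("GO:1", "GO:2", "GO:2", "GO:1", "GO:5", "GO:5"))),
    class = "ontology")
  gg <- toy_assoc("gene-go", g1 = c("GO:3", "GO:4"), g2 = c("GO:3", "GO:4"),
                  g3 = c("GO:6", "GO:7"))
  cg <- toy_assoc("circ-gene", c1 = "g1", c2 = "g2", c3 = "g3")
  corp <- build_corpus(onto, gg, cg)
  same <- numeric(5); other <- numeric(5)
  for (sd in 1:5) {
    emb <- train_embeddings(corp, seed = sd)
    m <- gofs_matrix(emb, cg, c("c1", "c2", "c3"))
    same[sd] <- m["c1", "c2"]; other[sd] <- m["c1", "c3"]
  }
  expect_gt(median(same), median(other))
})
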
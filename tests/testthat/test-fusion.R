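mk <- function(vals, labs = c("a", "b")) simmat(vals, labels = labs)

pairmat <- function(x, labs = c("a", "b")) {
  m <- matrix(c(1, x, x, 1), 2, 2)
  mk(m, labs)
}

test_that("fusion weights validate the simplex constraint", {
  w <- fusion_weights(0.1, 0.3, 0.6)
  expect_equal(w$alpha + w$beta + w$gamma, 1)
  expect_error(fusion_weights(0.5, 0.5, 0.5), "sum to 1")
  expect_error(fusion_weights(-0.1, 0.5, 0.6), "alpha")
})

test_that("fuse computes the convex combination entry-wise", {
  w <- fusion_weights(0.1, 0.3, 0.6)
  expect_equal(fuse(pairmat(1), pairmat(1), pairmat(1), w)["a", "b"], 1)
  expect_equal(fuse(pairmat(0.5), pairmat(0.2), pairmat(0.9), w)["a", "b"],
               0.65)
})

test_that("missing modalities renormalize the remaining weights", {
  w <- fusion_weights(0.1, 0.3, 0.6)
  f <- fuse(pairmat(NA), pairmat(0.4), pairmat(0.8), w)
  expect_equal(f["a", "b"], (0.3 * 0.4 + 0.6 * 0.8) / 0.9)
  # all missing: entry stays missing, diagonal stays 1
  f2 <- fuse(pairmat(NA), pairmat(NA), pairmat(NA), w)
  expect_true(is.na(f2["a", "b"]))
  expect_equal(f2["a", "a"], 1)
  # strict mode propagates the sentinel
  f3 <- fuse(pairmat(NA), pairmat(0.4), pairmat(0.8), w, renormalize = FALSE)
  expect_true(is.na(f3["a", "b"]))
})

test_that("fuse rejects mismatched labels, naming the first discrepancy", {
  w <- fusion_weights(0.1, 0.3, 0.6)
  expect_error(fuse(pairmat(0.5), pairmat(0.5, labs = c("a", "zzz")),
                    pairmat(0.5), w), "zzz")
})

test_that("fuse is affine in each input", {
  set.seed(61)
  labs <- sprintf("c%d", 1:5)
  rnd <- function() {
    m <- matrix(runif(25), 5); m <- (m + t(m)) / 2; diag(m) <- 1
    mk(m, labs)
  }
  a <- rnd(); b <- rnd(); cc <- rnd(); d <- rnd()
  w <- fusion_weights(0.2, 0.3, 0.5)
  lam <- 0.4
  mix <- mk(lam * unclass(a) + (1 - lam) * unclass(d), labs)
  f_mix <- fuse(mix, b, cc, w)
  f_a <- fuse(a, b, cc, w); f_d <- fuse(d, b, cc, w)
  off <- upper.tri(f_mix)
  expect_equal(unclass(f_mix)[off],
               (lam * unclass(f_a) + (1 - lam) * unclass(f_d))[off])
})

test_that("CMS is the Jaccard index of miRNA sets", {
  at <- toy_assoc("circ-mirna",
                  c1 = "m1", c2 = "m1", c3 = c("m1", "m2"),
                  c4 = c("m2", "m3"), c5 = "m4")
  m <- cms_matrix(at, c("c1", "c2", "c3", "c4", "c5", "c6", "c7"))
  expect_equal(m["c1", "c2"], 1)
  expect_equal(m["c3", "c4"], 1 / 3)
  expect_equal(m["c1", "c5"], 0)
  expect_true(is.na(m["c6", "c7"]))   # both sets empty
  expect_equal(m["c1", "c6"], 0)      # one empty, union non-empty
  expect_equal(m["c6", "c6"], 1)
})

test_that("CMS matches a brute-force set recomputation on random instances", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    ids <- sprintf("c%d", 1:n)
    sets <- lapply(ids, function(i) {
      sample(sprintf("m%d", 1:8), sample(0:5, 1))
    })
    names(sets) <- ids
    df <- data.frame(left = rep(ids, lengths(sets)),
                     right = unlist(sets, use.names = FALSE))
    at <- association_table(df, "circ-mirna")
    m <- cms_matrix(at, ids)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      u <- union(sets[[i]], sets[[j]])
      want <- if (!length(u)) NA_real_ else
        length(intersect(sets[[i]], sets[[j]])) / length(u)
      expect_equal(m[ids[i], ids[j]], want)
    }
  }
})

test_that("correlate respects affine relations and degenerate input", {
  set.seed(81)
  labs <- sprintf("c%d", 1:6)
  m <- matrix(runif(36, 0.1, 0.8), 6); m <- (m + t(m)) / 2; diag(m) <- 1
  a <- mk(m, labs)
  b <- mk({v <- 0.5 * unclass(a) + 0.1; diag(v) <- 1; v}, labs)
  ev <- correlate(a, b)
  expect_equal(ev$r, 1)
  expect_equal(ev$n_pairs, 15)
  b2 <- mk({v <- 1 - unclass(a); diag(v) <- 1; v}, labs)
  expect_equal(correlate(a, b2)$r, -1)
  const <- mk({v <- matrix(0.5, 6, 6); diag(v) <- 1; v}, labs)
  expect_error(correlate(const, a), "zero variance")
})

test_that("grid enumeration covers the constrained simplex", {
  set.seed(91)
  labs <- sprintf("c%d", 1:8)
  rnd <- function() {
    m <- matrix(runif(64), 8); m <- (m + t(m)) / 2; diag(m) <- 1
    mk(m, labs)
  }
  a <- rnd(); b <- rnd(); cc <- rnd(); ref <- rnd()
  gs <- grid_search(a, b, cc, ref, step = 0.1, alpha_max = 0.2)
  expect_equal(nrow(gs$table), 30)
  expect_true(all(abs(gs$table$alpha + gs$table$beta + gs$table$gamma - 1) < 1e-9))
  expect_true(all(gs$table$alpha <= 0.2 + 1e-9))
  # coarse grid: direct enumeration
  gs2 <- grid_search(a, b, cc, ref, step = 1, alpha_max = 0)
  expect_equal(nrow(gs2$table), 2)
  expect_equal(gs2$table[c("alpha", "beta", "gamma")],
               tibble::tibble(alpha = c(0, 0), beta = c(0, 1),
                              gamma = c(1, 0)))
  # full range includes the three pure-modality corners
  gs3 <- grid_search(a, b, cc, ref, step = 0.5, alpha_max = 1)
  corners <- dplyr::semi_join(
    tibble::tibble(alpha = c(1, 0, 0), beta = c(0, 1, 0), gamma = c(0, 0, 1)),
    gs3$table, by = c("alpha", "beta", "gamma"))
  expect_equal(nrow(corners), 3)
  expect_error(grid_search(a, b, cc, ref, step = 0.3), "divide 1")
  expect_error(grid_search(a, b, cc, ref, step = 0.2, alpha_max = 0.3),
               "multiple of step")
})

test_that("grid search recovers planted weights", {
  pf <- make_planted_fusion(synthetic_config(seed = 123),
                            fusion_weights(0.1, 0.3, 0.6), sigma = 0.01)
  gs <- grid_search(pf$cdfs, pf$gofs, pf$sqfs, pf$cms)
  expect_equal(c(gs$best$alpha, gs$best$beta, gs$best$gamma), c(0.1, 0.3, 0.6))
  expect_s3_class(tidy(gs), "tbl_df")
  expect_equal(glance(gs)$n_combinations, 30)
})

test_that("binned correlation is exact on a noiseless monotone coupling", {
  set.seed(101)
  n <- 15
  labs <- sprintf("c%d", 1:n)
  expr <- matrix(rnorm(n * 10), n, 10, dimnames = list(labs, NULL))
  # functional similarity defined as the expression similarity itself: the
  # coupling is the identity, the cleanest noiseless monotone function
  fs <- mk(abs(cor(t(expr))), labs)
  ev <- binned_expression_correlation(fs, expr, step = 0.1)
  expect_equal(ev$r, 1)
  expect_equal(ev$n_pairs, n * (n - 1) / 2)
  expect_true(all(ev$per_bin$mean_fs == ev$per_bin$mean_expr))
  expect_gte(nrow(ev$per_bin), 2)
  # unbinned mode on the same coupling is also exact
  expect_equal(binned_expression_correlation(fs, expr, unbinned = TRUE)$r, 1)
  # a single occupied bin cannot be correlated
  const <- mk({m <- matrix(0.55, n, n); diag(m) <- 1; m}, labs)
  expect_error(binned_expression_correlation(const, expr, step = 1),
               "bins")
})

test_that("threshold network counts, sorts and respects the cutoff", {
  labs <- c("x", "y", "z")
  m <- matrix(c(1, 0.82, 0.3, 0.82, 1, NA, 0.3, NA, 1), 3, 3)
  fs <- mk(m, labs)
  edges <- threshold_network(fs, cutoff = 0.7)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$circ_a, "x")
  expect_equal(edges$circ_b, "y")
  expect_equal(edges$score, 0.82)
  # cutoff 0: all non-sentinel off-diagonal pairs
  expect_equal(nrow(threshold_network(fs, cutoff = 0)), 2)
  # boundary inclusive at 1
  expect_equal(nrow(threshold_network(fs, cutoff = 1)), 0)
  m2 <- m; m2[1, 2] <- m2[2, 1] <- 1
  expect_equal(nrow(threshold_network(mk(m2, labs), cutoff = 1)), 1)
  # sorted by descending score
  m3 <- matrix(c(1, 0.8, 0.9, 0.8, 1, 0.75, 0.9, 0.75, 1), 3, 3)
  e3 <- threshold_network(mk(m3, labs), cutoff = 0.7)
  expect_equal(e3$score, c(0.9, 0.8, 0.75))
})
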
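test_that("alpha diversity indices match their closed forms", {
  expect_equal(alpha_diversity(c(5, 5, 5, 5), "shannon"), log(4), tolerance = 1e-9)
  expect_equal(alpha_diversity(c(1, 1, 2), "chao1"), 3.5, tolerance = 1e-9)
  expect_equal(alpha_diversity(c(5, 5, 5, 5), "pielou"), 1, tolerance = 1e-9)

  # Shannon depends only on proportions
  x <- c(3L, 9L, 1L, 7L)
  expect_equal(alpha_diversity(x, "shannon"), alpha_diversity(10L * x, "shannon"))

  expect_error(alpha_diversity(c(0, 0), "shannon"), "all-zero")
  expect_error(alpha_diversity(c(7, 0, 0), "pielou"), "single observed taxon")
})

test_that("Faith's PD equals total tree length when all tips are present", {
  tree <- simulate_tree(paste0("A", 1:6), seed = 4)
  counts <- stats::setNames(rep(2L, 6), tree$tip.label)
  expect_equal(alpha_diversity(counts, "faith_pd", tree = tree),
               sum(tree$edge.length), tolerance = 1e-9)
  bad <- stats::setNames(rep(1L, 2), c("A1", "ZZ"))
  expect_error(alpha_diversity(bad, "faith_pd", tree = tree), "absent")
})

test_that("Bray-Curtis matches the direct formula and its bounds", {
  m <- tbl(2, 2, 0,
           0, 2, 2,
           2, 2, 0, nrow = 3)
  d <- as.matrix(bray_curtis_matrix(m))
  expect_equal(d["S1", "S2"], 0.5, tolerance = 1e-9)
  expect_equal(d["S1", "S3"], 0, tolerance = 1e-12)

  disjoint <- tbl(4, 0, 0, 3, nrow = 2)
  expect_equal(as.vector(bray_curtis_matrix(disjoint)), 1, tolerance = 1e-12)

  set.seed(11)
  r <- matrix(rpois(40, 5), 4, 10,
              dimnames = list(paste0("S", 1:4), paste0("A", 1:10)))
  r[1, ] <- r[1, ] + 1L  # no all-zero row
  storage.mode(r) <- "integer"
  dr <- as.matrix(bray_curtis_matrix(r))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(dr[i, j], bray_direct(r[i, ], r[j, ]), tolerance = 1e-12)
  expect_true(all(dr >= 0 & dr <= 1))
  expect_equal(dr, t(dr))
})

test_that("PCoA round-trips Euclidean configurations and orders axes", {
  set.seed(2)
  pts <- matrix(rnorm(8), 4, 2)
  d <- stats::dist(pts)
  fit <- pcoa(d, n_axes = 3)
  expect_true(all(diff(fit$eigenvalues) <= 1e-8))
  rec <- stats::dist(fit$coordinates[, 1:2])
  expect_equal(as.vector(rec), as.vector(d), tolerance = 1e-8)

  # equidistant points: equal positive eigenvalues, equal proportions
  deq <- stats::as.dist(matrix(1, 4, 4) - diag(4))
  feq <- suppressWarnings(pcoa(deq, n_axes = 3))
  pos <- feq$eigenvalues[feq$eigenvalues > 1e-10]
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-10)
  expect_equal(feq$proportion_explained, rep(1 / 3, 3), tolerance = 1e-10)

  d2 <- stats::dist(matrix(c(0, 3), 2, 1, dimnames = list(c("a", "b"), NULL)))
  f2 <- pcoa(d2, n_axes = 1)
  expect_identical(ncol(f2$coordinates), 1L)
  expect_equal(f2$proportion_explained, 1, tolerance = 1e-12)
})

test_that("PERMANOVA pseudo-F agrees with vegan's adonis and p is seeded", {
  set.seed(21)
  m <- matrix(rpois(80, 8), 8, 10,
              dimnames = list(paste0("S", 1:8), paste0("A", 1:10)))
  storage.mode(m) <- "integer"
  g <- rep(c("x", "y"), each = 4)
  d <- bray_curtis_matrix(m)
  res <- permanova(d, g, n_perm = 199, seed = 5)
  ado <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ado$F[1], tolerance = 1e-10)
  expect_identical(res$df_between, 1L)
  expect_identical(permanova(d, g, n_perm = 199, seed = 5)$p_value, res$p_value)
  expect_gte(res$p_value, 1 / 200)

  expect_error(permanova(d, c("x", rep("y", 7)), n_perm = 99, seed = 1),
               "at least two samples")
  dc <- stats::as.dist(matrix(1, 8, 8) - diag(8))
  expect_error(permanova(dc, g, n_perm = 99, seed = 1), "constant distance")
})

test_that("disjoint-support groups reach the minimal attainable p", {
  m <- rbind(cbind(matrix(5L, 10, 6), matrix(0L, 10, 6)),
             cbind(matrix(0L, 10, 6), matrix(5L, 10, 6)))
  dimnames(m) <- list(paste0("S", 1:20), paste0("A", 1:12))
  g <- rep(c("x", "y"), each = 10)
  res <- permanova(bray_curtis_matrix(m), g, n_perm = 199, seed = 9)
  expect_equal(res$p_value, 1 / 200, tolerance = 1e-12)
})

test_that("two-group tests match their oracles", {
  w <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "wilcoxon")
  expect_equal(w$p_value, 1)

  tt <- compare_groups(c(1, 2, 3), c(11, 12, 13), test = "welch_t")
  expect_lt(tt$p_value, 0.01)
  expect_equal(tt$statistic, (2 - 12) / sqrt(1 / 3 + 1 / 3), tolerance = 1e-9)

  set.seed(8)
  for (i in 1:5) {
    a <- round(rnorm(4), 3)
    b <- round(rnorm(4, 1), 3)
    res <- compare_groups(a, b, test = "wilcoxon")
    expect_equal(res$p_value, wilcox_enum_p(a, b), tolerance = 1e-12)
  }

  expect_error(compare_groups(c(1, 1), c(2, 2), test = "welch_t"),
               "zero variance")
})
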
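meta_from_coords <- function(lat, lon) {
  data.frame(sample_id = paste0("S", seq_along(lat)), region = "R",
             lat = lat, lon = lon,
             row.names = paste0("S", seq_along(lat)))
}

test_that("haversine distances match closed forms on the 6371.0088 km sphere", {
  R_earth <- 6371.0088
  m <- meta_from_coords(c(10, 10), c(20, 20))
  expect_equal(as.vector(geographic_distance_matrix(m)), 0, tolerance = 1e-12)

  anti <- meta_from_coords(c(0, 0), c(0, 180))
  expect_equal(as.vector(geographic_distance_matrix(anti)), pi * R_earth,
               tolerance = 1e-9)

  deg <- meta_from_coords(c(0, 0), c(0, 1))
  expect_equal(as.vector(geographic_distance_matrix(deg)), R_earth * pi / 180,
               tolerance = 1e-9)
})

test_that("haversine is symmetric and satisfies the triangle inequality", {
  set.seed(31)
  m <- meta_from_coords(runif(6, -60, 60), runif(6, -150, 150))
  D <- as.matrix(geographic_distance_matrix(m))
  expect_equal(D, t(D))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
})

test_that("environmental distance standardizes variables and drops constants", {
  m <- meta_from_coords(c(0, 0, 0), c(0, 0, 0))
  m$v1 <- c(1, 2, 3); m$v2 <- c(10, 10, 40)
  d <- environmental_distance_matrix(m, c("v1", "v2"))
  z <- scale(cbind(m$v1, m$v2))
  expect_equal(as.vector(d), as.vector(stats::dist(z)), tolerance = 1e-12)

  m$flat <- 5
  expect_warning(d2 <- environmental_distance_matrix(m, c("v1", "v2", "flat")),
                 "flat")
  expect_equal(as.vector(d2), as.vector(d), tolerance = 1e-12)

  same <- meta_from_coords(c(0, 0), c(0, 0))
  same$v1 <- c(2, 2); same$v2 <- c(1, 1)
  expect_error(suppressWarnings(environmental_distance_matrix(same, c("v1", "v2"))))
})

test_that("distance-decay recovers an exactly linear similarity", {
  set.seed(41)
  n <- 6
  P <- matrix(runif(n * n, 10, 100), n, n); P <- (P + t(P)) / 2; diag(P) <- 0
  pd_m <- stats::as.dist(P)
  comm <- stats::as.dist(0.1 + 0.001 * as.matrix(pd_m))  # similarity 0.9 - 0.001 d
  fit <- distance_decay_fit(comm, pd_m)
  expect_equal(fit$slope, -0.001, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.9, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_pairs, n * (n - 1) / 2)

  # replacing similarity with dissimilarity flips the slope sign
  flip <- distance_decay_fit(stats::as.dist(1 - (0.1 + 0.001 * as.matrix(pd_m))), pd_m)
  expect_equal(flip$slope, 0.001, tolerance = 1e-10)

  expect_error(distance_decay_fit(comm, stats::as.dist(matrix(2, n, n) - 2 * diag(n))),
               "constant predictor")
})

test_that("niche-structured turnover produces a significant negative decay slope", {
  sim <- simulate_structured_table(150, 25, 2000, seed = 17)
  bc <- bray_curtis_matrix(sim$counts)
  envd <- environmental_distance_matrix(sim$metadata, "env")
  fit <- distance_decay_fit(bc, envd, predictor = "environmental")
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.05)
})

test_that("PCNM eigenfunctions behave like 1-D spatial waves", {
  pos <- 1:20
  geo <- stats::dist(pos)
  v <- pcnm_vectors(geo)
  expect_true(all(attr(v, "values") > 0))
  # the leading eigenfunction is the broadest-scale wave along the transect:
  # smooth (high lag-1 autocorrelation) and strongly position-structured
  expect_gt(stats::cor(v[-20, 1], v[-1, 1]), 0.9)
  expect_gt(abs(stats::cor(v[, 1], pos, method = "spearman")), 0.5)
  # higher-order eigenfunctions oscillate faster than the first
  nflips <- function(x) sum(diff(sign(x)) != 0)
  expect_lt(nflips(v[, 1]), nflips(v[, 6]))

  # rigid rotation of a planar configuration leaves eigenvalues unchanged
  set.seed(51)
  pts <- matrix(rnorm(24), 12, 2)
  th <- 0.7
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ev1 <- attr(pcnm_vectors(stats::dist(pts)), "values")
  ev2 <- attr(pcnm_vectors(stats::dist(rot)), "values")
  expect_equal(ev1, ev2, tolerance = 1e-8)

  v4 <- pcnm_vectors(stats::dist(c(0, 1, 2, 3)))
  expect_gte(ncol(v4), 1L)
})

test_that("Hellinger-transformed rows have unit sum of squares", {
  set.seed(61)
  m <- matrix(rpois(60, 4) + 1L, 6, 10,
              dimnames = list(paste0("S", 1:6), paste0("A", 1:10)))
  H <- hellinger(m)
  expect_equal(unname(rowSums(H^2)), rep(1, 6), tolerance = 1e-12)
})

test_that("variation partitioning matches vegan's varpart and its identity", {
  set.seed(71)
  n <- 20
  m <- matrix(rpois(n * 15, 6) + 1L, n, 15,
              dimnames = list(paste0("S", 1:n), paste0("A", 1:15)))
  env <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("e1", "e2")))
  spa <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  vp <- variation_partition(m, env, spa)
  expect_equal(vp$pure_env + vp$shared + vp$pure_spa + vp$unexplained, 1,
               tolerance = 1e-10)

  # vegan's two-matrix labels: [a] pure X1, [b] pure X2, [c] shared, [d] resid
  ref <- vegan::varpart(hellinger(m), env, spa)$part$indfract$Adj.R.square
  expect_equal(c(vp$pure_env, vp$pure_spa, vp$shared, vp$unexplained), ref,
               tolerance = 1e-8)

  # marginal identity: a + b and b + c are the single-matrix adjusted R2
  expect_equal(vp$pure_env + vp$shared, vp$adj_env, tolerance = 1e-12)
  expect_equal(vp$pure_spa + vp$shared, vp$adj_spa, tolerance = 1e-12)
})

test_that("totally confounded predictors put everything in the shared fraction", {
  sim <- simulate_structured_table(80, 18, 1500, seed = 81)
  env <- cbind(e = sim$metadata$env)
  vp <- variation_partition(sim$counts, env, env)
  expect_equal(vp$pure_env, 0, tolerance = 1e-12)
  expect_equal(vp$pure_spa, 0, tolerance = 1e-12)
  expect_equal(vp$shared, vp$adj_env, tolerance = 1e-12)

  dup <- cbind(e = sim$metadata$env, e2 = sim$metadata$env)
  expect_error(variation_partition(sim$counts, dup, env), "collinear")
})
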
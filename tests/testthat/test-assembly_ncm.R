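make_fit <- function(freq_pred, freq_obs, n_samples = 30, band = "binomial") {
  ci <- planktonAssembly:::occupancy_band(freq_pred, n_samples, 0.05, band)
  structure(list(m = 0.5, r_squared = NA_real_, N = 1000L, d = 1e-3,
                 n_samples = n_samples, ci_alpha = 0.05, band = band,
                 asv = data.frame(asv_id = paste0("A", seq_along(freq_pred)),
                                  p = freq_pred, freq_obs = freq_obs,
                                  freq_pred = freq_pred,
                                  ci_lower = ci$lower, ci_upper = ci$upper)),
            class = "ncm_fit")
}

test_that("occurrence statistics are exact on small tables", {
  m <- tbl(10, 0, 0,
            0, 0, 10, nrow = 2)
  st <- occurrence_stats(m)
  expect_setequal(st$asv_id, c("A1", "A3"))  # all-zero ASV excluded
  expect_equal(st$p[st$asv_id == "A1"], 0.5)
  expect_equal(st$freq_obs[st$asv_id == "A1"], 0.5)
  expect_identical(attr(st, "depth"), 10L)

  full <- tbl(4, 6, 5, 5, nrow = 2)
  expect_equal(occurrence_stats(full)$freq_obs, c(1, 1))

  uneq <- tbl(3, 1, 2, 0, nrow = 2)
  expect_error(occurrence_stats(uneq), "rarefied")
})

test_that("the neutral prediction is monotone in p and m with the right limits", {
  N <- 5000
  pr <- planktonAssembly:::ncm_freq_pred
  grid <- 10^seq(-5, -0.01, length.out = 60)
  for (m in c(0.05, 0.3, 0.7))
    expect_true(all(diff(pr(m, grid, N)) >= -1e-12))
  expect_gt(pr(0.3, 0.999, N), 1 - 1e-9)
  # larger m sharpens the occupancy curve toward a step at the detection limit
  lo <- pr(0.05, grid, N); hi <- pr(0.9, grid, N)
  expect_gt(max(abs(diff(hi))), max(abs(diff(lo))))
})

test_that("the fitted immigration rate minimizes the least-squares objective", {
  p <- simulate_metacommunity(200, 1, seed = 3)
  t1 <- simulate_neutral_table(p, 25, 3000, m = 0.4, seed = 13)
  st <- occurrence_stats(t1)
  fit <- fit_ncm(st)
  expect_true(fit$m > 0 && fit$m <= 1)
  expect_equal(fit$d, 1 / 3000)
  sse <- function(m) sum((st$freq_obs -
                            planktonAssembly:::ncm_freq_pred(m, st$p, fit$N))^2)
  for (s in c(0.01, 0.1, 0.5, 1)) expect_lte(sse(fit$m), sse(s) + 1e-12)
  expect_true(all(fit$asv$ci_lower <= fit$asv$freq_pred + 1e-12))
  expect_true(all(fit$asv$ci_upper >= fit$asv$freq_pred - 1e-12))
  expect_error(fit_ncm(st[1:5, ], N = 3000, n_samples = 25), ">= 10 ASVs")
})

test_that("partition labels respect the acceptance band", {
  # observed exactly at the prediction: neutral
  f1 <- make_fit(freq_pred = c(0.5, 0.2), freq_obs = c(0.5, 0.2))
  expect_identical(partition_asvs(f1)$partition, c("neutral", "neutral"))

  # full occupancy above a mid-range band: above
  f2 <- make_fit(freq_pred = 0.5, freq_obs = 1)
  expect_lt(f2$asv$ci_upper, 1)
  expect_identical(partition_asvs(f2)$partition, "above")

  f3 <- make_fit(freq_pred = 0.9, freq_obs = 0.1)
  expect_identical(partition_asvs(f3)$partition, "below")

  expect_error(partition_asvs(f1, alpha = 1.2), "alpha")
})

test_that("wilson bands remain available for comparability", {
  f <- make_fit(freq_pred = 0.97, freq_obs = 1, band = "wilson")
  # the wilson band excludes full occupancy here; the binomial band does not
  expect_identical(partition_asvs(f)$partition, "above")
  expect_identical(partition_asvs(f, band = "binomial")$partition, "neutral")
})

test_that("partition summaries report richness and abundance proportions", {
  n_asv <- 10
  m <- matrix(0L, 2, n_asv, dimnames = list(c("S1", "S2"), paste0("A", 1:n_asv)))
  m[1, ] <- 5L; m[2, ] <- 5L
  labels <- data.frame(asv_id = paste0("A", 1:n_asv),
                       partition = rep(c("neutral", "above", "below"), c(6, 3, 1)))
  ps <- partition_summary(labels, m)
  expect_equal(ps$overall$richness_prop[match(c("neutral", "above", "below"),
                                              ps$overall$partition)],
               c(0.6, 0.3, 0.1))
  expect_equal(sum(ps$overall$richness_prop), 1, tolerance = 1e-12)
  expect_equal(sum(ps$overall$abundance_prop), 1, tolerance = 1e-12)

  # one dominant above-partition ASV carries 90% of reads
  m2 <- matrix(1L, 2, n_asv, dimnames = dimnames(m))
  m2[, 1] <- 81L  # ASV 1 holds 162 of 180 reads = 0.9
  labels2 <- data.frame(asv_id = paste0("A", 1:n_asv),
                        partition = c("above", rep("neutral", 9)))
  ps2 <- partition_summary(labels2, m2)
  above <- ps2$overall[ps2$overall$partition == "above", ]
  expect_equal(above$abundance_prop, 0.9, tolerance = 1e-12)
  expect_equal(above$richness_prop, 0.1, tolerance = 1e-12)
})

test_that("per-lineage partition proportions are normalized within lineage", {
  sv <- simulate_survey(seed = 5, n_per_region = c(6, 6), S_phyto = 40,
                        S_zoo = 40, depth = 1500)
  phy <- split_by_group(sv$counts, sv$taxonomy)$phytoplankton
  phy <- phy[, colSums(phy) > 0]
  fit <- fit_ncm(occurrence_stats(phy))
  labels <- partition_asvs(fit)
  ps <- partition_summary(labels, phy, sv$taxonomy)
  for (l in unique(ps$by_lineage$lineage)) {
    sub <- ps$by_lineage[ps$by_lineage$lineage == l, ]
    expect_equal(sum(sub$richness_prop), 1, tolerance = 1e-12)
    expect_equal(sum(sub$abundance_prop), 1, tolerance = 1e-12)
  }
})
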
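#' Simulate a lognormal source metacommunity
#'
#' Relative abundances are drawn as `exp(Normal(0, sigma^2))` and
#' normalized; `sigma = 0` gives a uniform metacommunity. Species-abundance
#' distributions of plankton metabarcoding surveys are well approximated by
#' a lognormal with a long tail of rare taxa.
#'
#' @param S number of taxa (>= 2).
#' @param lognormal_sigma spread of the lognormal on the log scale.
#' @param seed integer seed.
#' @return numeric vector of length `S` summing to 1, named `ASV_1..ASV_S`.
#' @export
simulate_metacommunity <- function(S, lognormal_sigma = 1, seed) {
  if (S < 2) stop("S must be >= 2")
  if (lognormal_sigma < 0) stop("lognormal_sigma must be >= 0")
  set.seed(seed)
  x <- exp(stats::rnorm(S, 0, lognormal_sigma))
  p <- x / sum(x)
  names(p) <- paste0("ASV_", seq_len(S))
  p
}

#' Simulate a neutral community table (Dirichlet-multinomial)
#'
#' For each sample, local true relative abundances are drawn from
#' `Dirichlet(N m p)` — whose marginals are exactly the
#' `Beta(N m p_j, N m (1 - p_j))` distributions assumed by Sloan's neutral
#' model — and counts from `Multinomial(N, local proportions)`. Rows all sum
#' to `depth`, so the output is already "rarefied". Fitting the neutral
#' model to this output is therefore a fair parameter-recovery exercise
#' rather than a model-mismatch test.
#'
#' @param p source metacommunity relative abundances (sums to 1).
#' @param n_samples number of local communities.
#' @param depth reads per sample (the N of the neutral model).
#' @param m immigration rate in (0, 1].
#' @param seed integer seed.
#' @return integer ASV table (samples x taxa).
#' @export
simulate_neutral_table <- function(p, n_samples, depth, m, seed) {
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  conc <- depth * m * p
  if (all(conc < 1e-12)) stop("Dirichlet concentration underflow; increase S*m*N")
  set.seed(seed)
  counts <- matrix(0L, n_samples, length(p),
                   dimnames = list(paste0("S", seq_len(n_samples)),
                                   if (is.null(names(p))) paste0("ASV_", seq_along(p)) else names(p)))
  for (i in seq_len(n_samples)) {
    g <- stats::rgamma(length(p), shape = conc, rate = 1)
    if (sum(g) == 0) g[which.max(p)] <- 1  # numeric underflow guard
    counts[i, ] <- as.integer(stats::rmultinom(1, depth, g / sum(g)))
  }
  counts
}

#' Simulate a niche-structured community along an environmental gradient
#'
#' Each taxon j has a Gaussian response to the environment:
#' `lambda_ij = exp(-(e_i - mu_j)^2 / (2 sigma_j^2))`; counts are
#' multinomial draws of `depth` reads from the normalized response. Samples
#' are placed on a 1-D spatial transect and the environmental value follows
#' the transect, so environment and space are collinear unless
#' `spatial_noise > 0` adds noise that decouples them (large values shuffle
#' the environment relative to space).
#'
#' @param S number of taxa.
#' @param n_samples number of samples.
#' @param depth reads per sample.
#' @param env_gradient per-sample environmental values; default an even
#'   gradient on \[0, 1\] along the transect.
#' @param niche_optima per-taxon optima; default uniform over the gradient
#'   range.
#' @param niche_tolerances per-taxon tolerances (> 0); default narrow
#'   (strong selection), `runif(S, 0.05, 0.15)` on a unit gradient.
#' @param spatial_noise standard deviation (in units of the gradient's SD)
#'   of noise added to the environment, decoupling it from space.
#' @param seed integer seed.
#' @return list with `counts` (integer table) and `metadata` (data.frame
#'   with `sample_id`, `lat`, `lon`, `env`, plus a `position` column on the
#'   transect).
#' @export
simulate_structured_table <- function(S, n_samples, depth,
                                      env_gradient = seq(0, 1, length.out = n_samples),
                                      niche_optima = NULL,
                                      niche_tolerances = NULL,
                                      spatial_noise = 0, seed) {
  if (length(env_gradient) != n_samples) stop("env_gradient length must equal n_samples")
  if (spatial_noise < 0) stop("spatial_noise must be >= 0")
  set.seed(seed)
  rng <- range(env_gradient)
  if (is.null(niche_optima)) niche_optima <- stats::runif(S, rng[1], rng[2])
  if (is.null(niche_tolerances))
    niche_tolerances <- stats::runif(S, 0.05, 0.15) * max(diff(rng), 1e-12)
  if (any(niche_tolerances <= 0)) stop("niche tolerances must be > 0")
  env <- env_gradient
  if (spatial_noise > 0)
    env <- env + stats::rnorm(n_samples, 0, spatial_noise * stats::sd(env_gradient))
  loglam <- -sweep(outer(env, niche_optima, `-`)^2, 2, 2 * niche_tolerances^2, "/")
  counts <- matrix(0L, n_samples, S,
                   dimnames = list(paste0("S", seq_len(n_samples)),
                                   paste0("ASV_", seq_len(S))))
  for (i in seq_len(n_samples)) {
    # normalize in log space: multinomial probabilities are scale-invariant,
    # so subtracting the per-sample maximum avoids exp() underflow
    w <- exp(loglam[i, ] - max(loglam[i, ]))
    if (!any(is.finite(w)) || sum(w) == 0)
      stop("all niche responses zero for sample ", i)
    counts[i, ] <- as.integer(stats::rmultinom(1, depth, w / sum(w)))
  }
  # transect: ~1 km spacing northwards at a fixed longitude
  metadata <- data.frame(sample_id = rownames(counts),
                         region = "SIM",
                         lat = 40 + (seq_len(n_samples) - 1) * 0.009,
                         lon = rep(122, n_samples),
                         position = seq_len(n_samples),
                         env = env,
                         stringsAsFactors = FALSE)
  rownames(metadata) <- metadata$sample_id
  attr(metadata, "env_columns") <- "env"
  list(counts = counts, metadata = metadata)
}

#' Simulate a random coalescent phylogeny over ASV ids
#'
#' Coalescent topology with independent exponential branch lengths
#' (mean 1); tips are the supplied ids.
#'
#' @param asv_ids unique tip labels (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(asv_ids, seed) {
  if (length(asv_ids) < 2) stop("need >= 2 ids")
  if (anyDuplicated(asv_ids)) stop("duplicate ids")
  set.seed(seed)
  tree <- ape::rcoal(length(asv_ids), tip.label = asv_ids)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1)
  tree
}

#' Simulate a full two-estuary survey bundle
#'
#' Builds a dataset with the shape of a two-region plankton survey so the
#' whole pipeline can run end to end: a phytoplankton block assembled
#' neutrally (high immigration) and a microzooplankton block assembled under
#' niche selection along an environmental gradient, in two regions, plus
#' taxonomy, metadata with 15 environmental variables, and a phylogeny.
#' Region sample sizes default to the 15/18 layout of a two-estuary survey.
#'
#' @param n_per_region samples per region (length-2 integer).
#' @param S_phyto,S_zoo taxa per group.
#' @param depth reads per sample before rarefaction noise.
#' @param m_phyto immigration rate of the neutral (phytoplankton) block.
#' @param seed integer seed.
#' @return list with `counts`, `taxonomy`, `metadata`, `tree`.
#' @export
simulate_survey <- function(n_per_region = c(15, 18), S_phyto = 80, S_zoo = 150,
                            depth = 6000, m_phyto = 0.5, seed = 1) {
  regions <- c("LH", "YLJ")
  n_tot <- sum(n_per_region)
  p_src <- simulate_metacommunity(S_phyto, lognormal_sigma = 1.5, seed = seed)
  phyto <- simulate_neutral_table(p_src, n_tot, depth, m = m_phyto, seed = seed + 101)
  colnames(phyto) <- paste0("PHY_", seq_len(S_phyto))
  zoo_sim <- simulate_structured_table(S_zoo, n_tot, depth,
                                       spatial_noise = 0.3, seed = seed + 202)
  zoo <- zoo_sim$counts
  colnames(zoo) <- paste0("ZOO_", seq_len(S_zoo))
  counts <- cbind(phyto, zoo)
  rownames(counts) <- paste0("S", seq_len(n_tot))
  region <- rep(regions, n_per_region)
  set.seed(seed + 303)
  # 15 environmental variables: the niche gradient plus correlates and noise
  env_base <- zoo_sim$metadata$env
  env_names <- c("Temp", "Salinity", "DO", "COD", "PHs", "Nitrate", "Nitrite",
                 "Ammonium", "Phosphate", "Cu", "Pb", "Zn", "Cd", "Cr", "As")
  env <- sapply(seq_along(env_names), function(k) {
    w <- stats::runif(1, -1, 1)
    w * env_base + stats::rnorm(n_tot, 0, 0.5)
  })
  colnames(env) <- env_names
  lat0 <- ifelse(region == "LH", 40.8, 39.8)
  lon0 <- ifelse(region == "LH", 121.8, 124.2)
  metadata <- data.frame(sample_id = rownames(counts), region = region,
                         lat = lat0 + zoo_sim$metadata$position * 0.004,
                         lon = lon0 + stats::rnorm(n_tot, 0, 0.01),
                         env, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(metadata) <- metadata$sample_id
  attr(metadata, "env_columns") <- env_names
  lineages_p <- c("Pyrrophyta", "Bacillariophyta", "Charophyta", "Chlorophyta")
  lineages_z <- c("Ciliophora", "Trachylinae", "Arthropoda", "Cercozoa")
  taxonomy <- data.frame(
    asv_id = colnames(counts),
    group = rep(c("phytoplankton", "microzooplankton"), c(S_phyto, S_zoo)),
    lineage = c(sample(lineages_p, S_phyto, replace = TRUE),
                sample(lineages_z, S_zoo, replace = TRUE)),
    genus = "unknown", species = "unknown", stringsAsFactors = FALSE)
  rownames(taxonomy) <- taxonomy$asv_id
  tree <- simulate_tree(colnames(counts), seed = seed + 404)
  list(counts = counts, taxonomy = taxonomy, metadata = metadata, tree = tree)
}
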
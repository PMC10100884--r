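#' Alpha diversity of a single sample
#'
#' Indices used throughout the package:
#' \describe{
#'   \item{chao1}{bias-corrected Chao1, `S_obs + F1(F1-1) / (2(F2+1))` where
#'     `F1`/`F2` are the numbers of taxa observed exactly once/twice.}
#'   \item{shannon}{`-sum p_k log p_k` with natural log.}
#'   \item{pielou}{Shannon evenness `H / log(S_obs)`; undefined for a single
#'     observed taxon.}
#'   \item{faith_pd}{Faith's phylogenetic diversity: total branch length of
#'     the subtree spanning the present tips, including the path to the root.}
#' }
#'
#' @param counts nonnegative integer vector for one sample, named with taxon
#'   ids when `index = "faith_pd"`.
#' @param index one of `"chao1"`, `"shannon"`, `"pielou"`, `"faith_pd"`.
#' @param tree phylogeny (required for `faith_pd`).
#' @return scalar index value.
#' @export
alpha_diversity <- function(counts, index = c("chao1", "shannon", "pielou", "faith_pd"),
                            tree = NULL) {
  index <- match.arg(index)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) == 0) stop("all-zero count vector")
  s_obs <- sum(counts > 0)
  switch(index,
    chao1 = {
      f1 <- sum(counts == 1)
      f2 <- sum(counts == 2)
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    },
    shannon = {
      p <- counts[counts > 0] / sum(counts)
      -sum(p * log(p))
    },
    pielou = {
      if (s_obs < 2) stop("Pielou evenness undefined with a single observed taxon")
      p <- counts[counts > 0] / sum(counts)
      -sum(p * log(p)) / log(s_obs)
    },
    faith_pd = {
      if (is.null(tree)) stop("faith_pd requires a tree")
      present <- names(counts)[counts > 0]
      if (is.null(present)) stop("faith_pd requires named counts")
      absent <- setdiff(present, tree$tip.label)
      if (length(absent))
        stop("tips absent from tree: ", paste(utils::head(absent, 5), collapse = ", "))
      comm <- matrix(as.integer(tree$tip.label %in% present), nrow = 1,
                     dimnames = list("s", tree$tip.label))
      picante::pd(comm, tree, include.root = TRUE)$PD
    }
  )
}

#' Alpha diversity table for all samples
#'
#' @param t ASV table (samples x ASVs).
#' @param indices indices to compute (see [alpha_diversity()]).
#' @param tree phylogeny, needed only for `faith_pd`.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity_table <- function(t, indices = c("chao1", "shannon", "pielou"),
                                  tree = NULL) {
  t <- validate_asv_table(t)
  out <- data.frame(sample_id = rownames(t), stringsAsFactors = FALSE)
  for (idx in indices)
    out[[idx]] <- apply(t, 1, alpha_diversity, index = idx, tree = tree)
  rownames(out) <- out$sample_id
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param t ASV table with no all-zero sample.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis_matrix <- function(t) {
  t <- validate_asv_table(t)
  if (any(rowSums(t) == 0)) stop("all-zero sample row; Bray-Curtis undefined")
  vegan::vegdist(t, method = "bray")
}

#' Principal coordinates analysis
#'
#' Gower double-centering of the squared distances followed by
#' eigendecomposition (via [stats::cmdscale()]). Negative eigenvalues are
#' reported but excluded from the `proportion_explained` denominator and no
#' Lingoes/Cailliez correction is applied.
#'
#' @param d distance matrix (`dist` or symmetric matrix).
#' @param n_axes number of axes to return.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all, in
#'   decreasing order) and `proportion_explained` (per retained axis, over
#'   the positive-eigenvalue sum).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n_axes < 1) stop("n_axes must be >= 1")
  fit <- stats::cmdscale(d, k = min(n_axes, n - 1), eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_axes > n_pos) {
    warning("only ", n_pos, " positive eigenvalue(s); truncating axes")
    n_axes <- n_pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = eig[seq_len(n_axes)] / sum(eig[eig > 0]))
}

#' One-way PERMANOVA (Adonis) on a distance matrix
#'
#' Anderson's pseudo-F computed from pairwise squared distances:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` from within-group pairs,
#' `F = (SS_between/(g-1)) / (SS_within/(n-g))`. The p-value permutes group
#' labels, with the add-one correction
#' `p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`.
#'
#' @param d distance matrix (`dist` or symmetric matrix) labelled by sample.
#' @param groups group label per sample, in the order of the labels of `d`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation draw.
#' @return list with `pseudo_F`, `p_value`, `n_permutations`, `df_between`,
#'   `df_within`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed) {
  if (missing(seed)) stop("permanova requires an explicit seed")
  D <- as.matrix(stats::as.dist(d))
  n <- nrow(D)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("groups length must match distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least two samples")
  off <- D[upper.tri(D)]
  if (stats::sd(off) == 0) stop("constant distance matrix; pseudo-F undefined")
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  a <- nlevels(groups)
  f_stat <- function(g) {
    ssw <- ss_within(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm),
                   function(i) f_stat(groups[sample.int(n)]),
                   numeric(1))
  list(pseudo_F = f_obs,
       p_value = (sum(f_perm >= f_obs) + 1) / (n_perm + 1),
       n_permutations = as.integer(n_perm),
       df_between = as.integer(a - 1),
       df_within = as.integer(n - a))
}

#' Two-group comparison
#'
#' Welch's t-test (Satterthwaite df) or the Wilcoxon rank-sum test (exact
#' enumeration when both groups have n <= 10 and there are no ties, otherwise
#' the tie-corrected normal approximation).
#'
#' @param values_a,values_b numeric vectors.
#' @param test `"welch_t"` or `"wilcoxon"`.
#' @return list with `statistic` and `p_value`.
#' @export
compare_groups <- function(values_a, values_b, test = c("welch_t", "wilcoxon")) {
  test <- match.arg(test)
  if (test == "welch_t") {
    if (length(values_a) < 2 || length(values_b) < 2)
      stop("Welch t-test needs >= 2 values per group")
    if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0)
      stop("zero variance in both groups")
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  } else {
    exact <- length(values_a) <= 10 && length(values_b) <= 10 &&
      !anyDuplicated(c(values_a, values_b))
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = exact, correct = FALSE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
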
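#' Great-circle distance matrix between samples (km)
#'
#' Haversine distances on a sphere of radius 6371.0088 km.
#'
#' @param meta metadata data.frame with `lat` and `lon` in decimal degrees
#'   and sample ids as row names.
#' @return `dist` object in kilometres.
#' @export
geographic_distance_matrix <- function(meta) {
  if (anyNA(meta$lat) || anyNA(meta$lon)) stop("missing coordinates")
  coords <- cbind(lon = meta$lon, lat = meta$lat)
  n <- nrow(coords)
  M <- matrix(0, n, n, dimnames = list(rownames(meta), rownames(meta)))
  for (i in seq_len(n))
    M[i, ] <- geosphere::distHaversine(coords[i, , drop = FALSE], coords,
                                       r = 6371008.8) / 1000
  M <- (M + t(M)) / 2  # symmetrize away floating-point asymmetry
  stats::as.dist(M)
}

#' Environmental (Euclidean) distance matrix
#'
#' Each variable is z-score standardized across the included samples before
#' Euclidean distance; zero-variance variables are dropped with a warning.
#'
#' @param meta metadata data.frame; environmental variables are taken from
#'   its `env_columns` attribute unless given explicitly.
#' @param env_columns names of the environmental variable columns.
#' @return `dist` object.
#' @export
environmental_distance_matrix <- function(meta, env_columns = attr(meta, "env_columns")) {
  if (is.null(env_columns)) stop("env_columns not given and not on the metadata")
  X <- as.matrix(meta[, env_columns, drop = FALSE])
  if (anyNA(X)) stop("missing environmental values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(env_columns[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no environmental variables left after dropping")
  stats::dist(scale(X))
}

#' Distance-decay of community similarity
#'
#' Ordinary least squares of similarity (1 - Bray-Curtis) on the vectorized
#' upper triangle of a predictor distance matrix; slope, R² and the OLS
#' t-test p-value are reported. Because site pairs share samples the OLS
#' p-value treats dependent points as independent; an optional
#' label-permutation (Mantel-style) p-value is available via `mantel_perm`.
#'
#' @param community_d community distance matrix (`dist`), e.g. Bray-Curtis.
#' @param predictor_d predictor distance matrix with matching labels.
#' @param predictor label stored on the fit (`"geographic"` or
#'   `"environmental"`).
#' @param mantel_perm if > 0, also compute a permutation p-value for the
#'   slope by permuting sample labels of the predictor matrix.
#' @param seed seed for the optional permutation test.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_pairs`, `predictor` and (optionally) `mantel_p`.
#' @export
distance_decay_fit <- function(community_d, predictor_d,
                               predictor = c("geographic", "environmental"),
                               mantel_perm = 0, seed = NULL) {
  predictor <- match.arg(predictor)
  community_d <- stats::as.dist(community_d)
  predictor_d <- stats::as.dist(predictor_d)
  labs_c <- attr(community_d, "Labels"); labs_p <- attr(predictor_d, "Labels")
  if (!is.null(labs_c) && !is.null(labs_p) && !identical(labs_c, labs_p))
    stop("community and predictor distance labels differ")
  n <- attr(community_d, "Size")
  if (n < 4) stop("need >= 4 samples for a distance-decay fit")
  y <- 1 - as.vector(community_d)
  x <- as.vector(predictor_d)
  if (stats::sd(x) == 0) stop("constant predictor distances")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              p_value = sm$coefficients[2, 4],
              n_pairs = length(y),
              predictor = predictor)
  if (mantel_perm > 0) {
    if (is.null(seed)) stop("seed required for the permutation p-value")
    set.seed(seed)
    P <- as.matrix(predictor_d)
    obs <- abs(out$slope)
    hits <- 0
    for (b in seq_len(mantel_perm)) {
      idx <- sample.int(n)
      xb <- as.vector(stats::as.dist(P[idx, idx]))
      sb <- stats::cov(y, xb) / stats::var(xb)
      if (abs(sb) >= obs) hits <- hits + 1
    }
    out$mantel_p <- (hits + 1) / (mantel_perm + 1)
  }
  out
}

#' Spatial eigenfunctions (dbMEM / PCNM) from geographic distances
#'
#' Truncates the distance matrix above the longest edge of its minimum
#' spanning tree and returns the principal coordinates with positive
#' eigenvalues (via [vegan::pcnm()]), the standard spatial predictors for
#' variation partitioning.
#'
#' @param geo_d geographic distance matrix (`dist`).
#' @return matrix of spatial eigenvectors (samples x axes), with the
#'   eigenvalues as attribute `values`.
#' @export
pcnm_vectors <- function(geo_d) {
  geo_d <- stats::as.dist(geo_d)
  if (attr(geo_d, "Size") < 4) stop("need >= 4 samples for PCNM")
  fit <- vegan::pcnm(geo_d)
  if (is.null(fit$vectors) || ncol(fit$vectors) < 1)
    stop("no positive PCNM eigenvalues")
  v <- fit$vectors
  rownames(v) <- attr(geo_d, "Labels")
  attr(v, "values") <- fit$values[seq_len(ncol(v))]
  v
}

#' Hellinger transformation of a count table
#'
#' Square root of row-relative abundances; each transformed row has unit sum
#' of squares.
#'
#' @param t count table (samples x taxa).
#' @return transformed numeric matrix.
#' @export
hellinger <- function(t) {
  if (any(rowSums(t) == 0)) stop("all-zero sample row")
  vegan::decostand(as.matrix(t), method = "hellinger")
}

# Multivariate OLS (redundancy analysis) R-squared of a centered response on
# a centered predictor matrix: SS(fitted)/SS(total). Fitting uses the column
# span, so redundancy BETWEEN the env and spa blocks (total confounding) is
# legitimate; redundancy WITHIN a single block is an input error.
rda_r2 <- function(Yc, X, label = "predictors", strict = TRUE) {
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  q <- qr(Xc)
  if (strict && q$rank < ncol(Xc)) {
    dropped <- colnames(Xc)[q$pivot[(q$rank + 1):ncol(Xc)]]
    stop("rank-deficient ", label, "; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fitted <- qr.fitted(q, Yc)
  list(r2 = sum(fitted^2) / sum(Yc^2), p = q$rank)
}

adjust_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Variation partitioning between environmental and spatial predictors
#'
#' Partitions the adjusted R² of a redundancy analysis of the
#' Hellinger-transformed community on two predictor matrices into pure
#' environmental \[a\], shared \[b\], pure spatial \[c\] and unexplained \[d\]
#' fractions by inclusion-exclusion:
#' `a = R2adj(E+S) - R2adj(S)`, `c = R2adj(E+S) - R2adj(E)`,
#' `b = R2adj(E) + R2adj(S) - R2adj(E+S)`, `d = 1 - R2adj(E+S)`.
#' Negative fractions are reported as-is.
#'
#' @param t ASV count table (samples x ASVs).
#' @param env environmental predictor matrix (samples x variables).
#' @param spa spatial predictor matrix (samples x eigenfunctions).
#' @return list with `pure_env`, `shared`, `pure_spa`, `unexplained` and the
#'   marginal adjusted R² values `adj_env`, `adj_spa`, `adj_both`.
#' @export
variation_partition <- function(t, env, spa) {
  Y <- hellinger(t)
  env <- as.matrix(env); spa <- as.matrix(spa)
  n <- nrow(Y)
  if (nrow(env) != n || nrow(spa) != n) stop("predictor rows must match samples")
  if (ncol(env) + ncol(spa) >= n - 1)
    stop("too many predictors: need ncol(env) + ncol(spa) < n - 1")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  fe <- rda_r2(Yc, env, "environmental predictors")
  fs <- rda_r2(Yc, spa, "spatial predictors")
  fb <- rda_r2(Yc, cbind(env, spa), strict = FALSE)
  adj_e <- adjust_r2(fe$r2, n, fe$p)
  adj_s <- adjust_r2(fs$r2, n, fs$p)
  adj_b <- adjust_r2(fb$r2, n, fb$p)
  list(pure_env = adj_b - adj_s,
       shared = adj_e + adj_s - adj_b,
       pure_spa = adj_b - adj_e,
       unexplained = 1 - adj_b,
       adj_env = adj_e, adj_spa = adj_s, adj_both = adj_b)
}
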
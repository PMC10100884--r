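#' Levins' niche breadth per taxon
#'
#' `B_j = 1 / sum_i q_ij^2`, where `q_ij` is the fraction of taxon j's reads
#' found in sample i. B ranges from 1 (found in one sample only) to the
#' number of samples (spread perfectly evenly), and is invariant to
#' rescaling a taxon's counts.
#'
#' @param t ASV table (samples x taxa). Taxa with zero total are excluded
#'   with a warning.
#' @return named numeric vector of B values.
#' @export
levins_breadth <- function(t) {
  t <- validate_asv_table(t)
  tot <- colSums(t)
  if (any(tot == 0)) {
    warning("excluding ", sum(tot == 0), " taxa with zero total count")
    t <- t[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  q <- sweep(t, 2, tot, "/")
  1 / colSums(q^2)
}

#' Community-level niche breadth (Bcom) per sample
#'
#' The unweighted mean of Levins' B over the taxa present in each sample.
#'
#' @param t ASV table.
#' @param B per-taxon breadths from [levins_breadth()] computed on the same
#'   table; recomputed if missing.
#' @return named numeric vector, one Bcom per sample.
#' @export
community_breadth <- function(t, B = levins_breadth(t)) {
  t <- validate_asv_table(t)
  if (any(rowSums(t) == 0)) stop("empty sample")
  t <- t[, names(B), drop = FALSE]
  apply(t, 1, function(x) mean(B[x > 0]))
}

#' Shared-sequence dispersal proxy per sample
#'
#' For a pair of samples (s, u) with jointly present taxa A, the shared
#' proportion is the mean of each member's fraction of reads belonging to A:
#' `share(s,u) = (sum_A x_s / sum x_s + sum_A x_u / sum x_u) / 2`. The
#' per-sample proxy is the average share over all partners; a high value
#' indicates successful passive transport between sites. A min-based variant
#' (`sum_j min(prop_s, prop_u)`, proportional similarity) is available.
#'
#' @param t ASV table with >= 2 samples and no empty sample.
#' @param method `"mean"` (default) or `"min"`.
#' @return named numeric vector in \[0, 1\], one value per sample.
#' @export
dispersal_proxy <- function(t, method = c("mean", "min")) {
  method <- match.arg(method)
  t <- validate_asv_table(t)
  n <- nrow(t)
  if (n < 2) stop("need >= 2 samples")
  if (any(rowSums(t) == 0)) stop("empty sample")
  prop <- t / rowSums(t)
  share <- matrix(0, n, n, dimnames = list(rownames(t), rownames(t)))
  for (s in seq_len(n - 1)) {
    for (u in (s + 1):n) {
      if (method == "mean") {
        both <- t[s, ] > 0 & t[u, ] > 0
        val <- (sum(prop[s, both]) + sum(prop[u, both])) / 2
      } else {
        val <- sum(pmin(prop[s, ], prop[u, ]))
      }
      share[s, u] <- share[u, s] <- val
    }
  }
  rowSums(share) / (n - 1)
}

#' Niche breadth and dispersal summary per sample
#'
#' Convenience wrapper combining [community_breadth()] and
#' [dispersal_proxy()]. When a region factor is supplied, Levins' B and both
#' per-sample summaries are computed within each region separately (a
#' taxon's breadth is its spread over that region's samples only).
#'
#' @param t ASV table.
#' @param region optional factor/character of per-sample region labels.
#' @param method dispersal variant, see [dispersal_proxy()].
#' @return data.frame with columns `sample_id`, `region` (if given), `bcom`,
#'   `dispersal`.
#' @export
niche_dispersal_table <- function(t, region = NULL, method = c("mean", "min")) {
  method <- match.arg(method)
  t <- validate_asv_table(t)
  run_one <- function(sub) {
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    data.frame(sample_id = rownames(sub),
               bcom = unname(community_breadth(sub)),
               dispersal = unname(dispersal_proxy(sub, method = method)),
               stringsAsFactors = FALSE)
  }
  if (is.null(region)) return(run_one(t))
  region <- as.character(region)
  if (length(region) != nrow(t)) stop("region length must match samples")
  parts <- lapply(unique(region), function(r) {
    cbind(region = r, run_one(t[region == r, , drop = FALSE]))
  })
  do.call(rbind, parts)
}
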
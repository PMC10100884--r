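#' Per-ASV occurrence statistics from a rarefied table
#'
#' For each ASV: `p` = mean relative abundance across samples and
#' `freq_obs` = fraction of samples where it is detected. All-zero ASVs are
#' dropped. The table must be rarefied (equal row sums) so that the
#' detection limit 1/N is the same in every sample.
#'
#' @param t rarefied ASV table.
#' @return data.frame with columns `asv_id`, `p`, `freq_obs`; attributes
#'   `depth` (reads per sample) and `n_samples`.
#' @export
occurrence_stats <- function(t) {
  t <- validate_asv_table(t)
  rs <- rowSums(t)
  if (length(unique(rs)) != 1) stop("table must be rarefied (equal row sums)")
  depth <- rs[[1]]
  p <- colMeans(t / depth)
  freq <- colMeans(t > 0)
  keep <- p > 0
  out <- data.frame(asv_id = colnames(t)[keep], p = unname(p[keep]),
                    freq_obs = unname(freq[keep]), stringsAsFactors = FALSE)
  attr(out, "depth") <- as.integer(depth)
  attr(out, "n_samples") <- nrow(t)
  out
}

# Acceptance band of level 1-alpha for an observed occurrence fraction with
# n samples, around a predicted occurrence probability. "binomial" is the
# exact central prediction interval of Binomial(n, pred)/n and is correctly
# calibrated as an acceptance region; "wilson" is the score confidence
# interval used by most published neutral-model scripts, kept for
# comparability (as an acceptance region it is anti-conservative near
# pred = 0 or 1: e.g. at pred = 0.97, n = 30 it excludes freq_obs = 1
# although that outcome has probability 0.4).
occupancy_band <- function(pred, n, alpha = 0.05, band = c("binomial", "wilson")) {
  band <- match.arg(band)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (band == "wilson") return(wilson_interval(pred, n, alpha))
  # clamp so the band always contains the prediction itself (at extreme pred
  # the discrete quantiles can sit on one side of it)
  list(lower = pmin(stats::qbinom(alpha / 2, n, pred) / n, pred),
       upper = pmax(stats::qbinom(1 - alpha / 2, n, pred) / n, pred))
}

# Sloan NCM predicted occurrence frequency: probability that a taxon with
# source relative abundance p exceeds the detection limit d = 1/N in a local
# community of size N with immigration rate m. The local relative abundance
# is Beta(N m p, N m (1-p)); the prediction is its upper tail at d.
ncm_freq_pred <- function(m, p, N) {
  stats::pbeta(1 / N, N * m * p, N * m * (1 - p), lower.tail = FALSE)
}

#' Fit Sloan's neutral community model
#'
#' Estimates the immigration rate `m` by nonlinear least squares of observed
#' occurrence frequencies on the model prediction
#' `freq_pred(m) = 1 - pbeta(1/N, N m p, N m (1-p))`, with `m` bounded to
#' (0, 1] and multi-started from 0.01, 0.1, 0.5 and 1. The fit statistic is
#' `R² = 1 - SS_res/SS_tot` about the mean observed frequency (it can be
#' negative for strongly non-neutral data). Acceptance bands around the
#' prediction (level `1 - ci_alpha`, effective trials = number of samples)
#' are attached per ASV; see `band`.
#'
#' @param stats data.frame from [occurrence_stats()] (columns `asv_id`, `p`,
#'   `freq_obs`).
#' @param N community size: reads per sample after rarefaction. Defaults to
#'   the `depth` attribute of `stats`.
#' @param n_samples number of samples behind `freq_obs`; defaults to the
#'   attribute on `stats`.
#' @param ci_alpha level for the per-ASV bands (default 0.05 → 95% bands).
#' @param band band type: `"binomial"` (exact prediction interval, the
#'   default) or `"wilson"` (score interval, the convention of published
#'   neutral-model scripts).
#' @return object of class `ncm_fit`: list with `m`, `r_squared`, `N`, `d`,
#'   `n_samples` and per-ASV data.frame `asv` (columns `asv_id`, `p`,
#'   `freq_obs`, `freq_pred`, `ci_lower`, `ci_upper`).
#' @export
fit_ncm <- function(stats, N = attr(stats, "depth"),
                    n_samples = attr(stats, "n_samples"), ci_alpha = 0.05,
                    band = c("binomial", "wilson")) {
  band <- match.arg(band)
  if (is.null(N)) stop("N not given and not an attribute of stats")
  if (nrow(stats) < 10) stop("need >= 10 ASVs to fit the neutral model")
  if (N < 2) stop("N must be >= 2")
  p <- stats$p
  freq <- stats$freq_obs
  if (any(p <= 0)) stop("all fitted ASVs must have p > 0")
  sse <- function(m) sum((freq - ncm_freq_pred(m, p, N))^2)
  starts <- c(0.01, 0.1, 0.5, 1.0)
  fits <- lapply(starts, function(s) {
    tryCatch(stats::nlminb(s, sse, lower = 1e-8, upper = 1),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$objective), fits)
  if (!length(fits)) stop("neutral-model optimizer failed from every start")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  m_hat <- best$par
  pred <- ncm_freq_pred(m_hat, p, N)
  ss_res <- sum((freq - pred)^2)
  ss_tot <- sum((freq - mean(freq))^2)
  ci <- occupancy_band(pred, n_samples, ci_alpha, band)
  out <- list(m = m_hat,
              r_squared = 1 - ss_res / ss_tot,
              N = as.integer(N), d = 1 / N,
              n_samples = n_samples,
              ci_alpha = ci_alpha,
              band = band,
              asv = data.frame(asv_id = stats$asv_id, p = p, freq_obs = freq,
                               freq_pred = pred, ci_lower = ci$lower,
                               ci_upper = ci$upper, stringsAsFactors = FALSE))
  class(out) <- "ncm_fit"
  out
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.4g, R2 = %.4g, N = %d, %d ASVs over %d samples\n",
              x$m, x$r_squared, x$N, nrow(x$asv), x$n_samples))
  invisible(x)
}

# Wilson score interval for a proportion phat with n effective trials
# (non-integer successes allowed).
wilson_interval <- function(phat, n, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Partition ASVs against the neutral prediction
#'
#' Labels each fitted ASV `above`, `below` or `neutral` according to whether
#' its observed occurrence frequency lies above, below or within the
#' acceptance band (level `1 - alpha`) around the neutral prediction; see
#' [fit_ncm()] for the band types.
#'
#' @param fit an `ncm_fit` object.
#' @param alpha band level (default 0.05, i.e. 95% bands).
#' @param band band type; defaults to the one stored on the fit.
#' @return the fit's per-ASV data.frame with an added `partition` column.
#' @export
partition_asvs <- function(fit, alpha = 0.05, band = fit$band) {
  stopifnot(inherits(fit, "ncm_fit"))
  asv <- fit$asv
  if (!identical(alpha, fit$ci_alpha) || !identical(band, fit$band)) {
    ci <- occupancy_band(asv$freq_pred, fit$n_samples, alpha, band)
    asv$ci_lower <- ci$lower
    asv$ci_upper <- ci$upper
  }
  asv$partition <- ifelse(asv$freq_obs > asv$ci_upper, "above",
                          ifelse(asv$freq_obs < asv$ci_lower, "below", "neutral"))
  asv
}

#' Richness and abundance proportions of the neutral partitions
#'
#' Summarizes the above/neutral/below partition by the proportion of ASVs
#' (richness) and of sequence reads (abundance) in each class, overall and
#' within each lineage.
#'
#' @param labels data.frame from [partition_asvs()] (needs `asv_id`,
#'   `partition`).
#' @param t the ASV table the fit was computed on.
#' @param tax taxonomy data.frame (needs `asv_id`, `lineage`); optional —
#'   without it only the overall summary is returned.
#' @return list with data.frames `overall` and (if `tax` given) `by_lineage`;
#'   proportions sum to 1 within each summary row set.
#' @export
partition_summary <- function(labels, t, tax = NULL) {
  t <- validate_asv_table(t)
  missing_asv <- setdiff(labels$asv_id, colnames(t))
  if (length(missing_asv)) stop("labelled ASV(s) absent from table")
  lv <- c("above", "neutral", "below")
  reads <- colSums(t)[labels$asv_id]
  part <- factor(labels$partition, levels = lv)
  summarize <- function(part, reads) {
    n_asv <- tabulate(part, nbins = 3)
    ab <- vapply(lv, function(l) sum(reads[part == l]), numeric(1))
    data.frame(partition = lv,
               n_asv = n_asv,
               richness_prop = n_asv / sum(n_asv),
               reads = unname(ab),
               abundance_prop = unname(ab) / sum(ab),
               stringsAsFactors = FALSE)
  }
  out <- list(overall = summarize(part, reads))
  if (!is.null(tax)) {
    lineage <- tax[labels$asv_id, "lineage"]
    if (anyNA(lineage)) stop("lineage missing from taxonomy for some ASVs")
    by_lin <- lapply(unique(lineage), function(l) {
      sel <- lineage == l
      cbind(lineage = l, summarize(part[sel], reads[sel]))
    })
    out$by_lineage <- do.call(rbind, by_lin)
  }
  out
}
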
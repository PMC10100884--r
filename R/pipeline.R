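#' Assemble a pipeline configuration
#'
#' Collects the inputs and tuning parameters of the end-to-end analysis.
#' The seed and permutation count must be set explicitly: every stochastic
#' stage derives its own sub-seed from `seed`, so re-running an identical
#' configuration reproduces byte-identical tables.
#'
#' @param asv_table,taxonomy,metadata paths to the input TSV files.
#' @param tree optional newick path (enables Faith's PD).
#' @param samples_as orientation of the ASV table file.
#' @param env_columns environmental variable column names in the metadata.
#' @param depth rarefaction depth policy: `"min"` or an integer, applied per
#'   plankton group.
#' @param seed integer master seed.
#' @param n_perm PERMANOVA permutation count.
#' @param ncm_alpha level of the neutral-model partition bands.
#' @param out_dir output directory for result tables.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(asv_table, taxonomy, metadata, tree = NULL,
                            samples_as = "rows", env_columns,
                            depth = "min", seed, n_perm = 999,
                            ncm_alpha = 0.05, out_dir) {
  if (missing(seed)) stop("pipeline seed must be set explicitly")
  if (missing(n_perm)) n_perm <- 999
  cfg <- list(asv_table = asv_table, taxonomy = taxonomy, metadata = metadata,
              tree = tree, samples_as = samples_as, env_columns = env_columns,
              depth = depth, seed = as.integer(seed), n_perm = as.integer(n_perm),
              ncm_alpha = ncm_alpha, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full community-assembly pipeline
#'
#' Reads and validates the inputs, removes singleton ASVs, splits the table
#' by plankton group and rarefies each group to even depth, then per group
#' (and per region where the analysis is region-wise) computes: alpha
#' diversity with between-region tests, Bray-Curtis PCoA and PERMANOVA,
#' geographic and environmental distance-decay fits, variation partitioning
#' (environment vs dbMEM spatial eigenfunctions), the neutral community
#' model fit with above/neutral/below partitioning and lineage summaries,
#' and Levins/Bcom/dispersal tables with between-group tests. All result
#' families are written as TSV under `cfg$out_dir` together with a run log.
#'
#' @param cfg a [pipeline_config()] object.
#' @return (invisibly) a named list of the result tables, also written to
#'   disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (f in c(cfg$asv_table, cfg$taxonomy, cfg$metadata, cfg$tree))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  counts <- read_asv_table(cfg$asv_table, samples_as = cfg$samples_as)
  tax <- read_taxonomy(cfg$taxonomy)
  meta <- read_metadata(cfg$metadata, cfg$env_columns)
  tree <- if (!is.null(cfg$tree)) read_tree(cfg$tree) else NULL
  missing_meta <- setdiff(rownames(counts), meta$sample_id)
  if (length(missing_meta))
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  meta <- meta[rownames(counts), , drop = FALSE]
  region <- meta$region
  if (any(table(region) < 2)) stop("every region needs >= 2 samples")

  counts <- filter_singletons(counts)
  groups <- split_by_group(counts, tax)
  groups <- groups[vapply(groups, ncol, integer(1)) > 0]

  res <- list()
  alpha_rows <- list(); perma_rows <- list(); pcoa_rows <- list()
  decay_rows <- list(); vpa_rows <- list(); ncm_rows <- list()
  ncm_asv_rows <- list(); part_rows <- list(); lin_rows <- list()
  niche_rows <- list()

  for (g in names(groups)) {
    tg <- rarefy_table(groups[[g]], depth = cfg$depth, seed = cfg$seed + 11)
    depth_g <- sum(tg[1, ])

    ad <- alpha_diversity_table(tg, indices = c("chao1", "shannon", "pielou"),
                                tree = tree)
    if (!is.null(tree))
      ad$faith_pd <- apply(tg, 1, alpha_diversity, index = "faith_pd", tree = tree)
    alpha_rows[[g]] <- cbind(group = g, region = region, ad)

    bc <- bray_curtis_matrix(tg)
    pc <- pcoa(bc, n_axes = 2)
    pcoa_rows[[g]] <- data.frame(group = g, sample_id = rownames(tg),
                                 region = region,
                                 PCo1 = pc$coordinates[, 1],
                                 PCo2 = pc$coordinates[, min(2, ncol(pc$coordinates))],
                                 prop1 = pc$proportion_explained[1],
                                 prop2 = pc$proportion_explained[min(2, ncol(pc$coordinates))])
    pm <- permanova(bc, region, n_perm = cfg$n_perm, seed = cfg$seed + 23)
    perma_rows[[g]] <- data.frame(group = g, pseudo_F = pm$pseudo_F,
                                  p_value = pm$p_value,
                                  n_permutations = pm$n_permutations)

    for (r in unique(region)) {
      sel <- region == r
      tr <- tg[sel, , drop = FALSE]
      tr <- tr[, colSums(tr) > 0, drop = FALSE]
      mr <- meta[sel, , drop = FALSE]
      bc_r <- bray_curtis_matrix(tr)
      geo_r <- geographic_distance_matrix(mr)
      env_r <- suppressWarnings(environmental_distance_matrix(mr, cfg$env_columns))
      for (pred in c("geographic", "environmental")) {
        pd_mat <- if (pred == "geographic") geo_r else env_r
        fit <- distance_decay_fit(bc_r, pd_mat, predictor = pred)
        decay_rows[[paste(g, r, pred)]] <-
          data.frame(group = g, region = r, predictor = pred,
                     slope = fit$slope, intercept = fit$intercept,
                     r_squared = fit$r_squared, p_value = fit$p_value,
                     n_pairs = fit$n_pairs)
      }

      spa <- pcnm_vectors(geo_r)
      # keep the predictor count well under n to leave residual df:
      # reduce the environmental block to its leading principal components
      k_env <- min(length(cfg$env_columns), max(1, floor(sum(sel) / 4)))
      env_raw <- scale(as.matrix(mr[, cfg$env_columns, drop = FALSE]))
      env_mat <- stats::prcomp(env_raw)$x[, seq_len(k_env), drop = FALSE]
      k_spa <- min(ncol(spa), max(1, floor(sum(sel) / 4)))
      vp <- variation_partition(tr, env_mat, spa[, seq_len(k_spa), drop = FALSE])
      vpa_rows[[paste(g, r)]] <- data.frame(group = g, region = r,
                                            pure_env = vp$pure_env, shared = vp$shared,
                                            pure_spa = vp$pure_spa,
                                            unexplained = vp$unexplained)

      st <- occurrence_stats(tr)
      fit <- fit_ncm(st, ci_alpha = cfg$ncm_alpha)
      labels <- partition_asvs(fit, alpha = cfg$ncm_alpha)
      ncm_rows[[paste(g, r)]] <- data.frame(group = g, region = r, m = fit$m,
                                            r_squared = fit$r_squared, N = fit$N,
                                            n_asv = nrow(fit$asv))
      ncm_asv_rows[[paste(g, r)]] <- cbind(group = g, region = r, labels)
      ps <- partition_summary(labels, tr, tax)
      part_rows[[paste(g, r)]] <- cbind(group = g, region = r, ps$overall)
      lin_rows[[paste(g, r)]] <- cbind(group = g, region = r, ps$by_lineage)
    }

    nt <- niche_dispersal_table(tg, region = region)
    niche_rows[[g]] <- cbind(group = g, nt)
  }

  res$alpha_diversity <- do.call(rbind, alpha_rows)
  res$pcoa <- do.call(rbind, pcoa_rows)
  res$permanova <- do.call(rbind, perma_rows)
  res$distance_decay <- do.call(rbind, decay_rows)
  res$vpa <- do.call(rbind, vpa_rows)
  res$ncm_fits <- do.call(rbind, ncm_rows)
  res$ncm_asv <- do.call(rbind, ncm_asv_rows)
  res$partition_summary <- do.call(rbind, part_rows)
  res$partition_by_lineage <- do.call(rbind, lin_rows)
  res$niche_dispersal <- do.call(rbind, niche_rows)

  # between-group tests on Bcom and dispersal within each region
  if (length(groups) >= 2) {
    gg <- names(groups)[1:2]
    tests <- list()
    for (r in unique(region)) {
      for (metric in c("bcom", "dispersal")) {
        va <- res$niche_dispersal[res$niche_dispersal$group == gg[1] &
                                    res$niche_dispersal$region == r, metric]
        vb <- res$niche_dispersal[res$niche_dispersal$group == gg[2] &
                                    res$niche_dispersal$region == r, metric]
        ht <- compare_groups(va, vb, test = "welch_t")
        tests[[paste(r, metric)]] <- data.frame(region = r, metric = metric,
                                                group_a = gg[1], group_b = gg[2],
                                                statistic = ht$statistic,
                                                p_value = ht$p_value)
      }
    }
    res$niche_dispersal_tests <- do.call(rbind, tests)
  }

  for (nm in names(res)) write_tsv(res[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")))
  log_lines <- c(
    paste0("planktonAssembly ", as.character(utils::packageVersion("planktonAssembly"))),
    paste0("seed: ", cfg$seed),
    paste0("n_perm: ", cfg$n_perm),
    paste0("ncm_alpha: ", cfg$ncm_alpha),
    paste0("depth policy: ", paste(cfg$depth, collapse = ",")),
    paste0("inputs: ", paste(c(cfg$asv_table, cfg$taxonomy, cfg$metadata, cfg$tree),
                             collapse = ", ")))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(res)
}
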
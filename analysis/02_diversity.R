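#!/usr/bin/env Rscript
# Alpha diversity, Bray-Curtis ordination and PERMANOVA per plankton group,
# comparing the two regions. Reads the survey written by 01_simulate_survey.R
# and writes tables under results/diversity/.

library(planktonAssembly)

env_cols <- c("Temp", "Salinity", "DO", "COD", "PHs", "Nitrate", "Nitrite",
              "Ammonium", "Phosphate", "Cu", "Pb", "Zn", "Cd", "Cr", "As")
counts <- read_asv_table("results/data/asv_table.tsv")
tax <- read_taxonomy("results/data/taxonomy.tsv")
meta <- read_metadata("results/data/metadata.tsv", env_cols)
tree <- read_tree("results/data/tree.nwk")
meta <- meta[rownames(counts), ]

dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)
counts <- filter_singletons(counts)
groups <- split_by_group(counts, tax)

alpha_all <- NULL
perma_all <- NULL
for (g in names(groups)) {
  tg <- rarefy_table(groups[[g]], depth = "min", seed = 11)
  ad <- alpha_diversity_table(tg, c("chao1", "shannon", "pielou"), tree = tree)
  ad$faith_pd <- apply(tg, 1, alpha_diversity, index = "faith_pd", tree = tree)
  ad <- cbind(group = g, region = meta$region, ad)
  alpha_all <- rbind(alpha_all, ad)

  for (idx in c("chao1", "shannon", "pielou", "faith_pd")) {
    tt <- compare_groups(ad[[idx]][ad$region == "LH"],
                         ad[[idx]][ad$region == "YLJ"], "welch_t")
    cat(sprintf("%-18s %-9s LH vs YLJ: t = %6.2f, p = %.3g\n",
                g, idx, tt$statistic, tt$p_value))
  }

  bc <- bray_curtis_matrix(tg)
  pc <- pcoa(bc, n_axes = 2)
  pm <- permanova(bc, meta$region, n_perm = 999, seed = 23)
  cat(sprintf("%-18s PERMANOVA region: pseudo-F = %.2f, p = %.4f (PC1 %.1f%%)\n",
              g, pm$pseudo_F, pm$p_value, 100 * pc$proportion_explained[1]))
  perma_all <- rbind(perma_all,
                     data.frame(group = g, pseudo_F = pm$pseudo_F,
                                p_value = pm$p_value,
                                pc1_pct = 100 * pc$proportion_explained[1],
                                pc2_pct = 100 * pc$proportion_explained[2]))
  coords <- data.frame(group = g, sample_id = rownames(tg),
                       region = meta$region, pc$coordinates)
  write.table(coords, sprintf("results/diversity/pcoa_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(alpha_all, "results/diversity/alpha_diversity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(perma_all, "results/diversity/permanova.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/diversity/\n")
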
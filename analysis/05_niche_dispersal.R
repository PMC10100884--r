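#!/usr/bin/env Rscript
# Levins' niche breadth (per taxon and community-level Bcom) and the
# shared-sequence dispersal proxy, per region, with phytoplankton-vs-
# microzooplankton t-tests. Writes results/niche/.

library(planktonAssembly)

env_cols <- c("Temp", "Salinity", "DO", "COD", "PHs", "Nitrate", "Nitrite",
              "Ammonium", "Phosphate", "Cu", "Pb", "Zn", "Cd", "Cr", "As")
counts <- read_asv_table("results/data/asv_table.tsv")
tax <- read_taxonomy("results/data/taxonomy.tsv")
meta <- read_metadata("results/data/metadata.tsv", env_cols)
meta <- meta[rownames(counts), ]

dir.create("results/niche", showWarnings = FALSE, recursive = TRUE)
groups <- split_by_group(filter_singletons(counts), tax)

tabs <- lapply(names(groups), function(g) {
  tg <- rarefy_table(groups[[g]], depth = "min", seed = 11)
  cbind(group = g, niche_dispersal_table(tg, region = meta$region))
})
nd <- do.call(rbind, tabs)
write.table(nd, "results/niche/niche_dispersal.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tests <- NULL
for (r in unique(meta$region)) {
  for (metric in c("bcom", "dispersal")) {
    va <- nd[nd$group == "phytoplankton" & nd$region == r, metric]
    vb <- nd[nd$group == "microzooplankton" & nd$region == r, metric]
    ht <- compare_groups(va, vb, "welch_t")
    cat(sprintf("%-4s %-9s phyto %.3f vs zoo %.3f: t = %6.2f, p = %.3g\n",
                r, metric, mean(va), mean(vb), ht$statistic, ht$p_value))
    tests <- rbind(tests, data.frame(region = r, metric = metric,
                                     mean_phyto = mean(va), mean_zoo = mean(vb),
                                     statistic = ht$statistic,
                                     p_value = ht$p_value))
  }
}
write.table(tests, "results/niche/niche_dispersal_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/niche/\n")
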
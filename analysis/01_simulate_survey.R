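#!/usr/bin/env Rscript
# Simulate the two-estuary survey used by the downstream analysis scripts:
# a neutrally assembled phytoplankton block (high immigration) and a
# niche-structured microzooplankton block along an environmental gradient,
# with taxonomy, 15-variable metadata and a phylogeny. Written as plain TSV
# and newick under results/data/.

library(planktonAssembly)

seed <- 1
sv <- simulate_survey(seed = seed)
paths <- write_survey(sv, "results/data")

cat("Simulated survey (seed ", seed, "):\n", sep = "")
cat("  samples: ", nrow(sv$counts), " in regions ",
    paste(names(table(sv$metadata$region)), collapse = "/"),
    " (", paste(table(sv$metadata$region), collapse = "/"), ")\n", sep = "")
cat("  ASVs:    ", ncol(sv$counts), " (",
    sum(sv$taxonomy$group == "phytoplankton"), " phytoplankton, ",
    sum(sv$taxonomy$group == "microzooplankton"), " microzooplankton)\n", sep = "")
cat("  files:\n"); for (p in paths) cat("    ", p, "\n", sep = "")
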
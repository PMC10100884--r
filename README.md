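# planktonAssembly

Community-assembly analysis for plankton metabarcoding surveys.

Estuarine phytoplankton and microzooplankton communities profiled by 18S
amplicon sequencing (ASV count tables) can be structured by two very
different forces: passive dispersal plus ecological drift (stochastic,
"neutral" assembly) or selection along environmental gradients
(deterministic assembly). This package implements the standard toolkit used
to weigh those forces against each other for two regions of a survey:

* **Input handling** — ASV table / taxonomy / metadata / tree readers,
  singleton removal (ASVs with total count 1), seeded rarefaction to even
  depth, and splitting by plankton group.
* **Diversity and ordination** — Chao1, Shannon, Pielou evenness, Faith's
  PD; Bray-Curtis dissimilarity; PCoA; one-way PERMANOVA (Adonis) with a
  label-permutation p-value; Welch and Wilcoxon two-group tests.
* **Distance-decay of similarity** — OLS of `1 − Bray-Curtis` on geographic
  (haversine, km) or environmental (z-scored Euclidean) distance.
* **Variation partitioning (VPA)** — adjusted-R² decomposition of the
  Hellinger-transformed community into pure environmental \[a\], shared
  \[b\], pure spatial \[c\] (PCNM eigenfunctions) and unexplained \[d\]
  fractions.
* **Sloan's neutral community model (NCM)** — occurrence frequency of a
  taxon with mean relative abundance *p* in communities of size *N* with
  immigration rate *m* is predicted as the Beta tail
  `freq_pred = 1 − I(1/N; N m p, N m (1 − p))`; *m* is fitted by bounded
  least squares and taxa are partitioned into above / neutral / below a 95%
  acceptance band around the prediction, with richness and read-abundance
  summaries per partition and lineage.
* **Niche breadth and dispersal** — Levins' B per taxon, its per-sample
  mean (Bcom), and the pairwise shared-sequence proportion as a dispersal
  proxy.
* **Simulators** — a neutral Dirichlet-multinomial generator whose
  marginals match the NCM exactly, a Gaussian-niche generator along a
  spatially autocorrelated gradient, lognormal metacommunities, and random
  coalescent phylogenies, so every stage is testable without sequencing
  data.

## Worked example

```r
library(planktonAssembly)

p  <- simulate_metacommunity(S = 300, lognormal_sigma = 1, seed = 7)
tb <- simulate_neutral_table(p, n_samples = 30, depth = 5000, m = 0.3, seed = 11)

fit <- fit_ncm(occurrence_stats(tb))
fit
#> Sloan neutral community model fit
#>   m = 0.3496, R2 = 0.8909, N = 5000, 300 ASVs over 30 samples

labels <- partition_asvs(fit, alpha = 0.05)
table(labels$partition)
#>
#>   above   below neutral
#>       3      18     279
```

The fitted immigration rate (0.35 against a true 0.3; the least-squares NCM
estimator is mildly biased upward, see the vignette) and the high R² say
occupancy is explained by abundance plus dispersal alone; 93% of ASVs fall
inside the 95% neutral band.

The full survey workflow lives in `analysis/01_simulate_survey.R` …
`05_niche_dispersal.R`: simulate a two-region survey (a neutral
phytoplankton block, a niche-structured microzooplankton block), then run
diversity/ordination, distance-decay + VPA, the NCM, and niche/dispersal
contrasts, writing tables under `results/`. Running them in order prints,
e.g.:

```
phytoplankton      PERMANOVA region: pseudo-F = 0.85, p = 0.7350 (PC1 11.3%)
microzooplankton   PERMANOVA region: pseudo-F = 16.96, p = 0.0010 (PC1 48.1%)
phytoplankton      LH   m = 0.388  R2 = 0.937  neutral = 98.8% of 80 ASVs
microzooplankton   LH   m = 0.006  R2 = 0.743  neutral = 75.9% of 116 ASVs
LH   bcom      phyto 13.218 vs zoo 7.945: t =  24.65, p = 3.81e-13
```

i.e. the neutrally assembled group shows no regional structure, high
immigration, wide niche breadth and high dispersal, while the
niche-structured group shows strong regional separation, distance-decay and
a poor neutral fit — the diagnostic pattern the toolkit is built to expose.
An end-to-end, byte-reproducible run over the same inputs is available as
`run_pipeline()`; see `?pipeline_config`.

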
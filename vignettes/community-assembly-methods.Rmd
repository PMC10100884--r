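---
title: "Methods: quantifying neutral and niche assembly in plankton communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neutral and niche assembly in plankton communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models behind `planktonAssembly`, the choices
made where conventions diverge, what the simulators do and do not emulate,
and the package's known limitations. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The analysis at a glance

Starting from an ASV count table (samples × taxa), taxonomy, and sample
metadata (region, coordinates, environmental variables), the workflow asks
three questions per plankton group:

1. *Do the regions differ?* Alpha diversity with two-group tests; PCoA of
   Bray-Curtis dissimilarities; one-way PERMANOVA on region labels.
2. *What structures the communities in space?* Distance-decay of similarity
   against geographic and environmental distance; variation partitioning of
   the community matrix between environmental and spatial predictors.
3. *How much of assembly is neutral?* Sloan's neutral community model, with
   an above/neutral/below partition of taxa, plus Levins' niche breadth and
   a shared-sequence dispersal proxy as corroborating traits.

## Input processing

Counts are validated as nonnegative integers with unique sample and ASV
identifiers. Two normalizations follow the conventions of amplicon surveys:

* **Singleton removal.** An ASV whose *total* count across all samples is 1
  is removed (a per-table, not per-sample, criterion). The operation is
  idempotent and never drops samples.
* **Rarefaction.** Each sample is subsampled *without replacement*
  (multivariate hypergeometric) to a common depth, by default the smallest
  sample total, with a mandatory integer seed. A single seeded draw is used
  rather than an average over draws: the downstream neutral model needs an
  integer community of exactly N reads per sample, and averaging would
  destroy that. The expected post-rarefaction count of taxon *j* in sample
  *i* is `depth · x_ij / rowsum_i`, which the test suite verifies
  empirically over 200 seeds.

## Diversity and ordination

Shannon entropy uses the natural log (the common ecology default; base
changes only rescale comparisons). Chao1 uses the bias-corrected form
`S_obs + F1(F1−1)/(2(F2+1))`, finite even without doubletons. Pielou is
`H/ln(S_obs)` and is left undefined (an error) for single-taxon samples.
Faith's PD sums the branch lengths of the subtree spanning the present
tips *including the path to the root*, so a one-tip sample already has
nonzero PD; this convention must be fixed for comparability and is stated
here because both variants circulate.

PCoA double-centers the squared distance matrix (Gower) and
eigendecomposes. Negative eigenvalues — expected for Bray-Curtis, which is
not Euclidean — are reported but excluded from the denominator of the
variance-explained proportions, and no Lingoes/Cailliez correction is
applied: corrections change the geometry silently, and the proportions are
descriptive here.

PERMANOVA is the one-way pseudo-F of Anderson computed from pairwise
squared distances, with `p = (#{F_perm ≥ F_obs} + 1)/(n_perm + 1)` under
random label permutation (default 999 permutations, explicit seed). The
implementation is the package's own — the permutation loop is the
bottleneck of the calibration experiments — and the test suite pins its
pseudo-F to `vegan::adonis2` as an independent reference.

## Distance-decay of similarity

Similarity `1 − Bray-Curtis` is regressed by OLS on the vectorized upper
triangle of the predictor distance matrix: great-circle (haversine)
distance on a sphere of radius 6371.0088 km, or Euclidean distance of
z-scored environmental variables. No log transform is applied to either
axis. The reported p-value is the OLS t-test, which treats the
n(n−1)/2 pairs as independent although pairs sharing a sample are not; this
mirrors standard practice and keeps slopes and R² comparable with published
tables. For inference that respects the dependence, a label-permutation
(Mantel-style) p-value is available via the `mantel_perm` argument.

A consequence worth spelling out: the package's null-calibration experiment
permutes the *pair-level* predictor entries, under which the OLS p-value is
exactly uniform and the rejection rate is nominal. Permuting sample labels
instead leaves the shared-sample dependence in place, and OLS calibration
under that null is not guaranteed — that is precisely why the Mantel option
exists.

## Variation partitioning

The community matrix is Hellinger-transformed (square root of row relative
abundances; every transformed row has unit sum of squares), the standard
way to make linear ordination appropriate for counts. For each predictor
set X, the redundancy-analysis R² is `SS(fitted)/SS(total)` of the
multivariate OLS of the centered response on centered X, adjusted by
Ezekiel's formula `1 − (1−R²)(n−1)/(n−p−1)` with `p` the predictor rank.
Fractions follow inclusion–exclusion:
`a = R²adj(E∪S) − R²adj(S)`, `c = R²adj(E∪S) − R²adj(E)`,
`b = R²adj(E) + R²adj(S) − R²adj(E∪S)`, `d = 1 − R²adj(E∪S)`, so
`a+b+c+d = 1` holds as exact algebra on every input. Negative adjusted
fractions are reported as-is — clipping to zero is a presentation choice
that would break the identity. The combined model is fitted on the column
*span* of `[E S]`, so totally confounded predictors (identical matrices)
are legitimate and land everything in the shared fraction; collinearity
*within* a single block is an input error. The test suite pins the four
fractions to `vegan::varpart` as an independent reference.

Spatial predictors are classical PCNM eigenfunctions: geographic distances
above the longest edge of the minimum spanning tree are replaced by four
times that threshold, the truncated matrix is double-centered and
eigendecomposed, and eigenvectors with positive eigenvalues are kept. The
published survey analyses rarely say what their "spatial variables" are;
PCNM is the field's default and is stated prominently here.
Raw latitude/longitude can be substituted by passing them as the `spa`
matrix directly. On a regular transect the leading PCNM is a smooth
broad-scale wave — but a full-period wave, not a monotone half-wave (that
shape belongs to Dray-style MEM weighting); the tests assert smoothness and
scale ordering, not monotonicity. Because a region contributes only 15–18
samples while 15 environmental variables are measured, the pipeline reduces
the environmental block to its leading principal components (at most n/4)
before partitioning, keeping residual degrees of freedom positive.

## Sloan's neutral community model

The model predicts the occurrence frequency of taxon *j* across local
communities of N individuals connected to a source pool by immigration rate
*m*: the local relative abundance is `Beta(N m p_j, N m (1 − p_j))`, and
the taxon is detected when its abundance exceeds the detection limit
`d = 1/N`, so

```
freq_pred_j(m) = 1 − I_d(N m p_j, N m (1 − p_j))
```

with `I` the regularized incomplete beta. Here N is the post-rarefaction
read depth, `p_j` the observed mean relative abundance, and `freq_obs_j`
the fraction of samples where the taxon is detected; taxa never observed
are necessarily excluded. `m` is estimated by least squares on the
untransformed frequencies, bounded to (0, 1], multi-started from
{0.01, 0.1, 0.5, 1}; the 1-D objective is smooth and the tests verify the
optimum beats every start. The fit statistic `R² = 1 − SS_res/SS_tot` can
be negative when occupancy is strongly non-neutral.

**Known bias of the estimator.** When data are generated by the model's own
sampling process (Dirichlet-with-concentration-`N m p` proportions followed
by a multinomial read draw — exactly what `simulate_neutral_table` does),
the fitted `m̂` is systematically above the generating `m`. Two causes,
both intrinsic to the standard estimator: the threshold approximation
`P(Beta > 1/N)` under-predicts the true compound (beta-binomial) detection
probability, and `p_j` estimated from finitely many samples smears the
occupancy curve (errors-in-variables). At the package's reference
conditions (S = 300 lognormal taxa, n = 30 samples, N = 5000), the median
relative bias is roughly +25% at m ≤ 0.3 and +10% at m = 0.7 — the
acceptance script recomputes these numbers at run time. Comparisons of `m`
*between* groups fitted the same way (the typical use) are unaffected in
direction; absolute values should be read with this bias in mind.

**Partitioning.** Taxa are labelled `above`/`neutral`/`below` a level-95%
acceptance band around `freq_pred`. The default band is the exact central
prediction interval of `Binomial(n_samples, freq_pred)/n_samples`. The
widely used alternative — a Wilson score interval with the prediction
plugged in as if it were an observed proportion — is retained as
`band = "wilson"` for comparability with published scripts, but it is a
confidence interval misapplied as an acceptance region: near
`freq_pred ≈ 1` its upper limit drops below 1 and it labels fully occupant
taxa "above" even when full occupancy is the modal neutral outcome (at
`pred = 0.97`, `n = 30`, the probability of observing 1.0 is 0.4). Under
the generating model the binomial band keeps ~90–95% of taxa "neutral" at
α = 0.05 while the Wilson band keeps only ~65–75%; the calibration test
runs the default. Partition summaries report richness (ASV-count) and
abundance (read-sum) proportions, overall and within lineages.

## Niche breadth and dispersal

Levins' breadth `B_j = 1/Σ_i q_ij²` (with `q_ij` the fraction of taxon j's
reads in sample i) runs from 1 (single-sample endemic) to the number of
samples (perfectly even spread) and is invariant to rescaling a taxon's
counts. `Bcom` is the unweighted mean of B over the taxa present in a
sample — unweighted because the index is a per-taxon trait being averaged,
not a community aggregate; abundance weighting is available but off by
default. When regions are analysed separately, B is computed within each
region (a taxon's spread over that region's samples only), matching
region-wise boxplot comparisons.

The dispersal proxy for a sample pair (s, u) is the symmetric mean of each
member's fraction of reads belonging to jointly present taxa; a sample's
score is its average share over all partners. Shared-sequence dispersal
measures are described in the literature sometimes as a per-taxon and
sometimes as a per-sample-pair quantity; the per-sample-pair reading is
implemented because the result is displayed and tested per community, and
a min-based variant
(proportional similarity, `Σ_j min(prop_s, prop_u)`) is available behind
`method = "min"`. Under the neutral simulator the proxy increases
monotonically with the generating immigration rate, which is the property
that justifies calling it a dispersal proxy at all; the tests verify this.

## What the simulators emulate — and what they don't

`simulate_metacommunity` draws lognormal relative abundances (default
σ = 1, a moderate spread typical of plankton surveys: a long tail of rare
taxa without letting a single taxon dominate). `simulate_neutral_table`
draws per-sample true proportions from `Dirichlet(N m p)` — whose marginals
are exactly the Beta distributions the NCM assumes, making parameter
recovery a fair test of the estimator rather than of model mismatch — then
a multinomial read draw of depth N. `simulate_structured_table` gives each
taxon a Gaussian response to an environmental gradient laid along a spatial
transect (response normalized in log space to avoid underflow for narrow
niches), with `spatial_noise` decoupling environment from space when
nonzero. Default sizes for the recovery experiments (S = 300, n = 30,
depth = 5000) keep the full calibration suite at a few seconds on one CPU
while leaving enough taxa and samples for stable medians.

The simulators deliberately omit several features of real metabarcoding
data: PCR and copy-number amplification bias, chimeras and sequencing
error (assumed removed upstream by denoising), taxon correlations beyond
shared gradients, temporal dynamics, and phylogenetic signal in niches
(the coalescent trees are independent of the niche parameters). Passing
tests therefore certify the *statistical machinery* — estimators,
calibration, algebra — not that real communities satisfy the models'
assumptions.

## Numerical and degenerate-input choices

* Zero-variance environmental variables are dropped with a warning before
  z-scoring; an all-constant environmental block is an error.
* A constant distance matrix makes the PERMANOVA pseudo-F undefined and is
  an error, as is any group of size 1.
* Distances are symmetrized after haversine evaluation to erase
  floating-point asymmetry; the binomial acceptance band is clamped to
  contain the prediction itself (discrete quantiles can otherwise sit on
  one side of an extreme prediction).
* Ties in the Wilcoxon test switch the implementation from exact
  enumeration to the tie-corrected normal approximation; exact enumeration
  is used when both groups have ≤ 10 observations and no ties.
* The rarefaction and permutation seeds are mandatory arguments — there are
  no silent defaults in pipeline mode, and `run_pipeline` derives all stage
  seeds from the single configured seed, which is why two runs of the same
  configuration are byte-identical.

## Limitations

The NCM's absolute immigration estimates carry the positive bias described
above; the distance-decay OLS p-values inherit pair dependence; VPA with
few samples and many predictors is only usable after dimension reduction,
which trades interpretability of individual variables for stability; and
the above/below partition interprets lack-of-fit taxon by taxon, so its
composition should be read jointly with the global R², not as independent
evidence.
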
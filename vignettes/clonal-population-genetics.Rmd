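---
title: "Methods: clonal structure and population genetics of microsatellite data"
author: "clonepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal structure and population genetics of microsatellite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepop)
```

# The problem

Brooding corals and other partially clonal organisms recruit both sexually
(genetically novel larvae) and asexually (fragmentation, budding,
parthenogenesis). A sample of colonies therefore mixes distinct genets with
clonal ramets of the same genet, and every downstream population-genetic
quantity — heterozygosity, F-statistics, cluster memberships — is biased if
ramets are treated as independent samples. `clonepop` implements the full
workflow for diploid codominant microsatellite genotypes: detect clones,
quantify the sexual/asexual balance, censor clones, and then estimate
differentiation, admixture structure and isolation by distance on the
clone-censored ("per-genotype") data, mirroring the dual per-individual /
per-genotype design common in this literature.

# Data model

A `genotype_matrix` stores, per individual and locus, an unordered pair of
positive integer allele sizes in base pairs; a failed genotype is missing as
a whole (half-coded calls are promoted to missing with a warning, matching
how fragment analyses score failed sample-locus combinations). Allele
identity is the fragment size itself, not a repeat index; stepwise-mutation
arithmetic divides size differences by the locus motif length carried in the
locus metadata. Genepop (2- or 3-digit) and two-columns-per-locus CSV
formats are read and written; both round-trip losslessly, which the suite
fuzz-tests with simulated matrices.

# Clone detection

Two individuals share a multilocus genotype (MLG) when their calls agree at
every locus scored in both. With missing data this relation is not
transitive, so groups are defined as connected components of the pairwise
match graph. The default `observed` policy additionally requires the scored
overlap to span at least 4 loci (configurable) — with six markers this stops
two individuals scored at disjoint loci from being declared clonemates; the
`strict` policy only matches complete genotypes. Individuals missing at all
loci are reported as unassigned rather than silently grouped.

To absorb somatic mutation and scoring error, MLGs can be collapsed into
multilocus lineages (MLLs): the distance between two MLGs is the summed
per-locus minimum number of one-motif mutational steps (the smaller of the
two allele pairings), and MLGs within a threshold (default 4 steps) merge by
single linkage. At threshold 0 and complete data the MLL partition equals
the MLG partition, which is asserted as an invariant.

# Clonal structure statistics

With $N$ individuals in groups of sizes $n_i$ and $g_i = n_i/N$:

* clonal richness $R = (N_{MLG}-1)/(N-1)$;
* Stoddart–Taylor observed genotypic diversity $G_o = 1/\sum g_i^2$, its
  expectation under full sexuality $G_e = N$, and $G = G_o/G_e$;
* evenness $E_D = G_o/N_{MLG}$;
* unbiased Simpson index $(N/(N-1))(1-\sum g_i^2)$;
* Shannon–Wiener $H' = -\sum g_i \log_{10} g_i$.

Two conventions deserve comment. $G_e = N$ is forced by the published
summary tables this workflow reproduces, where $G_e$ equals the sample size
in every population. The Shannon index uses log base 10 because
all-singleton populations then reproduce the published values exactly
($\log_{10} 19 = 1.28$, $\log_{10} 11 = 1.04$); an optional first-order
small-sample correction flag exists (default off) but does not explain the
one published non-singleton cell that disagrees with every convention we
tried, which we treat as a transcription artifact. A reproductive-mode label
is attached from configurable $G$ thresholds (fully sexual at $G = 1$,
predominantly sexual at $G \ge 0.65$, mostly sexual at $G \ge 0.5$, mixed
clonal below).

The probability of identity
$P_{ID} = \prod_l \left[\sum_i p_i^4 + \sum_{i<j}(2p_ip_j)^2\right]$
quantifies whether shared MLGs can be chance products of sexual
reproduction; the test suite checks it against exhaustive enumeration of
genotype pairs. The randomization test for sexuality permutes allele copies
among individuals within each locus (preserving the missingness pattern),
recounts MLGs, and reports $p = (1 + \#\{N^*_{MLG} \le N_{MLG}\})/(B+1)$ —
the add-one convention avoids zero p-values. The test is conservative on
fully sexual data (the observed MLG count is already maximal), which the
suite verifies empirically at $\alpha = 0.05$.

# Per-population statistics

Heterozygosities are averaged over loci, with both the biased
($1-\sum p^2$) and Nei-unbiased ($2n/(2n-1)$-corrected) expected forms.
$F_{IS}$ is the Weir–Cockerham within-population $f$ from variance
components summed over alleles and loci, not the naive $1 - H_o/H_e$ ratio:
the two disagree exactly where clone-censored coral data show strong
heterozygote excess, and published values in this literature are consistent
with the variance-components estimator. Confidence intervals are a
percentile bootstrap over loci. The Hardy–Weinberg exact test conditions on
allele counts (Levene's distribution); genotype arrays are enumerated
exhaustively when the array space is small and sampled by allele-copy
permutation otherwise, with the number of heterozygotes as the one-sided
deficit statistic. The null-allele screen is a deliberately simple
homozygote-excess test plus the Chakraborty estimate
$r = (H_e-H_o)/(H_e+H_o)$ — a stand-in for full scoring-error diagnostics,
which are out of scope. Per-locus p-values get Benjamini–Hochberg
adjustment; raw values are also kept.

# Differentiation

Pairwise $\theta$ (F\_ST) uses the Weir–Cockerham variance components
$a$ (among populations), $b$ (among individuals within populations) and $c$
(within individuals): $\theta = \sum a / \sum(a+b+c)$ over alleles and loci,
with missing calls excluded per locus and monomorphic loci contributing
nothing. The implementation follows the closed-form mean-frequency
formulas; the test suite re-derives the components through an independent
ANOVA mean-squares route and requires agreement to $10^{-12}$. Negative
estimates are reported as computed — truncation is left to downstream
choices. Significance permutes individuals between the two populations
keeping sizes, again with add-one p-values. Regional estimates pool
populations by a user mapping before the same computation.

# Admixture clustering and ΔK

The Gibbs sampler (implemented in C++ for speed, driven by R's RNG so runs
are bit-reproducible given a seed) targets the no-linkage admixture model:
allele copy $c$ of individual $i$ originates in cluster $k$ with probability
$Q_{ik}$ and then carries allele $a$ with probability $P_{kla}$. Sweeps
alternate sampling origins $Z$, $P \mid Z \sim \mathrm{Dirichlet}(\lambda +
\text{counts})$ and $Q_i \mid Z \sim \mathrm{Dirichlet}(\alpha +
\text{copy counts})$, with a single shared $\alpha$ updated by a Metropolis
random walk on $\log \alpha$ (proposal sd 0.05, uniform prior on (0, 10]).
The estimated log probability of data is the usual harmonic adjustment
$\overline{\ell} - \mathrm{var}(\ell)/2$ over the post-burn-in
log-likelihood trace; on an enumerable two-individual toy it sits within a
few tenths of the exact Dirichlet-multinomial marginal, and the K = 1
posterior mean of $P$ matches the analytic Dirichlet posterior mean.

Design choices made here: allele frequencies are independent across
clusters (the correlated-frequencies F-model is not implemented); exact
replication of any particular external program is impossible anyway —
different RNG, different defaults — and ΔK-based model selection is robust
to this choice on well-separated simulations, which is what the acceptance
suite demonstrates. The optional location prior is a documented
simplification: it augments $\alpha$ with $r$ times the population's
current assignment proportions. Desk-scale defaults (burn-in 2&nbsp;000,
10&nbsp;000 sweeps, 3 replicates, K ∈ [1, 6]) keep a full scan in minutes;
publication-scale schedules remain configurable.

ΔK is Evanno's $|L(K+1) - 2L(K) + L(K-1)| / \mathrm{sd}(\ln P(D))$ over
replicate runs; the full table is returned, not only the argmax, because
secondary peaks are themselves informative. Replicate label switching is
resolved by greedy correlation matching of Q columns, verified exhaustively
against all permutations at small K. Cluster assignment applies the
conventional strict threshold (membership > 0.75 by default).

# Multivariate companions and isolation by distance

PCA and DAPC act on individuals × allele-count tables (counts in {0, 1, 2},
population-mean imputation of missing cells, imputation mask retained). DAPC
retains the PC axes explaining ≥ 90% of variance by default — the source
workflow does not state its retained-axis count — and a stratified k-fold
cross-validation helper guards against overfitting arbitrary groups. Nei's
standard (1972) and unbiased (1978) distances are provided, 1972 default;
infinite distances at fixed differences are capped and flagged. The minimum
spanning network processes Kruskal edges by weight level so tied co-minimal
edges are all retained; with distinct weights it equals the unique MST,
verified against exhaustive enumeration of spanning trees.

Isolation by distance regresses $\theta/(1-\theta)$ on pairwise geographic
distance. Over-water distances cannot be derived from coordinates, so a
labeled distance matrix is the primary input and great-circle haversine
(Earth radius 6371 km) is only a fallback. Both the OLS F-test p and the
Mantel permutation p (999 permutations by default, add-one convention) are
reported, since published workflows are often ambiguous about which they
used.

# The simulator and what passing tests mean

The generator draws ancestral allele frequencies from a Dirichlet and deme
frequencies from $\mathrm{Dirichlet}(\bar p (1-F)/F)$ — the F-model — so
island-mode simulations have an analytic expected F\_ST equal to
`target_F`; this is what makes differentiation recovery checkable at desk
scale. Stepping-stone mode applies the same Dirichlet drift per adjacent
step, giving monotone divergence with index distance (`target_F` is then
the adjacent-deme differentiation). Within a deme, $\lceil(1-c)n\rceil$
founders are Hardy–Weinberg draws; the remaining individuals copy a
uniformly chosen founder (clone groups are stars around founders — copies
of copies are not modeled), then optionally mutate one allele per locus by
one motif step. Null-allele carriers appear homozygous for the visible
allele; null homozygotes become missing; finally calls drop out
independently at the missing rate. Truth (founder/copy status, parent ids,
deme frequencies) is recorded before corruption.

Default parameters mirror the study system this package was built around:
nine demes with the observed sample sizes (11–56), six loci with di-, tri-
and tetranucleotide motifs, ~10% clonal copies (196 distinct genotypes
among 217 colonies), 24% missing data and moderate differentiation. The
simulator emulates drift-induced structure, clonality, missingness and null
alleles; it does **not** emulate linkage, selection, scoring error beyond
null alleles, triploid/chimeric multi-allele samples, or oceanographic
dispersal. Tests passing on simulated data therefore validate the
estimators under their own model assumptions — they do not certify behavior
on real electropherogram-derived data with correlated genotyping failure.

# Numerical choices and problem sizes

Add-one p-values everywhere a permutation test appears; enumeration bounds
(`max_tables`, default 2×10⁵ arrays) switch the HWE test to Monte Carlo;
non-integer mutational steps round to the nearest step with a warning;
degenerate Dirichlet draws fall back to the normalized shape; Q entries are
floored at 10⁻¹² to keep log densities finite. The validation suite sizes
its simulations for a single CPU: differentiation recovery uses 8 demes ×
20 individuals × 6 loci over 200 seeds per target; cluster-number selection
uses three demes of 30 at F\_ST 0.2 with 8 loci, K ∈ [1, 5] × 3 replicates
× 5 experiment seeds; clonality recovery uses single demes of 100 across
c ∈ {0, 0.25, 0.5, 0.75}. These sizes were chosen so each check is decided
by its statistics (Monte-Carlo CIs, binomial error bands) rather than by
runtime.

# Known limitations

* The admixture model omits the correlated-frequencies prior and linkage
  model; K selection on weakly differentiated data will be less sensitive
  than with the F-model.
* The location prior is a simplification, not a re-implementation of any
  specific published prior.
* The null-allele screen is a homozygote-excess test only; it cannot
  separate null alleles from inbreeding or Wahlund effects.
* MLG matching under the observed-overlap policy can chain through
  intermediate genotypes (single linkage); with heavy missingness the
  partition depends on the overlap threshold.
* Polyploid and multi-allele (> 2 peaks) samples are out of scope; inputs
  must already be biallelic per locus.
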
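---
title: "Quantifying community assembly processes from OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community assembly processes from OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Marine prokaryotic communities turn over in space and time, and a central
question is *why*: are differences between communities driven by
deterministic environmental selection, by limits on dispersal, by
homogenizing dispersal, or by ecological drift that no single process
dominates? `otuassembly` implements the two-step null-model framework that
answers this from three inputs — an OTU/ASV count table, a rooted
phylogeny over its taxa, and sample metadata — together with the
surrounding multivariate analyses a seasonal survey of this kind uses
(diversity, ordination, permutation tests, spatial variation partitioning,
seasonal indicator taxa and co-occurrence networks).

## The null-model core

**betaMNTD and betaNTI.** For samples $i$ and $j$, the between-community
mean nearest taxon distance is

$$\beta\mathrm{MNTD}_{ij} = \tfrac12\Big(\sum_{k \in i} f_{ki}\,
\min_{l \in j} d_{kl} + \sum_{l \in j} f_{lj}\, \min_{k \in i} d_{lk}\Big),$$

where $d_{kl}$ is the patristic (tree) distance between taxa and $f$ are
relative abundances (weighted variant) or $1/\text{richness}$ (unweighted).
The null model shuffles taxon labels across the tips of the phylogeny —
the regional pool is all taxa present in the filtered table — and
recomputes betaMNTD for every pair in each of `n_null` replicates (999 by
default). The standardized effect size
$\beta\mathrm{NTI} = (\mathrm{obs} - \mu_{\mathrm{null}})/\sigma_{\mathrm{null}}$
flags selection: values above $+2$ indicate heterogeneous selection
(communities more phylogenetically divergent than chance), below $-2$
homogeneous selection. One shuffle is shared by all pairs within a
replicate (matrix-wise nulls), and the shuffle is applied to the
precomputed patristic matrix rather than by re-traversing the tree; the
two are algebraically identical, and the kernel that locates each taxon's
nearest neighbour in the other sample is compiled (Rcpp) because it
dominates the cost of 999 replicates.

**RCbray.** Where $|\beta\mathrm{NTI}| < 2$, compositional turnover is
compared with a null that assembles communities stochastically from the
regional pool: each null community keeps its sample's observed richness
and read total; membership is drawn without replacement with probability
proportional to regional occupancy, each member receives one read, and
remaining reads are assigned multinomially in proportion to regional
relative abundance. The observed Bray–Curtis value is placed in the null
distribution and rescaled to $[-1, 1]$, ties counting half so the score
is symmetric under exchanging observation and null. $RC_{bray} > +0.95$
indicates dispersal limitation, $< -0.95$ homogenizing dispersal, and the
band between is "undominated". The regional pool defaults to the table
itself but can be supplied explicitly (`pool_occupancy`, `pool_abundance`),
which is also what makes exact self-calibration checks possible.

**Classification and summaries.** `classify_processes()` applies the
two-step rule pair by pair and `summarize_processes()` reports the
percentage of each of the five processes within months and between month
pairs. Pairs whose betaNTI null is degenerate (zero SD, e.g. equidistant
star-like geometry or identical memberships) are excluded and counted,
never silently imputed.

## Surrounding analyses

Alpha diversity (Faith's PD including the root path, richness, Shannon in
bits, Pielou evenness), Bray–Curtis and weighted/unweighted UniFrac
distances, PCoA with negative eigenvalues reported, ANOSIM, PERMANOVA,
simple and partial Mantel tests (one-tailed positive, matching the
distance-decay table convention), PCNM spatial eigenfunctions, forward
selection with the double-stopping rule (inclusion alpha *and* the global
adjusted-$R^2$ ceiling), and variation partitioning over environment,
linear trend and PCNM sets. The partitioning is computed by
inclusion–exclusion over distance-based RDA adjusted $R^2$ of the seven
set combinations, so the eight fractions sum to the full-model adjusted
$R^2$ exactly (machine precision); negative fractions are kept internally
and truncated to zero only for display, following standard practice.
Seasonal-specific OTUs are the intersection of a correlation-based
indicator analysis (point-biserial $r$, max-$r$ label-permutation test)
and a negative-binomial likelihood-ratio test, required to agree on the
season. Co-occurrence networks use Spearman correlations with strict
thresholds (edge iff $\rho > 0.7$ *and* $p < 0.001$; positive
correlations only) and fast-greedy modularity modules.

Established packages stand behind the standard steps — ape and phyloseq
for trees and UniFrac, vegan for the permutation and ordination machinery,
picante for Faith's PD, edgeR for TMM/CPM normalization, igraph for
modularity — while the null models, the classifier, the NB-LRT and the
indicator test are implemented in this package and validated against
independent brute-force oracles and cross-references in the test suite.

## Design choices where the design was open

- **Shannon base**: log2, with a `base` argument; Pielou evenness uses the
  same base (it cancels).
- **Weighted UniFrac**: non-normalized by default; the normalized variant
  is one flag away. Both conventions circulate; defaults follow the
  QIIME-era toolchain.
- **Temporal control matrix** for partial Mantel tests: binary
  same/different month — the weakest assumption that still controls for
  season as a category.
- **Abundance filter**: pooled relative abundance with strict `>`, so one
  global taxon list results (a per-sample variant would produce
  sample-dependent lists).
- **Rarefaction**: without replacement (multivariate hypergeometric),
  seed-controlled, applied per replicate sample.
- **NB-LRT dispersion**: a single common dispersion maximizing the
  Cox–Reid adjusted profile likelihood across OTUs. This is a deliberate
  simplification of tagwise empirical-Bayes shrinkage: it changes
  individual p-values slightly, and the test suite shows the resulting
  test holds its nominal size on null negative-binomial data. Per-OTU
  maximum likelihood is available (`dispersion = "tagwise"`).
- **Indicator association**: plain point-biserial $r$ (not the
  group-equalized variant); significance from permuting sample labels with
  the maximum-$r$ statistic.
- **Module tie-break**: when no partition improves on modularity zero
  (e.g. a single clique), connected components are returned rather than
  the arbitrary split at which the greedy merge happens to stop.
- **Geographic distance**: Euclidean on decimal degrees by default (the
  convention of the "Geo" rows in distance-decay tables), great-circle km
  behind a flag.

## The synthetic-data generator

Every stage is testable without survey downloads because
`simulate_communities()` produces datasets whose generating process is
known:

- a pure-birth phylogeny rescaled to unit depth;
- per-taxon environmental optima evolved by Brownian motion
  ($\sigma^2 = 25$ over the unit-depth tree, centred at 22 °C), giving the
  phylogenetic trait signal that betaNTI needs in order to see selection;
- month-level environments following the temperature regime of a temperate
  bay survey (May 17.48 ± 2.36 °C, Aug 28.09 ± 0.53 °C, Oct
  19.55 ± 1.26 °C), with 0.5 °C station-to-station spread;
- Gaussian environmental filtering of width `sigma_sel` applied to a
  heavy-tailed regional abundance profile (log-normal, $\sigma = 2$ —
  chosen so per-sample occupancy is realistically partial; a lighter tail
  makes every taxon present in every sample and degenerates the
  nearest-taxon null);
- dispersal limitation as per-station multiplicative log-normal drift of
  the local pool (`dispersal_sd`). Divergent abundances over a largely
  shared membership are exactly the signature RCbray is built to flag; a
  Dirichlet-resampling alternative was rejected because with a
  heavy-tailed pool it perturbs only the rare tail, driving both observed
  and null dissimilarities to saturation where the score is uninformative;
- multinomial read sampling as drift, and `plant_season_otus()` for
  ground-truth seasonal indicator taxa (fold-enrichment with multinomial
  re-normalization to the original depth).

What the generator does *not* emulate: taxon–taxon interactions,
sequencing error and chimeras, compositional correlations induced by a few
dominant blooms, or spatially continuous dispersal kernels. Passing
recovery tests therefore demonstrate that the inference machinery detects
the processes it targets when they are present in this idealized form —
not that any particular real dataset is dominated by them.

## Numerical choices and degenerate inputs

- Null SDs below $10^{-12}$ mark a pair's betaNTI as missing (flagged),
  since the standardization is meaningless; classification skips and
  counts such pairs.
- RCbray ties take weight 0.5; scores are clamped to $[-1, 1]$.
- Distance matrices are validated on construction (symmetry to $10^{-8}$,
  then symmetrized; diagonal forced to zero; negatives rejected).
- Exhaustible permutation sets (tiny $n$) are handled by vegan's complete
  enumeration; permutation p-values are never below $1/(n_{perm}+1)$.
- Every stochastic function takes a `seed` and uses an isolated RNG scope,
  so identical inputs give bit-identical outputs; the pipeline derives one
  sub-seed per stage from the master seed and records all of them in its
  manifest.

## Problem sizes used in validation

The shipped tests and the acceptance script run at sizes chosen to keep a
full validation in the minutes range while preserving the statistical
structure: oracle checks on 50 random trees of up to 16 tips; null-model
calibration at 200 taxa x 24 samples x 199 nulls x 5 seeds; scenario
recovery at 150-300 taxa, 8-12 stations, 2,000-26,000 reads; ssOTU
recovery at 200 taxa x 72 samples with 30 planted OTUs per month at
8-fold enrichment; survey-shaped end-to-end runs at 12 stations x 2
replicates x 3 months. Survey-scale analyses (thousands of taxa, 999
nulls) use the same code paths and scale linearly in pairs x nulls.

## Known limitations

- The betaNTI tip-shuffle null treats the regional pool as the filtered
  table; unobserved regional taxa are invisible to it.
- The RCbray null fixes richness and reads per sample; variants that fix
  richness only are published, and results can differ near the +-0.95
  thresholds.
- The common-dispersion NB-LRT is anti-conservative for OTUs with
  strongly atypical dispersion; use `dispersion = "tagwise"` when that
  matters.
- Process percentages from any single survey depend on its sampling
  design; the five-way classification is a coarse summary, not a
  mechanistic decomposition.
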
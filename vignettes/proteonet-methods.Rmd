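---
title: "Methods: longitudinal proteome dysregulation and network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal proteome dysregulation and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteonet)
```

proteonet analyses longitudinal label-free proteomics of a two-condition
(healthy vs disease) study with replicated collections across life, and
asks three questions: which proteins change in response to disease rather
than normal ageing, what temporal shapes those changes take, and whether
the altered proteins occupy distinctive positions in the protein
interaction network. This vignette records the models, the tunable
parameters, the numerical choices, and what the synthetic-data tests do and
do not establish.

## Study design and the synthetic generator

The emulated design collects brains from both conditions at days 5, 19, 31
and 46 after eclosion, plus days 54 and 80 for healthy animals only, with
three biological repeats each measured by at least two technical repeats.
`synthetic_config()` encodes these as its defaults, along with 1854 shared
proteins of which 228 carry a planted alteration.

Protein baselines are drawn log10-normally (mean 6, sd 0.8 in log10 units,
i.e. ion-intensity-like magnitudes around 10^6^). Planted alterations are
multiplicative on the linear scale with fold change `effect_size` (default
4) and follow four temporal archetypes: (1) constitutively elevated in
disease, (2) constitutively reduced, (3) rising with age in both
conditions, (4) declining with age in disease only. Archetype 3 ramps over
the full lifespan (days 5-80); archetype 4 ramps over the disease
condition's own collection window (days 5-46) so the configured fold
change is actually realised by the last disease collection rather than at
a never-observed age.

Biological noise is log-normal with CV `noise_cv` (default 0.2); technical
repeats share their biological repeat's expectation and add noise at half
that CV. Missingness (default rate 0.05) is intensity-dependent: entries
are removed with probability proportional to their low-abundance rank,
mimicking a detection floor; each sample always keeps at least one
observed value so per-run minimum imputation stays defined. Networks are
Erdos-Renyi or preferential-attachment graphs with uniform edge confidence
scores, an optional embedded clique whose edges score at least 0.9, and an
optional set of nodes given extra random edges (a planted high-centrality
set). All generators derive per-component seeds from the single root seed,
so outputs are bit-reproducible.

What the generator does *not* emulate: correlated co-regulation between
proteins, peptide-level interference, retention-time or ion-mobility
artefacts, batch effects, and any dependence between a protein's network
position and its abundance dynamics. Tests that pass on this generator
therefore validate the statistical machinery, not the biology of any
particular real dataset.

## Preprocessing

Hi3 rollup estimates a protein's abundance per sample as the mean of its
three most intense peptides; proteins with fewer than three peptides use
all available ones and are flagged rather than dropped, keeping proteome
coverage at the cost of a noisier estimate. Missing entries are imputed
with the minimum observed abundance of the same sample (run), the
detection-floor convention. Quantile normalisation (via limma, ties
averaged) then forces every sample onto the mean of the column-sorted
distributions; it is applied jointly across all conditions and days so
that later stages can compare them. For PCA and profile work the matrix is
log10-transformed and each protein is z-scored with the sample (n-1)
standard deviation; constant rows map to zeros and are flagged.

One subtlety worth recording: with the tie-averaging rule, quantile
normalisation is exactly idempotent and produces exactly identical column
distributions only on tie-free data. Minimum-imputed entries are ties by
construction, and columns with different numbers of imputed entries end up
with slightly different sorted vectors. The test suite therefore checks
distribution identity and idempotence on complete data, and rank
preservation everywhere.

## Consensus differential abundance

Three detectors span the statistical families commonly applied to
time-course expression data. Each returns per-protein p-values,
Benjamini-Hochberg q-values (`bh_adjust()`, applied per detector), and a
protein is declared significantly altered when at least `votes = 2` of the
detectors give q < 0.05 — the two-method consensus rule.

* **Moderated F** (`detect_moderated_f()`): per-protein linear models on
  log10 abundances with condition, day (categorical) and interaction.
  Residual variances are shrunk toward a common prior by moment-matching a
  scaled inverse-chi-square distribution to the observed variances
  (prior df `d0 = 4 + 2 m^2 / v`, scale `s0^2 = m (d0-2)/d0` from the mean
  `m` and variance `v` of the per-protein variances). The moderated F uses
  the posterior variance and `df2 = df_res + d0`; when the observed
  variances are homogeneous the prior df diverges and the statistic
  reduces to the ordinary pooled-variance F.
* **Negative-binomial LRT** (`detect_nb_lrt()`): abundances are scaled by
  median-of-ratios size factors and rounded half-to-even to pseudo-counts;
  a per-protein method-of-moments dispersion (pooled over replicated
  design cells, floored at 1e-8 and capped at 10) is shared by the full
  and reduced GLMs, and the deviance difference is referred to chi-square.
  All-zero proteins are reported with p = 1 and a flag.
* **Polynomial LRT** (`detect_polynomial_lrt()`): Gaussian likelihood
  ratio of a polynomial-in-day trend (default degree 2) that differs by
  condition against a shared trend, `n log(RSS0/RSS1)` on chi-square with
  the parameter-count difference. Degree 0 degenerates to a two-group
  comparison.

Design choices: technical repeats are averaged into their biological
repeat before fitting (pseudo-replication would otherwise inflate
significance); condition contrasts use only the days observed in both
conditions, because the healthy-only late collections carry no
between-condition information in an unbalanced factorial; the ageing
analysis runs the same detectors on healthy samples alone with a
day-effect vs intercept contrast. Rows that the reduced model already fits
to machine precision (for example rows made constant by quantile
normalisation) are assigned a zero statistic rather than a roundoff
ratio.

Recovery of planted alterations is assessed against the union of the
disease and ageing consensus sets: archetype-3 proteins are identical in
both conditions by construction and can only be found by the ageing
analysis, exactly as in the original two-analysis design.

## Profile clustering and cluster-count selection

Significant proteins are summarised as per-(condition, day) mean log10
z-scores and clustered with a diagonal-covariance Gaussian mixture fitted
by EM. Numerical choices: variance floor 1e-6 per dimension; five
k-means++-style random restarts plus one deterministic
hierarchical-clustering initialisation, keeping the best final
log-likelihood; convergence at a relative log-likelihood change of 1e-8;
the log-likelihood trace is checked to be non-decreasing on every fit.
Restarts in which a component collapses onto (nearly) a single point —
effective size below 2 or all variances at the floor — are flagged
degenerate and discarded when any non-degenerate restart exists: a
collapsed component inflates the log-likelihood by roughly
`d log(1/sqrt(2 pi floor))` without modelling anything.

`bic_score()` implements two penalties. The `"clusters"` mode is
`-2 ln L + ln(n) k` with k the number of clusters; the `"parameters"` mode
uses the standard free-parameter count of a diagonal mixture,
`k(2d+1) - 1`. Model selection (`select_cluster_count()`) defaults to the
parameter-count penalty: with ~10 profile dimensions one added component
buys tens of log-likelihood units while the cluster-count penalty charges
only `ln(n) ~ 5`, so the latter runs to `k_max` on essentially any data of
this shape. The cluster-count formula remains the default of
`bic_score()` itself and both modes are exposed. `k_max` defaults to
`min(n, 30)`: fits with k approaching n are degenerate by construction.
Ties in BIC break toward smaller k, and degenerate fits are excluded from
the argmin.

On complete four-archetype data at the generator's default noise the
selector finds k = 4 with adjusted Rand index near 1 (the suite requires
at least 8 of 10 seeds and mean ARI at least 0.9, on 400-protein/132-altered
datasets). Under the full study conditions — including minimum-imputation
noise — archetypes 2 and 4 partially merge, because heavily imputed
disease samples pull both shapes onto the detection floor; the pipeline
reports whatever k the data support. This is a property of floor
imputation, not of the mixture machinery.

## Network statistics of an altered set

The analysis network is an undirected simple graph with STRING-style
combined confidence scores; edges below 0.5 are removed on reading, scores
stored as 0-999 integers are auto-detected and divided by 1000. The
analysis subgraph is induced on the identified-protein universe and
reduced to its largest connected component (ties broken toward the
component containing the lexicographically smallest id, deterministically).

Four statistics summarise a node set: mean degree and mean normalised
betweenness computed on the whole analysis network; mean unweighted
shortest-path length between ordered pairs within the set, with paths
running through the whole network; and the size of the largest connected
component of the subgraph induced on the set alone. The null distribution
samples sets of the same size uniformly without replacement from the
analysis network's nodes (10,000 samples by default; the same samples are
reused for all four statistics). Empirical P values are one-sided with
tails fixed a priori — upper for degree, betweenness and LCC size, lower
for shortest path (closeness is the interesting direction) — and use the
add-one estimator `(1 + extreme) / (1 + n)` so P is never exactly zero;
the raw proportion is available. Betweenness is normalised by
`(n-1)(n-2)/2`; every downstream quantity (percentiles, empirical P) is
invariant to that constant.

Hubs and bottlenecks are nodes strictly above the 90th percentile
(linear-interpolation quantiles over the analysis network's nodes) of
degree and betweenness respectively; the four-way classification follows
from the two indicators.

## Dense modules (MCODE)

The module detector follows the MCODE scheme: a vertex is weighted by the
order of the highest k-core of its closed neighbourhood times that core's
density; modules grow greedily from the highest-weight unassigned vertex,
including neighbours whose weight exceeds `seed_weight * (1 - VWP)`
(VWP = 0.2 by default), breadth-limited to depth 100. Haircut iteratively
removes degree-1 module vertices; modules lacking a 2-core are dropped;
vertices belong to at most one module; score = density x size with
density `2E / (V(V-1))` (graphs are simple). Parameters default to the
canonical published values, and a reporting cutoff (`score > 10` in the
emulated study) is applied after search, not during it. Equal vertex
weights break lexicographically. For the modules-of-interest view the
package induces the subgraph on the altered proteins plus their direct
neighbours before clustering, compensating for proteins unobserved by MS.

## Overrepresentation

Fisher/hypergeometric enrichment restricts every term to the supplied
background universe first (the custom-background convention), drops terms
with fewer than 3 members after restriction, computes the one-sided
(greater) hypergeometric p per term and BH-adjusts across tested terms;
zero-overlap terms report p = 1. The ranked-list mHG statistic takes the
minimum over prefixes of the hypergeometric upper-tail probability of the
prefix overlap, reports the minimising prefix, and assesses significance
by label permutation (exact mHG p-values are a possible extension);
duplicate ids in a ranking are an error rather than silently broken ties.

## Pipeline and reproducibility

`run_pipeline()` wires the stages in study order — preprocess, disease and
ageing consensus, set comparison, profile clustering, network statistics,
module detection, enrichment — validates its configuration up front
(findings, not exceptions), names the failing stage on error, and returns
a report whose content hash is identical across runs with the same
configuration. Every stochastic stage derives its seed from the single
root seed.

## Problem sizes used by the tests

The suite exercises the generator defaults at reduced sizes chosen as the
smallest that make the statistical assertions stable: 2000 null proteins
for detector type-I error, 900 proteins / 180 altered for consensus
recovery, 400/132 over ten seeds for cluster-count recovery, 300-node
networks for planted-clique and planted-centrality detection, brute-force
graph oracles on all connected graphs up to 8 nodes over 50 seeds, and
exhaustive hypergeometric enumeration up to a 20-protein universe.
`scripts/acceptance.R` re-runs the pipeline at the full default scale
(1854 proteins, 228 altered, 1000-node network, 10,000 permutations).

## Known limitations

Exact reproduction of the emulated study's published network counts
requires its exact inputs (the fly STRING v10 links file and the published
protein lists), which must be supplied externally. MCODE module counts are
sensitive to unstated upstream parameters. The NB detector applies
count-family models to rounded intensity ratios — a faithful analogue of
applying RNA-seq tools to proteomics intensities, but not a principled
count model. The mHG permutation p is approximate. The consensus vote
treats detectors as exchangeable even though their statistical families
overlap partially.
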
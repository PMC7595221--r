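# proteonet

Longitudinal label-free proteomics meets protein interaction networks.
proteonet is an R package for studies that track a brain (or other tissue)
proteome across life in two conditions — for example an inducible
neurodegeneration model against healthy controls — and ask:

1. **Which proteins are altered by disease rather than by normal ageing?**
   A pluggable consensus of time-course detectors: a moderated F-test with
   empirical-Bayes-style variance shrinkage, a negative-binomial
   likelihood-ratio test on pseudo-counts, and a polynomial
   likelihood-ratio test. A protein is called significantly altered when
   at least two detectors agree at Benjamini–Hochberg FDR 5%:

   significant(p) ⇔ #{detectors d : q_d(p) < 0.05} ≥ 2.

2. **What temporal shapes do the alterations take?** Diagonal-covariance
   Gaussian mixtures fitted by EM on per-(condition, day) z-scored
   profiles, with the number of clusters selected by BIC
   (−2 ln L + ln(n)·k in the cluster-count convention, or the standard
   free-parameter count; selection uses the latter).

3. **Do altered proteins occupy special network positions?** For a node
   set S in the interaction network: mean degree, mean shortest-path
   length, induced largest-connected-component size and mean betweenness
   centrality, each tested against 10,000 uniformly resampled node sets
   with one-sided empirical P values; strict >90th-percentile
   hub/bottleneck classification; MCODE dense-module detection
   (k-core-based vertex weights, greedy expansion, haircut, score =
   density × size); and Fisher/hypergeometric overrepresentation against a
   custom background, plus a ranked-list minimum-hypergeometric (mHG)
   statistic.

A synthetic-data module (`synthetic_config()`, `simulate_abundance()`,
`simulate_peptides()`, `simulate_network()`, `simulate_annotations()`)
reproduces the statistical structure of such a study — log-normal
abundances, 3 biological × 2 technical repeats, unequal time points per
condition, detection-floor missingness, four planted temporal archetypes,
and networks with planted cliques and planted high-centrality sets — so
the entire pipeline runs and is tested without any external downloads.

## Worked example

```r
library(proteonet)

cfg <- pipeline_config(
  synthetic = synthetic_config(n_proteins = 300, n_altered = 60,
                               n_nodes = 250, edge_param = 0.03,
                               planted_clique = 8, seed = 42),
  permutations = 2000, seed = 42)
report <- run_pipeline(cfg)
print(report)
```

```
Pipeline report
  proteins: 300, samples: 60
  significant (disease): 52; (ageing): 15
  selected clusters: 3
  network LCC: 246 nodes / 512 edges
  network P: mean_degree=0.7841, mean_shortest_path=0.4433, lcc_size=0.901, mean_betweenness=0.6037
  modules: 3
  hash: 3e4fd7990a988877d35e0b7c2aafbd5d
```

Reading the output: of 300 simulated proteins (60 with planted
alterations at fold change 4), the two-vote consensus calls 52
significantly altered in the disease contrast and 15 in the healthy-only
ageing analysis. The significant profiles cluster into 3 temporal shapes
by BIC. The simulated interaction network's largest connected component
has 246 nodes and 512 edges; because the significant proteins were placed
on the network at random here, their four permutation P values are
unremarkable (all > 0.4) — planting a high-centrality set instead drives
the degree P below 10⁻³ (see the tests). MCODE finds 3 dense modules, the
top one being the planted 8-clique. The hash is the deterministic content
fingerprint: re-running the same config reproduces it exactly.

Individual stages are ordinary tibble-in/tibble-out functions that
compose with the pipe — e.g.
`simulate_abundance(cfg) |> ... |> impute_missing() |> quantile_normalise()`,
then `run_consensus()`, `profile_matrix()`, `select_cluster_count()`
(with `autoplot()` for the BIC trace), `network_significance()`,
`classify_hub_bottleneck()` (with `plot_hub_bottleneck()`), `mcode()` and
`fisher_overrepresentation()`. Fitted objects have broom-style `tidy()`
and `glance()` methods.

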
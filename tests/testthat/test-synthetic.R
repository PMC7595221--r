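# Generators: determinism, null configuration, planted-effect magnitudes,
# network edge counts and annotation closure.

small_cfg <- function(...) {
  defaults <- list(n_proteins = 80, n_altered = 16, n_nodes = 60,
                   edge_param = 0.05)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

test_that("config validation rejects impossible designs", {
  expect_error(synthetic_config(archetype_fractions = c(0.5, 0.5, 0.1, 0)),
               "summing to 1")
  expect_error(synthetic_config(n_proteins = 10, n_altered = 11), "n_altered")
  expect_error(synthetic_config(n_tech = 0), "n_bio and n_tech")
  expect_error(synthetic_config(n_bio = 0), "n_bio and n_tech")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate")
  expect_error(synthetic_config(n_nodes = 5, planted_clique = 6),
               "planted_clique")
})

test_that("null configuration plants nothing and loses nothing", {
  cfg <- small_cfg(n_altered = 0, missing_rate = 0, seed = 2)
  sim <- simulate_abundance(cfg)
  expect_equal(sum(is.na(as.matrix(sim$abundance[-1]))), 0)
  expect_length(sim$truth$altered_ids, 0)
  # one sample per (condition, day, bio, tech) combination
  expect_equal(nrow(sim$meta), (4 + 6) * 3 * 2)
  expect_equal(ncol(sim$abundance) - 1, nrow(sim$meta))
  expect_false(any(duplicated(sim$meta$sample_id)))
})

test_that("generators are bit-identical under the same seed", {
  cfg <- small_cfg(seed = 7, missing_rate = 0.1, planted_clique = 6,
                   planted_central = 3)
  expect_identical(serialize(simulate_abundance(cfg), NULL),
                   serialize(simulate_abundance(cfg), NULL))
  expect_identical(serialize(simulate_peptides(cfg), NULL),
                   serialize(simulate_peptides(cfg), NULL))
  n1 <- simulate_network(cfg)
  n2 <- simulate_network(cfg)
  expect_identical(igraph::as_edgelist(n1$network),
                   igraph::as_edgelist(n2$network))
  expect_identical(n1$truth, n2$truth)
  expect_identical(simulate_annotations(cfg), simulate_annotations(cfg))
})

test_that("archetype-1 disease/healthy ratio reflects the effect size", {
  # Monte-Carlo check: mean linear-scale ratio across disease days for
  # constitutively-elevated proteins stays within a factor 2 of effect 4
  ratios <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_proteins = 120, n_altered = 40,
                            effect_size = 4, missing_rate = 0, seed = s)
    sim <- simulate_abundance(cfg)
    arch1 <- names(sim$truth$archetype_of)[sim$truth$archetype_of == 1]
    m <- as.matrix(sim$abundance[-1])
    rownames(m) <- sim$abundance$protein
    meta <- sim$meta
    shared <- intersect(meta$day[meta$condition == "healthy"],
                        meta$day[meta$condition == "disease"])
    dis <- meta$sample_id[meta$condition == "disease"]
    hea <- meta$sample_id[meta$condition == "healthy" & meta$day %in% shared]
    mean(rowMeans(m[arch1, dis]) / rowMeans(m[arch1, hea]))
  }, numeric(1))
  expect_true(all(ratios >= 2 & ratios <= 8))
})

test_that("unaltered proteins have equal expected abundance in both conditions", {
  # with zero noise the generator is deterministic, so equality is exact
  cfg <- small_cfg(noise_cv = 0, missing_rate = 0, seed = 3)
  sim <- simulate_abundance(cfg)
  null_ids <- setdiff(sim$abundance$protein, sim$truth$altered_ids)
  m <- as.matrix(sim$abundance[-1])
  rownames(m) <- sim$abundance$protein
  meta <- sim$meta
  dis <- meta$sample_id[meta$condition == "disease" & meta$day == 19]
  hea <- meta$sample_id[meta$condition == "healthy" & meta$day == 19]
  expect_equal(rowMeans(m[null_ids, dis]), rowMeans(m[null_ids, hea]))
})

test_that("peptide tables honour the Hi3 contract", {
  cfg <- small_cfg(n_proteins = 50, noise_cv = 0, seed = 9)
  sim <- simulate_peptides(cfg)
  # exactly 50 distinct proteins per sample
  per_sample <- tapply(sim$peptides$protein_id, sim$peptides$sample_id,
                       dplyr::n_distinct)
  expect_true(all(per_sample == 50))
  # zero noise: mean of the 3 most intense peptides equals the target
  one <- sim$peptides[sim$peptides$sample_id == sim$meta$sample_id[1], ]
  top3 <- vapply(split(one$intensity, one$protein_id), function(x) {
    mean(sort(x, decreasing = TRUE)[seq_len(min(3, length(x)))])
  }, numeric(1))
  expect_equal(top3[names(sim$target)], sim$target, tolerance = 1e-12)
  # 1-8 peptides per protein
  npep <- dplyr::count(one, protein_id)
  expect_true(all(npep$n >= 1 & npep$n <= 8))
})

test_that("planted clique on an empty background gives exactly C(c,2) edges", {
  cfg <- synthetic_config(n_nodes = 100, edge_param = 0,
                          planted_clique = 10, seed = 4)
  net <- simulate_network(cfg)
  expect_equal(igraph::ecount(net$network), choose(10, 2))
  expect_length(net$truth$planted_module, 10)
  sub <- igraph::induced_subgraph(net$network, net$truth$planted_module)
  expect_equal(igraph::ecount(sub), choose(10, 2))
  expect_true(all(igraph::E(sub)$combined_score >= 0.9))
})

test_that("network generator respects model moments and invariants", {
  cfg <- synthetic_config(n_nodes = 200, edge_param = 0.05, seed = 7)
  net <- simulate_network(cfg)$network
  # binomial edge count: within 3 sd of p * C(200, 2)
  expected <- 0.05 * choose(200, 2)
  sdev <- sqrt(choose(200, 2) * 0.05 * 0.95)
  expect_lt(abs(igraph::ecount(net) - expected), 3 * sdev)
  expect_false(igraph::any_loop(net))
  expect_false(igraph::any_multiple(net))
  expect_true(all(igraph::E(net)$combined_score >= 0 &
                    igraph::E(net)$combined_score <= 1))
  # no planted structures requested
  truth <- simulate_network(cfg)$truth
  expect_length(truth$planted_module, 0)
  expect_length(truth$planted_central_set, 0)
})

test_that("planted central nodes actually get a degree boost", {
  cfg <- synthetic_config(n_nodes = 150, edge_param = 0.03,
                          planted_central = 5, central_boost = 0.2, seed = 5)
  net <- simulate_network(cfg)
  deg <- igraph::degree(net$network)
  boosted <- mean(deg[net$truth$planted_central_set])
  rest <- mean(deg[setdiff(names(deg), net$truth$planted_central_set)])
  expect_gt(boosted, rest * 2)
})

test_that("annotations cover only generated proteins and honour planting", {
  cfg <- small_cfg(seed = 6)
  planted <- sprintf("P%04d", 1:20)
  ann <- simulate_annotations(cfg, planted = planted)
  expect_length(ann$sets$planted, 20)
  expect_true(all(unlist(ann$sets) %in% ann$universe))
  expect_error(simulate_annotations(cfg, planted = "NOT_A_PROTEIN"),
               "generated protein ids")
})

test_that("missingness is biased toward low-abundance entries", {
  cfg <- synthetic_config(n_proteins = 300, n_altered = 0,
                          missing_rate = 0.15, seed = 8)
  sim <- simulate_abundance(cfg)
  m <- as.matrix(sim$abundance[-1])
  base <- simulate_abundance(synthetic_config(n_proteins = 300, n_altered = 0,
                                              missing_rate = 0, seed = 8))
  full <- as.matrix(base$abundance[-1])
  missing_vals <- full[is.na(m)]
  observed_vals <- full[!is.na(m)]
  expect_lt(median(missing_vals), median(observed_vals))
  # every sample column keeps at least one observed value
  expect_true(all(colSums(!is.na(m)) > 0))
})
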
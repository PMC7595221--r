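# Differential abundance: BH adjustment, the three detectors, consensus
# voting and disease/ageing set comparison.

null_sim <- function(n_proteins, seed, ...) {
  cfg <- synthetic_config(n_proteins = n_proteins, n_altered = 0,
                          missing_rate = 0, seed = seed, ...)
  sim <- simulate_abundance(cfg)
  sim$abundance <- quantile_normalise(sim$abundance)
  sim
}

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("bh_adjust agrees with brute-force step-up on permuted vectors", {
  base_sets <- list(
    c(0.001, 0.01, 0.04, 0.2, 0.5, 0.9),
    c(0.03, 0.03, 0.2, 0.6, 0.7, 1.0),   # with ties
    withr::with_seed(4, runif(6))
  )
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  for (p in base_sets) {
    for (i in seq_len(nrow(perms))) {
      v <- p[perms[i, ]]
      expect_equal(bh_adjust(v), bh_brute(v), tolerance = 1e-12)
    }
  }
})

test_that("size factors of identical columns are all 1", {
  m <- matrix(rep(c(10, 20, 40), 4), 3, 4)
  expect_equal(unname(size_factors(m)), rep(1, 4))
})

test_that("detectors control the false positive rate on null data", {
  sim <- null_sim(500, seed = 11)
  for (fun in list(detect_moderated_f, detect_nb_lrt, detect_polynomial_lrt)) {
    res <- fun(sim$abundance, sim$meta)
    expect_lte(mean(res$q < 0.05), 0.07)
    expect_true(all(res$p >= 0 & res$p <= 1))
    expect_true(all(res$q >= res$p - 1e-12))
  }
})

test_that("a strong constant condition shift is detected decisively", {
  sim <- null_sim(200, seed = 21, noise_cv = 0.1)
  m <- as.matrix(sim$abundance[-1])
  dis <- sim$meta$sample_id[sim$meta$condition == "disease"]
  m[1, dis] <- m[1, dis] * 8
  target <- sim$abundance$protein[1]
  data <- abundance_from_matrix(m, proteins = sim$abundance$protein,
                                samples = colnames(m))
  for (fun in list(detect_moderated_f, detect_nb_lrt, detect_polynomial_lrt)) {
    res <- fun(data, sim$meta)
    expect_lt(res$q[res$protein == target], 0.01)
  }
})

test_that("moderated F reduces to the pooled-variance F when variances are equal", {
  # equal residual variance across proteins forces an infinite prior df
  set.seed(3)
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:16),
    condition = rep(c("healthy", "disease"), each = 8),
    day = rep(rep(c(5, 19), each = 4), 2),
    bio_rep = rep(1:4, 4), tech_rep = 1L
  )
  X1 <- model.matrix(~ condition * factor(day), meta)
  X0 <- model.matrix(~ factor(day), meta)
  # give every protein the same residual vector: identical residual
  # variances => moment matching yields an infinite prior df
  e <- qr.resid(qr(X1), rnorm(16, 0, 0.05))
  signal <- matrix(rnorm(5 * ncol(X1), 0, 0.1), 5, ncol(X1))
  Y <- signal %*% t(X1) + matrix(e, 5, 16, byrow = TRUE) + 5
  data <- abundance_from_matrix(10^Y, samples = meta$sample_id)
  res <- detect_moderated_f(data, meta)
  rss1 <- colSums(qr.resid(qr(X1), t(Y))^2)
  rss0 <- colSums(qr.resid(qr(X0), t(Y))^2)
  df1 <- qr(X1)$rank - qr(X0)$rank
  df_res <- 16 - qr(X1)$rank
  pooled_f <- ((rss0 - rss1) / df1) / mean(rss1 / df_res)
  expect_equal(res$statistic, unname(pooled_f), tolerance = 1e-6)
})

test_that("polynomial LRT handles degeneracies as specified", {
  sim <- null_sim(50, seed = 31)
  # mirror the healthy samples into the disease samples at shared days so
  # the condition means coincide exactly: statistic 0, p 1
  m <- as.matrix(sim$abundance[-1])
  meta <- sim$meta
  for (i in which(meta$condition == "disease")) {
    twin <- meta$sample_id[meta$condition == "healthy" &
                             meta$day == meta$day[i] &
                             meta$bio_rep == meta$bio_rep[i] &
                             meta$tech_rep == meta$tech_rep[i]]
    m[, meta$sample_id[i]] <- m[, twin]
  }
  mirrored <- abundance_from_matrix(m, proteins = sim$abundance$protein,
                                    samples = colnames(m))
  res <- detect_polynomial_lrt(mirrored, meta)
  expect_true(all(res$statistic < 1e-6))
  expect_true(all(res$p > 1 - 1e-6))
  res <- detect_polynomial_lrt(sim$abundance, sim$meta)
  # a degree too high for the available days errors
  expect_error(detect_polynomial_lrt(sim$abundance, sim$meta, degree = 9),
               "too high")
  # degree 0 reduces to a two-group comparison pooled over days
  res0 <- detect_polynomial_lrt(sim$abundance, sim$meta, degree = 0)
  expect_equal(res0$df[1], 1)
})

test_that("an archetype-4 disease-only decline is caught by the polynomial LRT", {
  cfg <- synthetic_config(n_proteins = 150, n_altered = 40,
                          archetype_fractions = c(0, 0, 0, 1),
                          effect_size = 4, noise_cv = 0.15,
                          missing_rate = 0, seed = 13)
  sim <- simulate_abundance(cfg)
  res <- detect_polynomial_lrt(quantile_normalise(sim$abundance), sim$meta)
  hits <- res$q[res$protein %in% sim$truth$altered_ids]
  expect_gt(mean(hits < 0.05), 0.9)
})

test_that("nb detector flags all-zero proteins instead of failing", {
  sim <- null_sim(30, seed = 41)
  m <- as.matrix(sim$abundance[-1])
  m[1, ] <- 0
  data <- abundance_from_matrix(m, proteins = sim$abundance$protein,
                                samples = colnames(m))
  res <- detect_nb_lrt(data, sim$meta)
  zero_id <- sim$abundance$protein[1]
  expect_equal(res$p[res$protein == zero_id], 1)
  expect_equal(res$flag[res$protein == zero_id], "all_zero")
})

test_that("consensus voting applies the two-method rule", {
  fake <- function(name, q) {
    tibble::tibble(protein = c("A", "B", "C"), detector = name,
                   statistic = 1, df = 1, p = q, q = q)
  }
  res <- consensus_vote(list(fake("d1", c(0.01, 0.01, 0.5)),
                             fake("d2", c(0.5, 0.01, 0.5)),
                             fake("d3", c(0.01, 0.5, 0.5))))
  # {yes, no, yes} -> significant; {no, yes, no} with one vote -> not
  expect_true(res$significant[res$protein == "A"])
  expect_true(res$significant[res$protein == "B"])
  expect_false(res$significant[res$protein == "C"])
  expect_equal(res$votes, c(2L, 2L, 0L))
  # threshold 1: union of detector calls
  res1 <- consensus_vote(list(fake("d1", c(0.01, 0.5, 0.5)),
                              fake("d2", c(0.5, 0.5, 0.5))), votes = 1)
  expect_equal(res1$significant, c(TRUE, FALSE, FALSE))
  # mismatched universes are an error
  bad <- fake("d2", c(0.5, 0.5, 0.5))
  bad$protein <- c("A", "B", "D")
  expect_error(consensus_vote(list(fake("d1", c(1, 1, 1)), bad)), "universe")
  expect_error(consensus_vote(list(fake("d1", c(1, 1, 1)))), "2 detectors")
})

test_that("disease/ageing set comparison partitions correctly", {
  mk <- function(ids, sig) tibble::tibble(protein = ids,
                                          significant = ids %in% sig)
  universe <- sprintf("P%03d", 1:100)
  ageing_sig <- universe[1:61]
  disease_sig <- universe[32:92]   # overlap of 30 with ageing
  cmp <- compare_condition_sets(mk(universe, disease_sig),
                                mk(universe, ageing_sig))
  sizes <- attr(cmp, "sizes")
  expect_equal(unname(sizes["ageing"]), 61)
  expect_equal(unname(sizes["shared"]), 30)
  expect_equal(unname(sizes["ageing_only"]), 31)
  expect_equal(sum(cmp$label == "ageing_only"), 31)
  # disjoint sets share nothing; identical sets have no exclusive members
  cmp2 <- compare_condition_sets(mk(universe, universe[1:10]),
                                 mk(universe, universe[11:20]))
  expect_equal(unname(attr(cmp2, "sizes")["shared"]), 0)
  cmp3 <- compare_condition_sets(mk(universe, universe[1:10]),
                                 mk(universe, universe[1:10]))
  expect_equal(unname(attr(cmp3, "sizes")["disease_only"]), 0)
  expect_equal(unname(attr(cmp3, "sizes")["ageing_only"]), 0)
})

test_that("recovery increases with effect size", {
  recov <- vapply(c(1.5, 2, 4, 8), function(es) {
    cfg <- synthetic_config(n_proteins = 200, n_altered = 40,
                            effect_size = es, noise_cv = 0.2,
                            missing_rate = 0, seed = 17)
    sim <- simulate_abundance(cfg)
    m <- quantile_normalise(sim$abundance)
    cons <- run_consensus(m, sim$meta, "condition")
    hm <- sim$meta[sim$meta$condition == "healthy", ]
    age <- run_consensus(m[, c("protein", hm$sample_id)], hm, "time")
    hits <- union(cons$protein[cons$significant],
                  age$protein[age$significant])
    mean(sim$truth$altered_ids %in% hits)
  }, numeric(1))
  # monotone non-decreasing, allowing one inversion within MC noise
  expect_lte(sum(diff(recov) < -0.02), 1)
  expect_gte(recov[4], 0.9)
})

test_that("the ageing path reuses the detectors under the reduced design", {
  cfg <- synthetic_config(n_proteins = 120, n_altered = 30,
                          archetype_fractions = c(0, 0, 1, 0),
                          effect_size = 4, noise_cv = 0.15,
                          missing_rate = 0, seed = 19)
  sim <- simulate_abundance(cfg)
  m <- quantile_normalise(sim$abundance)
  hm <- sim$meta[sim$meta$condition == "healthy", ]
  age <- run_consensus(m[, c("protein", hm$sample_id)], hm, "time")
  hits <- age$protein[age$significant]
  expect_gt(mean(sim$truth$altered_ids %in% hits), 0.9)
})

test_that("technical repeats are averaged before fitting by default", {
  sim <- null_sim(40, seed = 23)
  avg <- proteonet:::average_technical(sim$abundance, sim$meta)
  expect_equal(ncol(avg$data) - 1, nrow(sim$meta) / 2)
  expect_true(all(avg$meta$tech_rep == 1))
  # averaging identical technical repeats leaves values unchanged
  m <- as.matrix(sim$abundance[-1])
  meta <- sim$meta
  for (i in which(meta$tech_rep == 2)) {
    twin <- meta$sample_id[meta$condition == meta$condition[i] &
                             meta$day == meta$day[i] &
                             meta$bio_rep == meta$bio_rep[i] &
                             meta$tech_rep == 1]
    m[, meta$sample_id[i]] <- m[, twin]
  }
  davg <- proteonet:::average_technical(
    abundance_from_matrix(m, proteins = sim$abundance$protein,
                          samples = colnames(m)), meta)
  t1 <- meta$sample_id[meta$tech_rep == 1]
  expected <- m[, t1]
  got <- as.matrix(davg$data[-1])
  key_new <- paste(davg$meta$condition, davg$meta$day, davg$meta$bio_rep)
  key_old <- paste(meta$condition[meta$tech_rep == 1],
                   meta$day[meta$tech_rep == 1],
                   meta$bio_rep[meta$tech_rep == 1])
  expect_equal(unname(got), unname(expected[, match(key_new, key_old)]),
               tolerance = 1e-12)
})
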
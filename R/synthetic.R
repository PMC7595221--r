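# Synthetic data generators emulating the structure of a longitudinal
# label-free brain proteomics study: two conditions with unequal numbers of
# collection days, replicated biological and technical repeats, log-normal
# abundances, detection-floor missingness, four planted temporal archetypes,
# and random interaction networks with planted dense modules and planted
# high-centrality node sets.

#' Configuration for the synthetic study generators
#'
#' Defaults mirror the design of the emulated study: 1854 proteins shared by
#' the two conditions, 228 altered, collections at days 5/19/31/46 for both
#' conditions plus days 54/80 for healthy flies only, three biological
#' repeats each measured twice. Altered proteins follow four temporal
#' archetypes: (1) constitutively elevated in disease, (2) constitutively
#' reduced in disease, (3) increasing with age in both conditions,
#' (4) declining with age in disease only.
#'
#' @param n_proteins number of proteins to simulate.
#' @param n_altered number of proteins given a planted alteration.
#' @param archetype_fractions four non-negative proportions (summing to 1)
#'   of altered proteins assigned to archetypes 1-4.
#' @param timepoints_disease,timepoints_healthy collection days per condition.
#' @param n_bio,n_tech biological repeats and technical repeats per
#'   biological repeat (both >= 1).
#' @param baseline_log_mean,baseline_log_sd log10-scale mean and sd of
#'   per-protein baseline abundance.
#' @param effect_size multiplicative fold change (>= 1) of planted effects.
#' @param noise_cv coefficient of variation of biological noise on the
#'   linear scale; technical noise uses `noise_cv / 2`.
#' @param missing_rate proportion of entries in [0, 1) marked missing,
#'   biased toward low-abundance entries (detection floor).
#' @param network_model random-graph model, `"erdos_renyi"` or
#'   `"scale_free"`.
#' @param n_nodes number of network nodes.
#' @param edge_param edge probability (Erdos-Renyi) or edges added per new
#'   vertex (scale-free preferential attachment).
#' @param planted_clique size of an embedded high-confidence clique
#'   (0 = none).
#' @param planted_central number of nodes given a degree boost (0 = none).
#' @param central_boost fraction of all nodes each boosted node gains extra
#'   edges to.
#' @param seed root integer seed; all generators derive per-component seeds
#'   from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 1854,
                             n_altered = 228,
                             archetype_fractions = c(0.25, 0.25, 0.25, 0.25),
                             timepoints_disease = c(5, 19, 31, 46),
                             timepoints_healthy = c(5, 19, 31, 46, 54, 80),
                             n_bio = 3,
                             n_tech = 2,
                             baseline_log_mean = 6,
                             baseline_log_sd = 0.8,
                             effect_size = 4,
                             noise_cv = 0.2,
                             missing_rate = 0.05,
                             network_model = c("erdos_renyi", "scale_free"),
                             n_nodes = 500,
                             edge_param = 0.02,
                             planted_clique = 0,
                             planted_central = 0,
                             central_boost = 0.1,
                             seed = 1L) {
  network_model <- match.arg(network_model)
  cfg <- list(
    n_proteins = as.integer(n_proteins), n_altered = as.integer(n_altered),
    archetype_fractions = as.numeric(archetype_fractions),
    timepoints_disease = as.numeric(timepoints_disease),
    timepoints_healthy = as.numeric(timepoints_healthy),
    n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    effect_size = effect_size, noise_cv = noise_cv,
    missing_rate = missing_rate, network_model = network_model,
    n_nodes = as.integer(n_nodes), edge_param = edge_param,
    planted_clique = as.integer(planted_clique),
    planted_central = as.integer(planted_central),
    central_boost = central_boost, seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$archetype_fractions) != 4 ||
      any(cfg$archetype_fractions < 0) ||
      abs(sum(cfg$archetype_fractions) - 1) > 1e-9) {
    abort("archetype_fractions must be 4 non-negative proportions summing to 1")
  }
  if (cfg$n_altered > cfg$n_proteins) abort("n_altered must be <= n_proteins")
  if (cfg$n_proteins < 0 || cfg$n_nodes < 0 || cfg$planted_clique < 0 ||
      cfg$planted_central < 0) {
    abort("all counts must be non-negative")
  }
  if (cfg$n_bio < 1 || cfg$n_tech < 1) {
    abort("n_bio and n_tech must both be >= 1")
  }
  if (cfg$effect_size < 1) abort("effect_size must be >= 1")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  if (cfg$planted_clique > cfg$n_nodes) {
    abort("planted_clique cannot exceed n_nodes")
  }
  invisible(cfg)
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))

# Deterministic archetype counts from fractions (largest-remainder rule).
archetype_counts <- function(fractions, n_altered) {
  raw <- fractions * n_altered
  base <- floor(raw)
  rem <- n_altered - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Expected (noise-free) abundance for one protein at one (condition, day).
# `s_life` scales the day to [0, 1] over the union of all collection days
# (ageing-coupled archetype 3 ramps across the whole lifespan); `s_dis`
# scales over the disease condition's own days, so the disease-specific
# decline of archetype 4 reaches the full 1/effect fold change by the last
# disease collection.
archetype_mean <- function(base, archetype, condition, s_life, s_dis, effect) {
  disease <- condition == "disease"
  switch(as.character(archetype),
    "0" = base,
    "1" = if (disease) base * effect else base,
    "2" = if (disease) base / effect else base,
    "3" = base * effect^s_life,
    "4" = if (disease) base * effect^(-s_dis) else base
  )
}

sample_sheet <- function(cfg) {
  rows <- list()
  for (condition in c("healthy", "disease")) {
    days <- if (condition == "healthy") cfg$timepoints_healthy else cfg$timepoints_disease
    for (day in days) for (b in seq_len(cfg$n_bio)) for (t in seq_len(cfg$n_tech)) {
      rows[[length(rows) + 1]] <- tibble(
        sample_id = sprintf("%s_d%02d_b%d_t%d", condition, day, b, t),
        condition = condition, day = day, bio_rep = b, tech_rep = t
      )
    }
  }
  bind_rows(rows)
}

#' Simulate a longitudinal two-condition abundance dataset
#'
#' Draws per-protein baselines from a log10-normal distribution, applies the
#' planted archetype effects multiplicatively on the linear scale, layers
#' biological then technical log-normal noise (technical at half the
#' biological CV), and marks a `missing_rate` fraction of entries missing
#' with probability proportional to their low-abundance rank (a detection
#' floor). Fully reproducible from the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `abundance` (wide tibble: `protein` + one column per
#'   sample, `NA` = missing), `meta` (sample metadata tibble) and `truth`
#'   (list with `altered_ids` and named `archetype_of`).
#' @export
simulate_abundance <- function(config) {
  validate_synthetic_config(config)
  meta <- sample_sheet(config)
  ids <- protein_ids(config$n_proteins)
  withr::with_seed(derive_seed(config$seed, 1L), {
    base <- 10^stats::rnorm(config$n_proteins, config$baseline_log_mean,
                            config$baseline_log_sd)
    altered <- sort(sample.int(config$n_proteins, config$n_altered))
    counts <- archetype_counts(config$archetype_fractions, config$n_altered)
    archetype <- integer(config$n_proteins)
    archetype[altered] <- sample(rep.int(1:4, counts))

    all_days <- sort(unique(c(config$timepoints_healthy,
                              config$timepoints_disease)))
    dis_days <- config$timepoints_disease
    scale_over <- function(day, days) {
      if (length(unique(days)) <= 1) return(0)
      min(max((day - min(days)) / (max(days) - min(days)), 0), 1)
    }

    sd_bio <- sqrt(log(1 + config$noise_cv^2))
    sd_tech <- sqrt(log(1 + (config$noise_cv / 2)^2))

    n_s <- nrow(meta)
    mat <- matrix(NA_real_, config$n_proteins, n_s,
                  dimnames = list(ids, meta$sample_id))
    # biological-repeat effects are shared by the technical repeats of the
    # same (condition, day, bio) cell
    bio_key <- paste(meta$condition, meta$day, meta$bio_rep)
    bio_levels <- unique(bio_key)
    bio_factor <- matrix(exp(stats::rnorm(config$n_proteins * length(bio_levels),
                                          -sd_bio^2 / 2, sd_bio)),
                         config$n_proteins, length(bio_levels))
    colnames(bio_factor) <- bio_levels

    for (j in seq_len(n_s)) {
      s_life <- scale_over(meta$day[j], all_days)
      s_dis <- scale_over(meta$day[j], dis_days)
      mu <- vapply(seq_len(config$n_proteins), function(i) {
        archetype_mean(base[i], archetype[i], meta$condition[j], s_life,
                       s_dis, config$effect_size)
      }, numeric(1))
      tech <- exp(stats::rnorm(config$n_proteins, -sd_tech^2 / 2, sd_tech))
      mat[, j] <- mu * bio_factor[, bio_key[j]] * tech
    }

    if (config$missing_rate > 0) {
      n_miss <- floor(config$missing_rate * length(mat))
      # never remove a column's maximum, so every sample keeps >= 1 value
      col_max <- apply(mat, 2, which.max)
      protected <- cbind(col_max, seq_len(n_s))
      candidate <- setdiff(seq_along(mat),
                           (protected[, 2] - 1) * nrow(mat) + protected[, 1])
      w <- rank(-mat[candidate])  # lowest abundance -> largest weight
      miss <- sample(candidate, min(n_miss, length(candidate)), prob = w)
      mat[miss] <- NA_real_
    }
  })
  truth <- list(
    altered_ids = ids[archetype > 0],
    archetype_of = stats::setNames(archetype[archetype > 0], ids[archetype > 0])
  )
  abundance <- matrix_to_tibble(mat)
  abundance <- add_step(abundance, "simulate_abundance")
  list(abundance = abundance, meta = meta, truth = truth)
}

#' Simulate a peptide-level intensity table
#'
#' Each protein gets 1-8 peptides with fixed relative ionisation
#' efficiencies, scaled so that the mean of its three most intense peptides
#' equals the protein's target abundance; per-measurement log-normal noise
#' at `noise_cv` is layered on top (none when `noise_cv = 0`).
#'
#' @param config a [synthetic_config()].
#' @return list with `peptides` (long tibble: protein_id, peptide_id,
#'   sample_id, intensity), `meta`, and `target` (named per-protein target
#'   abundance).
#' @export
simulate_peptides <- function(config) {
  validate_synthetic_config(config)
  meta <- sample_sheet(config)
  ids <- protein_ids(config$n_proteins)
  withr::with_seed(derive_seed(config$seed, 2L), {
    target <- 10^stats::rnorm(config$n_proteins, config$baseline_log_mean,
                              config$baseline_log_sd)
    names(target) <- ids
    n_pep <- sample(1:8, config$n_proteins, replace = TRUE)
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    rows <- vector("list", config$n_proteins)
    for (i in seq_len(config$n_proteins)) {
      eff <- sort(stats::rlnorm(n_pep[i], 0, 1), decreasing = TRUE)
      top <- mean(eff[seq_len(min(3, n_pep[i]))])
      eff <- eff / top  # top-3 mean of efficiencies is exactly 1
      pep <- sprintf("%s_pep%d", ids[i], seq_len(n_pep[i]))
      grid <- expand.grid(peptide_id = pep, sample_id = meta$sample_id,
                          stringsAsFactors = FALSE)
      noise <- if (config$noise_cv > 0) {
        exp(stats::rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
      } else 1
      rows[[i]] <- tibble(
        protein_id = ids[i],
        peptide_id = grid$peptide_id,
        sample_id = grid$sample_id,
        intensity = target[i] * eff[match(grid$peptide_id, pep)] * noise
      )
    }
  })
  list(peptides = bind_rows(rows), meta = meta, target = target)
}

#' Simulate a scored interaction network with planted structure
#'
#' Draws an Erdos-Renyi or preferential-attachment background with edge
#' confidence scores uniform on [0, 1], optionally embeds a clique whose
#' edges score at least 0.9, and optionally boosts the degree of a planted
#' node set with extra random edges.
#'
#' @param config a [synthetic_config()].
#' @return list with `network` (an undirected simple igraph with a
#'   `combined_score` edge attribute) and `truth` (list with
#'   `planted_module` and `planted_central_set` character vectors).
#' @export
simulate_network <- function(config) {
  validate_synthetic_config(config)
  # nodes carry protein ids so simulated networks and abundance datasets
  # from the same config share an identifier universe
  ids <- protein_ids(config$n_nodes)
  withr::with_seed(derive_seed(config$seed, 3L), {
    g <- if (config$network_model == "erdos_renyi") {
      igraph::sample_gnp(config$n_nodes, config$edge_param)
    } else {
      igraph::sample_pa(config$n_nodes, m = max(1, round(config$edge_param)),
                        directed = FALSE)
    }
    igraph::V(g)$name <- ids
    igraph::E(g)$combined_score <- stats::runif(igraph::ecount(g))

    planted_module <- character(0)
    if (config$planted_clique > 0) {
      planted_module <- sort(sample(ids, config$planted_clique))
      pairs <- utils::combn(planted_module, 2)
      g <- igraph::add_edges(g, as.vector(pairs),
                             combined_score = stats::runif(ncol(pairs), 0.9, 1))
    }

    planted_central <- character(0)
    if (config$planted_central > 0) {
      planted_central <- sort(sample(setdiff(ids, planted_module),
                                     config$planted_central))
      n_extra <- max(1L, ceiling(config$central_boost * config$n_nodes))
      for (v in planted_central) {
        targets <- sample(setdiff(ids, v), n_extra)
        g <- igraph::add_edges(g, as.vector(rbind(v, targets)),
                               combined_score = stats::runif(n_extra))
      }
    }
    g <- igraph::simplify(g, edge.attr.comb = list(combined_score = "max"))
  })
  list(network = g,
       truth = list(planted_module = planted_module,
                    planted_central_set = planted_central))
}

#' Simulate an annotation collection
#'
#' Random term-to-protein sets over the generated protein universe, plus an
#' optional planted term covering a chosen protein subset (for enrichment
#' recovery tests).
#'
#' @param config a [synthetic_config()].
#' @param n_terms number of random terms.
#' @param term_size_range inclusive range of random term sizes.
#' @param planted optional character vector of protein ids covered by a term
#'   named `"planted"`.
#' @return list with `sets` (named list of protein-id vectors) and
#'   `universe` (all generated protein ids).
#' @export
simulate_annotations <- function(config, n_terms = 20,
                                 term_size_range = c(5, 50),
                                 planted = NULL) {
  validate_synthetic_config(config)
  ids <- protein_ids(config$n_proteins)
  if (!is.null(planted) && !all(planted %in% ids)) {
    abort("planted proteins must be among the generated protein ids")
  }
  withr::with_seed(derive_seed(config$seed, 4L), {
    sizes <- sample(term_size_range[1]:min(term_size_range[2], length(ids)),
                    n_terms, replace = TRUE)
    sets <- lapply(sizes, function(k) sort(sample(ids, k)))
    names(sets) <- sprintf("T%03d", seq_len(n_terms))
  })
  if (!is.null(planted)) sets$planted <- sort(planted)
  list(sets = sets, universe = ids)
}
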
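# End-to-end orchestration: preprocess -> differential (disease and ageing
# designs) -> set comparison -> profile clustering -> network statistics ->
# dense modules -> enrichment, with a deterministic run report.

#' Pipeline configuration
#'
#' Either point the pipeline at files (`peptides`/`matrix`, `meta`, `links`,
#' `gmt`) or let it simulate its inputs from a [synthetic_config()]
#' (`simulate = TRUE`, the default, so the whole pipeline runs with no
#' downloads).
#'
#' @param simulate generate synthetic inputs from `synthetic` instead of
#'   reading files.
#' @param synthetic a [synthetic_config()] used when `simulate = TRUE`.
#' @param peptides,matrix,meta,links,gmt input file paths (TSV / STRING
#'   links / GMT) used when `simulate = FALSE`; give either `peptides` or
#'   `matrix`.
#' @param score_threshold STRING combined-score threshold.
#' @param alpha,votes consensus parameters.
#' @param degree polynomial detector degree.
#' @param k_max largest cluster count tried (default: min(30, n)).
#' @param permutations permutation samples for the network null.
#' @param mcode_score_cutoff report modules with score strictly greater
#'   (NULL reports all).
#' @param seed root seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, synthetic = synthetic_config(),
                            peptides = NULL, matrix = NULL, meta = NULL,
                            links = NULL, gmt = NULL,
                            score_threshold = 0.5, alpha = 0.05, votes = 2,
                            degree = 2, k_max = NULL, permutations = 10000,
                            mcode_score_cutoff = NULL, seed = 1L) {
  structure(list(simulate = simulate, synthetic = synthetic,
                 peptides = peptides, matrix = matrix, meta = meta,
                 links = links, gmt = gmt,
                 score_threshold = score_threshold, alpha = alpha,
                 votes = votes, degree = degree, k_max = k_max,
                 permutations = permutations,
                 mcode_score_cutoff = mcode_score_cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns findings rather than throwing: rows with level `"error"` or
#' `"warning"` and a message. A canonical default configuration yields zero
#' findings.
#'
#' @param config a [pipeline_config()].
#' @return tibble: level, message.
#' @export
validate_config <- function(config) {
  findings <- list()
  note <- function(level, message) {
    findings[[length(findings) + 1]] <<- tibble(level = level, message = message)
  }
  if (config$votes > 3) {
    note("error", "votes exceeds the number of detectors (3)")
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    note("error", "alpha must be in (0, 1)")
  }
  if (config$permutations < 1000) {
    note("warning", "fewer than 1000 permutations gives coarse empirical P values")
  }
  if (config$score_threshold < 0 || config$score_threshold > 1) {
    note("error", "score_threshold must be in [0, 1]")
  }
  if (!config$simulate) {
    for (f in c("meta", "links")) {
      if (is.null(config[[f]])) note("error", paste0("missing input path: ", f))
    }
    if (is.null(config$peptides) && is.null(config$matrix)) {
      note("error", "need either a peptides or a matrix input path")
    }
    for (f in c("peptides", "matrix", "meta", "links", "gmt")) {
      if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
        note("error", paste0("input file does not exist: ", config[[f]]))
      }
    }
  }
  if (length(findings) == 0) {
    return(tibble(level = character(0), message = character(0)))
  }
  bind_rows(findings)
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, the consensus differential analysis under the
#' condition-contrast (disease) and time-effect (ageing) designs, the
#' disease/ageing set comparison, profile clustering with BIC selection,
#' permutation network statistics of the altered set, MCODE module
#' detection on the altered-plus-neighbours subgraph, and Fisher
#' enrichment of the altered set. Two runs with the same configuration
#' produce reports with identical content hashes.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, intermediate tables are
#'   written there as TSV/JSON.
#' @return a `pipeline_report` list with per-stage summaries, the config
#'   echo, seeds used and a content `hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    abort(paste0("invalid configuration: ",
                 paste(findings$message[findings$level == "error"],
                       collapse = "; ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  # -- inputs ----------------------------------------------------------
  truth <- NULL
  if (config$simulate) {
    sim <- stage("simulate", simulate_abundance(config$synthetic))
    raw <- sim$abundance
    meta <- sim$meta
    truth <- sim$truth
    net_sim <- stage("simulate", simulate_network(config$synthetic))
    network <- net_sim$network
    network <- igraph::delete_edges(
      network, which(igraph::E(network)$combined_score < config$score_threshold))
    annotations <- stage("simulate",
                         simulate_annotations(config$synthetic,
                                              planted = truth$altered_ids))
    sets <- annotations$sets
    universe <- annotations$universe
  } else {
    meta <- stage("inputs", read_sample_meta_tsv(config$meta))
    raw <- if (!is.null(config$peptides)) {
      stage("preprocess", hi3_rollup(readr::read_tsv(config$peptides,
                                                     show_col_types = FALSE)))
    } else {
      stage("inputs", read_abundance_tsv(config$matrix))
    }
    network <- stage("network",
                     read_string_links(config$links, config$score_threshold))
    sets <- if (!is.null(config$gmt)) stage("enrichment", read_gmt(config$gmt)) else NULL
    universe <- raw$protein
  }

  # -- preprocess ------------------------------------------------------
  mat <- stage("preprocess", quantile_normalise(impute_missing(raw)))
  pca <- stage("preprocess", pca_summary(standardise(mat)))

  # -- differential ----------------------------------------------------
  disease <- stage("differential",
                   run_consensus(mat, meta, test = "condition",
                                 alpha = config$alpha, votes = config$votes,
                                 degree = config$degree))
  healthy_samples <- meta$sample_id[meta$condition == "healthy"]
  ageing <- stage("differential",
                  run_consensus(mat[, c("protein", healthy_samples)],
                                meta[meta$condition == "healthy", ],
                                test = "time", alpha = config$alpha,
                                votes = config$votes, degree = config$degree))
  sets_cmp <- stage("differential", compare_condition_sets(disease, ageing))
  sig <- disease$protein[disease$significant]
  altered_union <- union(sig, ageing$protein[ageing$significant])

  # -- profile clustering ---------------------------------------------
  clustering <- NULL
  if (length(sig) >= 2) {
    profiles <- stage("clustering", profile_matrix(mat, meta, sig))
    k_max <- config$k_max %||% min(30L, nrow(profiles))
    trace <- stage("clustering",
                   select_cluster_count(profiles, k_max = k_max,
                                        seeds = derive_seed(config$seed, 10L) %% 1000000L + 1:5))
    fit <- trace$fits[[trace$selected_k]]
    clustering <- list(selected_k = trace$selected_k,
                       trace = trace$trace,
                       assignment = assign_profiles(fit))
  }

  # -- network statistics ---------------------------------------------
  net_lcc <- stage("network", induce_lcc_subgraph(network,
                                                  igraph::V(network)$name))
  sig_in_net <- intersect(sig, igraph::V(net_lcc)$name)
  network_stats <- NULL
  if (length(sig_in_net) >= 2) {
    network_stats <- stage("network",
                           network_significance(net_lcc, sig_in_net,
                                                n_samples = config$permutations,
                                                seed = derive_seed(config$seed, 20L)))
  }
  hubs <- stage("network", classify_hub_bottleneck(net_lcc))

  # -- modules ---------------------------------------------------------
  modules <- NULL
  if (length(sig_in_net) >= 1) {
    nbhd <- stage("modules", neighbourhood_subgraph(network, sig_in_net))
    mods <- stage("modules", mcode(nbhd, score_cutoff = config$mcode_score_cutoff))
    if (nrow(mods) > 0) {
      mods$query_fraction <- vapply(mods$nodes, module_query_fraction,
                                    numeric(1), query = sig_in_net)
    }
    modules <- mods
  }

  # -- enrichment ------------------------------------------------------
  enrichment <- NULL
  if (!is.null(sets) && length(sig) > 0) {
    enrichment <- stage("enrichment",
                        suppressWarnings(
                          fisher_overrepresentation(sig, sets, universe)))
  }

  report <- list(
    config = config,
    preprocess = list(n_proteins = nrow(mat), n_samples = ncol(mat) - 1,
                      steps = provenance(mat),
                      variance_explained = pca$variance_explained[1:2]),
    differential = list(n_significant_disease = sum(disease$significant),
                        n_significant_ageing = sum(ageing$significant),
                        set_sizes = attr(sets_cmp, "sizes"),
                        disease = disease, ageing = ageing),
    clustering = clustering,
    network = list(n_nodes = igraph::vcount(net_lcc),
                   n_edges = igraph::ecount(net_lcc),
                   n_query_in_network = length(sig_in_net),
                   significance = network_stats,
                   hub_bottleneck_counts = table(hubs$class)),
    modules = modules,
    enrichment = enrichment,
    truth = truth,
    seeds = c(root = config$seed,
              clustering = derive_seed(config$seed, 10L),
              network = derive_seed(config$seed, 20L))
  )
  report$hash <- report_hash(report)
  class(report) <- "pipeline_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(disease, file.path(outdir, "consensus_disease.tsv"))
    readr::write_tsv(ageing, file.path(outdir, "consensus_ageing.tsv"))
    if (!is.null(clustering)) {
      readr::write_tsv(clustering$assignment, file.path(outdir, "clusters.tsv"))
      readr::write_tsv(clustering$trace, file.path(outdir, "bic_trace.tsv"))
    }
    if (!is.null(network_stats)) {
      readr::write_tsv(network_stats, file.path(outdir, "network_significance.tsv"))
    }
    if (!is.null(modules) && nrow(modules) > 0) {
      flat <- modules
      flat$nodes <- vapply(flat$nodes, paste, character(1), collapse = ",")
      readr::write_tsv(flat, file.path(outdir, "modules.tsv"))
    }
    if (!is.null(enrichment)) {
      readr::write_tsv(enrichment, file.path(outdir, "enrichment.tsv"))
    }
    jsonlite::write_json(list(hash = report$hash, seeds = as.list(report$seeds)),
                         file.path(outdir, "report.json"), auto_unbox = TRUE)
  }
  report
}

# Stable content hash of a report: drop volatile attributes, serialise the
# summaries deterministically.
report_hash <- function(report) {
  core <- report[c("preprocess", "differential", "clustering", "network",
                   "modules", "enrichment", "seeds")]
  core$network$hub_bottleneck_counts <-
    as.list(core$network$hub_bottleneck_counts)
  strip <- function(x) {
    if (is.data.frame(x)) {
      x <- as.data.frame(x)
      attributes(x)[setdiff(names(attributes(x)),
                            c("names", "row.names", "class"))] <- NULL
      x[] <- lapply(x, function(col) if (is.list(col)) col else unname(col))
      return(x)
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  rlang::hash(strip(core))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  proteins: %d, samples: %d\n",
              x$preprocess$n_proteins, x$preprocess$n_samples))
  cat(sprintf("  significant (disease): %d; (ageing): %d\n",
              x$differential$n_significant_disease,
              x$differential$n_significant_ageing))
  if (!is.null(x$clustering)) {
    cat(sprintf("  selected clusters: %d\n", x$clustering$selected_k))
  }
  cat(sprintf("  network LCC: %d nodes / %d edges\n",
              x$network$n_nodes, x$network$n_edges))
  if (!is.null(x$network$significance)) {
    p <- x$network$significance
    cat(sprintf("  network P: %s\n",
                paste(sprintf("%s=%.4g", p$statistic, p$p), collapse = ", ")))
  }
  if (!is.null(x$modules)) {
    cat(sprintf("  modules: %d\n", nrow(x$modules)))
  }
  cat(sprintf("  hash: %s\n", x$hash))
  invisible(x)
}
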
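# Preprocessing: Hi3 peptide rollup, detection-floor imputation, quantile
# normalisation, log10 z-standardisation, baseline-relative abundances, PCA
# and hierarchical biclustering QC summaries.

#' Hi3 rollup of peptide intensities to protein abundances
#'
#' Protein abundance per sample is the mean of its three most intense
#' peptides (Hi3 quantitation). Proteins with fewer than three peptides use
#' all available peptides; these are flagged in the provenance attribute
#' `hi3_low_coverage`.
#'
#' @param peptides long tibble with columns protein_id, peptide_id,
#'   sample_id, intensity (>= 0).
#' @return wide abundance tibble (`protein` + one column per sample).
#' @export
hi3_rollup <- function(peptides) {
  if (!is.data.frame(peptides) || nrow(peptides) == 0) {
    abort("peptide table is empty")
  }
  need <- c("protein_id", "peptide_id", "sample_id", "intensity")
  if (!all(need %in% names(peptides))) {
    abort(paste0("peptide table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(peptides$intensity < 0, na.rm = TRUE)) {
    abort("peptide intensities must be >= 0")
  }
  per_protein <- peptides |>
    group_by(.data$protein_id, .data$sample_id) |>
    summarise(
      abundance = mean(sort(.data$intensity, decreasing = TRUE)[
        seq_len(min(3L, length(.data$intensity)))]),
      n_peptides = dplyr::n(),
      .groups = "drop"
    )
  low <- per_protein |>
    group_by(.data$protein_id) |>
    summarise(low = any(.data$n_peptides < 3), .groups = "drop")
  out <- per_protein |>
    select("protein_id", "sample_id", "abundance") |>
    pivot_wider(names_from = "sample_id", values_from = "abundance") |>
    rename(protein = "protein_id") |>
    arrange(.data$protein)
  out <- add_step(out, "hi3_rollup")
  attr(out, "hi3_low_coverage") <- low$protein_id[low$low]
  out
}

#' Impute missing abundances with the per-sample minimum
#'
#' Every missing entry in a sample column is replaced by the minimum
#' observed abundance in that same column (run), emulating a detection
#' floor.
#'
#' @param data wide abundance tibble; `NA` marks missing entries.
#' @return the tibble with no missing entries; provenance records the count
#'   imputed.
#' @export
impute_missing <- function(data) {
  m <- abundance_matrix(data)
  empty <- colSums(!is.na(m)) == 0
  if (any(empty)) {
    abort(paste0("sample column(s) with zero observed values: ",
                 paste(colnames(m)[empty], collapse = ", ")))
  }
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    mins <- apply(m, 2, min, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mins[idx[, 2]]
  }
  out <- matrix_to_tibble(m, data)
  add_step(out, sprintf("impute_missing(n=%d)", n_missing))
}

#' Quantile normalisation across samples
#'
#' Replaces every sample column by the reference distribution (the mean of
#' the column-sorted value vectors) mapped back through the column's ranks,
#' so that each sample shares the same distribution; ties receive the mean
#' of the reference values at their tied ranks. All samples (both
#' conditions, all days) are normalised jointly.
#'
#' @param data wide abundance tibble with no missing entries.
#' @return quantile-normalised tibble.
#' @export
quantile_normalise <- function(data) {
  m <- abundance_matrix(data)
  if (anyNA(m)) {
    abort("matrix has missing entries; run impute_missing() first")
  }
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  out <- matrix_to_tibble(qn, data)
  add_step(out, "quantile_normalise")
}

#' Log10 transform and per-protein z-standardisation
#'
#' Each protein row is log10-transformed and scaled to zero mean and unit
#' sample (n-1) standard deviation. Constant rows are mapped to all zeros
#' and flagged in the `constant_proteins` attribute.
#'
#' @param data wide abundance tibble with strictly positive entries.
#' @return standardised tibble (log10 z-score scale).
#' @export
standardise <- function(data) {
  m <- abundance_matrix(data)
  if (anyNA(m) || any(m <= 0)) {
    abort("standardise() needs strictly positive, complete abundances")
  }
  lg <- log10(m)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1, stats::sd)
  const <- sdv == 0
  z <- (lg - mu) / ifelse(const, 1, sdv)
  z[const, ] <- 0
  out <- matrix_to_tibble(z, data)
  attr(out, "constant_proteins") <- rownames(m)[const]
  add_step(out, "standardise")
}

#' Abundances relative to a baseline group
#'
#' Divides each protein by its mean abundance over the baseline samples
#' (default: healthy at the earliest day present), so the baseline-group
#' mean becomes 1.
#'
#' @param data wide abundance tibble (linear scale, complete).
#' @param meta sample metadata tibble.
#' @param baseline_condition,baseline_day the baseline group.
#' @return tibble of baseline-relative abundances.
#' @export
baseline_relative <- function(data, meta, baseline_condition = "healthy",
                              baseline_day = NULL) {
  m <- abundance_matrix(data)
  meta <- align_meta(data, meta)
  baseline_day <- baseline_day %||% min(meta$day[meta$condition == baseline_condition])
  base_samples <- meta$sample_id[meta$condition == baseline_condition &
                                   meta$day == baseline_day]
  if (length(base_samples) == 0) abort("no baseline samples found")
  base_mean <- rowMeans(m[, base_samples, drop = FALSE])
  if (any(base_mean == 0)) {
    abort("zero baseline mean for at least one protein")
  }
  out <- matrix_to_tibble(m / base_mean, data)
  add_step(out, sprintf("baseline_relative(%s, day %s)",
                        baseline_condition, baseline_day))
}

#' Principal component summary of the samples
#'
#' PCA with samples as observations and proteins as variables, on a matrix
#' that has already been standardised (log10 z-scores). Reports the
#' percentage of variance explained per component and per-sample scores.
#'
#' @param data standardised wide abundance tibble.
#' @return object of class `pca_summary`: list with `variance_explained`
#'   (percentages, non-increasing) and `scores` (tibble sample_id, PC1...).
#' @export
pca_summary <- function(data) {
  m <- abundance_matrix(data)
  if (ncol(m) < 2) abort("PCA needs at least 2 samples")
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x, .name_repair = "minimal")
  scores <- bind_cols(tibble(sample_id = colnames(m)), scores)
  structure(list(variance_explained = ve, scores = scores),
            class = "pca_summary")
}

#' Hierarchical biclustering of proteins and samples
#'
#' Agglomerative clustering of rows (proteins) and columns (samples) with
#' the Euclidean distance and complete linkage, as used for
#' relative-abundance heatmaps.
#'
#' @param data wide abundance tibble with >= 2 rows and >= 2 sample columns.
#' @return object of class `bicluster`: list with `row_hclust`,
#'   `col_hclust` (stats::hclust objects) and `matrix` (the input reordered
#'   by dendrogram leaf order).
#' @export
hierarchical_bicluster <- function(data) {
  m <- abundance_matrix(data)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("biclustering needs at least 2 proteins and 2 samples")
  }
  rows <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "complete")
  cols <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                        method = "complete")
  structure(list(row_hclust = rows, col_hclust = cols,
                 matrix = m[rows$order, cols$order, drop = FALSE]),
            class = "bicluster")
}
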
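# Consensus time-course differential abundance. Three detectors spanning
# the statistical families used for time-course expression data: a
# moderated F-test (shrunken residual variances), a negative-binomial
# likelihood ratio test on pseudo-counts, and a Gaussian polynomial
# likelihood ratio test. A protein is called significantly altered when at
# least `votes` detectors call it at BH FDR `alpha`.

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values, monotone in rank and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must be in [0, 1] and non-missing")
  }
  stats::p.adjust(p, method = "BH")
}

# Average technical repeats into their biological repeat; returns a new
# (data, meta) pair with one column per (condition, day, bio_rep).
average_technical <- function(data, meta) {
  m <- abundance_matrix(data)
  meta <- align_meta(data, meta)
  key <- paste(meta$condition, meta$day, meta$bio_rep, sep = "|")
  groups <- split(seq_len(ncol(m)), key)
  avg <- vapply(groups, function(j) rowMeans(m[, j, drop = FALSE]),
                numeric(nrow(m)))
  new_meta <- meta |>
    distinct(.data$condition, .data$day, .data$bio_rep) |>
    mutate(sample_id = sprintf("%s_d%02d_b%d", .data$condition, .data$day,
                               .data$bio_rep),
           tech_rep = 1L) |>
    select("sample_id", "condition", "day", "bio_rep", "tech_rep")
  colnames(avg) <- new_meta$sample_id[
    match(names(groups), paste(new_meta$condition, new_meta$day,
                               new_meta$bio_rep, sep = "|"))]
  avg <- avg[, new_meta$sample_id, drop = FALSE]
  list(data = matrix_to_tibble(avg, data), meta = new_meta)
}

# Restrict a (data, meta) pair for a condition-contrast design to the days
# observed in both conditions (the unbalanced extra late days carry no
# between-condition information).
restrict_shared_days <- function(data, meta) {
  shared <- intersect(meta$day[meta$condition == "healthy"],
                      meta$day[meta$condition == "disease"])
  keep <- meta$sample_id[meta$day %in% shared]
  list(data = data[, c("protein", keep)], meta = meta[meta$sample_id %in% keep, ])
}

# Prepare matrices and designs common to the detectors. test = "condition"
# contrasts condition + condition:day against a day-only null;
# test = "time" contrasts a day effect against an intercept-only null
# (the ageing analysis on one condition's samples).
prepare_design <- function(data, meta, test, average_tech = TRUE) {
  meta <- align_meta(data, meta)
  if (average_tech && any(meta$tech_rep > 1)) {
    avg <- average_technical(data, meta)
    data <- avg$data
    meta <- avg$meta
  }
  if (test == "condition") {
    if (length(unique(meta$condition)) < 2) {
      abort("condition contrast needs samples from both conditions")
    }
    res <- restrict_shared_days(data, meta)
    data <- res$data
    meta <- res$meta
    cells <- table(meta$condition, meta$day)
    if (any(cells < 2)) abort("every (condition, day) cell needs >= 2 replicates")
    full <- stats::model.matrix(~ condition * factor(day), meta)
    reduced <- stats::model.matrix(~ factor(day), meta)
  } else {
    cells <- table(meta$day)
    if (any(cells < 2)) abort("every day needs >= 2 replicates")
    full <- stats::model.matrix(~ factor(day), meta)
    reduced <- stats::model.matrix(~ 1, meta)
  }
  list(data = data, meta = meta, full = full, reduced = reduced)
}

detector_result <- function(detector, protein, statistic, df, p, flag = NULL) {
  out <- tibble(protein = unname(protein), detector = detector,
                statistic = unname(statistic), df = df,
                p = unname(pmin(pmax(p, 0), 1)))
  out$q <- bh_adjust(out$p)
  if (!is.null(flag)) out$flag <- flag
  out
}

# Residual sums of squares of every protein under a design, via one QR.
rss_fit <- function(X, Y) {
  qr_x <- qr(X)
  res <- qr.resid(qr_x, t(Y))
  list(rss = colSums(res^2), rank = qr_x$rank)
}

#' Moderated F-test detector
#'
#' Fits per-protein linear models on log10 abundances with condition, day
#' (categorical) and their interaction, shrinks residual variances toward a
#' common prior by moment-matching a scaled inverse-chi-square distribution
#' to the observed variances, and tests the condition plus interaction
#' terms with a moderated F statistic (empirical-Bayes family). In the
#' infinite-prior-degrees-of-freedom limit the statistic reduces to the
#' ordinary F with pooled variance.
#'
#' @param data wide abundance tibble, linear scale, strictly positive.
#' @param meta sample metadata tibble.
#' @param test `"condition"` (condition + interaction vs day-only) or
#'   `"time"` (day effect vs intercept; the ageing design).
#' @param average_tech average technical repeats into their biological
#'   repeat before fitting (default TRUE, avoiding pseudo-replication).
#' @return detector tibble: protein, detector, statistic, df, p, q.
#' @export
detect_moderated_f <- function(data, meta, test = c("condition", "time"),
                               average_tech = TRUE) {
  test <- match.arg(test)
  prep <- prepare_design(data, meta, test, average_tech)
  m <- abundance_matrix(prep$data)
  if (anyNA(m) || any(m <= 0)) {
    abort("detector needs complete, strictly positive abundances")
  }
  Y <- log10(m)
  full <- rss_fit(prep$full, Y)
  red <- rss_fit(prep$reduced, Y)
  df1 <- full$rank - red$rank
  df_res <- ncol(Y) - full$rank
  if (df1 < 1 || df_res < 1) abort("design is not testable (no residual df)")

  s2 <- full$rss / df_res
  mom <- mean(s2)
  vom <- stats::var(s2)
  if (!is.finite(vom) || vom <= 0 || mom <= 0) {
    d0 <- Inf
  } else {
    d0 <- 4 + 2 * mom^2 / vom
  }
  if (is.finite(d0)) {
    s0_sq <- mom * (d0 - 2) / d0
    s2_post <- (d0 * s0_sq + df_res * s2) / (d0 + df_res)
  } else {
    s2_post <- rep(mom, length(s2))
  }
  fstat <- ((red$rss - full$rss) / df1) / s2_post
  fstat[!is.finite(fstat) | red$rss <= 1e-16] <- 0
  fstat <- pmax(fstat, 0)
  p <- stats::pf(fstat, df1, df_res + d0, lower.tail = FALSE)
  detector_result("moderated_f", rownames(m), fstat, df1, p)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: median across proteins of the ratio of the
#' sample's abundance to the protein's geometric mean over all samples
#' (proteins with any non-positive value are excluded from the reference).
#'
#' @param m numeric matrix, proteins x samples, non-negative.
#' @return named numeric vector of size factors (1 when no reference
#'   protein exists).
#' @export
size_factors <- function(m) {
  pos <- rowSums(m <= 0) == 0
  if (!any(pos)) {
    return(stats::setNames(rep(1, ncol(m)), colnames(m)))
  }
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE] / ref, 2, stats::median)
  stats::setNames(sf, colnames(m))
}

#' Negative-binomial likelihood-ratio detector
#'
#' Scales abundances to pseudo-counts with median-of-ratios size factors
#' and round-half-to-even, estimates a per-protein method-of-moments
#' dispersion from the replicated design cells (common to both models),
#' fits negative-binomial GLMs with a log link under the full and reduced
#' designs, and tests with a chi-square likelihood ratio. All-zero proteins
#' get p = 1 with a flag rather than an error.
#'
#' @inheritParams detect_moderated_f
#' @return detector tibble with a `flag` column (`"all_zero"` / `"fit"` /
#'   `NA`).
#' @export
detect_nb_lrt <- function(data, meta, test = c("condition", "time"),
                          average_tech = TRUE) {
  test <- match.arg(test)
  prep <- prepare_design(data, meta, test, average_tech)
  m <- abundance_matrix(prep$data)
  if (anyNA(m) || any(m < 0)) abort("detector needs complete non-negative abundances")

  sf <- size_factors(m)
  counts <- round(sweep(m, 2, sf, "/"))  # round() is half-to-even
  counts[counts < 0] <- 0

  full <- prep$full
  reduced <- prep$reduced
  df1 <- qr(full)$rank - qr(reduced)$rank
  cell <- interaction(prep$meta$condition, prep$meta$day, drop = TRUE)

  n_prot <- nrow(counts)
  stat <- p <- rep(NA_real_, n_prot)
  flag <- rep(NA_character_, n_prot)
  for (i in seq_len(n_prot)) {
    y <- counts[i, ]
    if (all(y == 0)) {
      stat[i] <- 0; p[i] <- 1; flag[i] <- "all_zero"
      next
    }
    mu_c <- tapply(y, cell, mean)
    va_c <- tapply(y, cell, stats::var)
    ok <- !is.na(va_c) & mu_c > 0
    alpha <- if (any(ok)) {
      sum(pmax(va_c[ok] - mu_c[ok], 0)) / sum(mu_c[ok]^2)
    } else 0
    alpha <- min(max(alpha, 1e-8), 10)
    fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
    fit <- tryCatch({
      f1 <- suppressWarnings(stats::glm.fit(full, y, family = fam))
      f0 <- suppressWarnings(stats::glm.fit(reduced, y, family = fam))
      max(f0$deviance - f1$deviance, 0)
    }, error = function(e) NA_real_)
    if (is.na(fit)) {
      stat[i] <- 0; p[i] <- 1; flag[i] <- "fit"
    } else {
      stat[i] <- fit
      p[i] <- stats::pchisq(fit, df1, lower.tail = FALSE)
    }
  }
  detector_result("nb_lrt", rownames(counts), stat, df1, p, flag)
}

#' Polynomial likelihood-ratio detector
#'
#' Gaussian log-likelihood ratio of a polynomial-in-day model that differs
#' by condition against the shared-polynomial null (for `test =
#' "condition"`), or of a polynomial day trend against a constant (for
#' `test = "time"`); p-values from the chi-square reference with degrees of
#' freedom equal to the difference in parameter counts. Degree 0 reduces to
#' a two-group mean comparison pooled over days.
#'
#' @inheritParams detect_moderated_f
#' @param degree polynomial degree in day (small integer; needs at least
#'   `degree + 1` distinct days and residual degrees of freedom).
#' @return detector tibble.
#' @export
detect_polynomial_lrt <- function(data, meta, test = c("condition", "time"),
                                  degree = 2, average_tech = TRUE) {
  test <- match.arg(test)
  prep <- prepare_design(data, meta, test, average_tech)
  meta2 <- prep$meta
  n_days <- length(unique(meta2$day))
  if (degree > n_days - 1) {
    abort(sprintf("degree %d too high for %d distinct time points",
                  degree, n_days))
  }
  m <- abundance_matrix(prep$data)
  if (anyNA(m) || any(m <= 0)) {
    abort("detector needs complete, strictly positive abundances")
  }
  Y <- log10(m)
  if (test == "condition") {
    if (degree == 0) {
      full <- stats::model.matrix(~ condition, meta2)
      reduced <- stats::model.matrix(~ 1, meta2)
    } else {
      full <- stats::model.matrix(~ poly(day, degree) * condition, meta2)
      reduced <- stats::model.matrix(~ poly(day, degree), meta2)
    }
  } else {
    if (degree == 0) abort("time test needs degree >= 1")
    full <- stats::model.matrix(~ poly(day, degree), meta2)
    reduced <- stats::model.matrix(~ 1, meta2)
  }
  f1 <- rss_fit(full, Y)
  f0 <- rss_fit(reduced, Y)
  if (ncol(Y) - f1$rank < 1) abort("degree too high: no residual degrees of freedom")
  df1 <- f1$rank - f0$rank
  stat <- ncol(Y) * log(pmax(f0$rss, 1e-300) / pmax(f1$rss, 1e-300))
  stat <- pmax(stat, 0)
  # rows the reduced model already fits to machine precision (e.g. rows made
  # constant by quantile normalisation) carry no testable signal
  stat[f0$rss <= 1e-16] <- 0
  p <- stats::pchisq(stat, df1, lower.tail = FALSE)
  detector_result("polynomial_lrt", rownames(m), stat, df1, p)
}

#' Combine detector calls by vote
#'
#' A protein is significantly altered when at least `votes` detectors give
#' it a BH q-value below `alpha`.
#'
#' @param results list of detector tibbles over the same protein universe.
#' @param alpha FDR level per detector (default 0.05).
#' @param votes minimum number of agreeing detectors (default 2).
#' @return consensus tibble: protein, votes, significant, plus one logical
#'   `called_<detector>` column per detector.
#' @export
consensus_vote <- function(results, alpha = 0.05, votes = 2) {
  if (length(results) < 2) abort("consensus needs at least 2 detectors")
  universe <- sort(results[[1]]$protein)
  for (r in results) {
    if (!identical(sort(r$protein), universe)) {
      abort("detectors disagree on the protein universe")
    }
  }
  calls <- lapply(results, function(r) {
    stats::setNames(r$q < alpha, r$protein)[universe]
  })
  names(calls) <- vapply(results, function(r) r$detector[1], character(1))
  call_mat <- do.call(cbind, calls)
  vote_threshold <- votes
  n_votes <- as.integer(rowSums(call_mat))
  out <- tibble(protein = universe,
                votes = n_votes,
                significant = n_votes >= vote_threshold)
  for (nm in colnames(call_mat)) out[[paste0("called_", nm)]] <- call_mat[, nm]
  attr(out, "alpha") <- alpha
  attr(out, "vote_threshold") <- votes
  out
}

#' Run the default detector trio and vote
#'
#' Convenience wrapper: moderated F, NB-LRT and polynomial LRT on the same
#' design, combined with [consensus_vote()].
#'
#' @inheritParams detect_moderated_f
#' @param alpha,votes consensus parameters.
#' @param degree polynomial degree for the polynomial LRT detector.
#' @return consensus tibble (see [consensus_vote()]); detector tibbles are
#'   attached as the `detectors` attribute.
#' @export
run_consensus <- function(data, meta, test = c("condition", "time"),
                          alpha = 0.05, votes = 2, degree = 2,
                          average_tech = TRUE) {
  test <- match.arg(test)
  detectors <- list(
    detect_moderated_f(data, meta, test, average_tech),
    detect_nb_lrt(data, meta, test, average_tech),
    detect_polynomial_lrt(data, meta, test, degree, average_tech)
  )
  out <- consensus_vote(detectors, alpha, votes)
  attr(out, "detectors") <- detectors
  out
}

#' Partition disease- and ageing-altered protein sets
#'
#' Given the condition-contrast consensus (disease vs healthy) and the
#' ageing consensus (time effect in healthy samples), labels every protein
#' as disease-only, ageing-only, shared or neither.
#'
#' @param disease,ageing consensus tibbles over the same protein universe.
#' @return tibble (protein, label); the named integer vector of set sizes
#'   is attached as the `sizes` attribute.
#' @export
compare_condition_sets <- function(disease, ageing) {
  if (!identical(sort(disease$protein), sort(ageing$protein))) {
    abort("consensus results cover different protein universes")
  }
  d <- stats::setNames(disease$significant, disease$protein)
  a <- stats::setNames(ageing$significant, ageing$protein)[names(d)]
  label <- dplyr::case_when(
    d & a ~ "shared",
    d & !a ~ "disease_only",
    !d & a ~ "ageing_only",
    TRUE ~ "neither"
  )
  out <- tibble(protein = names(d), label = label)
  sizes <- c(disease = sum(d), ageing = sum(a),
             shared = sum(d & a), disease_only = sum(d & !a),
             ageing_only = sum(!d & a), neither = sum(!d & !a))
  attr(out, "sizes") <- sizes
  out
}
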
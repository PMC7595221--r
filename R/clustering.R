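# Gaussian mixture profile clustering with a cluster-count BIC. Profiles
# are per-(condition, day) mean log10 z-scores of the significantly altered
# proteins; the mixture has diagonal covariances and is fitted by EM with
# k-means++-style restarts.

#' Build a profile matrix for clustering
#'
#' For each protein, the mean log10 abundance per (condition, day) cell,
#' z-scored per protein across the cells, so clustering sees temporal shape
#' rather than absolute level.
#'
#' @param data wide abundance tibble, linear scale, strictly positive.
#' @param meta sample metadata tibble.
#' @param proteins optional character vector restricting the rows (e.g. the
#'   consensus-significant proteins).
#' @return wide tibble `protein` + one column per `condition_day` cell,
#'   rows standardised to mean 0, sd 1.
#' @export
profile_matrix <- function(data, meta, proteins = NULL) {
  meta <- align_meta(data, meta)
  if (!is.null(proteins)) {
    data <- data[data$protein %in% proteins, , drop = FALSE]
    if (nrow(data) == 0) abort("none of the requested proteins are present")
  }
  m <- abundance_matrix(data)
  if (anyNA(m) || any(m <= 0)) abort("profiles need complete, positive abundances")
  lg <- log10(m)
  key <- paste(meta$condition, meta$day, sep = "_")
  ord <- order(match(meta$condition, c("healthy", "disease")), meta$day)
  cells <- unique(key[ord])
  prof <- vapply(cells, function(cl) {
    rowMeans(lg[, key == cl, drop = FALSE])
  }, numeric(nrow(lg)))
  mu <- rowMeans(prof)
  sdv <- apply(prof, 1, stats::sd)
  sdv[sdv == 0] <- 1
  prof <- (prof - mu) / sdv
  matrix_to_tibble(prof)
}

# k-means++-style selection of k initial means from the rows of X.
init_means <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k > 1) {
    d2 <- colSums((t(X) - centers[1, ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 else rep(1, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, colSums((t(X) - centers[j, ])^2))
    }
  }
  centers
}

log_dens_diag <- function(X, mean, var) {
  # log N(x | mean, diag(var)) for every row of X
  colSums(stats::dnorm(t(X), mean, sqrt(var), log = TRUE))
}

# Initial means from complete-linkage hierarchical clustering cut at k
# (mclust-style deterministic initialisation; good at separating
# well-defined temporal archetypes).
init_means_hclust <- function(X, k) {
  cl <- stats::cutree(stats::hclust(stats::dist(X), method = "complete"), k)
  t(vapply(seq_len(k), function(j) colMeans(X[cl == j, , drop = FALSE]),
           numeric(ncol(X))))
}

em_gmm_once <- function(X, k, var_floor = 1e-6, max_iter = 500, tol = 1e-8,
                        means = NULL) {
  n <- nrow(X); d <- ncol(X)
  means <- means %||% init_means(X, k)
  vars <- matrix(rep(pmax(apply(X, 2, stats::var), var_floor), each = k), k, d)
  weights <- rep(1 / k, k)
  trace <- numeric(0)
  ll_old <- -Inf
  resp <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j) {
      log(weights[j]) + log_dens_diag(X, means[j, ], vars[j, ])
    }, numeric(n))
    logp <- matrix(logp, n, k)
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logp - lse)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
    ll_old <- ll
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    weights <- nk / n
    means <- t(vapply(seq_len(k), function(j) {
      colSums(resp[, j] * X) / nk[j]
    }, numeric(d)))
    vars <- t(vapply(seq_len(k), function(j) {
      pmax(colSums(resp[, j] * (X - matrix(means[j, ], n, d, byrow = TRUE))^2) /
             nk[j], var_floor)
    }, numeric(d)))
  }
  nk <- colSums(resp)
  # a component collapsed onto (nearly) a single point, with variances at
  # the floor, inflates the likelihood without modelling anything
  degenerate <- any(nk < 2) || any(apply(vars <= var_floor * 1.001, 1, all))
  list(weights = weights, means = means, vars = vars,
       loglik = trace[length(trace)], trace = trace, resp = resp,
       degenerate = degenerate)
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' Best of several EM restarts (k-means++-style initial means, seeds
#' derived from `seeds`) by final log-likelihood. Variances are floored at
#' `var_floor`; the log-likelihood is checked to be non-decreasing across
#' EM iterations on every fit.
#'
#' @param profiles wide profile tibble from [profile_matrix()].
#' @param k number of mixture components (1 <= k <= number of proteins).
#' @param seeds integer vector, one EM restart per seed.
#' @param var_floor variance floor per dimension.
#' @return object of class `gmm_fit`: list with k, weights, means, vars,
#'   loglik, resp (responsibilities), trace, seed, proteins.
#' @export
fit_gmm <- function(profiles, k, seeds = 1:5, var_floor = 1e-6) {
  X <- abundance_matrix(profiles)
  n <- nrow(X)
  if (k < 1) abort("k must be >= 1")
  if (k > n) abort(sprintf("k = %d exceeds the %d available proteins", k, n))
  starts <- c(as.list(as.integer(seeds)), list("hclust"))
  best <- NULL
  for (s in starts) {
    fit <- if (identical(s, "hclust")) {
      withr::with_seed(0L, em_gmm_once(X, k, var_floor = var_floor,
                                       means = init_means_hclust(X, k)))
    } else {
      withr::with_seed(s, em_gmm_once(X, k, var_floor = var_floor))
    }
    if (any(diff(fit$trace) < -1e-8 * pmax(abs(fit$trace[-length(fit$trace)]), 1))) {
      abort("EM log-likelihood decreased; numerical failure")
    }
    better <- is.null(best) ||
      (best$degenerate && !fit$degenerate) ||
      (fit$degenerate == best$degenerate && fit$loglik > best$loglik)
    if (better) {
      best <- fit
      best$seed <- if (identical(s, "hclust")) NA_integer_ else s
    }
  }
  structure(list(k = as.integer(k), weights = best$weights,
                 means = best$means, vars = best$vars,
                 loglik = best$loglik, resp = best$resp,
                 trace = best$trace, seed = best$seed,
                 degenerate = best$degenerate,
                 proteins = rownames(X)),
            class = "gmm_fit")
}

#' Cluster-count BIC of a mixture fit
#'
#' Default penalty counts the number of clusters:
#' `BIC = -2 ln(L) + ln(n) k`. The `"parameters"` mode instead uses the
#' standard free-parameter count of a diagonal-covariance mixture,
#' `k(2d + 1) - 1`.
#'
#' @param fit a [fit_gmm()] object.
#' @param n number of clustered proteins (>= 1); defaults to the number of
#'   rows the model was fitted to.
#' @param penalty `"clusters"` (default) or `"parameters"`.
#' @return numeric BIC value (smaller is better).
#' @export
bic_score <- function(fit, n = length(fit$proteins),
                      penalty = c("clusters", "parameters")) {
  penalty <- match.arg(penalty)
  if (n < 1) abort("n must be >= 1")
  if (fit$k < 1) abort("k must be >= 1")
  d <- ncol(fit$means)
  n_par <- switch(penalty,
                  clusters = fit$k,
                  parameters = fit$k * (2 * d + 1) - 1)
  -2 * fit$loglik + log(n) * n_par
}

#' Select the number of clusters by BIC
#'
#' Fits mixtures for k = 1..`k_max` and picks the k with the smallest BIC
#' (ties broken toward smaller k). Deterministic given `seeds`. Fits in
#' which a component collapsed onto the variance floor are excluded from
#' the selection (their likelihood is inflated by the collapse).
#'
#' @inheritParams fit_gmm
#' @param k_max largest cluster count to try; default `min(n, 30)`.
#' @param penalty see [bic_score()]; selection defaults to the
#'   free-parameter count, which penalises each added component by its
#'   actual `2d + 1` parameters -- the cluster-count penalty is far weaker
#'   than one component's worth of likelihood gain and tends to run to
#'   `k_max`.
#' @return object of class `bic_trace`: list with `trace` (tibble k,
#'   loglik, bic), `selected_k`, `fits` (list of gmm_fit), `n`.
#' @export
select_cluster_count <- function(profiles, k_max = NULL, seeds = 1:5,
                                 penalty = c("parameters", "clusters"),
                                 var_floor = 1e-6) {
  penalty <- match.arg(penalty)
  n <- nrow(profiles)
  k_max <- k_max %||% min(n, 30L)
  if (k_max < 1) abort("k_max must be >= 1")
  if (k_max > n) abort("k_max cannot exceed the number of proteins")
  fits <- lapply(seq_len(k_max), function(k) {
    fit_gmm(profiles, k, seeds = seeds, var_floor = var_floor)
  })
  bic <- vapply(fits, bic_score, numeric(1), n = n, penalty = penalty)
  degen <- vapply(fits, function(f) isTRUE(f$degenerate), logical(1))
  trace <- tibble(k = seq_len(k_max),
                  loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                  bic = bic, degenerate = degen)
  # degenerate fits (a component collapsed to the variance floor) carry an
  # inflated likelihood; exclude them from selection when possible
  candidates <- if (all(degen)) seq_len(k_max) else which(!degen)
  selected <- candidates[which.min(bic[candidates])]
  structure(list(trace = trace, selected_k = selected,
                 fits = fits, n = n, penalty = penalty),
            class = "bic_trace")
}

#' Hard cluster assignment from a mixture fit
#'
#' Each protein is labelled by its argmax responsibility; exact ties go to
#' the lower-index cluster.
#'
#' @param fit a [fit_gmm()] object.
#' @return tibble: protein, cluster, responsibility (the winning posterior
#'   probability).
#' @export
assign_profiles <- function(fit) {
  cl <- max.col(fit$resp, ties.method = "first")
  tibble(protein = fit$proteins,
         cluster = as.integer(cl),
         responsibility = fit$resp[cbind(seq_along(cl), cl)])
}

#' Mean profile per cluster
#'
#' @param fit a [fit_gmm()] object.
#' @param profiles the profile tibble the model was fitted to.
#' @return tibble: cluster, cell, mean_z.
#' @export
cluster_mean_profiles <- function(fit, profiles) {
  X <- abundance_matrix(profiles)
  assign <- assign_profiles(fit)
  purrr::map_dfr(sort(unique(assign$cluster)), function(cl) {
    rows <- assign$protein[assign$cluster == cl]
    tibble(cluster = cl, cell = colnames(X),
           mean_z = colMeans(X[rows, , drop = FALSE]))
  })
}
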
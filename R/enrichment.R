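# Overrepresentation analysis: one-sided Fisher (hypergeometric) tests of a
# query set against annotation terms restricted to a custom background, BH
# corrected; plus a ranked-list minimum-hypergeometric (mHG) statistic.

#' Fisher overrepresentation of a query set
#'
#' Term sets are first intersected with the background universe; terms
#' smaller than `min_term_size` after restriction are not tested. For each
#' remaining term the one-sided (greater) hypergeometric p-value of the
#' query/term overlap is computed and BH-adjusted across tested terms.
#' Query ids outside the universe are dropped with a warning count.
#'
#' @param query character vector of protein ids.
#' @param sets named list of term -> protein-id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector, the custom background.
#' @param min_term_size smallest restricted term size tested (default 3).
#' @return tibble sorted by p: term, k (overlap), K (term size), n (query
#'   size), N (universe size), odds_ratio, p, q.
#' @export
fisher_overrepresentation <- function(query, sets, universe,
                                      min_term_size = 3) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe is empty")
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    warn(sprintf("%d query id(s) outside the universe were dropped",
                 length(dropped)))
  }
  query <- intersect(unique(query), universe)
  sets <- lapply(sets, intersect, universe)
  sets <- sets[vapply(sets, length, integer(1)) >= min_term_size]
  N <- length(universe)
  n <- length(query)
  rows <- purrr::map_dfr(names(sets), function(term) {
    K <- length(sets[[term]])
    k <- length(intersect(query, sets[[term]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
    tibble(term = term, k = k, K = K, n = n, N = N,
           odds_ratio = or, p = p)
  })
  if (nrow(rows) == 0) {
    return(tibble(term = character(0), k = integer(0), K = integer(0),
                  n = integer(0), N = integer(0), odds_ratio = numeric(0),
                  p = numeric(0), q = numeric(0)))
  }
  rows$q <- bh_adjust(rows$p)
  arrange(rows, .data$p, .data$term)
}

#' Minimum hypergeometric (mHG) statistic of a ranked list
#'
#' For every prefix of the ranked list, the hypergeometric upper-tail
#' probability of the observed prefix/term overlap is computed; the mHG
#' score is the minimum over prefixes, attained at the reported cutoff
#' (smallest minimising prefix). Significance is assessed by permuting the
#' term labels over the list.
#'
#' @param ranked_ids character vector ranked best-first, no duplicates.
#' @param term_set character vector of term members (subset of the list).
#' @param n_perm label permutations for the empirical p-value (0 skips it).
#' @param seed integer seed for the permutations.
#' @return list with `score` (the mHG minimum), `cutoff` (minimising prefix
#'   length) and `p_value` (add-one empirical, or NA when `n_perm = 0`).
#' @export
ranked_mhg <- function(ranked_ids, term_set, n_perm = 1000, seed = 1L) {
  if (anyDuplicated(ranked_ids)) abort("ranked list contains duplicates")
  if (!all(term_set %in% ranked_ids)) {
    abort("term_set must be contained in the ranked list")
  }
  N <- length(ranked_ids)
  B <- length(term_set)
  mhg_of <- function(member) {
    b <- cumsum(member)
    prefix_p <- stats::phyper(b - 1, B, N - B, seq_len(N), lower.tail = FALSE)
    list(score = min(prefix_p), cutoff = which.min(prefix_p))
  }
  obs <- mhg_of(ranked_ids %in% term_set)
  p_value <- NA_real_
  if (n_perm > 0) {
    perm_scores <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        member <- logical(N)
        member[sample.int(N, B)] <- TRUE
        mhg_of(member)$score
      }, numeric(1))
    })
    p_value <- (1 + sum(perm_scores <= obs$score)) / (1 + n_perm)
  }
  list(score = obs$score, cutoff = obs$cutoff, p_value = p_value)
}
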
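# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Gaussian mixture fit
#'
#' One row per mixture component and profile dimension, with the component
#' weight, mean and variance.
#'
#' @param x a [fit_gmm()] object.
#' @param ... unused.
#' @return tibble: component, weight, dimension, mean, variance.
#' @export
tidy.gmm_fit <- function(x, ...) {
  d <- ncol(x$means)
  dims <- colnames(x$means) %||% paste0("dim", seq_len(d))
  purrr::map_dfr(seq_len(x$k), function(j) {
    tibble(component = j, weight = x$weights[j], dimension = dims,
           mean = x$means[j, ], variance = x$vars[j, ])
  })
}

#' @rdname tidy.gmm_fit
#' @return `glance()`: one-row tibble with k, loglik, n, n_iter, bic.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, n = length(x$proteins),
         n_iter = length(x$trace), bic = bic_score(x))
}

#' Tidy a BIC model-selection trace
#'
#' @param x a [select_cluster_count()] object.
#' @param ... unused.
#' @return `tidy()`: the per-k trace tibble; `glance()`: one row with the
#'   selected k and its BIC.
#' @export
tidy.bic_trace <- function(x, ...) x$trace

#' @rdname tidy.bic_trace
#' @export
glance.bic_trace <- function(x, ...) {
  tibble(selected_k = x$selected_k,
         bic = x$trace$bic[x$selected_k],
         loglik = x$trace$loglik[x$selected_k],
         n = x$n, penalty = x$penalty)
}

#' Tidy a PCA summary
#'
#' @param x a [pca_summary()] object.
#' @param ... unused.
#' @return `tidy()`: tibble component / variance_explained; `glance()`:
#'   one row with the leading two components' percentages.
#' @export
tidy.pca_summary <- function(x, ...) {
  tibble(component = seq_along(x$variance_explained),
         variance_explained = x$variance_explained)
}

#' @rdname tidy.pca_summary
#' @export
glance.pca_summary <- function(x, ...) {
  tibble(pc1_pct = x$variance_explained[1],
         pc2_pct = x$variance_explained[2],
         n_components = length(x$variance_explained))
}
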
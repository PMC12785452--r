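# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ridge-Cox fit
#'
#' @param x a `morpho_ridge_cox`.
#' @param ... unused.
#' @return tibble: variable, coef, hr, ci_low, ci_high, p.
#' @export
tidy.morpho_ridge_cox <- function(x, ...) x$coefs

#' @rdname tidy.morpho_ridge_cox
#' @export
glance.morpho_ridge_cox <- function(x, ...) {
  tibble::tibble(c_index = x$c_index, c_index_cv = x$c_index_cv,
                 c_index_cv_sd = x$c_index_cv_sd, penalizer = x$penalizer,
                 scale = x$scale, n = x$n, n_events = x$n_events)
}

#' Tidy a log-rank result
#'
#' @param x a `morpho_logrank`.
#' @param ... unused.
#' @return pairwise comparisons when available, otherwise the global test.
#' @export
tidy.morpho_logrank <- function(x, ...) {
  if (!is.null(x$pairwise)) return(x$pairwise)
  tibble::tibble(chi2 = x$chi2, df = x$df, p = x$p)
}

#' @rdname tidy.morpho_logrank
#' @export
glance.morpho_logrank <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p = x$p,
                 n_groups = length(x$group_sizes))
}

#' Tidy an attractor model
#'
#' @param x an `attractor_model`.
#' @param ... unused.
#' @return tibble with one row per case: `case_id` (when known) and the
#'   0-based attractor `label`.
#' @export
tidy.attractor_model <- function(x, ...) {
  tibble::tibble(case_id = x$case_id %||% seq_along(x$labels),
                 label = x$labels)
}

#' @rdname tidy.attractor_model
#' @export
glance.attractor_model <- function(x, ...) {
  tibble::tibble(K = x$K, silhouette = x$indices$silhouette,
                 davies_bouldin = x$indices$davies_bouldin,
                 calinski_harabasz = x$indices$calinski_harabasz,
                 ari_mean = x$ari_mean, ari_sd = x$ari_sd,
                 ari_pairs = x$ari_pairs, inertia = x$inertia)
}

#' Tidy a K-scan
#'
#' @param x a `morpho_kscan`.
#' @param ... unused.
#' @return the per-K validity-index tibble.
#' @export
tidy.morpho_kscan <- function(x, ...) x$indices

#' @rdname tidy.morpho_kscan
#' @export
glance.morpho_kscan <- function(x, ...) {
  best <- x$indices[which.max(x$indices$silhouette), ]
  tibble::tibble(selected_k = x$selected_k,
                 silhouette = best$silhouette,
                 davies_bouldin = best$davies_bouldin,
                 calinski_harabasz = best$calinski_harabasz)
}

#' Tidy a permutation test
#'
#' @param x a `morpho_permtest`.
#' @param ... unused.
#' @return tibble of null silhouette scores (one row per replicate).
#' @export
tidy.morpho_permtest <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_scores),
                 silhouette = x$null_scores)
}

#' @rdname tidy.morpho_permtest
#' @export
glance.morpho_permtest <- function(x, ...) {
  tibble::tibble(observed_silhouette = x$observed_silhouette,
                 p_value = x$p_value, B = x$B, scheme = x$scheme,
                 null_mean = mean(x$null_scores),
                 null_sd = stats::sd(x$null_scores))
}

#' Tidy dynamic attractors
#'
#' @param x a `dynamic_attractors`.
#' @param ... unused.
#' @return tibble: case index, dynamic label, convergence flag,
#'   normalized trailing variance.
#' @export
tidy.dynamic_attractors <- function(x, ...) {
  tibble::tibble(case = seq_along(x$labels), attr_dynamic = x$labels,
                 converged = x$converged,
                 endpoint_variance = x$endpoint_variance)
}

#' @rdname tidy.dynamic_attractors
#' @export
glance.dynamic_attractors <- function(x, ...) {
  tibble::tibble(K = x$K, convergence_fraction = x$convergence_fraction,
                 mean_endpoint_variance = mean(x$endpoint_variance))
}
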
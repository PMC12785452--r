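# ---------------------------------------------------------------------------
# Static attractor discovery: K-means with cluster-validity model selection,
# seed-robustness (pairwise ARI), permutation validation of the silhouette,
# and canonical risk ordering of the basins.
# ---------------------------------------------------------------------------

#' Internal cluster-validity indices
#'
#' Silhouette (mean over cases), Davies-Bouldin and Calinski-Harabasz,
#' computed from first principles (Euclidean geometry).
#'
#' @param X numeric matrix (cases x features).
#' @param labels integer cluster labels.
#' @return named list: `silhouette`, `davies_bouldin`,
#'   `calinski_harabasz`.
#' @export
cluster_indices <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  K <- length(ks)
  n <- nrow(X)
  stopifnot(K >= 2, n == length(labels))
  D <- as.matrix(stats::dist(X))

  # silhouette: a = mean dist within own cluster, b = min over other clusters
  sil <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1L) return(0)
    a <- sum(D[i, own]) / (n_own - 1L)
    b <- min(vapply(ks[ks != labels[i]], function(k)
      mean(D[i, labels == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))

  cent <- t(vapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]),
                   numeric(ncol(X))))
  if (ncol(X) == 1L) cent <- matrix(cent, ncol = 1L)
  sizes <- vapply(ks, function(k) sum(labels == k), numeric(1))
  # Davies-Bouldin: mean over clusters of max (s_i + s_j) / d_ij
  s_k <- vapply(ks, function(k) {
    mean(sqrt(rowSums(sweep(X[labels == k, , drop = FALSE], 2,
                            cent[k, ])^2)))
  }, numeric(1))
  db <- mean(vapply(seq_len(K), function(i) {
    max(vapply(seq_len(K)[-i], function(j)
      (s_k[i] + s_k[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2)),
      numeric(1)))
  }, numeric(1)))
  # Calinski-Harabasz: (B/(K-1)) / (W/(n-K))
  gmean <- colMeans(X)
  B <- sum(sizes * rowSums(sweep(cent, 2, gmean)^2))
  W <- sum(vapply(ks, function(k)
    sum(sweep(X[labels == k, , drop = FALSE], 2, cent[k, ])^2),
    numeric(1)))
  ch <- (B / (K - 1)) / (W / (n - K))
  list(silhouette = mean(sil), davies_bouldin = db, calinski_harabasz = ch)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement, invariant to label permutation; 1 for
#' identical partitions.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

km_fit <- function(X, K, seed, nstart = 10L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  stats::kmeans(X, centers = K, nstart = nstart, iter.max = 100L)
}

#' Scan the number of clusters with validity indices
#'
#' Fits K-means for each K in `k_range` and reports silhouette (max is
#' best), Davies-Bouldin (min is best) and Calinski-Harabasz (max is best);
#' the selected K maximizes the silhouette.
#'
#' @param tbl embedding table or latent matrix.
#' @param k_range candidate cluster counts (default 2..10).
#' @param seed RNG seed for the K-means restarts.
#' @return object of class `morpho_kscan`: tibble `indices` plus
#'   `selected_k`.
#' @export
scan_k <- function(tbl, k_range = 2:10, seed = 42L) {
  X <- if (is.matrix(tbl)) tbl else latent_matrix(tbl)
  if (max(k_range) >= nrow(X))
    stop("scan_k: largest K must be below the number of cases")
  rows <- lapply(k_range, function(K) {
    fit <- km_fit(X, K, seed + K)
    idx <- cluster_indices(X, fit$cluster)
    tibble::tibble(k = K, silhouette = idx$silhouette,
                   davies_bouldin = idx$davies_bouldin,
                   calinski_harabasz = idx$calinski_harabasz)
  })
  indices <- dplyr::bind_rows(rows)
  structure(list(indices = indices,
                 selected_k = indices$k[which.max(indices$silhouette)]),
            class = "morpho_kscan")
}

#' Fit the attractor model
#'
#' Runs K-means from `n_seeds` independent seeds, retains the best-inertia
#' solution and reports the mean/sd adjusted Rand index over all pairwise
#' seed comparisons (`n_seeds * (n_seeds - 1) / 2` pairs) as the
#' reproducibility certificate.
#'
#' @param tbl embedding table or latent matrix.
#' @param K number of attractors (default 3).
#' @param n_seeds independent restarts (default 10).
#' @param seed base RNG seed.
#' @return object of class `attractor_model`: `centroids` (K x d),
#'   `labels` (0-based attractor index per case), `indices`, `ari_mean`,
#'   `ari_sd`, `ari_pairs`, `inertia`.
#' @export
fit_attractors <- function(tbl, K = 3L, n_seeds = 10L, seed = 42L) {
  X <- if (is.matrix(tbl)) tbl else latent_matrix(tbl)
  stopifnot(K >= 2, nrow(X) > K)
  fits <- lapply(seq_len(n_seeds), function(s) km_fit(X, K, seed + s))
  sizes_ok <- vapply(fits, function(f) all(f$size > 0), logical(1))
  if (!all(sizes_ok)) fits <- fits[sizes_ok]
  inertia <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  best <- fits[[which.min(inertia)]]
  pairs <- utils::combn(length(fits), 2)
  aris <- apply(pairs, 2, function(p)
    adjusted_rand_index(fits[[p[1]]]$cluster, fits[[p[2]]]$cluster))
  case_id <- if (!is.matrix(tbl) && "case_id" %in% names(tbl))
    tbl$case_id else NULL
  structure(list(
    K = as.integer(K),
    centroids = best$centers,
    labels = as.integer(best$cluster) - 1L,
    case_id = case_id,
    indices = cluster_indices(X, best$cluster),
    ari_mean = mean(aris), ari_sd = stats::sd(aris),
    ari_pairs = length(aris),
    inertia = min(inertia)
  ), class = "attractor_model")
}

#' Assign new latent vectors to attractors
#'
#' @param object an `attractor_model`.
#' @param newdata latent matrix or embedding table.
#' @param ... unused.
#' @return 0-based attractor labels; attribute `"margin"` carries the
#'   distance gap between the closest and second-closest centroid.
#' @export
predict.attractor_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else latent_matrix(newdata)
  D <- vapply(seq_len(object$K), function(k)
    sqrt(rowSums(sweep(X, 2, object$centroids[k, ])^2)), numeric(nrow(X)))
  D <- matrix(D, nrow = nrow(X))
  lab <- max.col(-D)
  margin <- vapply(seq_len(nrow(D)), function(i) {
    s <- sort(D[i, ])
    s[2] - s[1]
  }, numeric(1))
  structure(as.integer(lab) - 1L, margin = margin)
}

#' Permutation validation of the attractor silhouette
#'
#' The null destroys the dependence structure between latent coordinates by
#' shuffling each column independently across cases (marginals preserved);
#' K-means is refit and the silhouette recomputed for each replicate.
#' The p-value uses the add-one rule `(1 + #{null >= obs}) / (1 + B)`, so it
#' is never zero. The literal variant that reassigns whole vectors to
#' different case IDs (`scheme = "reassign"`) is exposed for completeness
#' but leaves the geometry unchanged by construction.
#'
#' @param tbl embedding table or latent matrix.
#' @param K clusters (default 3).
#' @param B permutation replicates (default 500).
#' @param seed RNG seed.
#' @param scheme `"column"` (default) or `"reassign"`.
#' @return object of class `morpho_permtest`: `observed_silhouette`,
#'   `null_scores`, `p_value`.
#' @export
permutation_test <- function(tbl, K = 3L, B = 500L, seed = 42L,
                             scheme = c("column", "reassign")) {
  scheme <- match.arg(scheme)
  if (B < 1) stop("permutation_test: B must be >= 1")
  X <- if (is.matrix(tbl)) tbl else latent_matrix(tbl)
  if (nrow(unique(X)) < K)
    stop("permutation_test: degenerate embeddings (fewer distinct points ",
         "than clusters)")
  obs_fit <- km_fit(X, K, seed)
  obs <- cluster_indices(X, obs_fit$cluster)$silhouette
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) + 1L)
  null_scores <- vapply(seq_len(B), function(b) {
    Xb <- if (scheme == "column")
      apply(X, 2, sample) else X[sample(nrow(X)), , drop = FALSE]
    fit <- stats::kmeans(Xb, centers = K, nstart = 10L, iter.max = 100L)
    cluster_indices(Xb, fit$cluster)$silhouette
  }, numeric(1))
  structure(list(observed_silhouette = obs, null_scores = null_scores,
                 p_value = (1 + sum(null_scores >= obs)) / (1 + B),
                 B = as.integer(B), scheme = scheme),
            class = "morpho_permtest")
}

#' Canonical risk ordering of attractors
#'
#' Attractor indices are arbitrary; the clinical reading orders them by
#' Kaplan-Meier median survival of their training cases: longest median =
#' low risk, shortest = high risk. Ties break by mean survival, then by
#' cluster size (larger first); clusters without survival data sort last.
#'
#' @param model an `attractor_model`.
#' @param surv tibble with `label` (0-based attractor), `time`, `event`.
#' @return tibble: `label`, `n`, `km_median`, `rank`, `risk`
#'   (low/intermediate/high for K = 3, otherwise risk_1..risk_K from low
#'   to high).
#' @export
canonical_risk_order <- function(model, surv) {
  stopifnot(all(c("label", "time", "event") %in% names(surv)))
  per <- lapply(0:(model$K - 1L), function(k) {
    d <- surv[surv$label == k, ]
    if (nrow(d) == 0 || sum(d$event) == 0) {
      tibble::tibble(label = k, n = nrow(d), km_median = NA_real_,
                     mean_surv = if (nrow(d)) mean(d$time) else NA_real_)
    } else {
      fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
      med <- unname(summary(fit)$table["median"])
      tibble::tibble(label = k, n = nrow(d), km_median = med,
                     mean_surv = mean(d$time))
    }
  })
  tab <- dplyr::bind_rows(per)
  ord <- order(-ifelse(is.na(tab$km_median), -Inf, tab$km_median),
               -ifelse(is.na(tab$mean_surv), -Inf, tab$mean_surv),
               -tab$n)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  tab$risk <- if (model$K == 3L) c("low", "intermediate", "high") else
    paste0("risk_", seq_len(model$K))
  dplyr::select(tab, "label", "n", "km_median", "rank", "risk")
}
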
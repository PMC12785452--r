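# ---------------------------------------------------------------------------
# Case-level embeddings, PCA diagnostics, decoder-sensitivity stability index
# and the unified embedding table.
# ---------------------------------------------------------------------------

#' Case-level latent embedding
#'
#' Samples `n_patches` patches inside the brain bounds, encodes each and
#' averages the latents to the case descriptor z-bar (patch averaging
#' suppresses sampling noise). Deterministic under `seed`.
#'
#' @param case a [standardized_case()].
#' @param model trained `ae_model`.
#' @param n_patches number of patches averaged (default 8).
#' @param seed RNG seed for patch sampling.
#' @return list with `case_id`, `split`, `z_bar`, `n_patches`.
#' @export
case_embed <- function(case, model, n_patches = 8L, seed = 42L) {
  patches <- sample_patches(case, n_patches, size = model$cfg$patch,
                            seed = seed)
  Z <- vapply(patches, function(p) ae_encode(model, p$tensor),
              numeric(model$cfg$latent_dim))
  list(case_id = case$case_id, split = case$split,
       z_bar = rowMeans(matrix(Z, nrow = model$cfg$latent_dim)),
       n_patches = as.integer(n_patches))
}

#' Embed a whole cohort
#'
#' @param cases list of standardized cases.
#' @param model trained `ae_model`.
#' @param n_patches patches per case.
#' @param seed base seed; case `i` uses `seed + i` so patch draws are
#'   independent across cases yet reproducible.
#' @return tibble with `case_id`, `split` and latent columns `z0..z{d-1}`.
#' @export
embed_cohort <- function(cases, model, n_patches = 8L, seed = 42L) {
  rows <- lapply(seq_along(cases), function(i)
    case_embed(cases[[i]], model, n_patches, seed = seed + i))
  Z <- do.call(rbind, lapply(rows, `[[`, "z_bar"))
  colnames(Z) <- paste0("z", seq_len(ncol(Z)) - 1L)
  dplyr::bind_cols(
    tibble::tibble(case_id = vapply(rows, `[[`, "", "case_id"),
                   split = vapply(rows, `[[`, "", "split")),
    tibble::as_tibble(Z))
}

#' Latent-matrix accessor for an embedding table
#' @param tbl tibble with `z*` columns.
#' @return numeric matrix (cases x latent dims).
#' @export
latent_matrix <- function(tbl) {
  as.matrix(tbl[, grep("^z[0-9]+$", names(tbl)), drop = FALSE])
}

#' PCA diagnostics of case-level embeddings
#'
#' @param tbl embedding table (or plain latent matrix).
#' @return list: `explained` tibble (component, variance share, cumulative),
#'   `scores` (2-D projection of all cases), `rotation`, `center` and the
#'   full `prcomp` fit.
#' @export
pca_diagnostics <- function(tbl) {
  Z <- if (is.matrix(tbl)) tbl else latent_matrix(tbl)
  if (nrow(Z) < 3) stop("pca_diagnostics: need at least 3 cases")
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(explained = tibble::tibble(component = seq_along(evr),
                                  variance_share = evr,
                                  cumulative = cumsum(evr)),
       scores = pc$x[, 1:min(2, ncol(pc$x)), drop = FALSE],
       rotation = pc$rotation, center = pc$center, fit = pc)
}

#' Monte-Carlo decoder-sensitivity stability index
#'
#' Estimates `E[ ||dec(z + eps) - dec(z)||_1 / ||eps||_2 ]` with
#' `eps ~ N(0, sigma^2 I)`: the expected L1 change of the decoder output per
#' unit L2 latent perturbation. Low values mark flat (stable) manifold
#' regions. The expectation is taken jointly over the supplied latents and
#' the perturbations.
#'
#' @param decode_fun function mapping a latent vector to a numeric array.
#' @param z_list list of latent vectors (probe anchors).
#' @param n_pert perturbations per anchor (default 4).
#' @param sigma perturbation scale (default 0.10).
#' @param seed RNG seed.
#' @return non-negative scalar.
#' @export
stability_index <- function(decode_fun, z_list, n_pert = 4L, sigma = 0.10,
                            seed = 42L) {
  if (sigma <= 0) stop("stability_index: sigma must be > 0")
  if (!is.list(z_list)) z_list <- list(z_list)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  vals <- unlist(lapply(z_list, function(z) {
    x0 <- decode_fun(z)
    vapply(seq_len(n_pert), function(j) {
      eps <- stats::rnorm(length(z), 0, sigma)
      sum(abs(decode_fun(z + eps) - x0)) / sqrt(sum(eps^2))
    }, numeric(1))
  }))
  mean(vals)
}

#' Case-level latent stability
#'
#' Estimates the stability index for one case from `n_patch` freshly
#' sampled patches x `n_pert` perturbations each (default 4 x 4 = 16
#' decodes), perturbing each patch latent.
#'
#' @param model trained `ae_model`.
#' @param case a [standardized_case()].
#' @param n_patch probe patches (default 4).
#' @param n_pert perturbations per patch (default 4).
#' @param sigma perturbation scale (default 0.10).
#' @param seed RNG seed.
#' @return scalar stability s(z-bar).
#' @export
latent_stability <- function(model, case, n_patch = 4L, n_pert = 4L,
                             sigma = 0.10, seed = 42L) {
  patches <- sample_patches(case, n_patch, size = model$cfg$patch,
                            seed = seed)
  z_list <- lapply(patches, function(p) ae_encode(model, p$tensor))
  stability_index(function(z) ae_decode(model, z), z_list,
                  n_pert = n_pert, sigma = sigma, seed = seed + 1L)
}

#' Build the unified embedding table
#'
#' One row per case: split, case_id, tensor path, stability, the latent
#' columns, and the clinical endpoints. Values are stored raw; z-scoring
#' happens only inside model-fitting stages.
#'
#' @param embeddings tibble from [embed_cohort()], optionally with a
#'   `stability` column.
#' @param metadata clinical tibble (must contain `case_id`, `age`,
#'   `resection`, `surv_days`, `event`).
#' @return tibble keyed by `case_id`.
#' @export
build_embedding_table <- function(embeddings, metadata) {
  if (anyDuplicated(embeddings$case_id) || anyDuplicated(metadata$case_id))
    stop("build_embedding_table: case_id must be unique")
  missing_ids <- setdiff(embeddings$case_id, metadata$case_id)
  if (length(missing_ids))
    stop("build_embedding_table: no metadata for ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  meta_cols <- intersect(c("case_id", "age", "resection", "surv_days",
                           "event", "tensor_path"), names(metadata))
  tbl <- dplyr::inner_join(embeddings, metadata[, meta_cols], by = "case_id")
  front <- intersect(c("split", "case_id", "tensor_path", "stability"),
                     names(tbl))
  dplyr::relocate(tbl, dplyr::all_of(front))
}

#' Restrict to the analysis cohort
#'
#' Training split with non-missing survival — the cohort rule applied to
#' every correlation, Kaplan-Meier and Cox stage.
#'
#' @param tbl embedding or metadata tibble.
#' @return filtered tibble.
#' @export
analysis_cohort <- function(tbl) {
  dplyr::filter(tbl, .data$split == "train", !is.na(.data$surv_days))
}
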
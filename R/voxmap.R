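# ---------------------------------------------------------------------------
# Voxel-level attractor sensitivity: Gaussian intensity bumps on the FLAIR
# channel at random foreground voxels; each bump's latent displacement and
# attractor-label flip are deposited into Shift/Flip maps weighted by the
# bump profile and normalized by perturbation coverage (Hit).
# ---------------------------------------------------------------------------

#' Bump perturbation settings
#'
#' @param kernel odd kernel edge in voxels (default 7).
#' @param sigma_spatial Gaussian sigma in voxels (default 1).
#' @param base_eps base perturbation amplitude (default 0.9).
#' @param scale_range range of the uniform amplitude multiplier
#'   (default c(1, 6); the applied amplitude is `base_eps * s`).
#' @param n_centers bump centers per replicate (default 300).
#' @param batch perturbations per processing batch (bookkeeping only).
#' @param mask_threshold foreground threshold on the channel-max intensity
#'   (default 0.15).
#' @param channel perturbed channel index (default 4 = FLAIR).
#' @param n_patches fixed encoding patches per case (default 4).
#' @param seed RNG seed.
#' @return list of class `bump_spec`.
#' @export
bump_spec <- function(kernel = 7L, sigma_spatial = 1, base_eps = 0.9,
                      scale_range = c(1, 6), n_centers = 300L, batch = 96L,
                      mask_threshold = 0.15, channel = 4L, n_patches = 4L,
                      seed = 42L) {
  stopifnot(kernel %% 2 == 1, base_eps > 0, n_centers >= 1,
            length(scale_range) == 2)
  structure(list(kernel = as.integer(kernel), sigma_spatial = sigma_spatial,
                 base_eps = base_eps, scale_range = scale_range,
                 n_centers = as.integer(n_centers), batch = as.integer(batch),
                 mask_threshold = mask_threshold, channel = as.integer(channel),
                 n_patches = as.integer(n_patches), seed = as.integer(seed)),
            class = "bump_spec")
}

#' Foreground mask of a standardized case
#'
#' Voxels where the channel-wise maximum exceeds the threshold.
#'
#' @param case a [standardized_case()].
#' @param threshold intensity threshold (default 0.15).
#' @return 3-D logical array; errors on an empty mask.
#' @export
foreground_mask <- function(case, threshold = 0.15) {
  m <- apply(case$tensor, c(2, 3, 4), max) > threshold
  if (!any(m)) stop("foreground_mask: empty mask for case ", case$case_id)
  m
}

# 3-D Gaussian kernel normalized to peak 1.
gaussian_kernel3 <- function(k, sigma) {
  r <- (seq_len(k) - (k + 1) / 2)
  g1 <- exp(-r^2 / (2 * sigma^2))
  outer(outer(g1, g1), g1)
}

#' Apply one Gaussian bump to a volume
#'
#' Adds `base_eps * scale` times a peak-normalized Gaussian kernel to the
#' target channel around `center` (kernel cropped at the volume boundary),
#' then clips the channel back to \[0, 1\].
#'
#' @param tensor 4-D case tensor `c(C, S, S, S)`.
#' @param center 1-based voxel coordinates, length 3.
#' @param spec a [bump_spec()].
#' @param scale amplitude multiplier s (the U(1,6) draw).
#' @return list: `tensor` (perturbed), `bump` (S^3 bump field),
#'   `support` (index ranges actually touched).
#' @export
apply_bump <- function(tensor, center, spec, scale) {
  S <- dim(tensor)[2]
  if (any(center < 1 | center > S)) stop("apply_bump: center outside volume")
  k <- spec$kernel
  h <- (k - 1L) %/% 2L
  kern <- gaussian_kernel3(k, spec$sigma_spatial)
  lo <- pmax(1L, center - h)
  hi <- pmin(S, center + h)
  klo <- lo - (center - h) + 1L
  khi <- k - ((center + h) - hi)
  sub <- kern[klo[1]:khi[1], klo[2]:khi[2], klo[3]:khi[3], drop = FALSE]
  eps <- spec$base_eps * scale
  bump <- array(0, dim = c(S, S, S))
  bump[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  ch <- spec$channel
  slab <- tensor[ch, lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  tensor[ch, lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    pmin(1, pmax(0, slab + eps * array(sub, dim = dim(sub))))
  list(tensor = tensor, bump = bump,
       support = list(lo = lo, hi = hi))
}

patch_overlaps <- function(origin, size, lo, hi) {
  all(origin + 1L <= hi & origin + size >= lo)
}

#' Voxel-level attractor sensitivity maps for one case
#'
#' For each of `n_centers` bumps at random foreground voxels the case is
#' re-embedded (patch positions fixed across bumps, so displacement is
#' bump-driven only); the latent shift `||z' - z||_2` and the flip
#' indicator `label(z') != label(z)` are accumulated into voxel maps
#' weighted by the bump profile, and both maps are normalized by coverage
#' `Hit(v) = sum_i bump_i(v)` floored at 1e-6. Deterministic under the
#' spec seed.
#'
#' @param case a [standardized_case()].
#' @param model trained `ae_model`.
#' @param attractors fitted `attractor_model` (global centroids).
#' @param spec a [bump_spec()].
#' @param centers optional explicit bump centers (n x 3 matrix of 1-based
#'   voxel coordinates) — used for test-retest replicates with identical
#'   centers.
#' @param scales optional explicit amplitude multipliers (length
#'   `nrow(centers)`).
#' @return object of class `sensitivity_maps`: `shift_heat`, `flip_heat`,
#'   `hit` (S^3 arrays), `label`, `margin`, `n_flips`, `mask`.
#' @export
sensitivity_maps <- function(case, model, attractors, spec = bump_spec(),
                             centers = NULL, scales = NULL) {
  stopifnot(inherits(case, "standardized_case"),
            inherits(model, "ae_model"),
            inherits(attractors, "attractor_model"))
  S <- dim(case$tensor)[2]
  mask <- foreground_mask(case, spec$mask_threshold)
  vox <- which(mask)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  if (is.null(centers)) {
    centers_idx <- vox[sample.int(length(vox), spec$n_centers,
                                  replace = TRUE)]
    centers <- arrayInd(centers_idx, dim(mask))
  } else {
    centers <- as.matrix(centers)
  }
  n_centers <- nrow(centers)
  if (is.null(scales))
    scales <- stats::runif(n_centers, spec$scale_range[1],
                           spec$scale_range[2])
  stopifnot(length(scales) == n_centers)

  size <- model$cfg$patch
  patches <- sample_patches(case, spec$n_patches, size = size,
                            seed = spec$seed + 1L)
  z_base <- lapply(patches, function(p) ae_encode(model, p$tensor))
  zbar <- rowMeans(do.call(cbind, z_base))
  base_pred <- predict(attractors, matrix(zbar, nrow = 1))
  label0 <- as.integer(base_pred)
  margin <- attr(base_pred, "margin")

  shift_num <- array(0, dim = c(S, S, S))
  flip_num <- array(0, dim = c(S, S, S))
  hit <- array(0, dim = c(S, S, S))
  n_flips <- 0L
  for (i in seq_len(n_centers)) {
    bp <- apply_bump(case$tensor, centers[i, ], spec, scales[i])
    z_new <- vapply(seq_along(patches), function(j) {
      pj <- patches[[j]]
      if (patch_overlaps(pj$origin, size, bp$support$lo, bp$support$hi)) {
        o <- pj$origin
        idx <- lapply(o, function(v) (v + 1L):(v + size))
        ae_encode(model,
                  bp$tensor[, idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
      } else z_base[[j]]
    }, numeric(model$cfg$latent_dim))
    zbar_new <- rowMeans(z_new)
    shift_i <- sqrt(sum((zbar_new - zbar)^2))
    flip_i <- as.integer(predict(attractors,
                                 matrix(zbar_new, nrow = 1))) != label0
    shift_num <- shift_num + shift_i * bp$bump
    if (flip_i) {
      flip_num <- flip_num + bp$bump
      n_flips <- n_flips + 1L
    }
    hit <- hit + bp$bump
  }
  denom <- pmax(hit, 1e-6)
  structure(list(shift_heat = shift_num / denom,
                 flip_heat = flip_num / denom, hit = hit,
                 label = label0, margin = margin, n_flips = n_flips,
                 mask = mask, centers = centers, scales = scales,
                 case_id = case$case_id),
            class = "sensitivity_maps")
}

#' ICC(3,1): two-way mixed, single-measure, consistency
#'
#' Test-retest agreement of two paired measurement vectors (e.g. the same
#' voxel map from two replicates with identical centers). Inputs with zero
#' variance return 0 by convention, so all-zero Flip maps score 0 rather
#' than NaN.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
icc_3_1 <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("icc_3_1: need at least 2 paired observations")
  M <- cbind(x, y)
  if (all(M == M[1, 1])) return(0)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  g <- mean(M)
  ssr <- 2 * sum((row_m - g)^2)
  ssc <- n * sum((col_m - g)^2)
  sst <- sum((M - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / (n - 1)
  if (msr + mse == 0) return(0)
  (msr - mse) / (msr + mse)
}

#' Test-retest reliability of sensitivity maps over a case set
#'
#' Computes ICC(3,1) per case between two replicates (identical centers,
#' independent amplitude draws) over voxels inside the case mask.
#'
#' @param reps_a,reps_b lists of `sensitivity_maps` (same cases, same
#'   order).
#' @param field `"shift_heat"` or `"flip_heat"`.
#' @return tibble: per-case ICC plus mean/sd summary rows in the
#'   attributes `icc_mean`, `icc_sd`.
#' @export
voxmap_icc <- function(reps_a, reps_b, field = c("shift_heat", "flip_heat")) {
  field <- match.arg(field)
  stopifnot(length(reps_a) == length(reps_b))
  vals <- vapply(seq_along(reps_a), function(i) {
    a <- reps_a[[i]]
    b <- reps_b[[i]]
    stopifnot(identical(dim(a[[field]]), dim(b[[field]])))
    icc_3_1(a[[field]][a$mask], b[[field]][a$mask])
  }, numeric(1))
  out <- tibble::tibble(
    case_id = vapply(reps_a, `[[`, "", "case_id"),
    icc = vals, field = field)
  attr(out, "icc_mean") <- mean(vals)
  attr(out, "icc_sd") <- stats::sd(vals)
  out
}
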
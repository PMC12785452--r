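# ---------------------------------------------------------------------------
# Standardization of raw multimodal volumes: QC, resampling to a cubic grid,
# per-volume percentile intensity normalization, packaging, patch sampling.
# ---------------------------------------------------------------------------

#' Quality-control one case's modality files
#'
#' Fails closed: any missing file, unreadable/invalid NIfTI header or
#' inter-modality shape mismatch marks the case as failed, with reasons.
#'
#' @param paths named character vector of the four modality files
#'   (T1, T1Gd, T2, FLAIR).
#' @return list with `pass` (logical) and `reasons` (character, empty when
#'   passing).
#' @export
qc_case <- function(paths) {
  want <- mf_channels()
  reasons <- character(0)
  if (is.null(names(paths))) names(paths) <- want[seq_along(paths)]
  missing_mod <- setdiff(want, names(paths))
  if (length(missing_mod))
    reasons <- c(reasons, paste0("missing modality: ",
                                 paste(missing_mod, collapse = ", ")))
  dims <- list()
  for (m in intersect(want, names(paths))) {
    p <- paths[[m]]
    if (!file.exists(p)) {
      reasons <- c(reasons, paste0("missing modality: ", m))
      next
    }
    hdr <- read_nifti_header(p)
    if (!hdr$ok) {
      reasons <- c(reasons, paste0("invalid header: ", m, " (", hdr$reason, ")"))
    } else {
      dims[[m]] <- hdr$dim
    }
  }
  if (length(dims) > 1 &&
      !all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    reasons <- c(reasons, "shape mismatch across modalities")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Resample a 3-D scalar field to a cubic grid
#'
#' Trilinear interpolation for intensities, nearest-neighbour for label
#' masks. Uses the corner-aligned coordinate convention, so an affine ramp
#' stays exactly affine and constants stay constant.
#'
#' @param volume 3-D numeric array.
#' @param target_edge output edge length (default 128).
#' @param mode `"trilinear"` or `"nearest"`.
#' @return array of dim `rep(target_edge, 3)`.
#' @export
resample_to_grid <- function(volume, target_edge = 128L,
                             mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(volume)
  if (length(d) != 3) stop("resample_to_grid: input must be 3-D")
  target_edge <- as.integer(target_edge)
  src_coord <- function(S, T) {
    if (T == 1L) return(rep((S + 1) / 2, 1))
    1 + (seq_len(T) - 1) * (S - 1) / (T - 1)
  }
  cs <- lapply(d, src_coord, T = target_edge)
  if (mode == "nearest") {
    idx <- Map(function(v, S) pmin(S, pmax(1, round(v))), cs, d)
    return(volume[idx[[1]], idx[[2]], idx[[3]], drop = FALSE] |>
             array(dim = rep(target_edge, 3)))
  }
  i0 <- Map(function(v, S) pmin(S - 1L, pmax(1L, floor(v))), cs, d)
  w <- Map(function(v, lo) v - lo, cs, i0)
  out <- array(0, dim = rep(target_edge, 3))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wx <- if (a) w[[1]] else 1 - w[[1]]
    wy <- if (b) w[[2]] else 1 - w[[2]]
    wz <- if (cc) w[[3]] else 1 - w[[3]]
    w3 <- outer(outer(wx, wy), wz)
    sub <- volume[i0[[1]] + a, i0[[2]] + b, i0[[3]] + cc, drop = FALSE]
    out <- out + w3 * array(sub, dim = rep(target_edge, 3))
  }
  out
}

#' Percentile-clip and rescale one volume to \[0, 1\]
#'
#' Clips at the per-volume 1st and 99th empirical percentiles (inverted-ECDF
#' definition, so normalization is exactly idempotent), then maps the clip
#' window affinely onto \[0, 1\]. Constant volumes map to all zeros.
#'
#' @param volume numeric array (any shape); must be finite.
#' @param probs clip percentiles, default `c(0.01, 0.99)`.
#' @return array of the same shape with values in \[0, 1\].
#' @export
normalize_channel <- function(volume, probs = c(0.01, 0.99)) {
  if (anyNA(volume) || any(!is.finite(volume)))
    stop("normalize_channel: non-finite values")
  q <- stats::quantile(volume, probs, type = 1, names = FALSE)
  if (q[2] <= q[1]) return(array(0, dim = dim(volume) %||% length(volume)))
  out <- pmin(q[2], pmax(q[1], volume))
  out <- (out - q[1]) / (q[2] - q[1])
  if (!is.null(dim(volume))) dim(out) <- dim(volume)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a standardized case
#'
#' @param tensor numeric array `c(C, S, S, S)` with C in \{4, 5\}, values in
#'   \[0, 1\].
#' @param case_id subject identifier.
#' @param split `"train"` or `"valid"`.
#' @param qc_flags character vector of QC annotations.
#' @return object of class `standardized_case`.
#' @export
standardized_case <- function(tensor, case_id, split = "train",
                              qc_flags = character(0)) {
  d <- dim(tensor)
  stopifnot(length(d) == 4, d[1] %in% c(4L, 5L), d[2] == d[3], d[3] == d[4])
  if (anyNA(tensor) || any(!is.finite(tensor)))
    stop("standardized_case: non-finite values")
  if (min(tensor) < 0 || max(tensor) > 1)
    stop("standardized_case: values outside [0, 1]")
  structure(list(tensor = tensor, spacing = 1.0, case_id = case_id,
                 split = split, qc_flags = qc_flags),
            class = "standardized_case")
}

#' Standardize one raw case into the packaged tensor
#'
#' Accepts either a raw 4-channel array or named per-modality NIfTI paths;
#' resamples every channel to `target_edge`^3 (trilinear) and normalizes
#' each channel independently.
#'
#' @param x 4 x S^3 array, or named character vector of NIfTI paths.
#' @param case_id,split case identity.
#' @param target_edge cubic output edge.
#' @return a [standardized_case()].
#' @export
standardize_case <- function(x, case_id, split = "train",
                             target_edge = 128L) {
  if (is.character(x)) {
    qc <- qc_case(x)
    if (!qc$pass)
      stop("standardize_case: QC failed for ", case_id, ": ",
           paste(qc$reasons, collapse = "; "))
    chans <- lapply(x[mf_channels()], function(p) read_nifti(p)$data)
    x <- array(0, dim = c(4, dim(chans[[1]])))
    for (i in 1:4) x[i, , , ] <- chans[[i]]
  }
  stopifnot(length(dim(x)) == 4)
  C <- dim(x)[1]
  out <- array(0, dim = c(C, rep(as.integer(target_edge), 3)))
  for (ch in seq_len(C)) {
    v <- x[ch, , , ]
    if (!all(dim(v) == target_edge)) v <- resample_to_grid(v, target_edge)
    out[ch, , , ] <- normalize_channel(v)
  }
  standardized_case(out, case_id = case_id, split = split)
}

#' Package a standardized case to disk / read it back
#'
#' Uses RDS as the native lossless tensor container.
#'
#' @param case a [standardized_case()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
package_case <- function(case, path) {
  stopifnot(inherits(case, "standardized_case"))
  saveRDS(case, path)
  invisible(path)
}

#' @rdname package_case
#' @export
read_case <- function(path) {
  case <- readRDS(path)
  stopifnot(inherits(case, "standardized_case"))
  case
}

#' Foreground bounding box (brain bounds)
#'
#' Bounding box of voxels where the channel-wise maximum exceeds 0; empty
#' foreground degenerates to whole-volume bounds.
#' @keywords internal
foreground_bbox <- function(tensor) {
  S <- dim(tensor)[2]
  mx <- apply(tensor, c(2, 3, 4), max)
  on <- which(mx > 0, arr.ind = TRUE)
  if (nrow(on) == 0) return(cbind(lo = c(1, 1, 1), hi = c(S, S, S)))
  cbind(lo = apply(on, 2, min), hi = apply(on, 2, max))
}

#' Sample cubic training patches from a standardized case
#'
#' Corners are uniform over valid positions inside the foreground bounding
#' box (half-open index ranges); deterministic under `seed`.
#'
#' @param case a [standardized_case()].
#' @param n number of patches.
#' @param size patch edge (default 64).
#' @param seed RNG seed.
#' @return list of patches, each `list(tensor, origin, case_id)` with
#'   `origin` 0-based voxel coordinates of the patch corner.
#' @export
sample_patches <- function(case, n, size = 64L, seed = 42L) {
  stopifnot(inherits(case, "standardized_case"))
  S <- dim(case$tensor)[2]
  size <- as.integer(size)
  if (size > S) stop("sample_patches: size exceeds volume edge")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  bb <- foreground_bbox(case$tensor)
  lo <- pmin(bb[, "lo"], S - size + 1L)
  hi <- pmax(bb[, "hi"] - size + 1L, lo)
  lapply(seq_len(n), function(i) {
    corner <- vapply(1:3, function(ax) {
      if (hi[ax] <= lo[ax]) lo[ax]
      else lo[ax] + sample.int(hi[ax] - lo[ax] + 1L, 1L) - 1L
    }, numeric(1))
    idx <- lapply(corner, function(cc) cc:(cc + size - 1L))
    list(tensor = case$tensor[, idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         origin = as.integer(corner) - 1L,
         case_id = case$case_id)
  })
}

#' Preprocess a whole cohort from its metadata table
#'
#' Reads each case's volume (RDS tensor or per-channel NIfTI), standardizes
#' it and packages it under `out_dir`; returns the metadata augmented with
#' a `tensor_path` column.
#'
#' @param metadata cohort tibble (see [read_metadata()]).
#' @param out_dir output directory.
#' @param target_edge cubic grid edge.
#' @return tibble: metadata + `tensor_path`.
#' @export
preprocess_cohort <- function(metadata, out_dir, target_edge = 128L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tensor_path <- character(nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    p <- metadata$volume_path[i]
    raw <- if (grepl("\\.rds$", p)) readRDS(p) else {
      base <- sub(paste0("_", mf_channels()[1], "\\.nii(\\.gz)?$"), "", p)
      paths <- stats::setNames(
        vapply(mf_channels(), function(m)
          paste0(base, "_", m, ".nii.gz"), character(1)), mf_channels())
      paths
    }
    sc <- standardize_case(raw, case_id = metadata$case_id[i],
                           split = metadata$split[i],
                           target_edge = target_edge)
    tensor_path[i] <- file.path(out_dir, sprintf("%s_%s.rds",
                                                 metadata$split[i],
                                                 metadata$case_id[i]))
    package_case(sc, tensor_path[i])
  }
  dplyr::mutate(metadata, tensor_path = tensor_path)
}
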
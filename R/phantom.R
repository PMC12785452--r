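# ---------------------------------------------------------------------------
# Synthetic multimodal phantom cohort.
#
# Stands in for a real preoperative glioma cohort: three latent morphotypes
# with distinct lesion architecture (necrotic fraction, enhancing rim,
# peritumoral FLAIR halo), survival times stochastically ordered by
# morphotype, and an age covariate that carries most of the hazard.
# Anatomy is deliberately schematic (brain ellipsoid + lesion); the pipeline
# consumes intensity structure only.
# ---------------------------------------------------------------------------

#' Specification of a synthetic phantom cohort
#'
#' @param n_cases number of subjects.
#' @param grid volume edge length in voxels (>= 16; 64 is the desk-scale
#'   default, 128 mirrors a full-resolution run).
#' @param morphotype_weights mixture weights of the three morphotypes
#'   (must sum to 1). Type 0 is the aggressive phenotype (large necrotic
#'   core, irregular rim enhancement, wide halo), type 2 the compact
#'   homogeneously enhancing one, type 1 intermediate.
#' @param lesion_radius_range lesion semi-axis range in voxels; default
#'   scales with the grid (16--18.5% of the edge).
#' @param necrosis_fraction_by_type necrotic volume fraction per morphotype.
#' @param edema_halo_by_type halo thickness per morphotype, voxels; default
#'   scales with the grid.
#' @param noise_sd additive Gaussian intensity noise (volumes are clipped
#'   back to \[0, 1\]).
#' @param survival_scale_by_type exponential survival scale (days) per
#'   morphotype at mean age.
#' @param age_mean_sd mean and sd of the age distribution (years).
#' @param age_log_hr log hazard ratio per age standard deviation; the
#'   default log(1.3) mirrors the dominant age effect reported for the
#'   motivating cohort.
#' @param censor_rate probability that a case is censored (in \[0, 1)).
#' @param seed RNG seed; the whole cohort is a pure function of the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_cases,
                         grid = 64L,
                         morphotype_weights = c(1, 1, 1) / 3,
                         lesion_radius_range = NULL,
                         necrosis_fraction_by_type = c(0.55, 0.30, 0.05),
                         edema_halo_by_type = NULL,
                         noise_sd = 0.02,
                         survival_scale_by_type = c(300, 420, 540),
                         age_mean_sd = c(60, 12),
                         age_log_hr = log(1.3),
                         censor_rate = 0.2,
                         seed = 42L) {
  grid <- as.integer(grid)
  if (grid < 16L) stop("phantom_spec: grid must be >= 16")
  if (abs(sum(morphotype_weights) - 1) > 1e-9)
    stop("phantom_spec: morphotype_weights must sum to 1")
  if (any(morphotype_weights < 0)) stop("phantom_spec: negative weight")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("phantom_spec: censor_rate must lie in [0, 1)")
  if (is.null(lesion_radius_range))
    lesion_radius_range <- c(0.135, 0.145) * grid
  if (is.null(edema_halo_by_type))
    edema_halo_by_type <- pmax(1, round(c(0.10, 0.05, 0.02) * grid))
  stopifnot(length(necrosis_fraction_by_type) == 3,
            all(necrosis_fraction_by_type >= 0 &
                  necrosis_fraction_by_type <= 1),
            length(survival_scale_by_type) == 3,
            length(age_mean_sd) == 2)
  structure(list(
    n_cases = as.integer(n_cases), grid = grid,
    morphotype_weights = morphotype_weights,
    lesion_radius_range = lesion_radius_range,
    necrosis_fraction_by_type = necrosis_fraction_by_type,
    edema_halo_by_type = edema_halo_by_type,
    noise_sd = noise_sd,
    survival_scale_by_type = survival_scale_by_type,
    age_mean_sd = age_mean_sd, age_log_hr = age_log_hr,
    censor_rate = censor_rate, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Channel order used throughout the package.
mf_channels <- function() c("T1", "T1Gd", "T2", "FLAIR")

#' Synthesize one phantom volume
#'
#' @param spec a [phantom_spec()].
#' @param morphotype 0, 1 or 2.
#' @param seed per-case seed.
#' @return numeric array of dim `c(4, grid, grid, grid)` with values in
#'   \[0, 1\]; channels ordered T1, T1Gd, T2, FLAIR.
#' @export
phantom_volume <- function(spec, morphotype, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  g <- spec$grid
  type <- as.integer(morphotype)
  stopifnot(type %in% 0:2)
  ax <- seq_len(g) - (g + 1) / 2
  sq <- function(v, r) (v / r)^2
  field3 <- function(fx, fy, fz) {
    outer(outer(fx, fy, "+"), fz, "+")
  }
  brain <- field3(sq(ax, 0.45 * g), sq(ax, 0.40 * g), sq(ax, 0.42 * g)) <= 1

  ctr <- stats::runif(3, -0.05, 0.05) * g
  r0 <- stats::runif(1, spec$lesion_radius_range[1],
                     spec$lesion_radius_range[2])
  rr <- r0 * stats::runif(3, 0.95, 1.05)
  dles <- sqrt(field3(sq(ax - ctr[1], rr[1]), sq(ax - ctr[2], rr[2]),
                      sq(ax - ctr[3], rr[3])))
  nf <- spec$necrosis_fraction_by_type[type + 1]
  halo_vox <- spec$edema_halo_by_type[type + 1]
  halo_norm <- halo_vox / mean(rr)
  lesion <- dles <= 1 & brain
  core <- dles <= nf^(1 / 3) & brain
  rim <- lesion & !core
  edema <- dles > 1 & dles <= 1 + halo_norm & brain

  base <- c(T1 = 0.55, T1Gd = 0.50, T2 = 0.45, FLAIR = 0.40)
  # enhancement profile by morphotype: 0 = bright irregular rim around a large
  # necrotic core, 1 = intermediate dim enhancement, 2 = compact homogeneous
  # bright enhancement (near-absent core)
  rim_gd <- c(0.95, 0.55, 0.90)[type + 1]
  vol <- array(0, dim = c(4, g, g, g))
  paint <- function(brain_v, edema_v, rim_v, core_v) {
    f <- array(0, dim = c(g, g, g))
    f[brain] <- brain_v
    f[edema] <- edema_v
    f[rim] <- rim_v
    f[core] <- core_v
    f
  }
  vol[1, , , ] <- paint(base["T1"], 0.45, 0.40, 0.30)
  gd <- paint(base["T1Gd"], 0.45, rim_gd, 0.15)
  if (type == 0L) {
    # irregular rim enhancement: multiplicative texture inside the rim
    tex <- array(stats::rnorm(g^3, 0, 0.10), dim = c(g, g, g))
    gd[rim] <- pmin(1, pmax(0, gd[rim] * (1 + tex[rim])))
  }
  vol[2, , , ] <- gd
  vol[3, , , ] <- paint(base["T2"], 0.65, 0.60, 0.85)
  vol[4, , , ] <- paint(base["FLAIR"], 0.85, 0.65, 0.45)

  if (spec$noise_sd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), dim(vol))
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  vol
}

#' Generate a phantom cohort (metadata + volumes)
#'
#' Draws each case's morphotype, age, resection status and survival, then
#' synthesizes and writes the corresponding 4-channel volume. Survival is
#' exponential with log-rate linear in standardized age plus a morphotype
#' offset (the per-type scale); censoring is an independent coin with a
#' uniform censoring time. The run is a pure function of the spec: the same
#' spec gives byte-identical outputs.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed).
#' @param format `"rds"` (native tensor container) and/or `"nifti"`
#'   (per-channel `.nii.gz`).
#' @param write_volumes set `FALSE` to generate metadata only (survival
#'   calibration studies).
#' @return a tibble with one row per case: `case_id`, `split`,
#'   `morphotype_true`, `age`, `resection`, `surv_days`, `event`,
#'   `volume_path`.
#' @export
generate_cohort <- function(spec, dir, format = "rds",
                            write_volumes = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  format <- match.arg(format, c("rds", "nifti"), several.ok = TRUE)
  if (write_volumes) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(dir, 2) != 0) stop("generate_cohort: '", dir,
                                       "' is not writable")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_cases
  type <- sample(0:2, n, replace = TRUE, prob = spec$morphotype_weights)
  age <- pmin(90, pmax(18, stats::rnorm(n, spec$age_mean_sd[1],
                                        spec$age_mean_sd[2])))
  zage <- (age - spec$age_mean_sd[1]) / spec$age_mean_sd[2]
  rate <- exp(spec$age_log_hr * zage) / spec$survival_scale_by_type[type + 1]
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < spec$censor_rate
  t_obs <- ifelse(censored, stats::runif(n) * t_event, t_event)
  surv_days <- pmax(1, round(t_obs))
  split <- sample(c("train", "valid"), n, replace = TRUE, prob = c(0.75, 0.25))
  resection <- sample(c("GTR", "STR", "NA"), n, replace = TRUE,
                      prob = c(0.30, 0.05, 0.65))
  case_id <- sprintf("case_%03d", seq_len(n))

  volume_path <- rep(NA_character_, n)
  if (write_volumes) {
    for (i in seq_len(n)) {
      vol <- phantom_volume(spec, type[i],
                            seed = (spec$seed + 7919L * i) %% .Machine$integer.max)
      if ("rds" %in% format) {
        volume_path[i] <- file.path(dir, paste0(case_id[i], ".rds"))
        saveRDS(vol, volume_path[i])
      }
      if ("nifti" %in% format) {
        for (ch in seq_len(4)) {
          write_nifti(vol[ch, , , ],
                      file.path(dir, sprintf("%s_%s.nii.gz", case_id[i],
                                             mf_channels()[ch])))
        }
        if (!"rds" %in% format)
          volume_path[i] <- file.path(dir,
                                      sprintf("%s_%s.nii.gz", case_id[i],
                                              mf_channels()[1]))
      }
    }
  }
  tibble::tibble(case_id = case_id, split = split,
                 morphotype_true = type, age = age, resection = resection,
                 surv_days = as.numeric(surv_days),
                 event = as.integer(!censored),
                 volume_path = volume_path)
}

#' Write cohort metadata (clinical CSV + quarantined truth file)
#'
#' The clinical CSV holds only what the pipeline may see (`split`,
#' `case_id`, `age`, `resection`, `surv_days`, `event`, `volume_path`).
#' Ground-truth morphotypes go into `<path>_truth.csv`, which no pipeline
#' stage reads.
#'
#' @param records cohort tibble from [generate_cohort()].
#' @param path metadata CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  stopifnot(nrow(records) > 0)
  if (anyDuplicated(records$case_id))
    stop("write_metadata: duplicate case_id")
  clinical <- records[, c("split", "case_id", "age", "resection",
                          "surv_days", "event", "volume_path")]
  utils::write.csv(clinical, path, row.names = FALSE, na = "")
  truth_path <- paste0(sub("\\.csv$", "", path), "_truth.csv")
  utils::write.csv(records[, c("case_id", "morphotype_true")],
                   truth_path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort metadata CSV
#'
#' @param path metadata CSV path written by [write_metadata()].
#' @return tibble of clinical records.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  df$resection[is.na(df$resection) | df$resection == ""] <- "NA"
  tibble::as_tibble(df)
}
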
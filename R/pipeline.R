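# ---------------------------------------------------------------------------
# Stage chaining: phantom -> preprocess -> ae -> latent -> attractors ->
# survival -> voxmap -> dynamics -> control, with a manifest (config hash,
# seed, per-file checksums) and resumability from any completed stage.
# ---------------------------------------------------------------------------

#' Desk-scale pipeline configuration
#'
#' One config drives every stage. Defaults are sized for a single CPU
#' (tiny autoencoder, 32-voxel grid); raise `grid`, the AE config and the
#' stage budgets to mirror a full-scale run.
#'
#' @param out_dir artifact root directory.
#' @param n_cases phantom cohort size.
#' @param grid phantom/volume edge.
#' @param seed global seed propagated to every stochastic stage.
#' @param ae an [ae_config()].
#' @param n_patches patches per case-level embedding.
#' @param k attractor count.
#' @param n_seeds K-means seed-robustness replicates.
#' @param permutations silhouette permutation replicates.
#' @param bump a [bump_spec()] for the voxel maps.
#' @param voxmap_cases number of cases mapped (voxel maps are the most
#'   expensive stage; 0 skips).
#' @param ode_epochs,ode_hidden neural-ODE training budget.
#' @param ode_steps long-term integration steps.
#' @param control_steps,control_m,control_lambda deterministic-control
#'   settings.
#' @param sac_timesteps SAC interaction budget (0 skips the agent).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            n_cases = 60L, grid = 32L, seed = 42L,
                            ae = NULL, n_patches = 8L,
                            k = 3L, n_seeds = 10L, permutations = 100L,
                            bump = NULL, voxmap_cases = 2L,
                            ode_epochs = 60L, ode_hidden = c(64L, 32L),
                            ode_steps = 200L,
                            control_steps = 50L, control_m = 8L,
                            control_lambda = 1e-3,
                            sac_timesteps = 4000L) {
  if (is.null(ae))
    ae <- ae_config_tiny(patch = min(32L, grid), max_epochs = 12L,
                         patience = 11L, lr = 3e-3, seed = seed)
  if (is.null(bump))
    bump <- bump_spec(n_centers = 60L, seed = seed)
  structure(list(out_dir = out_dir, n_cases = as.integer(n_cases),
                 grid = as.integer(grid), seed = as.integer(seed),
                 ae = ae, n_patches = as.integer(n_patches),
                 k = as.integer(k), n_seeds = as.integer(n_seeds),
                 permutations = as.integer(permutations),
                 bump = bump, voxmap_cases = as.integer(voxmap_cases),
                 ode_epochs = as.integer(ode_epochs),
                 ode_hidden = as.integer(ode_hidden),
                 ode_steps = as.integer(ode_steps),
                 control_steps = as.integer(control_steps),
                 control_m = as.integer(control_m),
                 control_lambda = control_lambda,
                 sac_timesteps = as.integer(sac_timesteps)),
            class = "pipeline_config")
}

#' Pipeline stages in dependency order
#' @return character vector of stage names.
#' @export
pipeline_stages <- function() {
  c("phantom", "preprocess", "ae", "latent", "attractors", "survival",
    "voxmap", "dynamics", "control")
}

need_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path))
    stop("run_pipeline: missing artifact '", basename(path),
         "' for stage '", needed_by, "' - run stage '", stage, "' first",
         call. = FALSE)
  path
}

#' Run the pipeline (all stages or a subset)
#'
#' Stages execute in dependency order; each writes its artifacts under
#' `<out_dir>/<stage>/` and the run manifest (config hash, seed, per-file
#' MD5 checksums) is updated after every stage, so a run can resume from
#' any completed stage. Asking for a stage whose inputs are missing fails
#' with a message naming the stage to run.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of [pipeline_stages()] (default: all).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = pipeline_stages()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  root <- config$out_dir
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  sdir <- function(s) {
    d <- file.path(root, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  p_meta <- file.path(root, "phantom", "metadata.csv")
  p_meta_pp <- file.path(root, "preprocess", "metadata_preprocessed.csv")
  p_model <- file.path(root, "ae", "ae_model.rds")
  p_embed <- file.path(root, "latent", "embeddings_caselevel.csv")
  p_embed_st <- file.path(root, "latent",
                          "embeddings_caselevel_with_stability.csv")
  p_attr_model <- file.path(root, "attractors", "attractor_model.rds")
  p_embed_attr <- file.path(root, "attractors",
                            "embeddings_with_attractor.csv")
  p_field <- file.path(root, "dynamics", "ode_field.rds")

  for (stage in pipeline_stages()[pipeline_stages() %in% stages]) {
    switch(stage,
      phantom = {
        d <- sdir("phantom")
        spec <- phantom_spec(config$n_cases, grid = config$grid,
                             seed = config$seed)
        rec <- generate_cohort(spec, file.path(d, "volumes"))
        write_metadata(rec, p_meta)
      },
      preprocess = {
        d <- sdir("preprocess")
        meta <- read_metadata(need_artifact(p_meta, "phantom", stage))
        pp <- preprocess_cohort(meta, file.path(d, "tensors"),
                                target_edge = config$grid)
        utils::write.csv(pp, p_meta_pp, row.names = FALSE)
      },
      ae = {
        d <- sdir("ae")
        meta <- utils::read.csv(need_artifact(p_meta_pp, "preprocess",
                                              stage))
        cases <- lapply(meta$tensor_path[meta$split == "train"], read_case)
        n_tr <- max(2L, floor(0.85 * length(cases)))
        tr <- lapply(cases[seq_len(n_tr)], function(cs)
          sample_patches(cs, 1L, size = config$ae$patch,
                         seed = config$seed)[[1]])
        va <- lapply(cases[(n_tr + 1L):length(cases)], function(cs)
          sample_patches(cs, 1L, size = config$ae$patch,
                         seed = config$seed)[[1]])
        model <- ae_train(ae_new(config$ae), tr, va)
        saveRDS(model, p_model)
        utils::write.csv(model$history, file.path(d, "training_log.csv"),
                         row.names = FALSE)
      },
      latent = {
        d <- sdir("latent")
        meta <- utils::read.csv(need_artifact(p_meta_pp, "preprocess",
                                              stage))
        model <- readRDS(need_artifact(p_model, "ae", stage))
        cases <- lapply(meta$tensor_path, read_case)
        emb <- embed_cohort(cases, model, n_patches = config$n_patches,
                            seed = config$seed)
        utils::write.csv(emb, p_embed, row.names = FALSE)
        emb$stability <- vapply(seq_along(cases), function(i)
          latent_stability(model, cases[[i]],
                           seed = config$seed + 13L * i), numeric(1))
        tbl <- build_embedding_table(emb, tibble::as_tibble(meta))
        utils::write.csv(tbl, p_embed_st, row.names = FALSE)
      },
      attractors = {
        d <- sdir("attractors")
        tbl <- tibble::as_tibble(
          utils::read.csv(need_artifact(p_embed_st, "latent", stage)))
        ks <- scan_k(tbl, k_range = 2:min(6, nrow(tbl) - 1L),
                     seed = config$seed)
        utils::write.csv(ks$indices, file.path(d, "kscan.csv"),
                         row.names = FALSE)
        model <- fit_attractors(tbl, K = config$k,
                                n_seeds = config$n_seeds,
                                seed = config$seed)
        saveRDS(model, p_attr_model)
        tbl$attractor <- model$labels
        utils::write.csv(tbl, p_embed_attr, row.names = FALSE)
        pt <- permutation_test(tbl, K = config$k, B = config$permutations,
                               seed = config$seed)
        saveRDS(pt, file.path(d, "permutation.rds"))
        ac <- analysis_cohort(tbl)
        risk <- canonical_risk_order(model,
          tibble::tibble(label = ac$attractor, time = ac$surv_days,
                         event = ac$event))
        utils::write.csv(risk, file.path(d, "risk_order.csv"),
                         row.names = FALSE)
      },
      survival = {
        d <- sdir("survival")
        tbl <- tibble::as_tibble(
          utils::read.csv(need_artifact(p_embed_attr, "attractors", stage)))
        ac <- analysis_cohort(tbl)
        rec <- tibble::tibble(time = ac$surv_days, event = ac$event)
        km <- km_curve(rec, ac$attractor)
        utils::write.csv(km$medians, file.path(d, "km_medians.csv"),
                         row.names = FALSE)
        lr <- logrank(rec, ac$attractor)
        saveRDS(lr, file.path(d, "logrank.rds"))
        bs <- bootstrap_spearman(ac$stability, ac$surv_days, B = 500L,
                                 seed = config$seed)
        utils::write.csv(bs, file.path(d, "stability_spearman.csv"),
                         row.names = FALSE)
        pcs <- pca_diagnostics(ac)
        for (j in 1:4) ac[[paste0("PC", j)]] <- pcs$fit$x[, j]
        cx <- ridge_cox(dplyr::rename(ac, time = "surv_days"),
                        c("age", "stability", paste0("PC", 1:4)),
                        penalizer = 0.5, seed = config$seed)
        utils::write.csv(tidy(cx), file.path(d, "cox_latent.csv"),
                         row.names = FALSE)
        for (k in seq_len(config$k - 1L))
          ac[[paste0("attr_", k)]] <- as.integer(ac$attractor == k)
        cx2 <- ridge_cox(dplyr::rename(ac, time = "surv_days"),
                         c("age", paste0("attr_", seq_len(config$k - 1L))),
                         penalizer = 1.0, seed = config$seed)
        utils::write.csv(tidy(cx2), file.path(d, "cox_attractor.csv"),
                         row.names = FALSE)
      },
      voxmap = {
        d <- sdir("voxmap")
        if (config$voxmap_cases > 0L) {
          meta <- utils::read.csv(need_artifact(p_meta_pp, "preprocess",
                                                stage))
          model <- readRDS(need_artifact(p_model, "ae", stage))
          amod <- readRDS(need_artifact(p_attr_model, "attractors", stage))
          ids <- utils::head(which(meta$split == "train"),
                             config$voxmap_cases)
          rows <- lapply(ids, function(i) {
            cs <- read_case(meta$tensor_path[i])
            spec_a <- config$bump
            spec_b <- config$bump
            spec_b$seed <- spec_a$seed      # identical centers
            mA <- sensitivity_maps(cs, model, amod, spec_a)
            mB <- sensitivity_maps(cs, model, amod, spec_b)
            saveRDS(mA, file.path(d, paste0(cs$case_id, "_maps.rds")))
            tibble::tibble(case_id = cs$case_id, label = mA$label,
                           margin = mA$margin, total_flip = mA$n_flips,
                           mean_shift = mean(mA$shift_heat[mA$mask]),
                           icc_shift = icc_3_1(mA$shift_heat[mA$mask],
                                               mB$shift_heat[mA$mask]),
                           icc_flip = icc_3_1(mA$flip_heat[mA$mask],
                                              mB$flip_heat[mA$mask]))
          })
          utils::write.csv(dplyr::bind_rows(rows),
                           file.path(d, "icc_voxel_maps.csv"),
                           row.names = FALSE)
        }
      },
      dynamics = {
        d <- sdir("dynamics")
        tbl <- tibble::as_tibble(
          utils::read.csv(need_artifact(p_embed_attr, "attractors", stage)))
        ds <- build_tangent_dataset(tbl, k = min(8L, nrow(tbl) - 1L))
        field <- train_field(ds, hidden = config$ode_hidden,
                             epochs = config$ode_epochs,
                             seed = config$seed)
        saveRDS(field, p_field)
        Z <- latent_matrix(tbl)
        dyn <- dynamic_attractors(field, Z, steps = config$ode_steps,
                                  K = config$k, seed = config$seed)
        ly <- lyapunov(field, Z[seq_len(min(10, nrow(Z))), , drop = FALSE],
                       seed = config$seed)
        utils::write.csv(ly, file.path(d, "lyapunov.csv"),
                         row.names = FALSE)
        out <- tbl
        out$attr_dynamic <- dyn$labels
        out$converged <- dyn$converged
        utils::write.csv(out,
                         file.path(d,
                                   "embeddings_with_dynamic_attractors.csv"),
                         row.names = FALSE)
        saveRDS(dyn, file.path(d, "dynamic_attractors.rds"))
      },
      control = {
        d <- sdir("control")
        tbl <- tibble::as_tibble(
          utils::read.csv(need_artifact(p_embed_attr, "attractors", stage)))
        field <- readRDS(need_artifact(p_field, "dynamics", stage))
        amod <- readRDS(need_artifact(p_attr_model, "attractors", stage))
        ac <- analysis_cohort(tbl)
        risk <- canonical_risk_order(amod,
          tibble::tibble(label = ac$attractor, time = ac$surv_days,
                         event = ac$event))
        low_label <- risk$label[risk$risk == "low"][1]
        target <- amod$centroids[low_label + 1L, ]
        Z <- latent_matrix(tbl)
        pca <- pca_diagnostics(Z)
        cfg_c <- control_config(target,
                                B = control_basis(pca, config$control_m),
                                u_bound = 1,
                                lambda_energy = config$control_lambda,
                                steps = config$control_steps)
        n_ctl <- min(10L, nrow(Z))
        det <- evaluate_control(field, Z[seq_len(n_ctl), , drop = FALSE],
                                cfg_c)
        utils::write.csv(det$per_case,
                         file.path(d, "deterministic_control.csv"),
                         row.names = FALSE)
        if (config$sac_timesteps > 0L) {
          env <- rl_environment(field, cfg_c, pca,
                                Z[seq_len(n_ctl), , drop = FALSE])
          pol <- train_sac(env, timesteps = config$sac_timesteps,
                           seed = config$seed)
          utils::write.csv(pol$evaluation,
                           file.path(d, "sac_evaluation.csv"),
                           row.names = FALSE)
        }
      }
    )
    update_manifest(config, stage)
  }
  invisible(jsonlite::read_json(file.path(root, "manifest.json")))
}

config_hash <- function(config) {
  # stable hash of the config (rds serialization of the sorted field list)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- config[order(names(config))]
  saveRDS(flat, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

update_manifest <- function(config, stage) {
  root <- config$out_dir
  mpath <- file.path(root, "manifest.json")
  manifest <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = TRUE) else
      list(config_hash = config_hash(config), seed = config$seed,
           r_version = paste(R.version$major, R.version$minor, sep = "."),
           stages = list())
  files <- list.files(file.path(root, stage), recursive = TRUE,
                      full.names = TRUE)
  manifest$stages[[stage]] <- lapply(stats::setNames(files,
                                                     basename(files)),
                                     function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
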
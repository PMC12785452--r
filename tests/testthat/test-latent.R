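test_that("case embedding: single-patch volume gives z-bar equal to the
           patch encoding; duplication leaves the average unchanged", {
  fx <- mf_small_cohort()
  ae <- mf_trained_ae()
  cs <- fx$cases[[1]]
  emb <- case_embed(cs, ae$trained, n_patches = 5L, seed = 3L)
  # grid == patch, so every patch is the full volume
  expect_equal(emb$z_bar, ae_encode(ae$trained, cs$tensor),
               tolerance = 1e-12)
  z1 <- case_embed(cs, ae$trained, n_patches = 2L, seed = 4L)$z_bar
  z2 <- case_embed(cs, ae$trained, n_patches = 2L, seed = 4L)$z_bar
  expect_identical(z1, z2)
})

test_that("embedding table joins clinical data, keeps raw values and
           enforces unique keys", {
  fx <- mf_small_cohort()
  emb <- mf_small_embeddings()
  expect_equal(nrow(emb), 16)
  expect_length(grep("^z[0-9]+$", names(emb)), 16)   # tiny latent = 16
  emb$stability <- seq_len(nrow(emb)) * 1.0
  tbl <- build_embedding_table(emb, fx$meta)
  expect_equal(nrow(tbl), 16)
  expect_true(all(c("split", "case_id", "stability", "age", "resection",
                    "surv_days", "event") %in% names(tbl)))
  expect_equal(tbl$stability, emb$stability)   # raw, not z-scored
  p <- file.path(tempdir(), "emb.csv")
  utils::write.csv(tbl, p, row.names = FALSE)
  back <- utils::read.csv(p, colClasses = c(case_id = "character"))
  expect_equal(latent_matrix(tibble::as_tibble(back)), latent_matrix(tbl),
               tolerance = 1e-12, ignore_attr = TRUE)
  bad <- emb
  bad$case_id[2] <- bad$case_id[1]
  expect_error(build_embedding_table(bad, fx$meta), "unique")
})

test_that("analysis cohort rule keeps train cases with survival only", {
  fx <- mf_small_cohort()
  emb <- mf_small_embeddings()
  meta <- fx$meta
  meta$surv_days[1] <- NA
  tbl <- build_embedding_table(emb, meta)
  ac <- analysis_cohort(tbl)
  expect_equal(nrow(ac),
               sum(meta$split == "train" & !is.na(meta$surv_days)))
  expect_true(all(ac$split == "train"))
})

test_that("PCA diagnostics: planar data is 2-D, cumulative curve is
           monotone, projection matches an eigen oracle", {
  set.seed(5)
  basis <- qr.Q(qr(matrix(rnorm(128 * 2), 128, 2)))
  coords <- matrix(rnorm(40), 20, 2) %*% t(basis)
  Z <- coords + matrix(rnorm(128, sd = 0), 20, 128, byrow = TRUE)
  colnames(Z) <- paste0("z", 0:127)
  pc <- pca_diagnostics(Z)
  expect_equal(pc$explained$cumulative[2], 1, tolerance = 1e-9)
  expect_true(all(diff(pc$explained$cumulative) >= -1e-12))
  expect_equal(utils::tail(pc$explained$cumulative, 1), 1,
               tolerance = 1e-9)
  # oracle: eigendecomposition of the covariance
  Zc <- scale(Z, scale = FALSE)
  ev <- eigen(crossprod(Zc) / (nrow(Z) - 1))
  oracle <- Zc %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    agree <- max(abs(pc$scores[, j] - oracle[, j]),
                 abs(pc$scores[, j] + oracle[, j]))
    flip_ok <- min(max(abs(pc$scores[, j] - oracle[, j])),
                   max(abs(pc$scores[, j] + oracle[, j])))
    expect_lt(flip_ok, 1e-8)
  }
  expect_error(pca_diagnostics(Z[1:2, ]), "3 cases")
})

test_that("stability index: constant and linear decoders give closed-form
           values; Monte-Carlo agrees with brute force; scale covariance", {
  expect_equal(stability_index(function(z) array(3.7, c(2, 2)),
                               list(rnorm(4)), seed = 1L), 0)
  # 1-D latent, linear decoder: s = sum(|W|) exactly
  W1 <- c(1.5, -2, 0.25)
  s1 <- stability_index(function(z) W1 * z, list(0.3), n_pert = 8L,
                        seed = 2L)
  expect_equal(s1, sum(abs(W1)), tolerance = 1e-12)
  # multi-d latent: MC estimate within 5% of a 1e5-sample oracle
  set.seed(7)
  d <- 8L
  W <- matrix(rnorm(20 * d), 20, d)
  sigma <- 0.1
  E <- matrix(rnorm(1e5 * d, 0, sigma), ncol = d)
  oracle <- mean(rowSums(abs(E %*% t(W))) / sqrt(rowSums(E^2)))
  est <- stability_index(function(z) drop(W %*% z), list(rnorm(d)),
                         n_pert = 400L, sigma = sigma, seed = 8L)
  expect_lt(abs(est - oracle) / oracle, 0.05)
  # scaling the decoder by c scales s by c
  est2 <- stability_index(function(z) 3 * drop(W %*% z), list(rnorm(d)),
                          n_pert = 50L, sigma = sigma, seed = 9L)
  est1 <- stability_index(function(z) drop(W %*% z), list(rnorm(d)),
                          n_pert = 50L, sigma = sigma, seed = 9L)
  expect_equal(est2, 3 * est1, tolerance = 1e-10)
  expect_error(stability_index(function(z) z, list(1), sigma = 0), "sigma")
})

test_that("case-level stability is deterministic and non-negative", {
  fx <- mf_small_cohort()
  ae <- mf_trained_ae()
  s1 <- latent_stability(ae$trained, fx$cases[[1]], seed = 5L)
  s2 <- latent_stability(ae$trained, fx$cases[[1]], seed = 5L)
  expect_identical(s1, s2)
  expect_gte(s1, 0)
})

test_that("patch averaging reduces embedding variance relative to single
           patches", {
  fx <- mf_small_cohort()
  ae <- mf_trained_ae()
  cs <- fx$cases[[2]]
  # use sub-volume patches so draws actually differ
  cfg16 <- ae_config_tiny(patch = 16L, seed = 42L)
  m16 <- ae_new(cfg16)
  zs <- vapply(1:30, function(i)
    ae_encode(m16, sample_patches(cs, 1L, 16L, seed = i)[[1]]$tensor),
    numeric(16))
  zbars <- vapply(1:30, function(i) {
    ps <- sample_patches(cs, 8L, 16L, seed = 100L + i)
    rowMeans(vapply(ps, function(p) ae_encode(m16, p$tensor), numeric(16)))
  }, numeric(16))
  expect_lt(mean(apply(zbars, 1, stats::var)),
            mean(apply(zs, 1, stats::var)))
})
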
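# Shared fixtures, built once per test run and cached (the trained tiny
# autoencoder is the expensive one).

.fixture_cache <- new.env(parent = emptyenv())

fixture_dir <- function(name) {
  d <- file.path(tempdir(), "morphoflow_fixtures", name)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# Small phantom cohort: 16 cases on a 32-voxel grid.
mf_small_cohort <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  spec <- phantom_spec(16, grid = 32L, seed = 7L)
  rec <- generate_cohort(spec, fixture_dir("small_vol"))
  meta <- preprocess_cohort(rec, fixture_dir("small_pp"), target_edge = 32L)
  cases <- lapply(meta$tensor_path, read_case)
  .fixture_cache$small <- list(spec = spec, records = rec, meta = meta,
                               cases = cases)
  .fixture_cache$small
}

# Tiny autoencoder trained briefly on the small cohort (full-volume
# patches); reused by the ae / latent / voxmap tests.
mf_trained_ae <- function() {
  if (!is.null(.fixture_cache$ae)) return(.fixture_cache$ae)
  fx <- mf_small_cohort()
  cfg <- ae_config_tiny(patch = 32L, max_epochs = 8L, patience = 7L,
                        lr = 3e-3, seed = 42L)
  tr <- lapply(fx$cases[1:12], function(cs)
    sample_patches(cs, 1L, size = 32L, seed = 1L)[[1]])
  va <- lapply(fx$cases[13:16], function(cs)
    sample_patches(cs, 1L, size = 32L, seed = 1L)[[1]])
  untrained <- ae_new(cfg)
  trained <- ae_train(untrained, tr, va)
  .fixture_cache$ae <- list(cfg = cfg, untrained = untrained,
                            trained = trained, train_patches = tr,
                            valid_patches = va)
  .fixture_cache$ae
}

# Case-level embeddings of the small cohort under the trained model.
mf_small_embeddings <- function() {
  if (!is.null(.fixture_cache$emb)) return(.fixture_cache$emb)
  fx <- mf_small_cohort()
  ae <- mf_trained_ae()
  emb <- embed_cohort(fx$cases, ae$trained, n_patches = 2L, seed = 7L)
  .fixture_cache$emb <- emb
  emb
}

# Three well-separated Gaussian clusters in d dimensions. Centers point in
# random directions so every coordinate carries structure (and a
# column-wise shuffle genuinely destroys it).
make_blobs <- function(n_per = 20L, d = 16L, sep = 30L, sd = 1, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  centers <- matrix(stats::rnorm(3 * d), 3, d)
  centers <- sep * centers / sqrt(rowSums(centers^2))
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(stats::rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[k, ], n_per, d, byrow = TRUE)))
  list(X = X, labels = rep(1:3, each = n_per))
}
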
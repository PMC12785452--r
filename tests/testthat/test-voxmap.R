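test_that("foreground mask equals the elementwise oracle and rejects empty
           volumes", {
  t4 <- array(0, c(4, 8, 8, 8))
  t4[2, 3:5, 3:5, 3:5] <- 0.2
  sc <- standardized_case(t4, "m1", "train")
  m <- foreground_mask(sc, 0.15)
  oracle <- apply(t4, c(2, 3, 4), max) > 0.15
  expect_identical(m, oracle)
  expect_true(all(m[3:5, 3:5, 3:5]))
  expect_error(foreground_mask(
    standardized_case(array(0, c(4, 8, 8, 8)), "z", "train")), "empty")
})

test_that("bump application: zero amplitude is the identity, corner kernels
           crop correctly, and the delta matches the Gaussian-sum oracle", {
  set.seed(1)
  t4 <- array(runif(4 * 16^3, 0.2, 0.4), c(4, 16, 16, 16))
  spec <- bump_spec(kernel = 7L, sigma_spatial = 1, base_eps = 0.9)
  b0 <- apply_bump(t4, c(8, 8, 8), spec, scale = 0)
  expect_identical(b0$tensor, t4)
  expect_true(all(b0$bump[b0$bump > 0] >= 0))

  # corner: support stays inside the volume
  bc <- apply_bump(t4, c(1, 1, 1), spec, scale = 2)
  expect_true(all(bc$support$lo >= 1 & bc$support$hi <= 16))
  expect_false(any(is.na(bc$tensor)))
  expect_error(apply_bump(t4, c(0, 8, 8), spec, 1), "outside")

  # interior bump, no clipping: sum of the applied delta = eps * kernel sum
  bi <- apply_bump(t4, c(8, 8, 8), spec, scale = 0.5)
  eps <- 0.9 * 0.5
  r <- -3:3
  g1 <- exp(-r^2 / 2)
  kernel_sum <- sum(outer(outer(g1, g1), g1))
  delta <- sum(bi$tensor[4, , , ] - t4[4, , , ])
  expect_equal(delta, eps * kernel_sum, tolerance = 1e-10)
  # only FLAIR changes, and only within the kernel support
  expect_identical(bi$tensor[1:3, , , ], t4[1:3, , , ])
  changed <- which(bi$tensor[4, , , ] != t4[4, , , ], arr.ind = TRUE)
  expect_true(all(changed >= 5 & changed <= 11))
})

test_that("sensitivity maps: locality, single-bump normalization identity,
           duplication invariance and seeded determinism", {
  fx <- mf_small_cohort()
  ae <- mf_trained_ae()
  emb <- mf_small_embeddings()
  amod <- fit_attractors(emb, K = 3L, n_seeds = 3L, seed = 1L)
  cs <- fx$cases[[1]]
  spec <- bump_spec(n_centers = 12L, n_patches = 2L, seed = 5L)
  sm <- sensitivity_maps(cs, ae$trained, amod, spec)
  expect_true(all(sm$shift_heat[sm$hit == 0] == 0))
  expect_true(all(sm$flip_heat[sm$hit == 0] == 0))
  expect_true(all(sm$shift_heat >= 0))
  sm2 <- sensitivity_maps(cs, ae$trained, amod, spec)
  expect_identical(sm$shift_heat, sm2$shift_heat)   # deterministic

  # single bump: map equals the latent shift across the kernel support
  ctr <- matrix(c(16, 16, 16), 1)
  s1 <- sensitivity_maps(cs, ae$trained, amod, spec, centers = ctr,
                         scales = 2)
  on_support <- s1$hit >= 1e-6
  vals <- unique(round(s1$shift_heat[on_support], 12))
  expect_length(vals, 1)                     # bump/bump = 1 everywhere
  expect_equal(s1$shift_heat[16, 16, 16], vals[1])
  out_support <- which(s1$hit < 1e-6)
  expect_true(all(s1$shift_heat[out_support] == 0))

  # duplicating every bump (same centers, same draws) leaves maps unchanged
  ctrs <- matrix(c(14, 14, 14, 18, 18, 18), 2, byrow = TRUE)
  a <- sensitivity_maps(cs, ae$trained, amod, spec, centers = ctrs,
                        scales = c(2, 3))
  b <- sensitivity_maps(cs, ae$trained, amod, spec,
                        centers = ctrs[c(1, 2, 1, 2), ],
                        scales = c(2, 3, 2, 3))
  expect_equal(a$shift_heat, b$shift_heat, tolerance = 1e-12)
})

test_that("linear encoder: doubling the amplitude doubles the latent
           displacement exactly", {
  # emulate the shift computation with a linear map of the FLAIR channel
  set.seed(2)
  # amplitudes small enough that no voxel clips (linearity regime)
  t4 <- array(runif(4 * 12^3, 0.1, 0.3), c(4, 12, 12, 12))
  spec <- bump_spec(kernel = 5L, base_eps = 0.1)
  W <- rnorm(12^3)
  enc <- function(x4) sum(W * x4[4, , , ])
  b1 <- apply_bump(t4, c(6, 6, 6), spec, scale = 1)
  b2 <- apply_bump(t4, c(6, 6, 6), spec, scale = 2)
  d1 <- abs(enc(b1$tensor) - enc(t4))
  d2 <- abs(enc(b2$tensor) - enc(t4))
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("ICC(3,1): identity, zero-map convention, and recovery of a known
           variance ratio", {
  x <- rnorm(500)
  expect_equal(icc_3_1(x, x), 1, tolerance = 1e-12)
  expect_equal(icc_3_1(rep(0, 500), rep(0, 500)), 0)
  set.seed(3)
  for (r in c(0.5, 2, 9)) {
    s <- rnorm(4000, sd = sqrt(r))
    a <- s + rnorm(4000)
    b <- s + rnorm(4000)
    expect_lt(abs(icc_3_1(a, b) - r / (r + 1)), 0.05)
  }
})

test_that("voxmap_icc summarizes replicates with identical centers", {
  fx <- mf_small_cohort()
  ae <- mf_trained_ae()
  emb <- mf_small_embeddings()
  amod <- fit_attractors(emb, K = 3L, n_seeds = 3L, seed = 1L)
  spec <- bump_spec(n_centers = 10L, n_patches = 2L, seed = 11L)
  cs <- fx$cases[[3]]
  mask <- foreground_mask(cs)
  vox <- which(mask)
  set.seed(4)
  ctrs <- arrayInd(vox[sample.int(length(vox), 10)], dim(mask))
  rep_a <- sensitivity_maps(cs, ae$trained, amod, spec, centers = ctrs,
                            scales = runif(10, 1, 6))
  rep_b <- sensitivity_maps(cs, ae$trained, amod, spec, centers = ctrs,
                            scales = runif(10, 1, 6))
  out <- voxmap_icc(list(rep_a), list(rep_b), "shift_heat")
  expect_equal(nrow(out), 1)
  expect_true(out$icc >= -1 && out$icc <= 1)
  # no flips anywhere -> flip ICC is 0 by convention
  if (rep_a$n_flips + rep_b$n_flips == 0) {
    fl <- voxmap_icc(list(rep_a), list(rep_b), "flip_heat")
    expect_equal(fl$icc, 0)
  }
})
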
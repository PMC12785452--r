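test_that("NIfTI round-trip preserves values and headers validate", {
  set.seed(1)
  vol <- array(runif(12 * 10 * 8), c(12, 10, 8))
  p <- file.path(tempdir(), "rt.nii.gz")
  write_nifti(vol, p)
  hdr <- read_nifti_header(p)
  expect_true(hdr$ok)
  expect_equal(hdr$dim, c(12, 10, 8))
  back <- read_nifti(p)
  expect_equal(back$data, vol, tolerance = 1e-7)  # float32 storage
  expect_equal(back$pixdim, c(1, 1, 1))
})

test_that("written NIfTI is readable by an independent implementation", {
  vol <- array(seq(0, 1, length.out = 4^3), c(4, 4, 4))
  p <- file.path(tempdir(), "xcheck.nii.gz")
  write_nifti(vol, p)
  out <- system2("python", c("-c", shQuote(paste0(
    "import nibabel, numpy; img = nibabel.load('", p, "'); ",
    "d = numpy.asarray(img.dataobj); ",
    "print(d.shape, float(d.sum()))"))), stdout = TRUE)
  expect_match(out[length(out)], "(4, 4, 4)", fixed = TRUE)
  got <- as.numeric(sub(".*\\) ", "", out[length(out)]))
  expect_equal(got, sum(vol), tolerance = 1e-4)
})

test_that("qc_case fails closed on missing, corrupt or mismatched inputs", {
  d <- file.path(tempdir(), "qc")
  dir.create(d, showWarnings = FALSE)
  paths <- sapply(c("T1", "T1Gd", "T2", "FLAIR"), function(m) {
    p <- file.path(d, paste0(m, ".nii.gz"))
    write_nifti(array(runif(8^3), c(8, 8, 8)), p)
    p
  })
  expect_true(qc_case(paths)$pass)
  miss <- paths
  miss["FLAIR"] <- file.path(d, "nope.nii.gz")
  r <- qc_case(miss)
  expect_false(r$pass)
  expect_match(paste(r$reasons, collapse = ";"), "missing modality")
  trunc <- paths
  writeBin(as.raw(sample(0:255, 100, TRUE)), file.path(d, "bad.nii"))
  trunc["T2"] <- file.path(d, "bad.nii")
  r2 <- qc_case(trunc)
  expect_false(r2$pass)
  expect_match(paste(r2$reasons, collapse = ";"), "invalid header")
  mm <- paths
  write_nifti(array(0, c(6, 6, 6)), file.path(d, "small.nii.gz"))
  mm["T1"] <- file.path(d, "small.nii.gz")
  r3 <- qc_case(mm)
  expect_false(r3$pass)
  expect_match(paste(r3$reasons, collapse = ";"), "shape mismatch")
})

test_that("trilinear resampling preserves affine ramps and constants;
           nearest preserves label sets", {
  g <- 24L
  ax <- seq_len(g)
  ramp <- outer(outer(2 * ax, 3 * ax, "+"), 5 * ax, "+")
  up <- resample_to_grid(ramp, 48L, mode = "trilinear")
  # still affine in each axis: residual of a linear fit is ~0
  co <- expand.grid(x = seq_len(48), y = seq_len(48), z = seq_len(48))
  fit <- stats::lm(as.vector(up) ~ co$x + co$y + co$z)
  expect_lt(max(abs(stats::residuals(fit))), 1e-5)
  const <- array(0.37, c(10, 10, 10))
  expect_equal(resample_to_grid(const, 17L), array(0.37, c(17, 17, 17)))
  mask <- array(sample(0:2, 12^3, TRUE), c(12, 12, 12))
  near <- resample_to_grid(mask, 30L, mode = "nearest")
  expect_true(all(near %in% 0:2))
  expect_error(resample_to_grid(matrix(1, 3, 3), 8L), "3-D")
})

test_that("percentile normalization matches a brute-force oracle and
           handles degenerate volumes", {
  set.seed(2)
  x <- array(stats::rnorm(10000), c(10, 10, 100))
  x[1:2] <- c(-50, 50)                      # extreme outliers
  got <- normalize_channel(x)
  # independent oracle: sorted order statistics (inverted ECDF)
  xs <- sort(as.vector(x))
  lo <- xs[ceiling(0.01 * length(xs))]
  hi <- xs[ceiling(0.99 * length(xs))]
  oracle <- pmin(hi, pmax(lo, x))
  oracle <- (oracle - lo) / (hi - lo)
  dim(oracle) <- dim(x)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(min(got), 0)
  expect_equal(max(got), 1)
  expect_true(got[1] == 0 && got[2] == 1)   # outliers land exactly at 0/1
  # linear ramp: min 0, max 1, interior affine
  r <- normalize_channel(array(seq_len(10000), c(10, 10, 100)))
  expect_equal(range(r), c(0, 1))
  # constant volume maps to zeros by convention
  expect_equal(normalize_channel(array(5, c(4, 4, 4))),
               array(0, c(4, 4, 4)))
  expect_error(normalize_channel(array(c(NA, 1:7), c(2, 2, 2))),
               "non-finite")
})

test_that("normalization is idempotent on phantom volumes", {
  fx <- mf_small_cohort()
  v <- readRDS(fx$records$volume_path[1])
  for (ch in 1:4) {
    n1 <- normalize_channel(v[ch, , , ])
    n2 <- normalize_channel(n1)
    expect_lt(max(abs(n2 - n1)), 1e-6)
  }
})

test_that("packaged tensors satisfy the standardized-case contract and
           round-trip losslessly", {
  fx <- mf_small_cohort()
  for (cs in fx$cases[1:4]) {
    expect_s3_class(cs, "standardized_case")
    expect_equal(dim(cs$tensor)[1], 4)
    expect_true(all(cs$tensor >= 0 & cs$tensor <= 1))
    expect_false(anyNA(cs$tensor))
  }
  sc <- fx$cases[[1]]
  p <- file.path(tempdir(), "case_rt.rds")
  package_case(sc, p)
  expect_identical(read_case(p)$tensor, sc$tensor)
  # 5-channel variant round-trips too
  t5 <- array(runif(5 * 16^3), c(5, 16, 16, 16))
  sc5 <- standardized_case(t5, "c5", "train")
  package_case(sc5, p)
  expect_identical(read_case(p)$tensor, t5)
  expect_error(standardized_case(t5 * 2, "bad", "train"), "outside")
})

test_that("patch sampling: forced corner, determinism, uniform corners", {
  t4 <- array(runif(4 * 16^3), c(4, 16, 16, 16))
  sc <- standardized_case(t4, "p1", "train")
  ps <- sample_patches(sc, 3L, size = 16L, seed = 1L)
  for (p in ps) {
    expect_equal(p$origin, c(0L, 0L, 0L))
    expect_identical(p$tensor, t4)
  }
  ps1 <- sample_patches(sc, 5L, size = 8L, seed = 9L)
  ps2 <- sample_patches(sc, 5L, size = 8L, seed = 9L)
  expect_identical(lapply(ps1, `[[`, "origin"), lapply(ps2, `[[`, "origin"))
  expect_error(sample_patches(sc, 1L, size = 32L), "exceeds")

  # corners approximately uniform over valid positions (chi-square)
  big <- standardized_case(array(0.5, c(4, 24, 24, 24)), "u", "train")
  draws <- sample_patches(big, 3000L, size = 8L, seed = 4L)
  xs <- vapply(draws, function(p) p$origin[1], numeric(1))
  tab <- table(factor(xs, levels = 0:16))
  p_val <- stats::chisq.test(tab)$p.value
  expect_gt(p_val, 0.01)
})

test_that("empty foreground degenerates to whole-volume bounds", {
  z <- standardized_case(array(0, c(4, 12, 12, 12)), "z", "train")
  ps <- sample_patches(z, 20L, size = 6L, seed = 2L)
  orig <- do.call(rbind, lapply(ps, `[[`, "origin"))
  expect_true(all(orig >= 0 & orig <= 6))
  expect_gt(max(orig), 0)   # not pinned to one corner
})
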
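test_that("validity indices equal textbook-formula oracles on a toy set", {
  set.seed(1)
  X <- rbind(matrix(rnorm(10, 0, 0.3), 5, 2),
             matrix(rnorm(10, 4, 0.3), 5, 2))
  labels <- rep(1:2, each = 5)
  idx <- cluster_indices(X, labels)
  # brute-force oracles
  D <- as.matrix(stats::dist(X))
  sil <- sapply(1:10, function(i) {
    a <- mean(D[i, setdiff(which(labels == labels[i]), i)])
    b <- mean(D[i, labels != labels[i]])
    (b - a) / max(a, b)
  })
  expect_equal(idx$silhouette, mean(sil), tolerance = 1e-12)
  c1 <- colMeans(X[1:5, ]); c2 <- colMeans(X[6:10, ])
  s1 <- mean(sqrt(rowSums(sweep(X[1:5, ], 2, c1)^2)))
  s2 <- mean(sqrt(rowSums(sweep(X[6:10, ], 2, c2)^2)))
  db <- mean(c((s1 + s2), (s1 + s2)) / sqrt(sum((c1 - c2)^2)))
  expect_equal(idx$davies_bouldin, db, tolerance = 1e-12)
  g <- colMeans(X)
  B <- 5 * sum((c1 - g)^2) + 5 * sum((c2 - g)^2)
  W <- sum(sweep(X[1:5, ], 2, c1)^2) + sum(sweep(X[6:10, ], 2, c2)^2)
  expect_equal(idx$calinski_harabasz, (B / 1) / (W / 8), tolerance = 1e-12)
})

test_that("indices are invariant to cluster relabeling", {
  blob <- make_blobs(n_per = 10L, d = 4L, seed = 2L)
  i1 <- cluster_indices(blob$X, blob$labels)
  relab <- c(3L, 1L, 2L)[blob$labels]
  i2 <- cluster_indices(blob$X, relab)
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("K-scan selects the planted number of clusters", {
  blob <- make_blobs(n_per = 15L, d = 128L, sep = 100L, seed = 3L)
  colnames(blob$X) <- paste0("z", seq_len(ncol(blob$X)) - 1L)
  ks <- scan_k(blob$X, k_range = 2:6, seed = 1L)
  expect_equal(ks$selected_k, 3L)
  expect_gt(max(ks$indices$silhouette), 0.8)
  # concordance: Davies-Bouldin minimal and Calinski-Harabasz maximal at 3
  expect_equal(ks$indices$k[which.min(ks$indices$davies_bouldin)], 3L)
  expect_equal(ks$indices$k[which.max(ks$indices$calinski_harabasz)], 3L)

  two <- make_blobs(n_per = 15L, d = 16L, seed = 4L)
  X2 <- two$X[two$labels != 3, ]
  ks2 <- scan_k(X2, k_range = 2:5, seed = 1L)
  expect_equal(ks2$selected_k, 2L)
  expect_error(scan_k(blob$X[1:5, ], k_range = 2:10), "below")
})

test_that("adjusted Rand index: identity, relabeling invariance, chance", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(2L, 3L, 1L)[a]), 1)
  b <- a[c(6:30, 1:5)]              # cyclic shift: genuinely different
  expect_lt(adjusted_rand_index(a, b), 1)
  set.seed(5)
  expect_lt(abs(adjusted_rand_index(sample(1:3, 300, TRUE),
                                    sample(1:3, 300, TRUE))), 0.1)
})

test_that("attractor fitting is seed-stable on separable clusters", {
  blob <- make_blobs(n_per = 12L, d = 32L, sep = 25L, seed = 6L)
  colnames(blob$X) <- paste0("z", seq_len(ncol(blob$X)) - 1L)
  fit <- fit_attractors(blob$X, K = 3L, n_seeds = 10L, seed = 42L)
  expect_equal(fit$ari_mean, 1.0, tolerance = 1e-12)
  expect_equal(fit$ari_sd, 0.0, tolerance = 1e-12)
  expect_equal(fit$ari_pairs, 45L)
  expect_equal(adjusted_rand_index(fit$labels, blob$labels), 1.0)
  expect_true(all(dim(fit$centroids) == c(3, 32)))
  # predictions on training data reproduce labels; margins positive
  pred <- predict(fit, blob$X)
  expect_equal(as.integer(pred), fit$labels)
  expect_true(all(attr(pred, "margin") > 0))
})

test_that("permutation test: structured data gives the minimal p; null
           embeddings give large p; B = 0 is rejected", {
  blob <- make_blobs(n_per = 12L, d = 16L, sep = 30L, seed = 7L)
  pt <- permutation_test(blob$X, K = 3L, B = 50L, seed = 1L)
  expect_equal(pt$p_value, 1 / 51)
  expect_gt(pt$observed_silhouette, max(pt$null_scores))
  expect_error(permutation_test(blob$X, K = 3L, B = 0L), "B")
  set.seed(8)
  null_cloud <- matrix(rnorm(60 * 8), 60, 8)
  pt2 <- permutation_test(null_cloud, K = 3L, B = 60L, seed = 2L)
  expect_gt(pt2$p_value, 0.05)
})

test_that("canonical risk order sorts by KM median with deterministic
           tie-breaks", {
  # labels 0,1,2 with medians 500, 300, 400 -> low=0, intermediate=2, high=1
  mk <- function(label, times) tibble::tibble(
    label = label, time = times, event = rep(1L, length(times)))
  surv <- dplyr::bind_rows(mk(0L, c(480, 500, 520)),
                           mk(1L, c(280, 300, 320)),
                           mk(2L, c(380, 400, 420)))
  model <- structure(list(K = 3L), class = "attractor_model")
  ro <- canonical_risk_order(model, surv)
  expect_equal(ro$label[ro$risk == "low"], 0L)
  expect_equal(ro$label[ro$risk == "intermediate"], 2L)
  expect_equal(ro$label[ro$risk == "high"], 1L)
  # equal medians: tie broken by mean survival, deterministically
  surv2 <- dplyr::bind_rows(mk(0L, c(300, 300, 800)),
                            mk(1L, c(300, 300, 400)),
                            mk(2L, c(600, 700, 800)))
  ro2a <- canonical_risk_order(model, surv2)
  ro2b <- canonical_risk_order(model, surv2)
  expect_identical(ro2a, ro2b)
  expect_equal(ro2a$label[ro2a$risk == "low"], 2L)
  expect_equal(ro2a$label[ro2a$risk == "intermediate"], 0L)  # higher mean
  # cluster with no survival data falls last
  surv3 <- dplyr::bind_rows(mk(0L, c(400, 500)), mk(1L, c(100, 200)))
  ro3 <- canonical_risk_order(model, surv3)
  expect_equal(ro3$label[ro3$risk == "high"], 2L)
})

test_that("tidiers expose the fitted attractor model", {
  blob <- make_blobs(n_per = 8L, d = 8L, seed = 9L)
  fit <- fit_attractors(blob$X, K = 3L, n_seeds = 3L)
  td <- tidy(fit)
  expect_equal(nrow(td), 24)
  gl <- glance(fit)
  expect_true(all(c("K", "silhouette", "ari_mean") %in% names(gl)))
  expect_equal(gl$K, 3L)
})
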
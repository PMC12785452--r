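test_that("tangent dataset: counts, collinear geometry and a brute-force
           neighbour oracle", {
  Z <- matrix(c(0, 1, 2.2, 0, 0, 0), 3, 2)
  ds <- build_tangent_dataset(Z, k = 1L)
  expect_equal(nrow(ds$X), 3)
  expect_true(all(ds$Y[, 2] == 0))          # displacements stay on the line
  expect_equal(ds$edges$to, c(2L, 1L, 2L))  # nearest neighbours

  set.seed(1)
  Zr <- matrix(rnorm(40), 10, 4)
  k <- 3L
  dsr <- build_tangent_dataset(Zr, k = k)
  expect_equal(nrow(dsr$X), 10 * k)
  D <- as.matrix(stats::dist(Zr))
  diag(D) <- Inf
  for (i in 1:10) {
    oracle <- order(D[i, ])[1:k]
    expect_setequal(dsr$edges$to[dsr$edges$from == i], oracle)
  }
  expect_error(build_tangent_dataset(Zr, k = 10L), "more cases")
})

test_that("field training: zero displacements give a near-zero field; a
           planted linear field is recovered; early loss decreases", {
  set.seed(2)
  Z <- matrix(rnorm(60 * 4), 60, 4)
  ds0 <- list(X = Z, Y = Z * 0)
  f0 <- train_field(ds0, hidden = c(16L, 8L), epochs = 400L, lr = 3e-2,
                    batch = 8L, seed = 1L)
  expect_lt(max(abs(field_eval(f0, Z))), 1e-2)

  A <- diag(c(-0.5, -1))
  Zp <- matrix(rnorm(400 * 2, sd = 2), 400, 2)
  ds <- list(X = Zp, Y = t(A %*% t(Zp)))
  fld <- train_field(ds, hidden = c(64L, 32L), epochs = 80L, lr = 3e-3,
                     seed = 5L)
  held <- matrix(rnorm(100 * 2, sd = 1.5), 100, 2)
  pred <- field_eval(fld, held)
  truth <- t(A %*% t(held))
  expect_lt(sqrt(sum((pred - truth)^2)) / sqrt(sum(truth^2)), 0.10)
  expect_true(all(diff(fld$history[1:5]) < 0))
})

test_that("field training is deterministic under the seed", {
  set.seed(3)
  ds <- list(X = matrix(rnorm(80), 20, 4), Y = matrix(rnorm(80), 20, 4))
  f1 <- train_field(ds, hidden = c(8L), epochs = 5L, seed = 7L)
  f2 <- train_field(ds, hidden = c(8L), epochs = 5L, seed = 7L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$W, f2$net$W)
})

test_that("RK4: constants, the exponential closed form, and fourth-order
           step refinement", {
  fz <- linear_field(matrix(0))
  tr0 <- integrate_field(fz, 2.5, steps = 10L)
  expect_true(all(tr0$states == 2.5))

  fm <- linear_field(matrix(-1))
  tr <- integrate_field(fm, 1, steps = 20L, dt = 0.05)
  expect_lt(abs(tr$endpoint - exp(-1)), 1e-6)

  A <- matrix(c(-0.3, 0.2, -0.1, -0.6), 2, 2)
  fl <- linear_field(A)
  e1 <- integrate_field(fl, c(1, 1), steps = 20L, dt = 0.05)$endpoint
  e2 <- integrate_field(fl, c(1, 1), steps = 40L, dt = 0.025)$endpoint
  expect_lt(sqrt(sum((e1 - e2)^2)), 1e-6)
  expect_error(integrate_field(fl, c(NA, 1), 5L), "is.finite")
})

test_that("divergence: linear fields give trace(A), rotations give zero,
           and the FD grid agrees with a VJP-trace oracle", {
  A <- diag(c(-0.5, -1))
  pc <- list(rotation = diag(2), center = c(0, 0))
  dv <- divergence_map(linear_field(A), pc, c(-1, 1), c(-1, 1), n_grid = 9L)
  expect_lt(max(abs(dv$divergence - (-1.5))), 1e-3)

  rot <- function(z) c(-z[2], z[1])
  dvr <- divergence_map(rot, pc, c(-1, 1), c(-1, 1), n_grid = 7L)
  expect_lt(max(abs(dvr$divergence)), 1e-6)

  # trained field: finite differences vs exact Jacobian trace via VJPs
  set.seed(4)
  ds <- list(X = matrix(rnorm(200 * 2), 200, 2),
             Y = matrix(rnorm(200 * 2), 200, 2) * 0.3)
  fld <- train_field(ds, hidden = c(16L), epochs = 10L, seed = 2L)
  pts <- matrix(runif(20, -0.5, 0.5), 10, 2)
  for (i in 1:10) {
    z <- pts[i, ]
    tr_vjp <- sum(vapply(1:2, function(j) {
      v <- c(0, 0)
      v[j] <- 1
      morphoflow:::field_vjp(fld, z, v)[j]
    }, numeric(1)))
    dv_fd <- divergence_map(fld, pc, z[1] + c(-0.01, 0.01),
                            z[2] + c(-0.01, 0.01), n_grid = 3L)
    expect_lt(abs(dv_fd$divergence[5] - tr_vjp), 1e-3)
  }
})

test_that("Lyapunov estimator: closed forms for linear fields, zero field,
           and sign for contraction", {
  for (a in c(-0.5, 0.3)) {
    ly <- lyapunov(linear_field(matrix(a)), matrix(rnorm(5), 5, 1),
                   steps = 200L, seed = 1L)
    expect_lt(abs(ly$lambda - a) / abs(a), 0.05)
  }
  ly0 <- lyapunov(linear_field(matrix(0)), matrix(1), steps = 100L)
  expect_equal(ly0$lambda, 0, tolerance = 1e-12)
  lyc <- lyapunov(linear_field(-0.4 * diag(3)), matrix(rnorm(9), 3, 3),
                  steps = 150L, seed = 2L)
  expect_lt(lyc$lambda, 0)
  expect_error(lyapunov(linear_field(matrix(0)), matrix(1),
                        separation = 0), "separation")
})

test_that("dynamic attractors: a 3-well gradient field collapses to its
           wells; zero field reproduces the static clustering; rotation
           never converges", {
  wells <- rbind(c(0, 0), c(10, 0), c(0, 10))
  well_field <- function(z) {
    d2 <- rowSums(sweep(wells, 2, z)^2)
    -(z - wells[which.min(d2), ])
  }
  set.seed(5)
  truth <- sample(1:3, 30, replace = TRUE)
  Z <- wells[truth, ] + matrix(rnorm(60, sd = 1), 30, 2)
  dyn <- dynamic_attractors(well_field, Z, steps = 200L, K = 3L, seed = 1L)
  expect_equal(dyn$convergence_fraction, 1.0)
  expect_equal(adjusted_rand_index(dyn$labels, truth), 1.0)
  # endpoints sit essentially on the wells
  expect_lt(max(abs(dyn$endpoints - wells[truth, ])), 0.01)

  f0 <- function(z) z * 0
  dyn0 <- dynamic_attractors(f0, Z, steps = 50L, K = 3L, seed = 1L)
  expect_equal(dyn0$endpoints, Z, ignore_attr = TRUE)
  static <- morphoflow:::km_fit(Z, 3L, seed = 1L)$cluster
  expect_equal(adjusted_rand_index(dyn0$labels, static), 1.0)

  rotf <- function(z) c(-z[2], z[1])
  ang <- runif(20, 0, 2 * pi)
  circ <- 2.5 * cbind(cos(ang), sin(ang))   # fixed-radius orbits
  dynr <- dynamic_attractors(rotf, circ, steps = 200L, K = 3L,
                             window = 20L, seed = 1L)
  expect_equal(dynr$convergence_fraction, 0)
})

test_that("endpoint clustering is invariant to case order", {
  wells <- rbind(c(0, 0), c(8, 0), c(0, 8))
  wf <- function(z) {
    d2 <- rowSums(sweep(wells, 2, z)^2)
    -(z - wells[which.min(d2), ])
  }
  set.seed(6)
  truth <- rep(1:3, each = 7)
  Z <- wells[truth, ] + matrix(rnorm(42, sd = 0.8), 21, 2)
  d1 <- dynamic_attractors(wf, Z, steps = 150L, K = 3L, seed = 2L)
  perm <- sample(21)
  d2 <- dynamic_attractors(wf, Z[perm, ], steps = 150L, K = 3L, seed = 2L)
  expect_equal(adjusted_rand_index(d1$labels[perm], d2$labels), 1.0)
})
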
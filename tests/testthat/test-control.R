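test_that("objective J: zero cases, pure terminal cost, and exact linearity
           in lambda", {
  states <- matrix(0, 11, 2)
  states[11, ] <- c(3, 4)
  U <- matrix(0, 10, 2)
  expect_equal(objective_J(states, U, target = c(3, 4),
                           lambda_energy = 1), 0)
  expect_equal(objective_J(states, U, target = c(0, 0), lambda_energy = 5),
               25)
  set.seed(1)
  U2 <- matrix(rnorm(20), 10, 2)
  dt <- 0.05
  j1 <- objective_J(states, U2, c(0, 0), lambda_energy = 1, dt = dt)
  j2 <- objective_J(states, U2, c(0, 0), lambda_energy = 2, dt = dt)
  expect_equal(j2 - j1, sum(U2^2) * dt, tolerance = 1e-12)
  expect_error(objective_J(states, matrix(0, 3, 2), c(0, 0), 1),
               "misaligned")
})

test_that("zero control reproduces the uncontrolled trajectory exactly", {
  A <- matrix(c(-0.4, 0.1, -0.2, -0.7), 2, 2)
  fl <- linear_field(A)
  z0 <- c(1.5, -0.5)
  U0 <- matrix(0, 30, 2)
  ro <- morphoflow:::rollout_cached(fl, z0, U0, diag(2), 0.05)
  unc <- integrate_field(fl, z0, 30L, 0.05)
  expect_identical(ro$states, unc$states)
})

test_that("the adjoint control gradient matches finite differences", {
  set.seed(2)
  A <- matrix(c(-0.5, 0.2, 0, -0.3), 2, 2)
  fl <- linear_field(A)
  B <- diag(2)
  z0 <- c(1, -1)
  U <- matrix(rnorm(10 * 2, sd = 0.3), 10, 2)
  dt <- 0.05
  lam <- 0.01
  target <- c(0.5, 0.5)
  ro <- morphoflow:::rollout_cached(fl, z0, U, B, dt)
  g <- morphoflow:::control_gradient(fl, ro, U, B, target, lam, dt)
  J_of <- function(Um) {
    r <- morphoflow:::rollout_cached(fl, z0, Um, B, dt)
    objective_J(r$states, Um, target, lam, dt)
  }
  eps <- 1e-6
  for (k in sample(length(U), 5)) {
    U2 <- U; U2[k] <- U2[k] + eps
    U3 <- U; U3[k] <- U3[k] - eps
    num <- (J_of(U2) - J_of(U3)) / (2 * eps)
    expect_equal(g[k], num, tolerance = 1e-6)
  }
})

test_that("bound and penalty limits: zero bound freezes the flow, huge
           lambda drives controls to zero", {
  fl <- linear_field(-0.5 * diag(2))
  z0 <- c(2, 1)
  cfg0 <- control_config(target = c(1, 1), B = diag(2), u_bound = 1e-12,
                         lambda_energy = 1e-3, steps = 20L)
  r0 <- deterministic_control(fl, z0, cfg0, max_iter = 10L)
  expect_lt(abs(r0$reduction), 1e-6)
  expect_equal(r0$dist_controlled, r0$dist_uncontrolled, tolerance = 1e-9)

  cfg_inf <- control_config(target = c(1, 1), B = diag(2), u_bound = 5,
                            lambda_energy = 1e9, steps = 20L)
  r_inf <- deterministic_control(fl, z0, cfg_inf, max_iter = 60L)
  expect_lt(max(abs(attr(r_inf, "controls"))), 1e-4)
  expect_equal(r_inf$J, r_inf$dist_uncontrolled^2, tolerance = 1e-3)
})

test_that("a controllable linear system is steered to the target: high
           success rate and large terminal-distance reduction", {
  set.seed(3)
  fl <- linear_field(-0.5 * diag(2))
  cfg <- control_config(target = c(2, 2), B = diag(2), u_bound = 10,
                        lambda_energy = 1e-4, steps = 50L)
  Z0 <- matrix(rnorm(20 * 2, sd = 2), 20, 2)
  res <- evaluate_control(fl, Z0, cfg, max_iter = 80L)
  expect_gte(res$success_rate, 0.95)
  expect_gte(res$median_reduction, 0.90)
  # energy accounting: reported integral equals the sum over steps
  r1 <- deterministic_control(fl, Z0[1, ], cfg, max_iter = 40L)
  expect_equal(r1$energy, sum(attr(r1, "controls")^2) * cfg$dt,
               tolerance = 1e-12)
})

test_that("RL environment contract: zero-action episodes match the
           uncontrolled integrator, resets are reproducible, rewards vanish
           at a fixed-point start", {
  A <- -0.5 * diag(4)
  target <- c(1, 1, 0, 0)
  fl <- linear_field(A, b = -drop(A %*% target))   # fixed point at target
  pca <- list(rotation = diag(4), center = rep(0, 4))
  set.seed(4)
  Z0 <- matrix(rnorm(6 * 4, sd = 2), 6, 4)
  cfg <- control_config(target = target, B = diag(4), u_bound = 2,
                        lambda_energy = 1e-3, horizon = 15L)
  env <- rl_environment(fl, cfg, pca, Z0)
  obs1 <- env$reset(2)
  obs2 <- env$reset(2)
  expect_identical(obs1, obs2)

  # u = 0 episode reproduces integrate_field and the reward oracle
  obs <- env$reset(1)
  rewards <- numeric(15)
  for (t in 1:15) {
    sr <- env$step(rep(0, 4))
    rewards[t] <- sr$reward
  }
  unc <- integrate_field(fl, Z0[1, ], 15L, cfg$dt)
  expect_equal(env$state(), unc$endpoint, tolerance = 1e-12)
  oracle <- -vapply(2:16, function(i)
    sum((env$proj(unc$states[i, ]) - env$proj(target))^2), numeric(1))
  expect_equal(rewards, oracle, tolerance = 1e-12)

  # starting at the fixed point with u = 0: rewards stay ~0
  env2 <- rl_environment(fl, cfg, pca, matrix(target, 1))
  env2$reset(1)
  r <- replicate(10, env2$step(rep(0, 4))$reward)
  expect_lt(max(abs(r)), 1e-10)
})

test_that("SAC: an untrained policy is no better than baseline; a trained
           one beats it; the deterministic controller stays ahead", {
  set.seed(11)
  fl <- linear_field(-0.5 * diag(4))
  Z0 <- matrix(rnorm(12 * 4, sd = 2), 12, 4)
  target <- c(1.5, 1.5, 0, 0)
  pca <- list(rotation = diag(4), center = rep(0, 4))
  cfg <- control_config(target = target, B = diag(4), u_bound = 2,
                        lambda_energy = 1e-3, steps = 50L, horizon = 60L)
  env <- rl_environment(fl, cfg, pca, Z0)

  # random (untrained) policy floor
  rnd_actor <- morphoflow:::mlp_new(c(4, 8, 8), seed = 1L)
  rnd_act <- function(obs) {
    out <- morphoflow:::mlp_forward(rnd_actor, matrix(obs, 1))
    tanh(out[, 1:4]) * env$u_bound * 0.1
  }
  ev_rnd <- sac_evaluate(env, rnd_act, n_eval = 8L)
  ev_base <- sac_evaluate(env, NULL, n_eval = 8L)
  expect_gt(mean(ev_rnd$dist_policy), 0.75 * mean(ev_base$dist_uncontrolled))

  pol <- train_sac(env, timesteps = 3500L, seed = 1L, n_eval = 10L)
  ev <- pol$evaluation
  expect_lt(mean(ev$dist_policy), mean(ev$dist_uncontrolled))

  # determinism of the deterministic evaluation path
  ev2 <- sac_evaluate(env, pol$act, n_eval = 10L)
  expect_equal(ev$dist_policy, ev2$dist_policy, tolerance = 1e-12)

  # strict-criterion ordering: deterministic >= SAC
  det <- evaluate_control(fl, Z0[1:8, ], cfg, max_iter = 60L)
  expect_gte(det$success_rate, mean(ev$success))
})
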
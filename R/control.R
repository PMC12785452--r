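# ---------------------------------------------------------------------------
# Latent-space control toward the low-risk basin.
#
# Deterministic: open-loop control sequence optimized by gradient descent
# through the unrolled RK4 integrator (hand-derived adjoint; the MLP's
# vector-Jacobian products come from its backward pass).
# Adaptive: a small soft actor-critic agent on a PCA-compressed observation
# of the latent state (hand-implemented; no RL library exists in this
# stack).
# ---------------------------------------------------------------------------

#' Control configuration
#'
#' @param target target latent state (low-risk attractor centroid).
#' @param B latent x m control-injection matrix; default = top-m principal
#'   directions of the embedding cloud (orthonormal columns).
#' @param m control dimension (used only when `B` is NULL).
#' @param u_bound per-component control bound (default 1).
#' @param lambda_energy energy penalty weight in J (default 1e-3).
#' @param steps horizon for the deterministic controller (default 50).
#' @param horizon RL episode length (default 60).
#' @param dt integrator step (default 0.05).
#' @return list of class `control_config`.
#' @export
control_config <- function(target, B = NULL, m = 8L, u_bound = 1,
                           lambda_energy = 1e-3, steps = 50L, horizon = 60L,
                           dt = 0.05) {
  stopifnot(u_bound > 0, lambda_energy >= 0, all(is.finite(target)))
  if (!is.null(B)) {
    B <- as.matrix(B)
    stopifnot(nrow(B) == length(target))
    m <- ncol(B)
  }
  structure(list(target = target, B = B, m = as.integer(m),
                 u_bound = u_bound, lambda_energy = lambda_energy,
                 steps = as.integer(steps), horizon = as.integer(horizon),
                 dt = dt),
            class = "control_config")
}

#' Default control-injection map from PCA directions
#'
#' @param pca a [pca_diagnostics()] result.
#' @param m number of control directions.
#' @return latent x m matrix with unit-norm columns.
#' @export
control_basis <- function(pca, m = 8L) {
  m <- min(m, ncol(pca$rotation))
  pca$rotation[, seq_len(m), drop = FALSE]
}

#' Control objective J
#'
#' Terminal squared distance to the target plus lambda-weighted control
#' energy (rectangle rule over the integrator step).
#'
#' @param trajectory an `ode_trajectory` (or plain state matrix).
#' @param controls steps x m control matrix.
#' @param target target latent state.
#' @param lambda_energy energy weight.
#' @param dt integrator step used for the energy integral.
#' @return scalar J.
#' @export
objective_J <- function(trajectory, controls, target, lambda_energy,
                        dt = 0.05) {
  states <- if (inherits(trajectory, "ode_trajectory")) trajectory$states
            else as.matrix(trajectory)
  controls <- as.matrix(controls)
  if (nrow(states) != nrow(controls) + 1L)
    stop("objective_J: trajectory and controls are misaligned")
  zT <- states[nrow(states), ]
  sum((zT - target)^2) + lambda_energy * sum(controls^2) * dt
}

# Forward rollout caching the RK4 stage states needed by the adjoint.
rollout_cached <- function(field, z0, U, B, dt) {
  steps <- nrow(U)
  d <- length(z0)
  states <- matrix(0, steps + 1L, d)
  states[1L, ] <- z0
  k_cache <- vector("list", steps)
  z <- z0
  for (t in seq_len(steps)) {
    add_u <- drop(B %*% U[t, ])
    k1 <- field_eval(field, z) + add_u
    k2 <- field_eval(field, z + dt / 2 * k1) + add_u
    k3 <- field_eval(field, z + dt / 2 * k2) + add_u
    k4 <- field_eval(field, z + dt * k3) + add_u
    k_cache[[t]] <- list(z = z, k1 = k1, k2 = k2, k3 = k3)
    z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    states[t + 1L, ] <- z
  }
  list(states = states, k = k_cache)
}

# Exact gradient of J w.r.t. the control sequence via the RK4 adjoint.
control_gradient <- function(field, ro, U, B, target, lambda_energy, dt) {
  steps <- nrow(U)
  dU <- matrix(0, steps, ncol(U))
  a <- 2 * (ro$states[steps + 1L, ] - target)
  for (t in steps:1L) {
    kc <- ro$k[[t]]
    g4 <- (dt / 6) * a
    v4 <- field_vjp(field, kc$z + dt * kc$k3, g4)
    g3 <- (2 * dt / 6) * a + dt * v4
    v3 <- field_vjp(field, kc$z + dt / 2 * kc$k2, g3)
    g2 <- (2 * dt / 6) * a + (dt / 2) * v3
    v2 <- field_vjp(field, kc$z + dt / 2 * kc$k1, g2)
    g1 <- (dt / 6) * a + (dt / 2) * v2
    v1 <- field_vjp(field, kc$z, g1)
    dU[t, ] <- drop(crossprod(B, g1 + g2 + g3 + g4)) +
      2 * lambda_energy * dt * U[t, ]
    a <- a + v1 + v2 + v3 + v4
  }
  dU
}

#' Deterministic energy-penalized control of one trajectory
#'
#' Optimizes an open-loop control sequence by projected gradient descent
#' (backtracking line search, controls clipped to the bound) through the
#' unrolled RK4 integrator. Success means the controlled terminal distance
#' is at most 10% of the uncontrolled terminal distance from the same
#' start; `success_abs` additionally reports the absolute-radius variant
#' (10% of the cohort RMS norm) when `ref_radius` is supplied.
#'
#' @param field vector field.
#' @param z0 start state.
#' @param config a [control_config()] with non-NULL `B`.
#' @param max_iter gradient iterations (default 200).
#' @param ref_radius optional absolute reference scale.
#' @return tibble row: terminal distances (uncontrolled/controlled),
#'   `reduction`, `success`, `success_abs`, `energy`, `J`, `converged`;
#'   attributes `trajectory`, `uncontrolled`, `controls`.
#' @export
deterministic_control <- function(field, z0, config, max_iter = 200L,
                                  ref_radius = NA_real_) {
  stopifnot(inherits(config, "control_config"), !is.null(config$B))
  B <- config$B
  dt <- config$dt
  steps <- config$steps
  lam <- config$lambda_energy
  target <- config$target
  U <- matrix(0, steps, ncol(B))
  unc <- integrate_field(field, z0, steps, dt)
  d_unc <- sqrt(sum((unc$endpoint - target)^2))
  ro <- rollout_cached(field, z0, U, B, dt)
  J <- objective_J(ro$states, U, target, lam, dt)
  lr <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dU <- control_gradient(field, ro, U, B, target, lam, dt)
    gn <- sqrt(sum(dU^2))
    if (gn < 1e-8) {
      converged <- TRUE
      break
    }
    improved <- FALSE
    for (bt in 1:12) {
      U_new <- pmax(pmin(U - lr * dU, config$u_bound), -config$u_bound)
      ro_new <- rollout_cached(field, z0, U_new, B, dt)
      J_new <- objective_J(ro_new$states, U_new, target, lam, dt)
      if (J_new < J - 1e-12) {
        U <- U_new
        ro <- ro_new
        J <- J_new
        lr <- lr * 1.5
        improved <- TRUE
        break
      }
      lr <- lr / 2
    }
    if (!improved) {
      converged <- TRUE
      break
    }
  }
  zT <- ro$states[nrow(ro$states), ]
  d_con <- sqrt(sum((zT - target)^2))
  out <- tibble::tibble(
    dist_uncontrolled = d_unc, dist_controlled = d_con,
    reduction = if (d_unc > 0) 1 - d_con / d_unc else 0,
    success = d_con <= 0.10 * d_unc,
    success_abs = if (is.na(ref_radius)) NA else d_con <= 0.10 * ref_radius,
    energy = sum(U^2) * dt, J = J, converged = converged)
  attr(out, "controls") <- U
  attr(out, "trajectory") <- ro$states
  attr(out, "uncontrolled") <- unc$states
  out
}

#' Run the deterministic controller over a cohort
#'
#' @param field vector field.
#' @param Z start states (matrix, one per row) or embedding table.
#' @param config a [control_config()].
#' @param max_iter per-case gradient iterations.
#' @return list: `per_case` tibble, `success_rate`, `median_reduction`.
#' @export
evaluate_control <- function(field, Z, config, max_iter = 120L) {
  Z <- if (is.matrix(Z)) Z else latent_matrix(Z)
  ref <- sqrt(mean(rowSums(Z^2)))
  rows <- lapply(seq_len(nrow(Z)), function(i)
    deterministic_control(field, Z[i, ], config, max_iter,
                          ref_radius = ref))
  per_case <- dplyr::bind_rows(rows)
  list(per_case = per_case,
       success_rate = mean(per_case$success),
       median_reduction = stats::median(per_case$reduction))
}

#' Episodic latent-control environment
#'
#' Observation = standardized PCA coordinates of the latent state; action =
#' m-dimensional control u (clipped to the bound) injected through B for
#' one RK4 step; reward = negative squared distance to the target in the
#' standardized PCA space minus an energy penalty.
#'
#' @param field vector field.
#' @param config a [control_config()] with non-NULL `B`.
#' @param pca a [pca_diagnostics()] result of the cohort embeddings.
#' @param z0_pool matrix of start states sampled at reset.
#' @param n_obs observed PCA components (default 4).
#' @param c_energy energy penalty weight in the reward (default =
#'   `lambda_energy`).
#' @return environment object (list of closures): `reset(i)`, `step(u)`,
#'   plus dimensions and the projection helpers.
#' @export
rl_environment <- function(field, config, pca, z0_pool, n_obs = 4L,
                           c_energy = NULL) {
  stopifnot(!is.null(config$B))
  if (is.null(c_energy)) c_energy <- config$lambda_energy
  n_obs <- min(n_obs, ncol(pca$rotation))
  rot <- pca$rotation[, seq_len(n_obs), drop = FALSE]
  ctr <- pca$center
  sds <- apply((z0_pool - matrix(ctr, nrow(z0_pool), length(ctr),
                                 byrow = TRUE)) %*% rot, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  proj <- function(z) drop(crossprod(rot, z - ctr)) / sds
  obs_target <- proj(config$target)
  e <- new.env()
  e$z <- NULL
  e$t <- 0L
  env <- list(
    m = ncol(config$B), obs_dim = n_obs, horizon = config$horizon,
    u_bound = config$u_bound, target = config$target, proj = proj,
    reset = function(i) {
      e$z <- z0_pool[((i - 1L) %% nrow(z0_pool)) + 1L, ]
      e$t <- 0L
      proj(e$z)
    },
    step = function(u) {
      u <- pmin(config$u_bound, pmax(-config$u_bound, u))
      e$z <- rk4_step(field, e$z, config$dt, u, config$B)
      e$t <- e$t + 1L
      ob <- proj(e$z)
      r <- -sum((ob - obs_target)^2) - c_energy * sum(u^2)
      list(obs = ob, reward = r, done = e$t >= config$horizon, z = e$z)
    },
    state = function() e$z)
  class(env) <- "latent_control_env"
  env
}

# --- soft actor-critic (desk scale) ----------------------------------------

sac_logp_corr <- function(pre) {
  t_ <- tanh(pre)
  list(t = t_, corr = log(1 - t_^2 + 1e-6), dcorr = 2 * t_ * (1 - t_^2) /
         (1 - t_^2 + 1e-6))
}

#' Train a soft actor-critic controller on a latent environment
#'
#' Minimal off-policy SAC: Gaussian tanh-squashed policy, twin critics
#' with Polyak-averaged targets, fixed entropy temperature. Deliberately
#' desk-scale (small networks, tens of thousands of steps); deterministic
#' under the seed.
#'
#' @param env a [rl_environment()].
#' @param timesteps environment interactions (default 6000).
#' @param hidden hidden widths of actor and critics (default c(32, 32)).
#' @param batch replay batch size.
#' @param lr Adam learning rate.
#' @param gamma discount (default 0.995).
#' @param alpha entropy temperature (fixed, default 0.1).
#' @param tau Polyak rate for target critics.
#' @param start_steps uniform-random warmup actions.
#' @param n_eval deterministic evaluation episodes.
#' @param seed RNG seed.
#' @return list of class `sac_policy`: `actor`, `evaluation` tibble
#'   (mean terminal distance controlled vs uncontrolled, success rate),
#'   `act` closure (deterministic policy).
#' @export
train_sac <- function(env, timesteps = 6000L, hidden = c(32L, 32L),
                      batch = 64L, lr = 3e-4, gamma = 0.995, alpha = 0.1,
                      tau = 0.01, start_steps = 500L, n_eval = 20L,
                      seed = 42L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  m <- env$m
  od <- env$obs_dim
  actor <- mlp_new(c(od, hidden, 2L * m), hidden_act = "relu", seed = seed)
  q1 <- mlp_new(c(od + m, hidden, 1L), hidden_act = "relu", seed = seed + 1L)
  q2 <- mlp_new(c(od + m, hidden, 1L), hidden_act = "relu", seed = seed + 2L)
  q1t <- q1
  q2t <- q2
  opt_a <- adam_new(mlp_params(actor))
  opt_1 <- adam_new(mlp_params(q1))
  opt_2 <- adam_new(mlp_params(q2))

  cap <- timesteps
  buf <- list(obs = matrix(0, cap, od), act = matrix(0, cap, m),
              rew = numeric(cap), nxt = matrix(0, cap, od),
              done = numeric(cap))
  n_buf <- 0L
  ptr <- 0L

  policy_sample <- function(obs_mat, deterministic = FALSE) {
    out <- mlp_forward(actor, obs_mat)
    mu <- out[, seq_len(m), drop = FALSE]
    logstd <- pmin(2, pmax(-5, out[, m + seq_len(m), drop = FALSE]))
    if (deterministic) {
      pre <- mu
      eps <- mu * 0
    } else {
      eps <- matrix(stats::rnorm(length(mu)), nrow(mu))
      pre <- mu + exp(logstd) * eps
    }
    lc <- sac_logp_corr(pre)
    logp <- rowSums(-0.5 * eps^2 - logstd - 0.5 * log(2 * pi) - lc$corr)
    list(a = lc$t, pre = pre, mu = mu, logstd = logstd, eps = eps,
         logp = logp)
  }

  update <- function() {
    idx <- sample.int(n_buf, min(batch, n_buf))
    ob <- buf$obs[idx, , drop = FALSE]
    ac <- buf$act[idx, , drop = FALSE]
    re <- buf$rew[idx]
    nx <- buf$nxt[idx, , drop = FALSE]
    dn <- buf$done[idx]
    # critic targets
    ps <- policy_sample(nx)
    qin_t <- cbind(nx, ps$a)
    qt <- pmin(mlp_forward(q1t, qin_t)[, 1], mlp_forward(q2t, qin_t)[, 1])
    y <- re + gamma * (1 - dn) * (qt - alpha * ps$logp)
    qin <- cbind(ob, ac)
    for (critic in 1:2) {
      net <- if (critic == 1) q1 else q2
      fw <- mlp_forward(net, qin, cache = TRUE)
      resid <- fw$out[, 1] - y
      g <- mlp_backward(net, fw, matrix(2 * resid / length(resid), ncol = 1))
      st <- adam_step(if (critic == 1) opt_1 else opt_2, mlp_params(net),
                      c(g$dW, g$db), lr)
      if (critic == 1) {
        opt_1 <<- st$opt
        q1 <<- mlp_set_params(q1, st$params)
      } else {
        opt_2 <<- st$opt
        q2 <<- mlp_set_params(q2, st$params)
      }
    }
    # actor update (reparameterized, through min critic)
    fa <- mlp_forward(actor, ob, cache = TRUE)
    mu <- fa$out[, seq_len(m), drop = FALSE]
    logstd_raw <- fa$out[, m + seq_len(m), drop = FALSE]
    logstd <- pmin(2, pmax(-5, logstd_raw))
    clip_mask <- (logstd_raw > -5 & logstd_raw < 2) * 1
    sigma <- exp(logstd)
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu))
    pre <- mu + sigma * eps
    lc <- sac_logp_corr(pre)
    a_new <- lc$t
    qin_a <- cbind(ob, a_new)
    f1 <- mlp_forward(q1, qin_a, cache = TRUE)
    f2 <- mlp_forward(q2, qin_a, cache = TRUE)
    use1 <- f1$out[, 1] <= f2$out[, 1]
    nb <- nrow(ob)
    dQ_da <- matrix(0, nb, m)
    sel <- matrix(0, nb, 1)
    sel[use1, 1] <- -1 / nb          # d(-mean minQ)/dQ1
    b1 <- mlp_backward(q1, f1, sel)
    dQ_da[use1, ] <- b1$dX[use1, od + seq_len(m), drop = FALSE]
    sel2 <- matrix(0, nb, 1)
    sel2[!use1, 1] <- -1 / nb
    b2 <- mlp_backward(q2, f2, sel2)
    dQ_da[!use1, ] <- b2$dX[!use1, od + seq_len(m), drop = FALSE]
    dtanh <- 1 - a_new^2
    # d/dpre of (alpha/nb)*logp + (-1/nb)*minQ via action
    dpre <- (alpha / nb) * lc$dcorr + dQ_da * dtanh
    dmu <- dpre
    dlogstd <- dpre * sigma * eps + (alpha / nb) * (-1) * clip_mask
    dOut <- cbind(dmu, dlogstd * clip_mask)
    ga <- mlp_backward(actor, fa, dOut)
    st <- adam_step(opt_a, mlp_params(actor), c(ga$dW, ga$db), lr)
    opt_a <<- st$opt
    actor <<- mlp_set_params(actor, st$params)
    # Polyak targets
    p1 <- mlp_params(q1)
    pt1 <- mlp_params(q1t)
    q1t <<- mlp_set_params(q1t, Map(function(p, pt) tau * p + (1 - tau) * pt,
                                    p1, pt1))
    p2 <- mlp_params(q2)
    pt2 <- mlp_params(q2t)
    q2t <<- mlp_set_params(q2t, Map(function(p, pt) tau * p + (1 - tau) * pt,
                                    p2, pt2))
  }

  ep <- 1L
  obs <- env$reset(ep)
  for (t in seq_len(timesteps)) {
    if (t <= start_steps) {
      a_unit <- stats::runif(m, -1, 1)
    } else {
      a_unit <- drop(policy_sample(matrix(obs, 1))$a)
    }
    sr <- env$step(a_unit * env$u_bound)
    ptr <- (ptr %% cap) + 1L
    buf$obs[ptr, ] <- obs
    buf$act[ptr, ] <- a_unit
    buf$rew[ptr] <- sr$reward
    buf$nxt[ptr, ] <- sr$obs
    buf$done[ptr] <- 0           # horizon end is a timeout, not terminal
    n_buf <- min(n_buf + 1L, cap)
    obs <- sr$obs
    if (sr$done) {
      ep <- ep + 1L
      obs <- env$reset(ep)
    }
    if (t > start_steps && n_buf >= batch) update()
    if (!all(is.finite(mlp_params(actor)[[1]])))
      stop("train_sac: NaN in actor parameters at step ", t)
  }

  act_det <- function(obs_vec) {
    drop(policy_sample(matrix(obs_vec, 1), deterministic = TRUE)$a) *
      env$u_bound
  }
  evaluation <- sac_evaluate(env, act_det, n_eval)
  structure(list(actor = actor, act = act_det, evaluation = evaluation,
                 timesteps = timesteps, alpha = alpha, gamma = gamma),
            class = "sac_policy")
}

#' Evaluate a policy (or the zero policy) on deterministic episodes
#'
#' @param env a [rl_environment()].
#' @param act function obs -> action; NULL evaluates u = 0.
#' @param n_eval episodes (reset indices 1..n_eval).
#' @return tibble: per-episode terminal distances for the policy and the
#'   uncontrolled flow, with success flags under the strict 10% criterion.
#' @export
sac_evaluate <- function(env, act, n_eval = 20L) {
  rows <- lapply(seq_len(n_eval), function(i) {
    obs <- env$reset(i)
    z0 <- env$state()
    for (t in seq_len(env$horizon)) {
      u <- if (is.null(act)) rep(0, env$m) else act(obs)
      sr <- env$step(u)
      obs <- sr$obs
    }
    d_pol <- sqrt(sum((env$state() - env$target)^2))
    obs <- env$reset(i)
    for (t in seq_len(env$horizon)) sr <- env$step(rep(0, env$m))
    d_unc <- sqrt(sum((env$state() - env$target)^2))
    tibble::tibble(episode = i, dist_policy = d_pol, dist_uncontrolled = d_unc,
                   success = d_pol <= 0.10 * d_unc)
  })
  dplyr::bind_rows(rows)
}
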
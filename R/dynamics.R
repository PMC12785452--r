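# ---------------------------------------------------------------------------
# Latent dynamics: k-NN tangent supervision, an MLP vector field trained on
# edge displacements, RK4 integration, divergence and Lyapunov diagnostics,
# and dynamic-attractor endpoint clustering. The learned flow encodes
# cross-sectional manifold geometry, not observed temporal evolution.
# ---------------------------------------------------------------------------

#' Linear test field dz/dt = A z + b
#'
#' Analytic field used for oracle checks of the integrator, divergence and
#' Lyapunov estimators, and as a controllable toy system.
#'
#' @param A square matrix.
#' @param b offset vector (default 0).
#' @return object of class `linear_field`.
#' @export
linear_field <- function(A, b = NULL) {
  A <- as.matrix(A)
  if (is.null(b)) b <- rep(0, nrow(A))
  structure(list(A = A, b = b, d = nrow(A)), class = "linear_field")
}

#' Evaluate a vector field
#'
#' @param field an `ode_field`, `linear_field`, or plain function
#'   mapping a state vector to its derivative.
#' @param z state vector, or matrix with one state per row.
#' @return derivative(s), same shape as `z`.
#' @export
field_eval <- function(field, z) {
  if (inherits(field, "ode_field")) {
    out <- mlp_forward(field$net, if (is.matrix(z)) z else matrix(z, 1))
    return(if (is.matrix(z)) out else drop(out))
  }
  if (inherits(field, "linear_field")) {
    if (is.matrix(z)) return(t(field$A %*% t(z) + field$b))
    return(drop(field$A %*% z + field$b))
  }
  if (is.function(field)) {
    if (is.matrix(z)) return(t(apply(z, 1, field)))
    return(field(z))
  }
  stop("field_eval: unsupported field type")
}

# Vector-Jacobian product v^T J_f(z); numeric fallback for plain functions.
field_vjp <- function(field, z, v) {
  if (inherits(field, "ode_field")) return(mlp_vjp(field$net, z, v))
  if (inherits(field, "linear_field")) return(drop(crossprod(field$A, v)))
  h <- 1e-6
  vapply(seq_along(z), function(i) {
    e <- z
    e[i] <- e[i] + h
    e2 <- z
    e2[i] <- e2[i] - h
    sum(v * (field(e) - field(e2))) / (2 * h)
  }, numeric(1))
}

#' Build the k-NN tangent-supervision dataset
#'
#' Every case contributes its `k` nearest neighbours (Euclidean, ties
#' broken by index); each directed edge i -> j yields a training pair
#' (z_i, z_j - z_i). Cross-sectional edges carry no intrinsic arrow, so the
#' field learns a local average of outgoing displacements.
#'
#' @param tbl embedding table or latent matrix.
#' @param k neighbours per node (default 8).
#' @return object of class `tangent_dataset`: `X` (n*k x d anchors),
#'   `Y` (n*k x d displacements), `edges` (from, to), `k`.
#' @export
build_tangent_dataset <- function(tbl, k = 8L) {
  Z <- if (is.matrix(tbl)) tbl else latent_matrix(tbl)
  n <- nrow(Z)
  if (n <= k) stop("build_tangent_dataset: need more cases than k")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    from <- c(from, rep(i, k))
    to <- c(to, nb)
  }
  structure(list(X = Z[from, , drop = FALSE],
                 Y = Z[to, , drop = FALSE] - Z[from, , drop = FALSE],
                 edges = tibble::tibble(from = from, to = to),
                 k = as.integer(k), n = n),
            class = "tangent_dataset")
}

#' Train the latent vector field
#'
#' MLP (tanh hidden layers, default widths 256 and 128) fit by Adam to
#' minimize the MSE between predicted and empirical k-NN displacements.
#'
#' @param dataset a [build_tangent_dataset()] result (or any list with
#'   matrices `X`, `Y`).
#' @param hidden hidden layer widths.
#' @param epochs training epochs (default 60).
#' @param lr learning rate (default 1e-3).
#' @param batch mini-batch size.
#' @param seed RNG seed (init + batching); runs are bit-reproducible.
#' @return object of class `ode_field` with the fitted `net` and
#'   `history` (per-epoch MSE).
#' @export
train_field <- function(dataset, hidden = c(256L, 128L), epochs = 60L,
                        lr = 1e-3, batch = 32L, seed = 42L) {
  stopifnot(nrow(dataset$X) > 0, all(dim(dataset$X) == dim(dataset$Y)))
  d <- ncol(dataset$X)
  net <- mlp_new(c(d, hidden, d), hidden_act = "tanh", seed = seed)
  net <- mlp_train(net, dataset$X, dataset$Y, epochs = epochs, lr = lr,
                   batch = batch, seed = seed + 1L, lr_schedule = "linear")
  structure(list(net = net, d = d, history = net$history),
            class = "ode_field")
}

rk4_step <- function(field, z, dt, u_vec = NULL, B = NULL) {
  add_u <- if (!is.null(u_vec) && !is.null(B)) drop(B %*% u_vec) else 0
  k1 <- field_eval(field, z) + add_u
  k2 <- field_eval(field, z + dt / 2 * k1) + add_u
  k3 <- field_eval(field, z + dt / 2 * k2) + add_u
  k4 <- field_eval(field, z + dt * k3) + add_u
  z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Integrate a latent trajectory (classical RK4)
#'
#' With a control sequence the integrated field is `f(z) + B u_t`
#' (u held constant within each step). Integration stops early (flagged)
#' if the state leaves the finite range.
#'
#' @param field vector field (see [field_eval()]).
#' @param z0 initial state.
#' @param steps number of RK4 steps.
#' @param dt step size (default 0.05).
#' @param control optional `steps x m` matrix of controls.
#' @param B latent x m control-injection matrix (required with `control`).
#' @return object of class `ode_trajectory`: `states`
#'   ((steps+1) x d matrix), `dt`, `completed`, `endpoint`.
#' @export
integrate_field <- function(field, z0, steps, dt = 0.05, control = NULL,
                            B = NULL) {
  stopifnot(all(is.finite(z0)), steps >= 1)
  if (!is.null(control)) {
    control <- as.matrix(control)
    stopifnot(!is.null(B), nrow(control) == steps)
  }
  d <- length(z0)
  states <- matrix(NA_real_, steps + 1L, d)
  states[1L, ] <- z0
  z <- z0
  completed <- TRUE
  for (t in seq_len(steps)) {
    u_vec <- if (!is.null(control)) control[t, ] else NULL
    z <- rk4_step(field, z, dt, u_vec, B)
    if (any(!is.finite(z))) {
      completed <- FALSE
      states <- states[seq_len(t), , drop = FALSE]
      warning("integrate_field: non-finite state at step ", t,
              "; returning partial trajectory")
      break
    }
    states[t + 1L, ] <- z
  }
  structure(list(states = states, dt = dt, completed = completed,
                 endpoint = states[nrow(states), ]),
            class = "ode_trajectory")
}

#' Divergence of the projected field on a 2-D PCA grid
#'
#' Grid points (a, b) are lifted to latent space through the first two
#' principal axes, the field is evaluated and projected back, and the
#' divergence of the resulting planar field is taken by central finite
#' differences. Negative regions are flow sinks.
#'
#' @param field vector field.
#' @param pca result of [pca_diagnostics()] (used for center/rotation),
#'   or a list with `center` and `rotation`.
#' @param a_range,b_range grid extents in PC1/PC2 coordinates.
#' @param n_grid grid resolution per axis (default 25).
#' @return tibble: `a`, `b`, `divergence`.
#' @export
divergence_map <- function(field, pca, a_range, b_range, n_grid = 25L) {
  v1 <- pca$rotation[, 1]
  v2 <- pca$rotation[, 2]
  ctr <- pca$center
  a_seq <- seq(a_range[1], a_range[2], length.out = n_grid)
  b_seq <- seq(b_range[1], b_range[2], length.out = n_grid)
  ha <- a_seq[2] - a_seq[1]
  hb <- b_seq[2] - b_seq[1]
  lift <- function(a, b) ctr + a * v1 + b * v2
  F1 <- function(a, b) sum(v1 * field_eval(field, lift(a, b)))
  F2 <- function(a, b) sum(v2 * field_eval(field, lift(a, b)))
  out <- expand.grid(a = a_seq, b = b_seq)
  out$divergence <- vapply(seq_len(nrow(out)), function(i) {
    a <- out$a[i]
    b <- out$b[i]
    (F1(a + ha, b) - F1(a - ha, b)) / (2 * ha) +
      (F2(a, b + hb) - F2(a, b - hb)) / (2 * hb)
  }, numeric(1))
  tibble::as_tibble(out)
}

#' Largest Lyapunov exponent by paired-trajectory evolution
#'
#' Evolves each start point together with a companion displaced by
#' `separation`; the pair distance is renormalized back to `separation`
#' every `renorm_every` steps and the exponent is the time average of
#' `log(d_after / separation)`.
#'
#' @param field vector field.
#' @param z0s matrix of start states (one per row) or single vector.
#' @param separation initial pair separation (default 1e-4).
#' @param steps total integration steps (default 200).
#' @param dt RK4 step (default 0.05).
#' @param renorm_every renormalization interval in steps (default 10).
#' @param seed RNG seed for the displacement directions.
#' @return tibble: `lambda` (mean), `lambda_sd`, `n_starts`.
#' @export
lyapunov <- function(field, z0s, separation = 1e-4, steps = 200L, dt = 0.05,
                     renorm_every = 10L, seed = 42L) {
  if (separation <= 0) stop("lyapunov: separation must be > 0")
  if (!is.matrix(z0s)) z0s <- matrix(z0s, nrow = 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lams <- vapply(seq_len(nrow(z0s)), function(i) {
    za <- z0s[i, ]
    dir <- stats::rnorm(length(za))
    zb <- za + separation * dir / sqrt(sum(dir^2))
    log_sum <- 0
    n_ren <- 0L
    for (t in seq_len(steps)) {
      za <- rk4_step(field, za, dt)
      zb <- rk4_step(field, zb, dt)
      if (t %% renorm_every == 0L) {
        d_after <- sqrt(sum((za - zb)^2))
        if (d_after == 0) return(-Inf)
        log_sum <- log_sum + log(d_after / separation)
        zb <- za + separation * (zb - za) / d_after
        n_ren <- n_ren + 1L
      }
    }
    log_sum / (n_ren * renorm_every * dt)
  }, numeric(1))
  tibble::tibble(lambda = mean(lams), lambda_sd = stats::sd(lams),
                 n_starts = nrow(z0s))
}

#' Dynamic attractors from long-term integration
#'
#' Integrates every case embedding for `steps` RK4 steps; a case counts as
#' converged when its trailing-window state variance, normalized by the
#' cohort embedding variance, falls below `var_threshold`. Endpoints are
#' clustered with K-means into dynamic attractor labels.
#'
#' @param field trained vector field.
#' @param tbl embedding table or latent matrix.
#' @param steps integration steps (default 200).
#' @param dt RK4 step (default 0.05).
#' @param K endpoint clusters (default 3).
#' @param window trailing window for the convergence criterion (default 20).
#' @param var_threshold normalized-variance convergence cutoff
#'   (default 0.05).
#' @param seed RNG seed for the endpoint K-means.
#' @return object of class `dynamic_attractors`: `endpoints`, `labels`
#'   (0-based), `converged` (logical), `convergence_fraction`,
#'   `endpoint_variance` (per-case normalized trailing variance),
#'   `trajectories`.
#' @export
dynamic_attractors <- function(field, tbl, steps = 200L, dt = 0.05, K = 3L,
                               window = 20L, var_threshold = 0.05,
                               seed = 42L) {
  Z <- if (is.matrix(tbl)) tbl else latent_matrix(tbl)
  n <- nrow(Z)
  cohort_var <- mean(apply(Z, 2, stats::var))
  if (cohort_var == 0) cohort_var <- 1
  trajs <- lapply(seq_len(n), function(i)
    integrate_field(field, Z[i, ], steps, dt))
  ok <- vapply(trajs, `[[`, logical(1), "completed")
  if (!any(ok))
    stop("dynamic_attractors: all trajectories diverged")
  endpoints <- do.call(rbind, lapply(trajs, `[[`, "endpoint"))
  norm_var <- vapply(trajs, function(tr) {
    st <- tr$states
    w <- min(window, nrow(st))
    tail_states <- st[(nrow(st) - w + 1L):nrow(st), , drop = FALSE]
    mean(apply(tail_states, 2, stats::var)) / cohort_var
  }, numeric(1))
  converged <- ok & norm_var < var_threshold
  km <- km_fit(endpoints[ok, , drop = FALSE], K, seed)
  labels <- rep(NA_integer_, n)
  labels[ok] <- as.integer(km$cluster) - 1L
  structure(list(endpoints = endpoints, labels = labels,
                 converged = converged,
                 convergence_fraction = mean(converged),
                 endpoint_variance = norm_var,
                 centroids = km$centers, K = as.integer(K),
                 trajectories = trajs),
            class = "dynamic_attractors")
}
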
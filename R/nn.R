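#' @useDynLib morphoflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal dense neural-network toolkit (manual backprop + Adam).
# Shared by the autoencoder heads, the neural-ODE vector field and the SAC
# agent.  Everything is plain matrices: X is n_samples x n_features.
# ---------------------------------------------------------------------------

nn_act <- function(z, act) {
  switch(act,
    relu = pmax(z, 0),
    tanh = tanh(z),
    sigmoid = 1 / (1 + exp(-z)),
    identity = z,
    stop("unknown activation: ", act)
  )
}

nn_act_grad <- function(z, a, act) {
  switch(act,
    relu = (z > 0) * 1,
    tanh = 1 - a^2,
    sigmoid = a * (1 - a),
    identity = array(1, dim = dim(z)),
    stop("unknown activation: ", act)
  )
}

#' Create a fully connected network
#'
#' He-initialised multilayer perceptron used internally for the latent
#' vector field and the actor/critic heads of the SAC controller.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param hidden_act activation of hidden layers (`"relu"` or `"tanh"`).
#' @param out_act activation of the output layer.
#' @param seed RNG seed for the weight draw.
#' @return an object of class `mlp`.
#' @keywords internal
mlp_new <- function(sizes, hidden_act = "tanh", out_act = "identity",
                    seed = 42L) {
  stopifnot(length(sizes) >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    sd_l <- sqrt(2 / sizes[l])
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd_l),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  structure(list(W = W, b = b, sizes = sizes, hidden_act = hidden_act,
                 out_act = out_act), class = "mlp")
}

# Save/restore global RNG so internal seeding never disturbs the caller.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

mlp_forward <- function(net, X, cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  L <- length(net$W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    act <- if (l < L) net$hidden_act else net$out_act
    A[[l + 1]] <- nn_act(Z[[l]], act)
  }
  if (cache) list(out = A[[L + 1]], A = A, Z = Z) else A[[L + 1]]
}

# Returns gradients w.r.t. parameters and the input (vector-Jacobian product).
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  d <- dOut
  for (l in rev(seq_len(L))) {
    act <- if (l < L) net$hidden_act else net$out_act
    d <- d * nn_act_grad(fw$Z[[l]], fw$A[[l + 1]], act)
    dW[[l]] <- crossprod(fw$A[[l]], d)
    db[[l]] <- colSums(d)
    d <- d %*% t(net$W[[l]])
  }
  list(dW = dW, db = db, dX = d)
}

# Vector-Jacobian product v^T J_f(x) for a single input row.
mlp_vjp <- function(net, x, v) {
  fw <- mlp_forward(net, matrix(x, nrow = 1), cache = TRUE)
  drop(mlp_backward(net, fw, matrix(v, nrow = 1))$dX)
}

# --- Adam ------------------------------------------------------------------

adam_new <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (i in seq_along(params)) {
    opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * grads[[i]]
    opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (opt$m[[i]] / c1) / (sqrt(opt$v[[i]] / c2) + eps)
  }
  list(opt = opt, params = params)
}

# Flatten/unflatten helpers so one Adam state covers a whole network.
mlp_params <- function(net) c(net$W, net$b)

mlp_set_params <- function(net, params) {
  L <- length(net$W)
  net$W <- params[seq_len(L)]
  net$b <- params[L + seq_len(L)]
  net
}

#' Fit an MLP by mini-batch Adam on a squared-error objective
#' @keywords internal
mlp_train <- function(net, X, Y, epochs = 60L, lr = 1e-3, batch = 32L,
                      seed = 42L, lr_schedule = c("constant", "linear"),
                      verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(nrow(X) == nrow(Y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(X)
  opt <- adam_new(mlp_params(net))
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- if (lr_schedule == "linear") lr * (1 - (ep - 1) / epochs) else lr
    idx <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch)) {
      rows <- idx[start:min(start + batch - 1L, n)]
      fw <- mlp_forward(net, X[rows, , drop = FALSE], cache = TRUE)
      resid <- fw$out - Y[rows, , drop = FALSE]
      loss <- mean(resid^2)
      g <- mlp_backward(net, fw, 2 * resid / length(resid))
      step <- adam_step(opt, mlp_params(net), c(g$dW, g$db), lr_ep)
      opt <- step$opt
      net <- mlp_set_params(net, step$params)
      ep_loss <- ep_loss + loss
      nb <- nb + 1L
    }
    history[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d  mse %.5f", ep, history[ep]))
    if (!is.finite(history[ep])) stop("mlp_train: loss diverged")
  }
  net$history <- history
  net
}
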
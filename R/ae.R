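# ---------------------------------------------------------------------------
# 3-D convolutional autoencoder.
#
# Encoder: four Conv3D blocks (kernel 3, stride 2, pad 1), each followed by
# per-channel normalization and ReLU; global mean pooling; FC to the latent.
# Decoder: FC, then four ConvTranspose3D blocks (kernel 4, stride 2, pad 1,
# exact doubling), sigmoid output so reconstructions live in [0, 1].
# Objective: L1. All forward/backward passes are hand-written on top of the
# Rcpp vol2col/col2vol kernels; training is mini-batch Adam with early
# stopping on validation loss.
# ---------------------------------------------------------------------------

#' Autoencoder configuration
#'
#' @param channels channel progression of the four encoder blocks.
#' @param latent_dim latent dimensionality.
#' @param patch cubic patch edge (must be divisible by 16).
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param max_epochs,patience early-stopping schedule.
#' @param seed global seed for weight init and batching.
#' @param augment_flips random axis flips during training.
#' @return list of class `ae_config`.
#' @export
ae_config <- function(channels = c(32L, 64L, 128L, 256L), latent_dim = 128L,
                      patch = 64L, lr = 1e-3, batch = 2L, max_epochs = 150L,
                      patience = 15L, seed = 42L, augment_flips = TRUE) {
  stopifnot(length(channels) == 4, latent_dim > 0, patch %% 16 == 0,
            patience < max_epochs)
  structure(list(channels = as.integer(channels),
                 latent_dim = as.integer(latent_dim),
                 patch = as.integer(patch), lr = lr, batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 augment_flips = isTRUE(augment_flips)),
            class = "ae_config")
}

#' Desk-scale configuration for CPU tests
#' @param ... overrides passed to [ae_config()].
#' @export
ae_config_tiny <- function(...) {
  args <- utils::modifyList(list(channels = c(8L, 16L, 32L, 64L),
                                 latent_dim = 16L, patch = 16L,
                                 max_epochs = 8L, patience = 3L), list(...))
  do.call(ae_config, args)
}

#' Initialise an untrained autoencoder
#'
#' @param config an [ae_config()].
#' @param channels_in number of input channels (4, or 5 with the optional
#'   train-only segmentation channel).
#' @return object of class `ae_model`.
#' @export
ae_new <- function(config, channels_in = 4L) {
  stopifnot(inherits(config, "ae_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  ch <- c(channels_in, config$channels)
  s0 <- config$patch / 16L
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nc)),
                                nr, nc)
  par <- list()
  bn <- list()
  for (l in 1:4) {
    par[[paste0("enc_W", l)]] <- he(ch[l + 1], ch[l] * 27)
    par[[paste0("enc_b", l)]] <- rep(0, ch[l + 1])
    par[[paste0("enc_g", l)]] <- rep(1, ch[l + 1])
    par[[paste0("enc_a", l)]] <- rep(0, ch[l + 1])
    bn[[paste0("enc", l)]] <- list(mean = rep(0, ch[l + 1]),
                                   var = rep(1, ch[l + 1]))
  }
  par$fce_W <- he(config$latent_dim, ch[5])
  par$fce_b <- rep(0, config$latent_dim)
  par$fcd_W <- he(ch[5] * s0^3, config$latent_dim)
  par$fcd_b <- rep(0, ch[5] * s0^3)
  dch <- c(rev(config$channels), channels_in)   # c4, c3, c2, c1, C_in
  for (l in 1:4) {
    par[[paste0("dec_W", l)]] <- matrix(
      stats::rnorm(dch[l] * dch[l + 1] * 64, sd = sqrt(2 / (dch[l] * 64))),
      dch[l], dch[l + 1] * 64)
    par[[paste0("dec_b", l)]] <- rep(0, dch[l + 1])
    if (l < 4) {
      par[[paste0("dec_g", l)]] <- rep(1, dch[l + 1])
      par[[paste0("dec_a", l)]] <- rep(0, dch[l + 1])
      bn[[paste0("dec", l)]] <- list(mean = rep(0, dch[l + 1]),
                                     var = rep(1, dch[l + 1]))
    }
  }
  structure(list(cfg = config, channels_in = as.integer(channels_in),
                 par = par, bn = bn, trained = FALSE),
            class = "ae_model")
}

# --- normalization layer ---------------------------------------------------

.bn_eps <- 1e-5

# Per-channel normalization over spatial positions. With a single spatial
# position (innermost block of very small patches) batch moments are
# degenerate, so the layer freezes to the running statistics instead.
bn_fw <- function(x, g, a, stats_ln, train, momentum = 0.9) {
  frozen <- !train || ncol(x) < 2L
  if (!frozen) {
    mu <- rowMeans(x)
    v <- rowMeans(x^2) - mu^2
    stats_ln$mean <- momentum * stats_ln$mean + (1 - momentum) * mu
    stats_ln$var <- momentum * stats_ln$var + (1 - momentum) * v
  } else {
    mu <- stats_ln$mean
    v <- stats_ln$var
  }
  ivar <- 1 / sqrt(v + .bn_eps)
  xhat <- (x - mu) * ivar
  list(out = g * xhat + a, xhat = xhat, ivar = ivar, frozen = frozen,
       stats = stats_ln)
}

bn_bw <- function(dY, g, cache) {
  N <- ncol(dY)
  dg <- rowSums(dY * cache$xhat)
  da <- rowSums(dY)
  dxhat <- dY * g
  if (cache$frozen) return(list(dx = dxhat * cache$ivar, dg = dg, da = da))
  dx <- (cache$ivar / N) *
    (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dx = dx, dg = dg, da = da)
}

# --- forward passes --------------------------------------------------------

as_cmat <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(x, nrow = d[1])
}

ae_encode_fw <- function(model, x, train = FALSE, cache = FALSE) {
  p <- model$par
  S <- model$cfg$patch
  xm <- as_cmat(x)
  cc <- list(x = list(), cols = list(), bn = list(), mask = list())
  for (l in 1:4) {
    cc$x[[l]] <- xm
    cols <- vol2col_cpp(xm, S, 3L, 2L, 1L)
    pre <- p[[paste0("enc_W", l)]] %*% cols + p[[paste0("enc_b", l)]]
    b <- bn_fw(pre, p[[paste0("enc_g", l)]], p[[paste0("enc_a", l)]],
               model$bn[[paste0("enc", l)]], train)
    if (train) model$bn[[paste0("enc", l)]] <- b$stats
    xm <- pmax(b$out, 0)
    if (cache) {
      cc$cols[[l]] <- cols
      cc$bn[[l]] <- b
      cc$mask[[l]] <- b$out > 0
    }
    S <- S / 2L
  }
  pool <- rowMeans(xm)
  z <- drop(p$fce_W %*% pool + p$fce_b)
  list(z = z, pool = pool, npool = ncol(xm), cache = cc, model = model)
}

ae_decode_fw <- function(model, z, train = FALSE, cache = FALSE) {
  p <- model$par
  cfg <- model$cfg
  s0 <- cfg$patch / 16L
  c4 <- cfg$channels[4]
  h <- drop(p$fcd_W %*% z + p$fcd_b)
  hr <- pmax(h, 0)
  xm <- matrix(hr, c4, s0^3)
  S <- s0
  cc <- list(h = h, x = list(), bn = list(), mask = list())
  for (l in 1:4) {
    cc$x[[l]] <- xm
    S_out <- 2L * S
    tmp <- crossprod(p[[paste0("dec_W", l)]], xm)
    y <- col2vol_cpp(tmp, ncol(p[[paste0("dec_W", l)]]) / 64L, S_out, 4L, 2L,
                     1L)
    y <- y + p[[paste0("dec_b", l)]]
    if (l < 4) {
      b <- bn_fw(y, p[[paste0("dec_g", l)]], p[[paste0("dec_a", l)]],
                 model$bn[[paste0("dec", l)]], train)
      if (train) model$bn[[paste0("dec", l)]] <- b$stats
      xm <- pmax(b$out, 0)
      if (cache) {
        cc$bn[[l]] <- b
        cc$mask[[l]] <- b$out > 0
      }
    } else {
      xm <- 1 / (1 + exp(-y))
      if (cache) cc$sig <- xm
    }
    S <- S_out
  }
  list(xhat = xm, S = S, cache = cc, model = model)
}

#' Encode a patch to its latent vector / decode a latent vector
#'
#' `ae_encode` maps a `C x patch^3` tensor to a `latent_dim` vector;
#' `ae_decode` is the mirror map. Both run in eval mode (running
#' normalization statistics) and are deterministic for fixed weights.
#'
#' @param model an `ae_model`.
#' @param x patch tensor, array `c(C, S, S, S)` or `C x S^3` matrix.
#' @param z latent vector.
#' @return `ae_encode`: numeric vector; `ae_decode`: array `c(C, S, S, S)`.
#' @export
ae_encode <- function(model, x) {
  stopifnot(inherits(model, "ae_model"))
  d <- if (is.matrix(x)) c(nrow(x), rep(round(ncol(x)^(1 / 3)), 3)) else dim(x)
  if (d[1] != model$channels_in || d[2] != model$cfg$patch)
    stop("ae_encode: expected ", model$channels_in, " x ", model$cfg$patch,
         "^3 input")
  ae_encode_fw(model, x)$z
}

#' @rdname ae_encode
#' @export
ae_decode <- function(model, z) {
  stopifnot(inherits(model, "ae_model"),
            length(z) == model$cfg$latent_dim)
  fw <- ae_decode_fw(model, z)
  S <- model$cfg$patch
  array(fw$xhat, dim = c(model$channels_in, S, S, S))
}

#' L1 reconstruction objective
#'
#' Mean absolute difference between a patch and its reconstruction.
#'
#' @param x,xhat equally shaped numeric arrays.
#' @return non-negative scalar, zero iff identical.
#' @export
ae_loss <- function(x, xhat) {
  if (!identical(dim(x) %||% length(x), dim(xhat) %||% length(xhat)))
    stop("ae_loss: shape mismatch")
  mean(abs(x - xhat))
}

# --- full backward pass ----------------------------------------------------

ae_backprop <- function(model, x, train = TRUE) {
  p <- model$par
  cfg <- model$cfg
  xm <- as_cmat(x)
  enc <- ae_encode_fw(model, xm, train = train, cache = TRUE)
  model <- enc$model
  dec <- ae_decode_fw(model, enc$z, train = train, cache = TRUE)
  model <- dec$model
  xhat <- dec$xhat
  n_tot <- length(xm)
  loss <- mean(abs(xm - xhat))
  g <- list()

  # decoder backward
  d <- sign(xhat - xm) / n_tot
  d <- d * xhat * (1 - xhat)                       # sigmoid
  S <- cfg$patch
  for (l in 4:1) {
    if (l < 4) {
      d <- d * dec$cache$mask[[l]]
      bb <- bn_bw(d, p[[paste0("dec_g", l)]], dec$cache$bn[[l]])
      g[[paste0("dec_g", l)]] <- bb$dg
      g[[paste0("dec_a", l)]] <- bb$da
      d <- bb$dx
    }
    g[[paste0("dec_b", l)]] <- rowSums(d)
    dtmp <- vol2col_cpp(d, S, 4L, 2L, 1L)
    g[[paste0("dec_W", l)]] <- tcrossprod(dec$cache$x[[l]], dtmp)
    d <- p[[paste0("dec_W", l)]] %*% dtmp
    S <- S / 2L
  }
  dh <- as.vector(d) * (dec$cache$h > 0)
  g$fcd_W <- dh %o% enc$z
  g$fcd_b <- dh
  dz <- drop(crossprod(p$fcd_W, dh))

  # encoder backward
  g$fce_W <- dz %o% enc$pool
  g$fce_b <- dz
  dpool <- drop(crossprod(p$fce_W, dz))
  d <- matrix(dpool / enc$npool, length(dpool), enc$npool)
  S <- cfg$patch / 16L
  for (l in 4:1) {
    d <- d * enc$cache$mask[[l]]
    bb <- bn_bw(d, p[[paste0("enc_g", l)]], enc$cache$bn[[l]])
    g[[paste0("enc_g", l)]] <- bb$dg
    g[[paste0("enc_a", l)]] <- bb$da
    d <- bb$dx
    g[[paste0("enc_b", l)]] <- rowSums(d)
    g[[paste0("enc_W", l)]] <- tcrossprod(d, enc$cache$cols[[l]])
    dcols <- crossprod(p[[paste0("enc_W", l)]], d)
    S_in <- 2L * S
    d <- col2vol_cpp(dcols, nrow(enc$cache$x[[l]]), S_in, 3L, 2L, 1L)
    S <- S_in
  }
  list(loss = loss, grads = g, model = model)
}

flip_patch <- function(x, C, S) {
  a <- array(x, dim = c(C, S, S, S))
  for (ax in 2:4) if (stats::runif(1) < 0.5) {
    idx <- rev(seq_len(S))
    a <- switch(ax - 1, a[, idx, , , drop = FALSE],
                a[, , idx, , drop = FALSE], a[, , , idx, drop = FALSE])
  }
  a
}

#' Train the autoencoder
#'
#' Mini-batch Adam on the L1 objective with optional random axis flips and
#' early stopping on validation loss (patience epochs without improvement);
#' the weights achieving the best validation loss are returned. Fully
#' deterministic under the config seed.
#'
#' @param model an untrained (or warm) `ae_model`.
#' @param train_patches,valid_patches lists of patches (each `$tensor` is a
#'   `C x patch^3` array, as produced by [sample_patches()]).
#' @return the trained `ae_model`, with a `history` tibble (epoch, train and
#'   validation loss) and `best_epoch` attached.
#' @export
ae_train <- function(model, train_patches, valid_patches) {
  stopifnot(inherits(model, "ae_model"), length(train_patches) > 0,
            length(valid_patches) > 0)
  cfg <- model$cfg
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  opt <- adam_new(model$par)
  best <- list(loss = Inf, par = model$par, bn = model$bn, epoch = 0L)
  hist <- list()
  wait <- 0L
  C <- model$channels_in
  S <- cfg$patch
  val_loss <- function(m) {
    mean(vapply(valid_patches, function(pt) {
      fw <- ae_decode_fw(m, ae_encode_fw(m, pt$tensor)$z)
      mean(abs(as_cmat(pt$tensor) - fw$xhat))
    }, numeric(1)))
  }
  for (ep in seq_len(cfg$max_epochs)) {
    idx <- sample(length(train_patches))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, length(idx), by = cfg$batch)) {
      rows <- idx[start:min(start + cfg$batch - 1L, length(idx))]
      gsum <- NULL
      bloss <- 0
      for (r in rows) {
        xt <- train_patches[[r]]$tensor
        if (cfg$augment_flips) xt <- flip_patch(xt, C, S)
        bp <- ae_backprop(model, xt, train = TRUE)
        model <- bp$model
        bloss <- bloss + bp$loss
        gsum <- if (is.null(gsum)) bp$grads else
          Map(`+`, gsum, bp$grads[names(gsum)])
      }
      gsum <- lapply(gsum[names(model$par)], function(gg) gg / length(rows))
      step <- adam_step(opt, model$par, gsum, cfg$lr)
      opt <- step$opt
      model$par <- step$params
      ep_loss <- ep_loss + bloss / length(rows)
      nb <- nb + 1L
    }
    vl <- val_loss(model)
    hist[[ep]] <- c(epoch = ep, train_loss = ep_loss / nb, valid_loss = vl)
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, par = model$par, bn = model$bn, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$par <- best$par
  model$bn <- best$bn
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$history <- tibble::as_tibble(do.call(rbind, hist))
  model
}

# --- reconstruction metrics ------------------------------------------------

boxmean2d <- function(m, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 1, nc + 1)
  pad[-1, -1] <- cs
  i <- seq_len(nr - w + 1); j <- seq_len(nc - w + 1)
  (pad[i + w, j + w] - pad[i, j + w] - pad[i + w, j] + pad[i, j]) / w^2
}

#' Structural similarity of two 2-D images
#'
#' Uniform 7x7 window, K1 = 0.01, K2 = 0.03, data range 1 (documented
#' defaults; window statistics are population moments).
#' @keywords internal
ssim2d <- function(a, b, w = 7L, K1 = 0.01, K2 = 0.03, data_range = 1) {
  stopifnot(all(dim(a) == dim(b)), all(dim(a) >= w))
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu_a <- boxmean2d(a, w); mu_b <- boxmean2d(b, w)
  va <- boxmean2d(a^2, w) - mu_a^2
  vb <- boxmean2d(b^2, w) - mu_b^2
  cov <- boxmean2d(a * b, w) - mu_a * mu_b
  mean(((2 * mu_a * mu_b + C1) * (2 * cov + C2)) /
         ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
}

#' Reconstruction fidelity over a set of patches
#'
#' MSE over the full tensors; SSIM and PSNR on the central axial slice of
#' each channel, averaged over channels, then over cases. PSNR of a perfect
#' reconstruction is capped at 100 dB to keep aggregates finite.
#'
#' @param model trained `ae_model`.
#' @param patches list of patches (`$tensor` arrays).
#' @return one-row tibble: mean and sd of mse, ssim, psnr_db.
#' @export
recon_metrics <- function(model, patches) {
  S <- model$cfg$patch
  mid <- S %/% 2L
  per <- t(vapply(patches, function(pt) {
    x <- array(as_cmat(pt$tensor), c(model$channels_in, S, S, S))
    xhat <- ae_decode(model, ae_encode(model, x))
    mse <- mean((x - xhat)^2)
    sl <- vapply(seq_len(model$channels_in), function(ch) {
      a <- x[ch, , , mid]; b <- xhat[ch, , , mid]
      ms <- mean((a - b)^2)
      c(ssim = ssim2d(a, b),
        psnr = if (ms == 0) 100 else min(100, 10 * log10(1 / ms)))
    }, numeric(2))
    c(mse = mse, ssim = mean(sl["ssim", ]), psnr = mean(sl["psnr", ]))
  }, numeric(3)))
  tibble::tibble(
    mse = mean(per[, "mse"]), mse_sd = stats::sd(per[, "mse"]),
    ssim = mean(per[, "ssim"]), ssim_sd = stats::sd(per[, "ssim"]),
    psnr_db = mean(per[, "psnr"]), psnr_db_sd = stats::sd(per[, "psnr"]),
    n = nrow(per))
}
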
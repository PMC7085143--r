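# Unsupervised representation learners: streaming PCA (Oja-style stochastic
# approximation), stacked denoising autoencoder with layerwise pretraining,
# variational autoencoder with KL annealing, and the identity control.

#' Training specification for the neural embedders
#'
#' @param epochs,batch_size,learning_rate,momentum SGD settings.
#' @param noise_sd standard deviation of the additive Gaussian input
#'   corruption of the denoising autoencoder.
#' @param l2 l2 weight penalty.
#' @param kl_horizon epochs over which the VAE's KL weight ramps linearly
#'   from 0 to 1; must not exceed `epochs`.
#' @param seed RNG seed.
#' @return a `train_spec` list.
#' @export
train_spec <- function(epochs = 30, batch_size = 64, learning_rate = 0.05,
                       momentum = 0.9, noise_sd = 0.3, l2 = 1e-4,
                       kl_horizon = min(10, epochs), seed = 1) {
  stopifnot(epochs > 0, batch_size > 0, learning_rate > 0, noise_sd >= 0,
            l2 >= 0, kl_horizon <= epochs)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, momentum = momentum,
                 noise_sd = noise_sd, l2 = l2, kl_horizon = kl_horizon,
                 seed = seed),
            class = "train_spec")
}

as_features <- function(x) {
  if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
}

new_embedder <- function(kind, input_dim, latent_dim, params = list(),
                         log = NULL) {
  structure(list(kind = kind, input_dim = input_dim,
                 latent_dim = latent_dim, params = params, log = log),
            class = "embedder")
}

#' @export
print.embedder <- function(x, ...) {
  cat(sprintf("embedder [%s]: %d -> %d\n", x$kind, x$input_dim,
              x$latent_dim))
  invisible(x)
}

#' The identity (no-embedding) control
#'
#' @param input_dim feature count; the latent dimension equals it.
#' @return an `embedder` of kind `"identity"`.
#' @export
identity_embedder <- function(input_dim) {
  new_embedder("identity", input_dim, input_dim)
}

#' Streaming PCA by stochastic approximation
#'
#' Fits an orthonormal d-frame maximizing captured variance on mean-centered
#' data with Oja-style minibatch updates (`W <- W + lr * X'XW / B`),
#' re-orthonormalized by QR every few steps for numerical stability. After
#' the streaming pass the frame is rotated onto the principal axes of the
#' projected data, so components come out ordered by explained variance.
#'
#' @param data matrix or [expression_matrix()], samples x genes.
#' @param d latent dimension, at most `min(n, p)`.
#' @param spec a [train_spec()].
#' @param reorth_every QR re-orthonormalization period in steps.
#' @return an `embedder` of kind `"pca"` with the frame, the column means
#'   and the per-component explained variance.
#' @export
fit_pca_stochastic <- function(data, d, spec = train_spec(),
                               reorth_every = 10) {
  X <- as_features(data)
  n <- nrow(X); p <- ncol(X)
  if (d > min(n, p)) stop("d must be at most min(n_samples, n_genes)")
  old <- local_rng_seed(spec$seed)
  on.exit(restore_rng(old))
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  W <- qr.Q(qr(matrix(stats::rnorm(p * d), p, d)))
  step <- 0L
  for (ep in seq_len(spec$epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = spec$batch_size)) {
      b <- idx[start:min(start + spec$batch_size - 1, n)]
      Xb <- Xc[b, , drop = FALSE]
      W <- W + spec$learning_rate * crossprod(Xb, Xb %*% W) / length(b)
      step <- step + 1L
      if (step %% reorth_every == 0L) W <- qr.Q(qr(W))
    }
  }
  W <- qr.Q(qr(W))
  # rotate onto principal axes of the captured subspace
  P <- Xc %*% W
  e <- eigen(crossprod(P) / n, symmetric = TRUE)
  W <- W %*% e$vectors
  new_embedder("pca", p, d,
               params = list(frame = W, center = center,
                             explained_variance = e$values))
}

# ---- dense-network engine ---------------------------------------------------

act_forward <- function(z, act) {
  switch(act,
         linear = z,
         tanh = tanh(z),
         selu = {
           l <- 1.0507009873554805; a <- 1.6732632423543772
           l * ifelse(z > 0, z, a * (exp(z) - 1))
         })
}

act_backward <- function(z, h, act) {            # d h / d z
  switch(act,
         linear = 1,
         tanh = 1 - h^2,
         selu = {
           l <- 1.0507009873554805; a <- 1.6732632423543772
           l * ifelse(z > 0, 1, a * exp(z))
         })
}

init_layer <- function(n_in, n_out, act) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(1 / n_in)), n_in,
                  n_out),
       b = numeric(n_out), act = act)
}

net_forward <- function(layers, X) {
  h <- list(X); z <- list()
  for (i in seq_along(layers)) {
    z[[i]] <- sweep(h[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    h[[i + 1]] <- act_forward(z[[i]], layers[[i]]$act)
  }
  list(h = h, z = z)
}

# returns gradients for every layer plus the gradient wrt the input
net_backward <- function(layers, fwd, d_out, l2) {
  grads <- vector("list", length(layers))
  da <- d_out
  for (i in rev(seq_along(layers))) {
    dz <- da * act_backward(fwd$z[[i]], fwd$h[[i + 1]], layers[[i]]$act)
    grads[[i]] <- list(W = crossprod(fwd$h[[i]], dz) + 2 * l2 *
                         layers[[i]]$W,
                       b = colSums(dz))
    da <- dz %*% t(layers[[i]]$W)
  }
  list(grads = grads, d_input = da)
}

sgd_update <- function(layers, grads, vel, lr, momentum) {
  for (i in seq_along(layers)) {
    vel[[i]]$W <- momentum * vel[[i]]$W - lr * grads[[i]]$W
    vel[[i]]$b <- momentum * vel[[i]]$b - lr * grads[[i]]$b
    layers[[i]]$W <- layers[[i]]$W + vel[[i]]$W
    layers[[i]]$b <- layers[[i]]$b + vel[[i]]$b
  }
  list(layers = layers, vel = vel)
}

zero_vel <- function(layers) {
  lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

# train a plain (denoising) autoencoder stack: corrupt input, reconstruct
# clean target, MSE loss averaged over entries
train_dae <- function(layers, X, target, spec, stage, log_env) {
  n <- nrow(X)
  vel <- zero_vel(layers)
  best <- layers; best_loss <- Inf
  for (ep in seq_len(spec$epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      b <- idx[start:min(start + spec$batch_size - 1, n)]
      Xb <- X[b, , drop = FALSE]
      if (spec$noise_sd > 0)
        Xb <- Xb + matrix(stats::rnorm(length(Xb), 0, spec$noise_sd),
                          nrow(Xb))
      Tb <- target[b, , drop = FALSE]
      fwd <- net_forward(layers, Xb)
      out <- fwd$h[[length(fwd$h)]]
      loss <- mean((out - Tb)^2)
      if (!is.finite(loss))
        stop("autoencoder training diverged (non-finite loss); see log")
      d_out <- 2 * (out - Tb) / length(Tb)
      bwd <- net_backward(layers, fwd, d_out, spec$l2)
      upd <- sgd_update(layers, bwd$grads, vel, spec$learning_rate,
                        spec$momentum)
      layers <- upd$layers; vel <- upd$vel
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    log_env$log <- rbind(log_env$log,
                         data.frame(stage = stage, epoch = ep,
                                    loss = ep_loss))
    if (ep_loss < best_loss) { best_loss <- ep_loss; best <- layers }
  }
  best
}

sdae_widths <- function(input_dim, d) {
  h1 <- max(d, ceiling(sqrt(input_dim * d)))
  h2 <- max(d, 2 * d)
  c(h1 = h1, h2 = h2)
}

#' Fit a stacked denoising autoencoder
#'
#' A seven-layer hourglass (input -> h1 -> h2 -> d -> h2 -> h1 -> input,
#' with h1 the geometric mean of input and latent widths and h2 = 2d)
#' trained to reconstruct the clean input from additive-Gaussian-corrupted
#' input under mean squared error. Each encoder/decoder pair is greedily
#' pretrained as a shallow denoising autoencoder, then the assembled network
#' is fine-tuned end to end; the best epoch by training loss is kept, so
#' fine-tuning never degrades the pretrained solution.
#'
#' @param data matrix or [expression_matrix()], samples x genes.
#' @param d latent dimension.
#' @param spec a [train_spec()]; `noise_sd` is the corruption variance's
#'   square root, `l2` the weight penalty.
#' @return an `embedder` of kind `"sdae"` with encoder/decoder layers and a
#'   per-epoch training log.
#' @export
fit_sdae <- function(data, d, spec = train_spec()) {
  X <- as_features(data)
  n <- nrow(X); p <- ncol(X)
  if (n < spec$batch_size) stop("need at least one full batch of samples")
  old <- local_rng_seed(spec$seed)
  on.exit(restore_rng(old))
  w <- sdae_widths(p, d)
  log_env <- new.env(); log_env$log <- NULL

  # layerwise pretraining of the three encoder/decoder pairs
  ae1 <- list(init_layer(p, w["h1"], "tanh"),
              init_layer(w["h1"], p, "linear"))
  ae1 <- train_dae(ae1, X, X, spec, "pretrain1", log_env)
  H1 <- net_forward(ae1[1], X)$h[[2]]
  ae2 <- list(init_layer(w["h1"], w["h2"], "tanh"),
              init_layer(w["h2"], w["h1"], "linear"))
  ae2 <- train_dae(ae2, H1, H1, spec, "pretrain2", log_env)
  H2 <- net_forward(ae2[1], H1)$h[[2]]
  ae3 <- list(init_layer(w["h2"], d, "tanh"),
              init_layer(d, w["h2"], "linear"))
  ae3 <- train_dae(ae3, H2, H2, spec, "pretrain3", log_env)

  # assemble the hourglass and fine-tune end to end
  retanh <- function(l) { l$act <- "tanh"; l }
  full <- list(ae1[[1]], ae2[[1]], ae3[[1]],
               retanh(ae3[[2]]), retanh(ae2[[2]]),
               ae1[[2]])
  full <- train_dae(full, X, X, spec, "finetune", log_env)

  new_embedder("sdae", p, d,
               params = list(encoder = full[1:3], decoder = full[4:6]),
               log = log_env$log)
}

#' KL-annealing weight schedule
#'
#' Linear ramp from 0 at epoch 0 to 1 at the annealing horizon, and 1
#' thereafter.
#'
#' @param epoch 0-based epoch index.
#' @param horizon annealing horizon in epochs.
#' @return weight in \[0, 1\].
#' @export
kl_weight <- function(epoch, horizon) {
  if (horizon <= 0) return(1)
  min(1, epoch / horizon)
}

#' Fit a variational autoencoder
#'
#' Gaussian-latent VAE with self-normalizing (SELU) hidden layers. The
#' encoder maps input -> h1 -> h2 -> (d means, d log-variances); the decoder
#' mirrors it. The loss is per-sample squared reconstruction error plus the
#' KL divergence of the latent posterior from the standard normal, with the
#' KL term annealed linearly from 0 to 1 over `spec$kl_horizon` epochs.
#' `encode()` returns the latent means only, so the feature map is d- (not
#' 2d-) dimensional and deterministic.
#'
#' @inheritParams fit_sdae
#' @return an `embedder` of kind `"vae"`.
#' @export
fit_vae <- function(data, d, spec = train_spec()) {
  X <- as_features(data)
  n <- nrow(X); p <- ncol(X)
  if (n < spec$batch_size) stop("need at least one full batch of samples")
  old <- local_rng_seed(spec$seed)
  on.exit(restore_rng(old))
  w <- sdae_widths(p, d)
  enc <- list(init_layer(p, w["h1"], "selu"),
              init_layer(w["h1"], w["h2"], "selu"))
  head_mu <- init_layer(w["h2"], d, "linear")
  head_lv <- init_layer(w["h2"], d, "linear")
  dec <- list(init_layer(d, w["h2"], "selu"),
              init_layer(w["h2"], w["h1"], "selu"),
              init_layer(w["h1"], p, "linear"))
  vel <- list(enc = zero_vel(enc), mu = zero_vel(list(head_mu))[[1]],
              lv = zero_vel(list(head_lv))[[1]], dec = zero_vel(dec))
  log <- NULL
  lr <- spec$learning_rate; mom <- spec$momentum

  for (ep in seq_len(spec$epochs)) {
    wkl <- kl_weight(ep - 1, spec$kl_horizon)
    idx <- sample.int(n)
    ep_loss <- 0; ep_kl <- 0; nb <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      b <- idx[start:min(start + spec$batch_size - 1, n)]
      Xb <- X[b, , drop = FALSE]
      B <- nrow(Xb)
      f_enc <- net_forward(enc, Xb)
      h2 <- f_enc$h[[3]]
      f_mu <- net_forward(list(head_mu), h2)
      f_lv <- net_forward(list(head_lv), h2)
      mu <- f_mu$h[[2]]; lv <- pmin(f_lv$h[[2]], 10)
      eps <- matrix(stats::rnorm(B * d), B, d)
      z <- mu + eps * exp(0.5 * lv)
      f_dec <- net_forward(dec, z)
      out <- f_dec$h[[4]]
      recon <- sum((out - Xb)^2) / B
      kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / B
      loss <- recon + wkl * kl
      if (!is.finite(loss))
        stop("VAE training diverged (non-finite loss); see log")

      d_out <- 2 * (out - Xb) / B
      bwd_dec <- net_backward(dec, f_dec, d_out, spec$l2)
      dz <- bwd_dec$d_input
      dmu <- dz + wkl * mu / B
      dlv <- dz * eps * 0.5 * exp(0.5 * lv) +
        wkl * 0.5 * (exp(lv) - 1) / B
      bwd_mu <- net_backward(list(head_mu), f_mu, dmu, spec$l2)
      bwd_lv <- net_backward(list(head_lv), f_lv, dlv, spec$l2)
      dh2 <- bwd_mu$d_input + bwd_lv$d_input
      bwd_enc <- net_backward(enc, f_enc, dh2, spec$l2)

      u <- sgd_update(enc, bwd_enc$grads, vel$enc, lr, mom)
      enc <- u$layers; vel$enc <- u$vel
      u <- sgd_update(list(head_mu), bwd_mu$grads, list(vel$mu), lr, mom)
      head_mu <- u$layers[[1]]; vel$mu <- u$vel[[1]]
      u <- sgd_update(list(head_lv), bwd_lv$grads, list(vel$lv), lr, mom)
      head_lv <- u$layers[[1]]; vel$lv <- u$vel[[1]]
      u <- sgd_update(dec, bwd_dec$grads, vel$dec, lr, mom)
      dec <- u$layers; vel$dec <- u$vel

      ep_loss <- ep_loss + loss; ep_kl <- ep_kl + kl; nb <- nb + 1
    }
    log <- rbind(log, data.frame(stage = "train", epoch = ep,
                                 loss = ep_loss / nb, kl = ep_kl / nb,
                                 kl_weight = wkl))
  }
  new_embedder("vae", p, d,
               params = list(encoder = enc, head_mu = head_mu,
                             head_lv = head_lv, decoder = dec),
               log = log)
}

#' Encode data through a fitted embedder
#'
#' Deterministic for every kind: identity returns the input unchanged, PCA
#' projects centered data on the frame, SDAE runs the encoder half, VAE
#' returns the latent means.
#'
#' @param model an `embedder`.
#' @param data matrix or [expression_matrix()] with `model$input_dim`
#'   columns.
#' @return latent matrix, samples x `model$latent_dim`.
#' @export
encode <- function(model, data) {
  stopifnot(inherits(model, "embedder"))
  X <- as_features(data)
  if (ncol(X) != model$input_dim)
    stop(sprintf("input has %d features, embedder expects %d", ncol(X),
                 model$input_dim))
  switch(model$kind,
         identity = X,
         pca = sweep(X, 2, model$params$center) %*% model$params$frame,
         sdae = {
           f <- net_forward(model$params$encoder, X)
           f$h[[length(f$h)]]
         },
         vae = {
           h2 <- net_forward(model$params$encoder, X)$h[[3]]
           net_forward(list(model$params$head_mu), h2)$h[[2]]
         },
         stop("unknown embedder kind: ", model$kind))
}
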
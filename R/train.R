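#' Training configuration
#'
#' @param learning_rate RMSprop learning rate (default 1e-4, small
#'   enough for stable convergence across dataset sizes).
#' @param max_epochs Hard cap on training epochs (default 5000; early
#'   stopping usually fires much sooner).
#' @param patience_epochs Stop when the best loss has not improved by
#'   more than `min_loss_delta` for this many consecutive epochs
#'   (default 50).
#' @param batch_size Mini-batch size; `NULL` means `min(n_cells, 256)`.
#' @param min_loss_delta Absolute improvement that counts as "obvious
#'   decrease" for early stopping (default 1e-4).
#' @param seed Seed controlling every stochastic element of training:
#'   batch shuffling, input dropout masks, latent noise and Gumbel
#'   draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4,
                         max_epochs = 5000,
                         patience_epochs = 50,
                         batch_size = NULL,
                         min_loss_delta = 1e-4,
                         seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (patience_epochs < 1) stop("`patience_epochs` must be >= 1")
  if (min_loss_delta < 0) stop("`min_loss_delta` must be non-negative")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 min_loss_delta = min_loss_delta,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' KL divergence from a diagonal Gaussian posterior to N(0, I)
#'
#' Closed form, per cell:
#' `-0.5 * sum_j (1 + log_var_j - mu_j^2 - exp(log_var_j))`.
#' It is zero exactly when the posterior equals the prior (`mu = 0`,
#' `log_var = 0`) and positive otherwise. With a fixed identity
#' covariance it reduces to `||mu||^2 / 2`.
#'
#' @param post A `latent_posterior` (matrices `mu`, `log_var`).
#' @return Numeric vector, one non-negative KL value per cell.
#' @export
kl_divergence <- function(post) {
  mu <- post$mu; lv <- post$log_var
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  if (is.null(dim(lv))) lv <- matrix(lv, nrow = 1)
  -0.5 * rowSums(1 + lv - mu^2 - exp(lv))
}

#' Per-cell binary cross-entropy reconstruction loss
#'
#' `sum_genes [-x log y - (1 - x) log(1 - y)]` with `y` clamped away
#' from 0 and 1 by 1e-7. Appropriate because both the scaled input and
#' the sigmoid/ZI output live in the unit interval; for fixed `x` the
#' loss is minimized at `y = x`.
#'
#' @param x Original batch (cells x genes), values in `[0, 1]`.
#' @param y Reconstructed batch, same shape.
#' @return Numeric vector, one non-negative loss per cell.
#' @export
reconstruction_loss <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (!all(dim(x) == dim(y))) {
    stop(sprintf("shape mismatch: x is %dx%d but y is %dx%d",
                 nrow(x), ncol(x), nrow(y), ncol(y)))
  }
  yc <- pmin(pmax(y, .p_eps), 1 - .p_eps)
  rowSums(-x * log(yc) - (1 - x) * log1p(-yc))
}

#' Total training loss
#'
#' Mean over the batch of reconstruction loss plus KL divergence, plus
#' the L1 penalty on the first encoder layer's weights.
#'
#' @param x Original batch.
#' @param y Reconstructed batch.
#' @param post `latent_posterior` for the batch.
#' @param params A [zivae_params()] object (supplies `l1_weight` and the
#'   first-layer weights).
#' @return Single numeric loss value.
#' @export
total_loss <- function(x, y, post, params) {
  mean(reconstruction_loss(x, y) + kl_divergence(post)) +
    params$l1_weight * sum(abs(params$weights$e1_W))
}

#' Gumbel-softmax temperature at a given epoch
#'
#' The constant schedule returns `params$tau`. The annealing schedule
#' interpolates linearly from `tau_start` (at epoch 0) to `tau_end` (at
#' epoch `tau_span`) and stays at `tau_end` thereafter; e.g. with the
#' default 1.0 -> 0.5 over 200 epochs, epoch 100 gives 0.75.
#'
#' @param epoch Epoch number, starting at 1.
#' @param params A [zivae_params()] object.
#' @return Positive temperature.
#' @export
anneal_tau <- function(epoch, params) {
  if (params$tau_schedule == "constant") return(params$tau)
  frac <- min(epoch / params$tau_span, 1)
  params$tau_start + frac * (params$tau_end - params$tau_start)
}

# Gradients of the total loss for one mini-batch, given the forward
# state from .forward_pass(). Returns a flat list matching
# params$weights. Derivation: straight reverse-mode differentiation of
# BCE(x, clamp((1-s)*yt)) + KL, with the clamps treated as zero-gradient
# regions.
.backward_pass <- function(st, params) {
  w <- params$weights
  n <- st$n
  ne <- length(params$encoder_dims)
  nd <- length(params$decoder_dims)
  g <- list()

  x <- st$x; y <- st$y; yt <- st$yt
  yc <- pmin(pmax(y, .p_eps), 1 - .p_eps)
  dY <- (((1 - x) / (1 - yc)) - (x / yc)) / n
  dY <- dY * ((y > .p_eps) & (y < 1 - .p_eps))

  if (!is.null(st$s)) {                       # ZI layer active
    s <- st$s; pc <- st$pc
    dS <- -dY * yt
    dYT <- dY * (1 - s)
    dA <- dS * s * (1 - s)                    # pre-sigmoid of Gumbel-softmax
    dPC <- dA * (1 / pc + 1 / (1 - pc)) / st$tau
    dP <- dPC * st$inb
    dYT <- dYT + dP * (-2 * yt * pc)
  } else {
    dYT <- dY
  }
  dO <- dYT * yt * (1 - yt)                   # sigmoid backward

  # decoder output layer
  nm <- paste0("d", nd + 1)
  g[[paste0(nm, "_W")]] <- crossprod(st$dact[[nd]], dO)
  g[[paste0(nm, "_b")]] <- colSums(dO)
  dB <- tcrossprod(dO, w[[paste0(nm, "_W")]])
  for (j in rev(seq_len(nd))) {
    dC <- dB * (st$dpre[[j]] > 0)
    below <- if (j == 1) st$z else st$dact[[j - 1]]
    g[[paste0("d", j, "_W")]] <- crossprod(below, dC)
    g[[paste0("d", j, "_b")]] <- colSums(dC)
    dB <- tcrossprod(dC, w[[paste0("d", j, "_W")]])
  }
  dZ <- dB

  mu <- st$mu; lv <- st$lv
  dMU <- dZ + mu / n
  dA_enc <- NULL
  if (params$sigma_mode == "learned") {
    dLV <- dZ * st$eps * 0.5 * exp(lv / 2) + (exp(lv) - 1) / (2 * n)
    dTLV <- dLV * stats::plogis(st$tlv)       # softplus backward
    g$lv_W <- crossprod(st$act[[ne]], dTLV)
    g$lv_b <- colSums(dTLV)
    dA_enc <- tcrossprod(dTLV, w$lv_W)
  }
  g$mu_W <- crossprod(st$act[[ne]], dMU)
  g$mu_b <- colSums(dMU)
  dA <- tcrossprod(dMU, w$mu_W)
  if (!is.null(dA_enc)) dA <- dA + dA_enc

  for (j in rev(seq_len(ne))) {
    dZj <- if (j == 1) dA else dA * (st$pre[[j]] > 0)  # first layer linear
    below <- if (j == 1) st$xd else st$act[[j - 1]]
    g[[paste0("e", j, "_W")]] <- crossprod(below, dZj)
    g[[paste0("e", j, "_b")]] <- colSums(dZj)
    if (j > 1) dA <- tcrossprod(dZj, w[[paste0("e", j, "_W")]])
  }
  g$e1_W <- g$e1_W + params$l1_weight * sign(w$e1_W)
  g
}

#' Train the zero-inflated VAE
#'
#' Optimizes the composite loss (binary cross-entropy reconstruction +
#' KL divergence + L1 penalty) with RMSprop over shuffled mini-batches.
#' Training stops when the best epoch loss has not improved by more
#' than `min_loss_delta` for `patience_epochs` consecutive epochs, or at
#' `max_epochs`; the weights from the best-loss epoch are returned.
#' All randomness derives from `config$seed`, so two runs with the same
#' seed, data and initial parameters produce identical histories.
#'
#' @param x An [expression_matrix()] in `scaled` space, or a plain
#'   numeric matrix with values in `[0, 1]`.
#' @param params A [zivae_params()] object; its `sigma_mode` should
#'   respect the sample-size rule (see [resolve_sigma_mode()]).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress to standard error.
#' @return A list with `params` (trained, best-epoch weights) and
#'   `history` (class `train_history`: data frame of per-epoch loss
#'   terms and temperature, plus `stopped_epoch`, `stop_reason`,
#'   `best_epoch` and the RMSprop settings used).
#' @export
train_vae <- function(x, params, config = train_config(), verbose = FALSE) {
  if (inherits(x, "ExpressionMatrix")) {
    stopifnot_em(x, "scaled", "x")
    x <- x$values
  }
  if (any(x < 0) || any(x > 1)) {
    stop("training input must be scaled to [0, 1]; run preprocessing first")
  }
  n <- nrow(x)
  if (ncol(x) != params$input_dim) {
    stop(sprintf("model expects %d genes, data has %d",
                 params$input_dim, ncol(x)))
  }
  batch_size <- if (is.null(config$batch_size)) min(n, 256L)
                else min(config$batch_size, n)

  rms_rho <- 0.9; rms_eps <- 1e-8
  w <- params$weights
  v <- lapply(w, function(u) u * 0)           # RMSprop second-moment state

  set.seed(config$seed)
  hist_loss <- hist_recon <- hist_kl <- hist_tau <- numeric(config$max_epochs)
  best_loss <- Inf; best_epoch <- 0L; best_w <- w
  stall <- 0L; stop_reason <- "max_epochs"; epoch <- 0L

  l1w <- params$l1_weight
  for (epoch in seq_len(config$max_epochs)) {
    tau <- anneal_tau(epoch, params)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- ep_recon <- ep_kl <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      params$weights <- w
      st <- .forward_pass(xb, params, training = TRUE, tau = tau)
      recon <- reconstruction_loss(xb, st$y)
      kl <- kl_divergence(structure(list(mu = st$mu, log_var = st$lv),
                                    class = "latent_posterior"))
      bloss <- mean(recon + kl) + l1w * sum(abs(w$e1_W))
      if (!is.finite(bloss)) {
        stop(sprintf(paste0("non-finite loss at epoch %d ",
                            "(reconstruction %.4g, KL %.4g)"),
                     epoch, mean(recon), mean(kl)))
      }
      nb <- length(idx)
      ep_loss <- ep_loss + bloss * nb
      ep_recon <- ep_recon + mean(recon) * nb
      ep_kl <- ep_kl + mean(kl) * nb

      g <- .backward_pass(st, params)
      for (k in names(w)) {
        v[[k]] <- rms_rho * v[[k]] + (1 - rms_rho) * g[[k]]^2
        w[[k]] <- w[[k]] - config$learning_rate * g[[k]] / (sqrt(v[[k]]) + rms_eps)
      }
    }
    ep_loss <- ep_loss / n; ep_recon <- ep_recon / n; ep_kl <- ep_kl / n
    hist_loss[epoch] <- ep_loss
    hist_recon[epoch] <- ep_recon
    hist_kl[epoch] <- ep_kl
    hist_tau[epoch] <- tau
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  recon %.4f  kl %.4f  tau %.3f",
                      epoch, ep_loss, ep_recon, ep_kl, tau))
    }
    if (ep_loss < best_loss - config$min_loss_delta) {
      best_loss <- ep_loss; best_epoch <- epoch; best_w <- w; stall <- 0L
    } else {
      if (ep_loss < best_loss) { best_loss <- ep_loss; best_epoch <- epoch; best_w <- w }
      stall <- stall + 1L
      if (stall >= config$patience_epochs) { stop_reason <- "patience"; break }
    }
  }

  params$weights <- best_w
  history <- structure(list(
    epochs = data.frame(epoch = seq_len(epoch),
                        loss = hist_loss[seq_len(epoch)],
                        reconstruction = hist_recon[seq_len(epoch)],
                        kl = hist_kl[seq_len(epoch)],
                        tau = hist_tau[seq_len(epoch)]),
    stopped_epoch = epoch,
    stop_reason = stop_reason,
    best_epoch = best_epoch,
    best_loss = best_loss,
    batch_size = batch_size,
    rmsprop = list(learning_rate = config$learning_rate,
                   rho = rms_rho, epsilon = rms_eps),
    seed = config$seed), class = "train_history")
  list(params = params, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("train_history: %d epochs (%s), best epoch %d, best loss %.4f\n",
              x$stopped_epoch, x$stop_reason, x$best_epoch, x$best_loss))
  invisible(x)
}

#' Embed cells into the latent space
#'
#' Returns the posterior mean `mu` for every cell with every stochastic
#' layer disabled: no input dropout, no latent sampling, no
#' zero-inflation. The embedding is therefore a pure function of the
#' data and the trained parameters.
#'
#' @param x An [expression_matrix()] in `scaled` space, or a numeric
#'   matrix in `[0, 1]`.
#' @param params Trained [zivae_params()].
#' @return Numeric matrix, cells x `latent_dim`, with cell ids as row
#'   names when available.
#' @export
embed_cells <- function(x, params) {
  ids <- NULL
  if (inherits(x, "ExpressionMatrix")) {
    stopifnot_em(x, "scaled", "x")
    ids <- x$cell_ids
    x <- x$values
  }
  post <- vae_encode(x, params)
  emb <- post$mu
  rownames(emb) <- ids
  colnames(emb) <- paste0("dim", seq_len(ncol(emb)))
  emb
}
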
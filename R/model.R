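#' Construct model parameters for the zero-inflated VAE
#'
#' Builds the full parameter set of the network: a three-layer encoder
#' (first layer linear, acting as a learned PCA-like projection with an
#' L1 penalty on its weights; subsequent layers ReLU), a diagonal
#' Gaussian latent posterior, a three-layer ReLU decoder with a sigmoid
#' output, and the configuration of the stochastic zero-inflation (ZI)
#' output layer.
#'
#' Weights are initialized with symmetric uniform draws scaled by layer
#' fan (Glorot-style), from a dedicated seed so that repeated
#' construction is bit-for-bit reproducible.
#'
#' The posterior covariance can be fixed to the identity
#' (`sigma_mode = "fixed"`, the log-variance head is absent and the
#' per-cell log-variance is identically zero) or learned through a
#' softplus head (`"learned"`). `"auto"` applies the sample-size rule:
#' fixed for datasets of at most 1000 cells, learned above, where there
#' is enough data to estimate per-cell variances stably.
#'
#' @param input_dim Number of genes the model consumes.
#' @param latent_dim Dimension of the latent space (default 2, for
#'   visualization).
#' @param encoder_dims Hidden widths of the encoder, strictly decreasing
#'   (default `c(512, 128, 32)`).
#' @param decoder_dims Hidden widths of the decoder, strictly increasing
#'   (default `c(32, 128, 512)`).
#' @param input_dropout_rate Probability of zeroing each input entry
#'   during training (default 0.5); mimics extra dropout events and
#'   regularizes the encoder.
#' @param sigma_mode `"auto"`, `"fixed"` or `"learned"`; see Details.
#' @param n_cells Number of cells in the training set; required when
#'   `sigma_mode = "auto"`.
#' @param tau Gumbel-softmax temperature for the constant schedule;
#'   recommended range is 0.5-1 (default 0.75).
#' @param tau_schedule `"constant"` or `"anneal"`. The annealing
#'   schedule ramps tau linearly from `tau_start` to `tau_end` over
#'   `tau_span` epochs and holds it there; useful for datasets with more
#'   than about 1000 cells.
#' @param tau_start,tau_end,tau_span Annealing parameters (defaults 1.0,
#'   0.5, 200).
#' @param l1_weight Weight of the L1 penalty on the first encoder
#'   layer's weights (default 0.01).
#' @param use_zi Whether the zero-inflation output layer is active
#'   during training (default `TRUE`); disable for ablation studies.
#' @param seed Integer seed for weight initialization.
#'
#' @return An object of class `zivae_params`.
#' @export
zivae_params <- function(input_dim,
                         latent_dim = 2,
                         encoder_dims = c(512, 128, 32),
                         decoder_dims = c(32, 128, 512),
                         input_dropout_rate = 0.5,
                         sigma_mode = c("auto", "fixed", "learned"),
                         n_cells = NULL,
                         tau = 0.75,
                         tau_schedule = c("constant", "anneal"),
                         tau_start = 1.0, tau_end = 0.5, tau_span = 200,
                         l1_weight = 0.01,
                         use_zi = TRUE,
                         seed = 1L) {
  sigma_mode <- match.arg(sigma_mode)
  tau_schedule <- match.arg(tau_schedule)
  if (input_dim < 1) stop("`input_dim` must be a positive integer")
  if (any(diff(encoder_dims) >= 0)) {
    stop("`encoder_dims` must be strictly decreasing")
  }
  if (any(diff(decoder_dims) <= 0)) {
    stop("`decoder_dims` must be strictly increasing")
  }
  if (input_dropout_rate < 0 || input_dropout_rate >= 1) {
    stop("`input_dropout_rate` must be in [0, 1)")
  }
  if (tau <= 0 || tau_start <= 0 || tau_end <= 0) {
    stop("Gumbel-softmax temperatures must be positive")
  }
  if (sigma_mode == "auto") {
    if (is.null(n_cells)) {
      stop("`n_cells` is required to resolve sigma_mode = 'auto'")
    }
    sigma_mode <- resolve_sigma_mode(n_cells)
  }

  dims_in  <- c(input_dim, encoder_dims)
  dims_dec <- c(latent_dim, decoder_dims, input_dim)

  set.seed(as.integer(seed))
  glorot <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  w <- list()
  for (j in seq_along(encoder_dims)) {
    w[[paste0("e", j, "_W")]] <- glorot(dims_in[j], dims_in[j + 1])
    w[[paste0("e", j, "_b")]] <- numeric(dims_in[j + 1])
  }
  last_enc <- encoder_dims[length(encoder_dims)]
  w$mu_W <- glorot(last_enc, latent_dim)
  w$mu_b <- numeric(latent_dim)
  if (sigma_mode == "learned") {
    w$lv_W <- glorot(last_enc, latent_dim)
    w$lv_b <- numeric(latent_dim)
  }
  for (j in seq_len(length(dims_dec) - 1)) {
    w[[paste0("d", j, "_W")]] <- glorot(dims_dec[j], dims_dec[j + 1])
    w[[paste0("d", j, "_b")]] <- numeric(dims_dec[j + 1])
  }

  structure(list(input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 encoder_dims = as.integer(encoder_dims),
                 decoder_dims = as.integer(decoder_dims),
                 input_dropout_rate = input_dropout_rate,
                 sigma_mode = sigma_mode,
                 tau = tau,
                 tau_schedule = tau_schedule,
                 tau_start = tau_start, tau_end = tau_end,
                 tau_span = as.integer(tau_span),
                 l1_weight = l1_weight,
                 use_zi = isTRUE(use_zi),
                 seed = as.integer(seed),
                 weights = w),
            class = "zivae_params")
}

#' Sample-size rule for the posterior covariance
#'
#' Datasets of at most 1000 cells use a fixed identity covariance;
#' larger datasets learn the diagonal covariance from the data.
#'
#' @param n_cells Number of cells.
#' @return `"fixed"` or `"learned"`.
#' @export
resolve_sigma_mode <- function(n_cells) {
  if (n_cells > 1000) "learned" else "fixed"
}

#' @export
print.zivae_params <- function(x, ...) {
  cat(sprintf("zivae_params: %d genes -> latent %d\n", x$input_dim, x$latent_dim))
  cat(sprintf("  encoder %s | decoder %s\n",
              paste(x$encoder_dims, collapse = "/"),
              paste(x$decoder_dims, collapse = "/")))
  cat(sprintf("  sigma_mode=%s  tau=%s(%g)  dropout=%g  l1=%g  ZI=%s\n",
              x$sigma_mode, x$tau_schedule, x$tau,
              x$input_dropout_rate, x$l1_weight, x$use_zi))
  invisible(x)
}

relu <- function(x) (x > 0) * x

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Input dropout layer
#'
#' During training, independently zeroes each entry of the batch with
#' probability `rate`, emulating additional technical dropout events and
#' forcing the encoder to be robust to them. At inference the layer is
#' the identity. Entries are not rescaled by `1/(1-rate)`: the layer is
#' pure zero-noise injection. Draws come from R's global random number
#' stream; seed with `set.seed()` for reproducibility.
#'
#' @param x Numeric matrix batch (cells x genes), values in `[0, 1]`.
#' @param rate Dropout probability in `[0, 1)`.
#' @param training Logical; when `FALSE` the input is returned unchanged.
#' @return Matrix of the same shape.
#' @export
input_dropout <- function(x, rate = 0.5, training = TRUE) {
  if (!training || rate == 0) return(x)
  mask <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x))
  x * mask
}

#' Encode a batch of cells into the latent posterior
#'
#' Runs the encoder network: a linear first layer, ReLU hidden layers,
#' then a linear head for the posterior mean `mu` and, when the
#' covariance is learned, a softplus head for the log-variance.
#' With `sigma_mode = "fixed"` the log-variance is identically zero
#' (identity covariance).
#'
#' @param x Numeric matrix batch (cells x genes), width `input_dim`.
#' @param params A [zivae_params()] object.
#' @return A list of class `latent_posterior` with matrices `mu` and
#'   `log_var` (cells x latent_dim).
#' @export
vae_encode <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != params$input_dim) {
    stop(sprintf("encoder expects %d input features, got %d",
                 params$input_dim, ncol(x)))
  }
  w <- params$weights
  a <- x %*% w$e1_W
  a <- sweep(a, 2L, w$e1_b, "+")     # linear first layer
  for (j in seq_along(params$encoder_dims)[-1]) {
    a <- relu(sweep(a %*% w[[paste0("e", j, "_W")]], 2L,
                    w[[paste0("e", j, "_b")]], "+"))
  }
  mu <- sweep(a %*% w$mu_W, 2L, w$mu_b, "+")
  log_var <- if (params$sigma_mode == "learned") {
    softplus(sweep(a %*% w$lv_W, 2L, w$lv_b, "+"))
  } else {
    matrix(0, nrow(mu), ncol(mu))
  }
  structure(list(mu = mu, log_var = log_var), class = "latent_posterior")
}

#' Reparameterized sample from the latent posterior
#'
#' Draws `z = mu + exp(log_var / 2) * noise` with `noise ~ N(0, I)`,
#' which keeps the sampling step differentiable in `mu` and `log_var`.
#'
#' @param post A `latent_posterior` (from [vae_encode()]).
#' @param noise Standard-normal noise of the same shape as `post$mu`;
#'   drawn from the global RNG when `NULL`.
#' @param deterministic When `TRUE`, returns `mu` (the mode); used at
#'   inference so embeddings are a pure function of the input.
#' @return Matrix of latent coordinates (cells x latent_dim).
#' @export
sample_latent <- function(post, noise = NULL, deterministic = FALSE) {
  mu <- post$mu
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  if (deterministic) return(mu)
  lv <- post$log_var
  if (is.null(dim(lv))) lv <- matrix(lv, nrow = 1)
  if (is.null(noise)) {
    noise <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  if (is.null(dim(noise))) noise <- matrix(noise, nrow = 1)
  if (!all(dim(noise) == dim(mu))) {
    stop("`noise` must match the shape of the posterior mean")
  }
  mu + exp(lv / 2) * noise
}

#' Decode latent coordinates into a reconstructed expression profile
#'
#' ReLU hidden layers followed by a sigmoid output, so every
#' reconstructed value lies strictly in (0, 1) — the same unit-interval
#' space the scaled input occupies.
#'
#' @param z Matrix of latent coordinates (cells x latent_dim).
#' @param params A [zivae_params()] object.
#' @return Reconstruction matrix `y_tilde` (cells x input_dim).
#' @export
vae_decode <- function(z, params) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != params$latent_dim) {
    stop(sprintf("decoder expects latent width %d, got %d",
                 params$latent_dim, ncol(z)))
  }
  w <- params$weights
  b <- z
  nd <- length(params$decoder_dims)
  for (j in seq_len(nd)) {
    b <- relu(sweep(b %*% w[[paste0("d", j, "_W")]], 2L,
                    w[[paste0("d", j, "_b")]], "+"))
  }
  o <- sweep(b %*% w[[paste0("d", nd + 1, "_W")]], 2L,
             w[[paste0("d", nd + 1, "_b")]], "+")
  stats::plogis(o)
}

#' Dropout probability of a reconstructed expression value
#'
#' The probability that an entry is zeroed by a technical dropout event
#' is modeled as `exp(-y^2)`, a double-exponential decay in the
#' reconstructed expression: zero expression is dropped with certainty,
#' and the probability falls to `exp(-1)` at the per-cell maximum
#' (`y = 1` on unit-interval-scaled data).
#'
#' @param y_tilde Reconstructed values in `[0, 1]`.
#' @return Dropout probabilities, same shape, in `[exp(-1), 1]`.
#' @export
dropout_probability <- function(y_tilde) {
  exp(-y_tilde^2)
}

# clamping bounds for probabilities/reconstructions before logs
.p_eps <- 1e-7

#' Gumbel-softmax sample of a relaxed dropout indicator
#'
#' Draws a continuous sample `s` in (0, 1) that concentrates on the
#' Bernoulli outcomes `{0, 1}` as the temperature `tau` decreases:
#' `s = sigmoid((log p - log q + g0 - g1) / tau)` with `q = 1 - p` and
#' independent Gumbel(0,1) noise `g = -log(-log u)`. Unlike a hard
#' Bernoulli draw, `s` is differentiable in `p`, which is what lets
#' dropout sampling live inside a backpropagated network. `p` is clamped
#' to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param p Dropout probabilities (any numeric array).
#' @param tau Positive temperature; smaller is closer to discrete.
#' @param u0,u1 Uniform(0,1) draws of the same shape as `p`; drawn from
#'   the global RNG when `NULL`.
#' @return Relaxed samples `s`, same shape as `p`, strictly in (0, 1);
#'   `s` near 1 means "dropout".
#' @export
gumbel_softmax_sample <- function(p, tau, u0 = NULL, u1 = NULL) {
  if (tau <= 0) stop("`tau` must be positive")
  if (is.null(u0)) u0 <- stats::runif(length(p))
  if (is.null(u1)) u1 <- stats::runif(length(p))
  pc <- pmin(pmax(p, .p_eps), 1 - .p_eps)
  g0 <- -log(-log(u0))
  g1 <- -log(-log(u1))
  s <- stats::plogis((log(pc) - log1p(-pc) + g0 - g1) / tau)
  if (!is.null(dim(p))) dim(s) <- dim(p)
  s
}

#' Apply relaxed zero-inflation to a reconstruction
#'
#' Multiplies the reconstruction elementwise by `(1 - s)`: where the
#' relaxed dropout indicator `s` is near 1 the value is pushed to zero,
#' where it is near 0 the value passes through. The soft product keeps
#' the layer differentiable; in the low-temperature limit it coincides
#' with Bernoulli zero-setting.
#'
#' @param y_tilde Reconstructed values.
#' @param s Relaxed dropout indicators in (0, 1), same shape.
#' @return Zero-inflated output `y = (1 - s) * y_tilde`.
#' @export
zero_inflate <- function(y_tilde, s) {
  (1 - s) * y_tilde
}

#' Full forward pass of the zero-inflated VAE
#'
#' Composes input dropout, the encoder, reparameterized latent sampling,
#' the decoder, and the zero-inflation layer. With `training = FALSE`
#' all stochastic components are disabled (no input dropout, `z = mu`,
#' no ZI masking), so the map is a pure function of the input — run
#' twice, it returns identical output.
#'
#' @param x Scaled input batch (cells x genes, values in `[0, 1]`).
#' @param params A [zivae_params()] object.
#' @param training Logical; enables the stochastic layers.
#' @param tau Gumbel-softmax temperature for this pass (defaults to
#'   `params$tau`).
#' @return A list with `y` (output batch), `y_tilde` (pre-ZI
#'   reconstruction) and `posterior` (a `latent_posterior`).
#' @export
vae_forward <- function(x, params, training = FALSE, tau = params$tau) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  st <- .forward_pass(x, params, training = training, tau = tau)
  list(y = st$y, y_tilde = st$yt,
       posterior = structure(list(mu = st$mu, log_var = st$lv),
                             class = "latent_posterior"))
}

# Internal forward pass retaining every intermediate needed by backprop.
.forward_pass <- function(x, params, training, tau) {
  w <- params$weights
  n <- nrow(x)
  ne <- length(params$encoder_dims)
  nd <- length(params$decoder_dims)

  if (training && params$input_dropout_rate > 0) {
    mask <- matrix(stats::runif(length(x)) >= params$input_dropout_rate,
                   n, ncol(x))
    xd <- x * mask
  } else {
    xd <- x
  }

  # encoder: first layer linear, rest ReLU
  pre <- vector("list", ne); act <- vector("list", ne)
  pre[[1]] <- sweep(xd %*% w$e1_W, 2L, w$e1_b, "+")
  act[[1]] <- pre[[1]]
  for (j in seq_len(ne)[-1]) {
    pre[[j]] <- sweep(act[[j - 1]] %*% w[[paste0("e", j, "_W")]], 2L,
                      w[[paste0("e", j, "_b")]], "+")
    act[[j]] <- relu(pre[[j]])
  }
  mu <- sweep(act[[ne]] %*% w$mu_W, 2L, w$mu_b, "+")
  if (params$sigma_mode == "learned") {
    tlv <- sweep(act[[ne]] %*% w$lv_W, 2L, w$lv_b, "+")
    lv <- softplus(tlv)
  } else {
    tlv <- NULL
    lv <- matrix(0, n, params$latent_dim)
  }

  if (training) {
    eps <- matrix(stats::rnorm(length(mu)), n, params$latent_dim)
    z <- mu + exp(lv / 2) * eps
  } else {
    eps <- NULL
    z <- mu
  }

  # decoder: ReLU hidden layers, sigmoid output
  dpre <- vector("list", nd); dact <- vector("list", nd)
  b <- z
  for (j in seq_len(nd)) {
    dpre[[j]] <- sweep(b %*% w[[paste0("d", j, "_W")]], 2L,
                       w[[paste0("d", j, "_b")]], "+")
    dact[[j]] <- relu(dpre[[j]])
    b <- dact[[j]]
  }
  o <- sweep(b %*% w[[paste0("d", nd + 1, "_W")]], 2L,
             w[[paste0("d", nd + 1, "_b")]], "+")
  yt <- stats::plogis(o)

  if (training && params$use_zi) {
    pr <- exp(-yt^2)
    pc <- pmin(pmax(pr, .p_eps), 1 - .p_eps)
    inb <- (pr > .p_eps) & (pr < 1 - .p_eps)
    u0 <- stats::runif(length(yt)); u1 <- stats::runif(length(yt))
    g0 <- -log(-log(u0)); g1 <- -log(-log(u1))
    s <- stats::plogis((log(pc) - log1p(-pc) + g0 - g1) / tau)
    dim(s) <- dim(yt)
    dim(inb) <- dim(yt)
    y <- (1 - s) * yt
  } else {
    pc <- NULL; inb <- NULL; s <- NULL
    y <- yt
  }

  list(x = x, xd = xd, pre = pre, act = act, mu = mu, tlv = tlv, lv = lv,
       eps = eps, z = z, dpre = dpre, dact = dact, yt = yt,
       pc = pc, inb = inb, s = s, y = y, tau = tau, n = n)
}
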
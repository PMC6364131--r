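test_that("input dropout is a no-op at rate 0 and at inference", {
  x <- matrix(runif(50), 5, 10)
  expect_identical(input_dropout(x, rate = 0, training = TRUE), x)
  expect_identical(input_dropout(x, rate = 0.5, training = FALSE), x)
})

test_that("input dropout zeroes the configured fraction of entries", {
  set.seed(1234)
  x <- matrix(runif(1e5, min = 0.1, max = 1), 100, 1000)
  xd <- input_dropout(x, rate = 0.5, training = TRUE)
  frac <- mean(xd == 0)
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("encoder returns mu from the linear head and zero log-var when sigma is fixed", {
  p <- zivae_params(input_dim = 4, latent_dim = 2, encoder_dims = c(3, 2),
                    decoder_dims = c(2, 3), sigma_mode = "fixed", seed = 1)
  p$weights <- lapply(p$weights, function(w) w * 0)
  post <- vae_encode(matrix(runif(8), 2, 4), p)
  expect_equal(post$mu, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(post$log_var, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(vae_encode(matrix(0, 2, 5), p), "expects 4 input features, got 5")
})

test_that("encoder mu matches an independent loop-based forward pass", {
  p <- tiny_handset_params()
  x <- matrix(c(0.5, 0.1, 0.9, 0.3, 0, 1, 0.2, 0.7), 2, 4, byrow = TRUE)
  expect_equal(vae_encode(x, p)$mu, naive_encode(x, p), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("learned sigma uses a softplus head and fixed sigma omits it", {
  pf <- zivae_params(8, latent_dim = 2, encoder_dims = c(4, 3),
                     decoder_dims = c(3, 4), sigma_mode = "fixed", seed = 2)
  expect_null(pf$weights$lv_W)
  pl <- zivae_params(8, latent_dim = 2, encoder_dims = c(4, 3),
                     decoder_dims = c(3, 4), sigma_mode = "learned", seed = 2)
  post <- vae_encode(matrix(runif(16), 2, 8), pl)
  expect_true(all(post$log_var >= 0))   # softplus is non-negative
})

test_that("latent sampling implements z = mu + exp(log_var/2) * noise", {
  post <- structure(list(mu = matrix(c(1, 2), 1), log_var = matrix(c(log(4), 0), 1)),
                    class = "latent_posterior")
  expect_equal(sample_latent(post, noise = matrix(c(0, 0), 1)),
               matrix(c(1, 2), 1))
  expect_equal(sample_latent(post, noise = matrix(c(1, -1), 1)),
               matrix(c(3, 1), 1))
  expect_equal(sample_latent(post, deterministic = TRUE), matrix(c(1, 2), 1))
  p0 <- structure(list(mu = matrix(c(0.3, -0.2), 1), log_var = matrix(0, 1, 2)),
                  class = "latent_posterior")
  n <- matrix(c(0.5, 0.25), 1)
  expect_equal(sample_latent(p0, noise = n), p0$mu + n)
})

test_that("latent samples have the posterior's mean and variance", {
  set.seed(77)
  mu <- c(1.5, -0.7); lv <- c(log(2), -0.5)
  post <- structure(list(mu = matrix(rep(mu, each = 1e4), 1e4, 2),
                         log_var = matrix(rep(lv, each = 1e4), 1e4, 2)),
                    class = "latent_posterior")
  z <- sample_latent(post)
  for (j in 1:2) {
    se_mean <- sqrt(exp(lv[j]) / 1e4)
    expect_lt(abs(mean(z[, j]) - mu[j]), 4 * se_mean)
    se_var <- exp(lv[j]) * sqrt(2 / 1e4)
    expect_lt(abs(var(z[, j]) - exp(lv[j])), 4 * se_var)
  }
})

test_that("decoder outputs sigmoid values in (0,1), 0.5 for zero weights", {
  p <- zivae_params(6, latent_dim = 2, encoder_dims = c(4, 3),
                    decoder_dims = c(3, 4), sigma_mode = "fixed", seed = 3)
  z <- matrix(rnorm(10), 5, 2)
  y <- vae_decode(z, p)
  expect_true(all(y > 0 & y < 1))
  p0 <- p; p0$weights <- lapply(p$weights, function(w) w * 0)
  expect_equal(vae_decode(z, p0), matrix(0.5, 5, 6), ignore_attr = TRUE)
  expect_error(vae_decode(matrix(0, 2, 3), p), "latent width")
})

test_that("decoder matches an independent loop-based forward pass", {
  p <- tiny_handset_params()
  z <- matrix(c(0.4, -1.2, 2.0, 0.1), 2, 2, byrow = TRUE)
  expect_equal(vae_decode(z, p), naive_decode(z, p), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("dropout probability is exp(-y^2), decreasing on [0,1]", {
  expect_equal(dropout_probability(0), 1)
  expect_equal(dropout_probability(1), exp(-1))
  expect_equal(dropout_probability(sqrt(log(2))), 0.5)
  y <- seq(0, 1, by = 0.01)
  expect_true(all(diff(dropout_probability(y)) < 0))
})

test_that("gumbel-softmax sample matches the closed form and its symmetries", {
  # equal noise cancels: s = p at p = 0.5 regardless of temperature
  u <- 0.42
  for (tau in c(0.3, 1, 2)) {
    expect_equal(gumbel_softmax_sample(0.5, tau, u0 = u, u1 = u), 0.5)
  }
  # g0 = 1, g1 = 0 at p = 0.5, tau = 1 gives e/(e+1)
  u0 <- exp(-exp(-1)); u1 <- exp(-1)
  expect_equal(gumbel_softmax_sample(0.5, 1, u0, u1), exp(1) / (exp(1) + 1),
               tolerance = 1e-12)
  # monotone in p for fixed noise
  set.seed(8)
  for (r in 1:20) {
    u0 <- runif(1); u1 <- runif(1); tau <- runif(1, 0.2, 2)
    s <- gumbel_softmax_sample(seq(0.05, 0.95, by = 0.1), tau,
                               u0 = rep(u0, 10), u1 = rep(u1, 10))
    expect_true(all(diff(s) > 0))
    # swapping (p,u0) with (q,u1) reflects the sample
    p1 <- runif(1, 0.05, 0.95)
    s1 <- gumbel_softmax_sample(p1, tau, u0, u1)
    s2 <- gumbel_softmax_sample(1 - p1, tau, u1, u0)
    expect_equal(s1, 1 - s2, tolerance = 1e-10)
  }
})

test_that("gumbel-softmax approaches Bernoulli(p) as tau shrinks", {
  set.seed(99)
  p <- 0.8; ndraw <- 1e4
  s <- gumbel_softmax_sample(rep(p, ndraw), tau = 0.01)
  hard <- round(s)
  se <- sqrt(p * (1 - p) / ndraw)
  expect_lt(abs(mean(hard) - p), 3 * se)
  # Kolmogorov distance between round(s) and Bernoulli(p) below 0.02
  emp0 <- mean(hard == 0)
  expect_lt(abs(emp0 - (1 - p)), 0.02)
})

test_that("zero inflation multiplies by one minus the dropout indicator", {
  yt <- c(0.4, 0.8)
  expect_equal(zero_inflate(yt, c(0, 0)), yt)
  expect_equal(zero_inflate(yt, c(1, 1)), c(0, 0))
  expect_equal(zero_inflate(yt, c(0.5, 0.25)), c(0.2, 0.6))
})

test_that("inference forward pass is deterministic with outputs in [0,1]", {
  p <- tiny_handset_params()
  x <- matrix(runif(12), 3, 4)
  f1 <- vae_forward(x, p, training = FALSE)
  f2 <- vae_forward(x, p, training = FALSE)
  expect_identical(f1$y, f2$y)
  expect_identical(f1$posterior$mu, f2$posterior$mu)
  expect_true(all(f1$y >= 0 & f1$y <= 1))
  # inference composes encode then decode exactly (no ZI masking)
  expect_equal(f1$y, naive_decode(naive_encode(x, p), p), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("training forward pass is reproducible under the same RNG state", {
  p <- tiny_handset_params()
  p$input_dropout_rate <- 0.5
  x <- matrix(runif(12), 3, 4)
  set.seed(31); f1 <- vae_forward(x, p, training = TRUE)
  set.seed(31); f2 <- vae_forward(x, p, training = TRUE)
  expect_identical(f1$y, f2$y)
  expect_true(all(f1$y >= 0 & f1$y <= 1))
})
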
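# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: naive loops and direct formula evaluation.

# O(n^2) pair-counting adjusted Rand index
pair_count_ari <- function(p, t) {
  n <- length(p)
  same_p <- outer(p, p, "==")[upper.tri(diag(n))]
  same_t <- outer(t, t, "==")[upper.tri(diag(n))]
  a <- sum(same_p & same_t)        # agreements: together in both
  b <- sum(!same_p & !same_t)      # agreements: apart in both
  c1 <- sum(same_p & !same_t)
  d1 <- sum(!same_p & same_t)
  npairs <- n * (n - 1) / 2
  # expected index under permutation model
  sum_a <- a + c1                  # pairs together in p
  sum_b <- a + d1                  # pairs together in t
  expected <- sum_a * sum_b / npairs
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

random_partition <- function(n, kmax = 5) {
  sample.int(kmax, n, replace = TRUE)
}

# naive dense forward pass through explicit loops, for hand-set weights
naive_affine <- function(x, W, b) {
  out <- matrix(0, nrow(x), ncol(W))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(W))) {
    out[i, j] <- sum(x[i, ] * W[, j]) + b[j]
  }
  out
}

naive_relu <- function(x) pmax(x, 0)

naive_sigmoid <- function(x) 1 / (1 + exp(-x))

# tiny hand-set model: 4 genes -> encoder 3/2 -> latent 2 -> decoder 2/3 -> 4
tiny_handset_params <- function() {
  p <- zivae_params(input_dim = 4, latent_dim = 2,
                    encoder_dims = c(3, 2), decoder_dims = c(2, 3),
                    sigma_mode = "fixed", input_dropout_rate = 0,
                    seed = 7L)
  w <- p$weights
  set.seed(42)
  for (k in names(w)) {
    w[[k]] <- if (is.matrix(w[[k]])) {
      matrix(round(stats::runif(length(w[[k]]), -1, 1), 2),
             nrow(w[[k]]), ncol(w[[k]]))
    } else round(stats::runif(length(w[[k]]), -0.5, 0.5), 2)
  }
  p$weights <- w
  p
}

# naive encoder/decoder for tiny_handset_params (fixed sigma)
naive_encode <- function(x, p) {
  w <- p$weights
  a <- naive_affine(x, w$e1_W, w$e1_b)              # linear first layer
  a <- naive_relu(naive_affine(a, w$e2_W, w$e2_b))
  naive_affine(a, w$mu_W, w$mu_b)
}

naive_decode <- function(z, p) {
  w <- p$weights
  b <- naive_relu(naive_affine(z, w$d1_W, w$d1_b))
  b <- naive_relu(naive_affine(b, w$d2_W, w$d2_b))
  naive_sigmoid(naive_affine(b, w$d3_W, w$d3_b))
}

# small scaled fixture for fast training tests
scaled_tiny <- function() {
  s <- make_fixture("tiny3")
  list(x = rescale_unit_interval(s$matrix), labels = s$labels)
}
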
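test_that("contingency table has the right margins", {
  ct <- cluster_contingency(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(ct), rbind(c(2, 0), c(0, 2)))
  ct2 <- cluster_contingency(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_true(all(ct2 == 1))
  set.seed(12)
  p <- random_partition(50); t <- random_partition(50)
  ct3 <- cluster_contingency(p, t)
  expect_equal(sum(ct3), 50)
  expect_equal(unname(rowSums(ct3)), unname(as.vector(table(p))))
  expect_equal(unname(colSums(ct3)), unname(as.vector(table(t))))
  expect_error(cluster_contingency(1:3, 1:4), "length mismatch")
})

test_that("NMI matches hand-computed values and its conventions", {
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(nmi(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
  # P=[0,0,0,1], T=[0,0,1,1]: MI and entropies summed by hand
  mi <- 0.5 * log(4 / 3) + 0.25 * log(2 / 3) + 0.25 * log(2)
  hp <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  ht <- log(2)
  expect_equal(nmi(c(0, 0, 0, 1), c(0, 0, 1, 1)), mi / sqrt(hp * ht),
               tolerance = 1e-12)
  expect_equal(mi / sqrt(hp * ht), 0.3455920, tolerance = 1e-6)
  # degenerate single-cluster conventions
  expect_equal(nmi(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(nmi(c(1, 1, 1), c(1, 2, 3)), 0)
})

test_that("ARI matches hand computation and the pair-counting oracle", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # crossed pair: (0 - 2*2/6) / ((2+2)/2 - 2*2/6) = -0.5
  expect_equal(ari(c(0, 1, 0, 1), c(0, 0, 1, 1)), -0.5, tolerance = 1e-12)
  set.seed(13)
  for (r in 1:30) {
    n <- sample(5:40, 1)
    p <- random_partition(n, sample(2:5, 1))
    t <- random_partition(n, sample(2:5, 1))
    expect_equal(ari(p, t), pair_count_ari(p, t), tolerance = 1e-12)
  }
  # degenerate denominators
  expect_equal(ari(1:4, 1:4), 1)           # all singletons
  expect_equal(ari(rep(1, 4), rep(2, 4)), 1)  # both one cluster
})

test_that("homogeneity and completeness match definitions and duality", {
  expect_equal(homogeneity(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(homogeneity(1:4, c(0, 0, 1, 1)), 1)  # singletons are pure
  # P=[0,0,0,1], T=[0,0,1,1]: H(T|P) = 0.75 * H(2/3, 1/3)
  h_exp <- 1 - 0.75 * (-(2/3) * log(2/3) - (1/3) * log(1/3)) / log(2)
  expect_equal(homogeneity(c(0, 0, 0, 1), c(0, 0, 1, 1)), h_exp,
               tolerance = 1e-12)
  expect_equal(h_exp, 0.311278, tolerance = 1e-6)
  expect_equal(completeness(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(completeness(rep(1, 5), c(1, 1, 2, 2, 3)), 1)
  set.seed(14)
  for (r in 1:20) {
    p <- random_partition(30); t <- random_partition(30)
    expect_equal(completeness(p, t), homogeneity(t, p), tolerance = 1e-12)
  }
})

test_that("all four metrics are relabeling-invariant and 1 at P = T", {
  set.seed(15)
  for (r in 1:10) {
    p <- random_partition(40, 4); t <- random_partition(40, 4)
    # remap labels arbitrarily
    map_p <- sample(100, 4); map_t <- sample(100, 4)
    p2 <- map_p[p]; t2 <- map_t[t]
    expect_equal(nmi(p, t), nmi(p2, t2), tolerance = 1e-12)
    expect_equal(ari(p, t), ari(p2, t2), tolerance = 1e-12)
    expect_equal(homogeneity(p, t), homogeneity(p2, t2), tolerance = 1e-12)
    expect_equal(completeness(p, t), completeness(p2, t2), tolerance = 1e-12)
    expect_equal(nmi(t, t), 1)
    expect_equal(ari(t, t), 1)
    expect_equal(homogeneity(t, t), 1)
    expect_equal(completeness(t, t), 1)
  }
})

test_that("k-means recovers tight well-separated 2D Gaussians exactly", {
  set.seed(16)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  lab <- rep(1:3, each = 10)
  pts <- centers[lab, ] + matrix(rnorm(60, sd = 0.01), 30, 2)
  cl <- kmeans_cluster(pts, 3, seed = 1)
  # exhaustive nearest-center check: partition must equal generating labels
  expect_equal(nmi(cl, lab), 1)
  expect_equal(ari(cl, lab), 1)
  # two far-separated pairs
  pts2 <- rbind(c(0, 0), c(0.1, 0), c(50, 50), c(50.1, 50))
  cl2 <- kmeans_cluster(pts2, 2, seed = 1)
  expect_equal(cl2[1], cl2[2])
  expect_equal(cl2[3], cl2[4])
  expect_true(cl2[1] != cl2[3])
  # k = n gives singletons
  expect_equal(sort(kmeans_cluster(pts2, 4, seed = 1)), 1:4)
  expect_error(kmeans_cluster(pts2, 5), "exceeds")
})

test_that("more k-means restarts never worsen the objective", {
  set.seed(17)
  pts <- matrix(rnorm(200), 100, 2)
  wss <- function(labels) {
    sum(vapply(unique(labels), function(k) {
      sub <- pts[labels == k, , drop = FALSE]
      sum(scale(sub, scale = FALSE)^2)
    }, numeric(1)))
  }
  w1 <- wss(kmeans_cluster(pts, 5, seed = 3, restarts = 1))
  w10 <- wss(kmeans_cluster(pts, 5, seed = 3, restarts = 10))
  expect_lte(w10, w1 + 1e-8)
})

test_that("evaluate_embedding composes k-means with the four metrics", {
  set.seed(18)
  lab <- rep(1:3, each = 100)
  emb <- rbind(matrix(rnorm(200, 0, 0.1), 100),
               matrix(rnorm(200, 5, 0.1), 100),
               matrix(rnorm(200, -5, 0.1), 100))
  rep1 <- evaluate_embedding(emb, lab, seed = 1)
  expect_equal(rep1$nmi, 1)
  expect_equal(rep1$ari, 1)
  expect_equal(rep1$homogeneity, 1)
  expect_equal(rep1$completeness, 1)
  expect_identical(rep1$k_used, 3L)
  expect_true(all(is.finite(c(rep1$nmi, rep1$ari, rep1$homogeneity,
                              rep1$completeness))))
  # permuted truth carries no information about the embedding
  rep2 <- evaluate_embedding(emb, sample(lab), seed = 1)
  expect_lt(rep2$nmi, 0.1)
  expect_error(evaluate_embedding(emb, lab[-1]), "labels")
})

test_that("gene-axis Spearman correlations and ranks are correct", {
  set.seed(19)
  axis <- rnorm(20)
  m <- expression_matrix(
    cbind(axis - min(axis),                       # identical ordering: rho 1
          max(axis) - axis,                       # reversed: rho -1
          rep(2, 20),                             # constant: flagged 0
          runif(20)),
    gene_ids = c("up", "down", "flat", "noise"), space_tag = "log")
  res <- correlate_genes_with_axes(m, matrix(axis, ncol = 1))
  expect_equal(res$cor_dim1[1], 1)
  expect_equal(res$cor_dim1[2], -1)
  expect_equal(res$cor_dim1[3], 0)
  expect_true(res$constant[3])
  expect_true(all(res$rank_dim1[1:2] < res$rank_dim1[3]))
  # hand-computed 5-cell toy: d = (-1,1,-1,1,0), rho = 1 - 24/120
  m5 <- expression_matrix(matrix(c(1, 2, 3, 4, 5), ncol = 1),
                          space_tag = "log")
  r5 <- correlate_genes_with_axes(m5, matrix(c(2, 1, 4, 3, 5), ncol = 1))
  expect_equal(r5$cor_dim1, 0.8, tolerance = 1e-12)
  expect_equal(r5$cor_dim1,
               unname(cor(1:5, c(2, 1, 4, 3, 5), method = "spearman")))
})
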
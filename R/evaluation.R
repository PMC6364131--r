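#' Seeded k-means clustering of an embedding
#'
#' Runs `stats::kmeans` with multiple random restarts and returns the
#' labeling with the lowest within-cluster sum of squares. Seeded, so
#' results are reproducible.
#'
#' @param embedding Numeric matrix, cells x dims.
#' @param k Number of clusters (`<= n_cells`).
#' @param seed Integer seed.
#' @param restarts Number of random restarts (default 10).
#' @return Integer label vector of length `n_cells`.
#' @export
kmeans_cluster <- function(embedding, k, seed = 1L, restarts = 10L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k > n) stop(sprintf("k (%d) exceeds the number of cells (%d)", k, n))
  set.seed(as.integer(seed))
  n_distinct <- nrow(unique(embedding))
  if (k >= n_distinct) {
    # every distinct point its own center; assign by matching
    centers <- unique(embedding)
    d <- as.matrix(stats::dist(rbind(centers, embedding)))
    d <- d[-seq_len(nrow(centers)), seq_len(nrow(centers)), drop = FALSE]
    return(unname(apply(d, 1L, which.min)))
  }
  fit <- stats::kmeans(embedding, centers = k, nstart = as.integer(restarts),
                       iter.max = 100L)
  as.integer(fit$cluster)
}

# validate a pair of partitions and coerce to integer codes
.pair_codes <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop(sprintf("partition length mismatch: predicted has %d cells, truth has %d",
                 length(predicted), length(truth)))
  }
  list(p = as.integer(factor(predicted)),
       t = as.integer(factor(truth)),
       n = length(predicted))
}

#' Contingency table of two partitions
#'
#' Cross-tabulates predicted cluster against true type: entry `n_ij` is
#' the number of cells in predicted cluster `i` and true type `j`. Row
#' sums give the predicted cluster sizes `a_i`, column sums the type
#' sizes `b_j`.
#'
#' @param predicted,truth Label vectors of equal length; label values
#'   are arbitrary (only the grouping matters).
#' @return Integer matrix `n_ij`.
#' @export
cluster_contingency <- function(predicted, truth) {
  cd <- .pair_codes(predicted, truth)
  unclass(table(cd$p, cd$t))
}

.entropy <- function(counts) {
  # natural-log entropy of a count vector
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' `NMI(P, T) = MI(P, T) / sqrt(H(P) H(T))` with natural-log entropies.
#' When both partitions are the trivial single cluster they are
#' identical and NMI is defined as 1; when exactly one has zero entropy
#' the mutual information is 0 and NMI is defined as 0.
#'
#' @inheritParams cluster_contingency
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(predicted, truth) {
  ct <- cluster_contingency(predicted, truth)
  n <- sum(ct)
  hp <- .entropy(rowSums(ct))
  ht <- .entropy(colSums(ct))
  if (hp == 0 && ht == 0) return(1)
  if (hp == 0 || ht == 0) return(0)
  mi <- 0
  a <- rowSums(ct); b <- colSums(ct)
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + nij / n * log(nij * n / (a[i] * b[j]))
  }
  as.numeric(mi / sqrt(hp * ht))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance under the permutation
#' model:
#' `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)` and
#' `max = [sum_i C(a_i,2) + sum_j C(b_j,2)] / 2`.
#' Equals 1 iff the partitions are identical up to relabeling. In the
#' degenerate case where the denominator vanishes (both partitions
#' all-singletons or all-one-cluster) the pair-counting limit gives 1
#' for equal partitions and 0 otherwise.
#'
#' @inheritParams cluster_contingency
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(predicted, truth) {
  ct <- cluster_contingency(predicted, truth)
  n <- sum(ct)
  if (n < 2) stop("ARI requires at least 2 cells")
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) {
    # only reachable when both partitions are all-singletons or both a
    # single cluster; either way they are identical, so agreement is 1
    return(1)
  }
  as.numeric((sum_ij - expected) / denom)
}

.conditional_entropy <- function(ct) {
  # H(columns | rows) of a contingency table, natural log
  n <- sum(ct)
  h <- 0
  a <- rowSums(ct)
  for (i in seq_len(nrow(ct))) {
    if (a[i] == 0) next
    for (j in seq_len(ncol(ct))) {
      nij <- ct[i, j]
      if (nij > 0) h <- h - nij / n * log(nij / a[i])
    }
  }
  h
}

#' Homogeneity of a clustering with respect to true types
#'
#' `h = 1 - H(T|P) / H(T)`: equals 1 when every predicted cluster
#' contains cells of a single true type. Defined as 1 when `H(T) = 0`.
#'
#' @inheritParams cluster_contingency
#' @return Homogeneity in `[0, 1]`.
#' @export
homogeneity <- function(predicted, truth) {
  ct <- cluster_contingency(predicted, truth)
  ht <- .entropy(colSums(ct))
  if (ht == 0) return(1)
  as.numeric(1 - .conditional_entropy(ct) / ht)
}

#' Completeness of a clustering with respect to true types
#'
#' `c = 1 - H(P|T) / H(P)`: equals 1 when all cells of each true type
#' land in a single predicted cluster. Defined as 1 when `H(P) = 0`.
#' Dual to homogeneity: `completeness(P, T) = homogeneity(T, P)`.
#'
#' @inheritParams cluster_contingency
#' @return Completeness in `[0, 1]`.
#' @export
completeness <- function(predicted, truth) {
  homogeneity(truth, predicted)
}

#' Cluster an embedding and score it against known cell types
#'
#' Applies [kmeans_cluster()] to the embedding with `k` set to the
#' number of distinct true labels, then computes NMI, ARI, homogeneity
#' and completeness of the predicted partition against the truth.
#'
#' @param embedding Numeric matrix, cells x dims.
#' @param truth Known cell-type labels, one per cell.
#' @param seed Seed for k-means.
#' @param restarts k-means restarts.
#' @return A list of class `metrics_report` with fields `nmi`, `ari`,
#'   `homogeneity`, `completeness`, `k_used`, `kmeans_seed`.
#' @export
evaluate_embedding <- function(embedding, truth, seed = 1L, restarts = 10L) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != length(truth)) {
    stop(sprintf("embedding has %d cells but truth has %d labels",
                 nrow(embedding), length(truth)))
  }
  k <- length(unique(truth))
  pred <- kmeans_cluster(embedding, k, seed = seed, restarts = restarts)
  structure(list(nmi = nmi(pred, truth),
                 ari = ari(pred, truth),
                 homogeneity = homogeneity(pred, truth),
                 completeness = completeness(pred, truth),
                 k_used = k,
                 kmeans_seed = as.integer(seed),
                 predicted = pred),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (k = %d, seed = %d)\n", x$k_used, x$kmeans_seed))
  cat(sprintf("  NMI          %.4f\n", x$nmi))
  cat(sprintf("  ARI          %.4f\n", x$ari))
  cat(sprintf("  homogeneity  %.4f\n", x$homogeneity))
  cat(sprintf("  completeness %.4f\n", x$completeness))
  invisible(x)
}

#' Rank genes by Spearman correlation with embedding axes
#'
#' For every gene, computes the Spearman rank correlation between its
#' expression across cells and each embedding axis, then ranks genes per
#' axis by absolute correlation (rank 1 = strongest association, ties by
#' average rank). Genes with constant expression have no defined rank
#' correlation; their correlation is reported as 0 and flagged.
#'
#' @param m An [expression_matrix()] (typically `log` space) with the
#'   same cells, in the same order, as the embedding.
#' @param embedding Numeric matrix, cells x dims.
#' @return A data frame with one row per gene: `gene_id`, `constant`,
#'   and per axis `cor_dim<k>` and `rank_dim<k>`.
#' @export
correlate_genes_with_axes <- function(m, embedding) {
  stopifnot_em(m)
  embedding <- as.matrix(embedding)
  if (nrow(m$values) != nrow(embedding)) {
    stop(sprintf("matrix has %d cells but embedding has %d",
                 nrow(m$values), nrow(embedding)))
  }
  constant <- apply(m$values, 2L, function(g) length(unique(g)) == 1)
  out <- data.frame(gene_id = m$gene_ids, constant = constant,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (d in seq_len(ncol(embedding))) {
    rho <- suppressWarnings(
      as.vector(stats::cor(m$values, embedding[, d], method = "spearman")))
    rho[constant] <- 0
    out[[paste0("cor_dim", d)]] <- rho
    out[[paste0("rank_dim", d)]] <- rank(-abs(rho), ties.method = "average")
  }
  out
}
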
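#' Configuration for the synthetic expression simulator
#'
#' The simulator emulates the structure the model is built for:
#' cluster-structured log-scale expression with zero inflation whose
#' dropout probability decays with expression magnitude. Each gene gets
#' one center per cluster drawn from
#' `Normal(mean_log_expression, between_cluster_sd^2)`; cells draw their
#' values around their cluster's centers with `within_cluster_sd` and
#' are clipped at zero (log-scale expression is non-negative).
#'
#' Defaults describe a typical desk-scale test regime: 300 cells, 500
#' genes, 3 balanced clusters, log2 expression centered at 2 (a few
#' tens of counts), a between/within spread ratio of 5 giving
#' well-separated but noisy clusters.
#'
#' @param n_cells,n_genes Matrix dimensions (defaults 300, 500).
#' @param k_clusters Number of cell clusters (default 3).
#' @param cluster_proportions Probability vector of length `k_clusters`
#'   (default balanced).
#' @param mean_log_expression Mean of the cluster-center distribution on
#'   the log2 scale (default 2).
#' @param between_cluster_sd Spread of centers across clusters (default
#'   1); controls cluster separation.
#' @param within_cluster_sd Cell-level noise around the center (default
#'   0.2).
#' @param dropout_strength Decay rate `lambda` of the dropout
#'   probability `exp(-lambda * x^2)` applied by [apply_dropout()];
#'   0 disables the dropout step entirely here (default 0.5, a moderate
#'   regime).
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 300, n_genes = 500, k_clusters = 3,
                       cluster_proportions = NULL,
                       mean_log_expression = 2,
                       between_cluster_sd = 1,
                       within_cluster_sd = 0.2,
                       dropout_strength = 0.5,
                       seed = 1L) {
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / k_clusters, k_clusters)
  }
  if (length(cluster_proportions) != k_clusters) {
    stop("`cluster_proportions` must have length `k_clusters`")
  }
  if (any(cluster_proportions < 0) ||
      abs(sum(cluster_proportions) - 1) > 1e-8) {
    stop("`cluster_proportions` must be non-negative and sum to 1")
  }
  if (k_clusters > n_cells) stop("`k_clusters` must not exceed `n_cells`")
  if (between_cluster_sd <= 0 || within_cluster_sd < 0) {
    stop("cluster spread parameters must be positive")
  }
  if (dropout_strength < 0) stop("`dropout_strength` must be non-negative")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 k_clusters = as.integer(k_clusters),
                 cluster_proportions = cluster_proportions,
                 mean_log_expression = mean_log_expression,
                 between_cluster_sd = between_cluster_sd,
                 within_cluster_sd = within_cluster_sd,
                 dropout_strength = dropout_strength,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate cluster-structured log-scale expression
#'
#' Draws per-gene cluster centers, assigns cells to clusters by the
#' configured proportions (largest-remainder rounding, so cluster sizes
#' are deterministic), and samples each cell's values around its
#' cluster's centers, clipped at zero. Fully determined by
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `matrix` (an [expression_matrix()] in `log`
#'   space) and `labels` (integer cluster per cell).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$k_clusters
  n <- config$n_cells
  g <- config$n_genes

  # deterministic cluster sizes by largest remainder
  raw <- config$cluster_proportions * n
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1
  }
  labels <- rep(seq_len(k), times = sizes)

  centers <- matrix(stats::rnorm(k * g, config$mean_log_expression,
                                 config$between_cluster_sd), k, g)
  values <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * g, 0, config$within_cluster_sd), n, g)
  values <- pmax(values, 0)

  m <- expression_matrix(values,
                         cell_ids = sprintf("cell%04d", seq_len(n)),
                         gene_ids = sprintf("gene%04d", seq_len(g)),
                         space_tag = "log")
  list(matrix = m, labels = labels)
}

#' Apply expression-dependent dropout to a matrix
#'
#' Independently zeroes each entry `x` with probability
#' `exp(-lambda * x^2)`: lowly expressed values are very likely to drop
#' out, highly expressed ones rarely do, mirroring the technical
#' dropout process in scRNA-seq. Note the degenerate case `lambda = 0`
#' zeroes every entry (the probability is identically 1). On data
#' scaled to `[0, 1]`, `lambda = 1` reproduces the model's own
#' zero-inflation law. Uniform draws are made per entry position in
#' column-major order from `seed`.
#'
#' @param m An [expression_matrix()] with log-scale (non-negative)
#'   values, or a plain numeric matrix.
#' @param lambda_ Non-negative decay rate of dropout with expression.
#' @param seed Integer seed.
#' @return Object of the same type with entries zeroed.
#' @export
apply_dropout <- function(m, lambda_, seed = 1L) {
  if (lambda_ < 0) stop("`lambda_` must be non-negative")
  v <- if (inherits(m, "ExpressionMatrix")) m$values else m
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(length(v)), nrow(v), ncol(v))
  v[u < exp(-lambda_ * v^2)] <- 0
  if (inherits(m, "ExpressionMatrix")) em_replace(m, v) else v
}

# fixture registry: small, pinned datasets for tests and examples
.fixture_registry <- list(
  tiny3 = function() {
    cfg <- sim_config(n_cells = 60, n_genes = 200, k_clusters = 3,
                      dropout_strength = 0.5, seed = 101L)
    sim <- simulate_expression(cfg)
    sim$matrix <- apply_dropout(sim$matrix, cfg$dropout_strength, seed = 102L)
    sim$config <- cfg
    sim
  },
  clusters3 = function() {
    cfg <- sim_config(n_cells = 300, n_genes = 500, k_clusters = 3,
                      dropout_strength = 0.5, seed = 201L)
    sim <- simulate_expression(cfg)
    sim$matrix <- apply_dropout(sim$matrix, cfg$dropout_strength, seed = 202L)
    sim$config <- cfg
    sim
  },
  heavy_dropout = function() {
    cfg <- sim_config(n_cells = 300, n_genes = 500, k_clusters = 3,
                      dropout_strength = 0.08, seed = 301L)
    sim <- simulate_expression(cfg)
    sim$matrix <- apply_dropout(sim$matrix, cfg$dropout_strength, seed = 302L)
    sim$config <- cfg
    sim
  }
)

#' Bundled deterministic fixtures
#'
#' Returns a pinned small dataset from the registry, regenerated
#' in-memory from fixed seeds so it is identical on every call and
#' platform:
#' * `"tiny3"` — 60 cells x 200 genes, 3 balanced clusters, moderate
#'   dropout; fast smoke-test fixture.
#' * `"clusters3"` — 300 cells x 500 genes, 3 balanced clusters,
#'   moderate dropout; the standard training fixture.
#' * `"heavy_dropout"` — 300 cells x 500 genes with aggressive dropout
#'   (well over half of all entries zeroed); stresses the
#'   zero-inflation layer.
#'
#' @param name Fixture name.
#' @return A list with `matrix` (log space), `labels` and the
#'   generating `config`.
#' @export
make_fixture <- function(name) {
  if (!name %in% names(.fixture_registry)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(.fixture_registry), collapse = ", ")))
  }
  .fixture_registry[[name]]()
}
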
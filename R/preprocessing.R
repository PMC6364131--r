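#' Log-transform an expression matrix
#'
#' Applies `log2(x + pseudocount)` elementwise. Log transformation damps
#' the heavy right tail of expression values and makes the subsequent
#' per-cell rescaling robust to a few extreme genes.
#'
#' @param m An [expression_matrix()] in `counts`, `umi` or `tpm_like` space.
#' @param pseudocount Positive offset added before taking the log
#'   (default 1, so zeros map to zero).
#' @return An `ExpressionMatrix` in `log` space, same shape and ids.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(0, 1, 3, 7), 2, byrow = TRUE),
#'                        space_tag = "counts")
#' log_transform(m)$values
log_transform <- function(m, pseudocount = 1) {
  stopifnot_em(m, c("counts", "umi", "tpm_like"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number")
  }
  em_replace(m, log2(m$values + pseudocount), space_tag = "log")
}

#' Rescale every cell to the unit interval
#'
#' Divides each cell's row by that cell's maximum value so the largest
#' entry of every cell is exactly 1. This is what makes a sigmoid output
#' layer a valid reconstruction space. All-zero cells are passed through
#' unchanged (their maximum is zero and dividing would be 0/0); callers
#' are advised to filter such cells beforehand.
#'
#' @param m An `ExpressionMatrix` in `log` space.
#' @return An `ExpressionMatrix` in `scaled` space; per-cell maxima are
#'   in `{0, 1}`.
#' @export
rescale_unit_interval <- function(m) {
  stopifnot_em(m, "log")
  mx <- apply(m$values, 1L, max)
  div <- ifelse(mx > 0, mx, 1)
  em_replace(m, m$values / div, space_tag = "scaled")
}

#' Filter cells by number of detected genes
#'
#' Retains cells in which at least `min_genes` genes have a nonzero
#' value. Run before [umi_normalize()] so that no zero-total cell
#' reaches the normalization step.
#'
#' @param m An `ExpressionMatrix` in `counts` or `umi` space.
#' @param min_genes Minimum number of detected (nonzero) genes.
#' @return The filtered `ExpressionMatrix`; cell order preserved.
#' @export
filter_cells_min_genes <- function(m, min_genes) {
  stopifnot_em(m, c("counts", "umi"))
  if (!is.numeric(min_genes) || length(min_genes) != 1 || min_genes < 1) {
    stop("`min_genes` must be a positive integer")
  }
  detected <- rowSums(m$values > 0)
  keep <- detected >= min_genes
  if (!any(keep)) {
    stop(sprintf("no cells have >= %d detected genes; filtering would leave an empty matrix",
                 as.integer(min_genes)))
  }
  em_replace(m, m$values[keep, , drop = FALSE],
             cell_ids = m$cell_ids[keep])
}

#' Library-size normalization for UMI counts
#'
#' Divides each cell by its total UMI count and multiplies by `scale`,
#' yielding transcripts-per-`scale` values whose per-cell totals all
#' equal `scale` (TPM-like when `scale = 1e4`).
#'
#' @param m An `ExpressionMatrix` in `umi` space; every cell must have a
#'   positive total.
#' @param scale Target per-cell total (default 10000).
#' @return An `ExpressionMatrix` in `tpm_like` space.
#' @export
umi_normalize <- function(m, scale = 10000) {
  stopifnot_em(m, "umi")
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("`scale` must be a single positive number")
  }
  totals <- rowSums(m$values)
  if (any(totals == 0)) {
    bad <- m$cell_ids[which(totals == 0)[1]]
    stop(sprintf("cell '%s' has zero total count; run filter_cells_min_genes() first",
                 bad))
  }
  em_replace(m, m$values / totals * scale, space_tag = "tpm_like")
}

#' Keep the most variable genes
#'
#' Ranks genes by a dispersion statistic (variance over mean of the
#' log-scale values) and retains the top `n_keep`. Dispersion favours
#' genes whose variation exceeds what their expression level alone would
#' predict; ties are broken by gene order, so the selection is
#' deterministic.
#'
#' @param m An `ExpressionMatrix` in `log` or `tpm_like` space.
#' @param n_keep Number of genes to retain (`<= n_genes`).
#' @return The `ExpressionMatrix` restricted to the selected genes, in
#'   their original column order.
#' @export
select_variable_genes <- function(m, n_keep) {
  stopifnot_em(m, c("log", "tpm_like"))
  ng <- ncol(m$values)
  if (!is.numeric(n_keep) || length(n_keep) != 1 || n_keep < 1) {
    stop("`n_keep` must be a positive integer")
  }
  if (n_keep > ng) {
    stop(sprintf("n_keep (%d) exceeds the number of genes (%d)",
                 as.integer(n_keep), ng))
  }
  v <- if (m$space_tag == "log") m$values else log2(m$values + 1)
  mu <- colMeans(v)
  va <- apply(v, 2L, stats::var)
  disp <- ifelse(mu > 0, va / mu, 0)
  # order(-disp) is stable: ties resolve to the earlier gene
  keep <- sort(order(-disp)[seq_len(n_keep)])
  em_replace(m, m$values[, keep, drop = FALSE],
             gene_ids = m$gene_ids[keep])
}

#' Standard preprocessing pipeline
#'
#' Convenience composition: optional min-gene filtering, library-size
#' normalization for UMI data, log2(x+1), optional highly-variable-gene
#' selection, then per-cell unit-interval rescaling.
#'
#' @param m An `ExpressionMatrix` in `counts`, `umi` or `tpm_like` space.
#' @param min_genes If not `NULL`, cells with fewer detected genes are
#'   removed first (count/UMI input only).
#' @param n_genes If not `NULL`, keep only this many top-dispersion genes.
#' @param umi_scale Per-cell total used when normalizing UMI input.
#' @param pseudocount Passed to [log_transform()].
#' @return An `ExpressionMatrix` in `scaled` space, ready for training.
#' @export
preprocess_matrix <- function(m, min_genes = NULL, n_genes = NULL,
                              umi_scale = 10000, pseudocount = 1) {
  stopifnot_em(m, c("counts", "umi", "tpm_like"))
  if (!is.null(min_genes) && m$space_tag %in% c("counts", "umi")) {
    m <- filter_cells_min_genes(m, min_genes)
  }
  if (m$space_tag == "umi") m <- umi_normalize(m, umi_scale)
  m <- log_transform(m, pseudocount)
  if (!is.null(n_genes)) m <- select_variable_genes(m, n_genes)
  rescale_unit_interval(m)
}
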
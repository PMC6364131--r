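#' Cell-by-gene expression matrix
#'
#' Container for single-cell expression data. Values are stored cells in
#' rows, genes in columns, and a `space_tag` records which transformation
#' stage the values are in, so downstream operations can check their
#' preconditions (e.g. the model only accepts `"scaled"` matrices).
#'
#' @param values Numeric matrix, cells x genes, non-negative, no missing
#'   entries.
#' @param cell_ids Character vector of cell identifiers, one per row.
#' @param gene_ids Character vector of gene identifiers, one per column.
#' @param space_tag One of `"counts"`, `"umi"`, `"tpm_like"`, `"log"`,
#'   `"scaled"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `cell_ids`, `gene_ids`, `space_tag`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(0:5, nrow = 2), space_tag = "counts")
#' dim(m$values)
expression_matrix <- function(values,
                              cell_ids = NULL,
                              gene_ids = NULL,
                              space_tag = c("counts", "umi", "tpm_like",
                                            "log", "scaled")) {
  space_tag <- match.arg(space_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (cells x genes)")
  }
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) {
    cell_ids <- if (!is.null(rownames(values))) rownames(values)
                else paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- if (!is.null(colnames(values))) colnames(values)
                else paste0("gene", seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) must equal nrow(values)")
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) must equal ncol(values)")
  }
  if (anyNA(values)) stop("expression values must not contain missing entries")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at cell '%s', gene '%s'",
                 cell_ids[bad[1]], gene_ids[bad[2]]))
  }
  if (space_tag == "scaled" && any(values > 1 + 1e-12)) {
    stop("space_tag = 'scaled' requires all values <= 1")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 space_tag = space_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$space_tag))
  zf <- mean(x$values == 0)
  cat(sprintf("  zero fraction: %.3f\n", zf))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# internal: rebuild with new values/subset, preserving class invariants
em_replace <- function(m, values, cell_ids = m$cell_ids,
                       gene_ids = m$gene_ids, space_tag = m$space_tag) {
  expression_matrix(values, cell_ids, gene_ids, space_tag)
}

stopifnot_em <- function(m, tags = NULL, arg = "m") {
  if (!inherits(m, "ExpressionMatrix")) {
    stop(sprintf("`%s` must be an ExpressionMatrix", arg))
  }
  if (!is.null(tags) && !(m$space_tag %in% tags)) {
    stop(sprintf("`%s` has space_tag '%s'; expected one of: %s",
                 arg, m$space_tag, paste(tags, collapse = ", ")))
  }
  invisible(m)
}
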
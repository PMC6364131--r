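#' Read an expression matrix from disk
#'
#' Two formats are supported:
#' * `"dense"` — delimited text (TSV or CSV, sniffed from the
#'   extension) with a header row of gene ids and a first column of
#'   cell ids. Set `transposed = TRUE` for files shipped genes x cells.
#' * `"mtx"` — 10x Genomics v2 layout: a directory containing
#'   `matrix.mtx` (MatrixMarket coordinate, genes x cells, 1-based
#'   indices), `genes.tsv` (1 or 2 columns: id, optional symbol) and
#'   `barcodes.tsv` (one barcode per line). Densified on read.
#'
#' @param path File path (dense) or directory path (mtx).
#' @param format `"dense"` or `"mtx"`.
#' @param transposed Dense only: file is genes x cells.
#' @param space_tag Space tag to stamp on the result (default
#'   `"counts"`).
#' @return An [expression_matrix()], cells x genes.
#' @export
read_matrix <- function(path, format = c("dense", "mtx"),
                        transposed = FALSE, space_tag = "counts") {
  format <- match.arg(format)
  if (format == "dense") {
    .read_dense(path, transposed, space_tag)
  } else {
    .read_mtx(path, space_tag)
  }
}

.read_dense <- function(path, transposed, space_tag) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop(sprintf("malformed header in %s: no data columns", path))
  v <- as.matrix(df)
  if (!is.numeric(v)) stop(sprintf("non-numeric entries in %s", path))
  if (transposed) v <- t(v)
  expression_matrix(v, cell_ids = rownames(v), gene_ids = colnames(v),
                    space_tag = space_tag)
}

.read_mtx <- function(dir, space_tag) {
  mtx_path <- file.path(dir, "matrix.mtx")
  genes_path <- file.path(dir, "genes.tsv")
  barcodes_path <- file.path(dir, "barcodes.tsv")
  for (p in c(mtx_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) {
      stop(sprintf("missing companion file: %s (10x v2 layout needs matrix.mtx, genes.tsv, barcodes.tsv)", p))
    }
  }
  sp <- Matrix::readMM(mtx_path)           # genes x cells
  genes <- utils::read.table(genes_path, sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.table(barcodes_path, sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(genes) != nrow(sp)) {
    stop(sprintf("dimension mismatch: matrix.mtx declares %d genes but genes.tsv has %d",
                 nrow(sp), nrow(genes)))
  }
  if (length(barcodes) != ncol(sp)) {
    stop(sprintf("dimension mismatch: matrix.mtx declares %d cells but barcodes.tsv has %d",
                 ncol(sp), length(barcodes)))
  }
  v <- t(as.matrix(sp))                    # cells x genes
  expression_matrix(v, cell_ids = barcodes, gene_ids = genes[[1]],
                    space_tag = space_tag)
}

#' Write an expression matrix as dense delimited text
#'
#' Cells in rows, header row of gene ids, first column of cell ids —
#' the same layout [read_matrix()] expects.
#'
#' @param m An [expression_matrix()].
#' @param path Output path; `.csv` writes comma-separated, anything
#'   else tab-separated.
#' @export
write_matrix <- function(m, path) {
  stopifnot_em(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(m$values)
  utils::write.table(data.frame(cell_id = m$cell_ids, df,
                                check.names = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labels file (one label per line)
#'
#' @param path File path.
#' @return Character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  readLines(path)
}

#' @rdname read_labels
#' @param labels Vector of labels, order matching the matrix's cells.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

# full-precision number formatting so that write -> read -> write is
# byte-stable
.fmt_full <- function(x) sprintf("%.17g", x)

#' Write an embedding as TSV
#'
#' Columns `cell_id`, `dim1`, `dim2`, ... Numbers are written with full
#' double precision so the file round-trips bit-for-bit.
#'
#' @param embedding Numeric matrix, cells x dims, with cell ids as row
#'   names (or `cell_ids` given).
#' @param path Output path.
#' @param cell_ids Optional explicit cell ids.
#' @export
write_embedding <- function(embedding, path, cell_ids = NULL) {
  embedding <- as.matrix(embedding)
  if (is.null(cell_ids)) {
    cell_ids <- if (!is.null(rownames(embedding))) rownames(embedding)
                else paste0("cell", seq_len(nrow(embedding)))
  }
  header <- paste(c("cell_id", paste0("dim", seq_len(ncol(embedding)))),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(embedding)), function(i) {
    paste(c(cell_ids[i], .fmt_full(embedding[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_embedding
#' @return `read_embedding` returns the numeric matrix with cell ids as
#'   row names.
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  emb <- as.matrix(df[, -1, drop = FALSE])
  rownames(emb) <- df[[1]]
  emb
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding the full configuration
#' and every weight tensor at full double precision, sufficient to
#' reload the model and reproduce embeddings bit-for-bit on the same
#' platform.
#'
#' @param params A [zivae_params()] object.
#' @param path Output path (JSON).
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "zivae_params"))
  w <- lapply(params$weights, function(u) {
    if (is.matrix(u)) list(dim = dim(u), data = as.vector(u))
    else list(dim = NULL, data = as.vector(u))
  })
  obj <- unclass(params)
  obj$weights <- w
  # I(17) significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `zivae_params`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- lapply(obj$weights, function(u) {
    d <- u$dim
    if (!is.null(d) && length(d) == 2) matrix(u$data, d[1], d[2])
    else as.numeric(u$data)
  })
  params <- list(input_dim = as.integer(obj$input_dim),
                 latent_dim = as.integer(obj$latent_dim),
                 encoder_dims = as.integer(obj$encoder_dims),
                 decoder_dims = as.integer(obj$decoder_dims),
                 input_dropout_rate = obj$input_dropout_rate,
                 sigma_mode = obj$sigma_mode,
                 tau = obj$tau,
                 tau_schedule = obj$tau_schedule,
                 tau_start = obj$tau_start, tau_end = obj$tau_end,
                 tau_span = as.integer(obj$tau_span),
                 l1_weight = obj$l1_weight,
                 use_zi = obj$use_zi,
                 seed = as.integer(obj$seed),
                 weights = w)
  class(params) <- "zivae_params"
  params
}

#' Write / read a run manifest
#'
#' A manifest records everything needed to replay a run: input paths,
#' orientation, preprocessing options, model and training
#' configuration, seeds, output paths and the package version. Replayed
#' manifests reproduce outputs bit-for-bit on the same platform.
#'
#' @param manifest Named list of run options.
#' @param path Output path (JSON).
#' @export
write_manifest <- function(manifest, path) {
  manifest$tool_version <- as.character(utils::packageVersion("zivae"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a metrics report
#'
#' Writes both a human-readable `key: value` text block and, when
#' `json_path` is given, a machine-readable JSON version.
#'
#' @param report A `metrics_report` from [evaluate_embedding()].
#' @param path Output path for the text report.
#' @param json_path Optional output path for the JSON report.
#' @export
write_metrics <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  keys <- c("nmi", "ari", "homogeneity", "completeness", "k_used",
            "kmeans_seed")
  lines <- vapply(keys, function(k) {
    v <- report[[k]]
    sprintf("%s: %s", k, if (is.numeric(v) && v %% 1 != 0)
      format(v, digits = 10) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(report[keys], json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write a training history log
#'
#' Line-oriented TSV: epoch, total loss, reconstruction term, KL term,
#' temperature.
#'
#' @param history A `train_history` from [train_vae()].
#' @param path Output path.
#' @export
write_history <- function(history, path) {
  stopifnot(inherits(history, "train_history"))
  utils::write.table(history$epochs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
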
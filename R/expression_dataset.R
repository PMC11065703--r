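#' Expression dataset container
#'
#' Bundles a non-negative gene-by-cell expression matrix (sparse `dgCMatrix`)
#' with per-cell annotations. This is the post-QC substrate for gene-set
#' scoring: upstream alignment, ambient-RNA and doublet filtering are assumed
#' done. A `normalised` flag records whether the matrix holds raw counts or
#' log-normalised values; scoring functions state which form they require.
#'
#' @param matrix Non-negative numeric matrix or `Matrix::sparseMatrix`,
#'   genes in rows, cells in columns.
#' @param gene_ids Character vector of unique gene symbols, one per row.
#' @param cell_ids Character vector of unique cell barcodes, one per column.
#' @param cell_meta Data frame of per-cell annotations with at least
#'   `cell_id`, `sample_id` and `diagnosis` (`"AD"` or `"NDC"`); typically also
#'   `cell_type`, `region` (`EC`, `MTG`, `SSC` or `other`), `age`, `sex` and
#'   `amyloid_load` (% stained area).
#' @param normalised Logical; `TRUE` if the matrix is log-normalised.
#'
#' @return An object of class `expression_dataset`.
#' @export
#' @examples
#' m <- matrix(rpois(6, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
#' meta <- tibble::tibble(cell_id = c("c1", "c2"), sample_id = "s1",
#'                        diagnosis = "NDC", cell_type = "Micro")
#' expression_dataset(m, rownames(m), colnames(m), meta)
expression_dataset <- function(matrix, gene_ids, cell_ids, cell_meta,
                               normalised = FALSE) {
  mat <- methods::as(methods::as(Matrix::Matrix(matrix, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  gene_ids <- trimws(as.character(gene_ids))
  cell_ids <- trimws(as.character(cell_ids))
  if (nrow(mat) != length(gene_ids)) {
    stop_("matrix has %d rows but %d gene ids were given",
          nrow(mat), length(gene_ids))
  }
  if (ncol(mat) != length(cell_ids)) {
    stop_("matrix has %d columns but %d cell ids were given",
          ncol(mat), length(cell_ids))
  }
  if (anyDuplicated(gene_ids)) stop_("gene ids are not unique")
  if (anyDuplicated(cell_ids)) stop_("cell ids are not unique")
  if (length(mat@x) && min(mat@x) < 0) stop_("expression matrix has negative entries")
  dimnames(mat) <- list(gene_ids, cell_ids)

  cell_meta <- as_tibble(cell_meta)
  check_columns(cell_meta, c("cell_id", "sample_id", "diagnosis"), "cell_meta")
  if (!setequal(cell_meta$cell_id, cell_ids) ||
      nrow(cell_meta) != length(cell_ids)) {
    stop_("cell_meta$cell_id must match the matrix cell ids one-to-one")
  }
  if (anyNA(cell_meta$sample_id) || anyNA(cell_meta$diagnosis)) {
    stop_("every cell needs a sample_id and a diagnosis")
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), ]

  structure(
    list(matrix = mat, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_meta = cell_meta, normalised = isTRUE(normalised)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d cells (%s)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (x$normalised) "log-normalised" else "raw counts"))
  cat(sprintf("  samples: %d, diagnoses: %s\n",
              dplyr::n_distinct(x$cell_meta$sample_id),
              paste(sort(unique(x$cell_meta$diagnosis)), collapse = "/")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Library-size log-normalisation
#'
#' Scales each cell's counts to a common library size and applies `log1p`,
#' the standard transform ahead of module scoring. Rank-based AUC scoring is
#' invariant to this per-cell monotone transform, but the normalised form is
#' the default scoring input. Sets the dataset's `normalised` flag.
#'
#' @param dataset An [expression_dataset()] holding raw counts.
#' @param scale_factor Target library size (default 10000).
#' @return The dataset with a log-normalised matrix and `normalised = TRUE`.
#' @export
normalise_expression <- function(dataset, scale_factor = 1e4) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$normalised) {
    warn_("dataset is already log-normalised; returning unchanged")
    return(dataset)
  }
  libs <- Matrix::colSums(dataset$matrix)
  libs[libs == 0] <- 1
  mat <- dataset$matrix %*% Matrix::Diagonal(x = scale_factor / libs)
  mat@x <- log1p(mat@x)
  dimnames(mat) <- dimnames(dataset$matrix)
  dataset$matrix <- methods::as(mat, "CsparseMatrix")
  dataset$normalised <- TRUE
  dataset
}
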
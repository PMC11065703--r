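#' Read an expression dataset from MatrixMarket + sidecar files
#'
#' Reads the on-disk layout used throughout the package: a sparse
#' MatrixMarket `.mtx` matrix (genes x cells), one-column gene and cell id
#' sidecars (TSV, no header; a `gene_id`/`cell_id` header line is tolerated),
#' and a per-cell metadata CSV/TSV with a header. Dimension or id mismatches
#' are rejected with an error naming the offending file.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param genes_path Path to the gene-id sidecar (rows of the matrix).
#' @param cells_path Path to the cell-id sidecar (columns of the matrix).
#' @param meta_path Path to the per-cell metadata table (`cell_id`,
#'   `sample_id`, `diagnosis`, ...); delimiter inferred from the extension.
#' @param normalised Logical flag recorded on the dataset.
#' @return An [expression_dataset()].
#' @seealso [write_expression()]
#' @export
read_expression <- function(matrix_path, genes_path, cells_path, meta_path,
                            normalised = FALSE) {
  mat <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    stop_("failed to parse MatrixMarket file '%s': %s",
          matrix_path, conditionMessage(e))
  })
  genes <- read_id_sidecar(genes_path, "gene_id")
  cells <- read_id_sidecar(cells_path, "cell_id")
  if (nrow(mat) != length(genes)) {
    stop_("matrix '%s' has %d rows but '%s' lists %d gene ids",
          matrix_path, nrow(mat), genes_path, length(genes))
  }
  if (ncol(mat) != length(cells)) {
    stop_("matrix '%s' has %d columns but '%s' lists %d cell ids",
          matrix_path, ncol(mat), cells_path, length(cells))
  }
  meta <- read_table_auto(meta_path)
  expression_dataset(mat, genes, cells, meta, normalised = normalised)
}

#' Write an expression dataset to MatrixMarket + sidecar files
#'
#' Inverse of [read_expression()]: writes `matrix.mtx`, `genes.tsv`,
#' `cells.tsv` and `cell_meta.csv` into `dir`. Round-trips losslessly.
#'
#' @param dataset An [expression_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the four file paths.
#' @export
write_expression <- function(dataset, dir) {
  stopifnot(inherits(dataset, "expression_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    matrix = file.path(dir, "matrix.mtx"),
    genes  = file.path(dir, "genes.tsv"),
    cells  = file.path(dir, "cells.tsv"),
    meta   = file.path(dir, "cell_meta.csv")
  )
  Matrix::writeMM(dataset$matrix, paths$matrix)
  writeLines(dataset$gene_ids, paths$genes)
  writeLines(dataset$cell_ids, paths$cells)
  write.csv(dataset$cell_meta, paths$meta, row.names = FALSE)
  invisible(paths)
}

read_id_sidecar <- function(path, header_name) {
  ids <- readLines(path)
  ids <- trimws(vapply(strsplit(ids, "\t"), `[[`, character(1), 1))
  ids <- ids[nzchar(ids)]
  if (length(ids) && identical(ids[1], header_name)) ids <- ids[-1]
  if (!length(ids)) stop_("id sidecar '%s' is empty", path)
  ids
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  as_tibble(read.delim(path, sep = sep, stringsAsFactors = FALSE,
                       check.names = FALSE, comment.char = "#"))
}

#' Read a GMT gene-set file
#'
#' Parses the standard GMT layout (set name, description, then tab-separated
#' gene symbols) into a named list of gene sets. Symbols are whitespace-trimmed
#' and de-duplicated within each set; sets smaller than `min_genes` *after*
#' de-duplication are dropped, mirroring the usual pathway-curation rule of
#' excluding sets with fewer than 10 genes. The number of dropped sets is
#' reported via `message()`.
#'
#' @param path Path to the GMT file.
#' @param min_genes Minimum retained set size (default 10).
#' @return A named list of character vectors with attributes
#'   `descriptions` (named character) and `n_dropped` (integer).
#' @export
read_gmt <- function(path, min_genes = 10) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop_("GMT file '%s', line %d: expected at least 3 tab-separated fields",
          path, bad[1])
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  descr <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  names(sets) <- names_
  keep <- lengths(sets) >= min_genes
  if (any(!keep)) {
    message(sprintf("read_gmt: dropped %d set(s) with fewer than %d genes",
                    sum(!keep), min_genes))
  }
  out <- sets[keep]
  if (!length(out)) stop_("no gene set with >= %d genes in '%s'",
                          min_genes, path)
  attr(out, "descriptions") <- setNames(descr[keep], names_[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to `"na"`.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descr <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descr[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
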
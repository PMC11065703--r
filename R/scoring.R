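#' Per-cell gene rankings
#'
#' Ranks every gene within each cell by descending expression, the first step
#' of recovery-curve (AUC) scoring. Zero-inflated single-nucleus matrices make
#' the tie policy material: by default ties are broken by a seeded uniform
#' shuffle within each tie group, so an all-zero cell yields a random
#' permutation rather than an input-order artefact. An `"average"` mode
#' assigns midranks instead and is fully deterministic.
#'
#' @param dataset An [expression_dataset()].
#' @param seed Integer seed for tie-breaking (ignored for `"average"`).
#' @param ties `"random"` (seeded shuffle within ties) or `"average"`
#'   (midranks).
#' @return A genes x cells numeric matrix of ranks (1 = highest expression),
#'   with the dataset's dimnames.
#' @export
rank_genes_per_cell <- function(dataset, seed = 1L, ties = c("random", "average")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  ties <- match.arg(ties)
  n_genes <- length(dataset$gene_ids)
  n_cells <- length(dataset$cell_ids)
  if (n_genes == 0 || n_cells == 0) stop_("dataset is empty")
  ranks <- matrix(0, n_genes, n_cells,
                  dimnames = list(dataset$gene_ids, dataset$cell_ids))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  dense <- as.matrix(dataset$matrix)
  seq_g <- seq_len(n_genes)
  for (j in seq_len(n_cells)) {
    x <- dense[, j]
    if (ties == "random") {
      ord <- order(-x, runif(n_genes))
      ranks[ord, j] <- seq_g
    } else {
      ranks[, j] <- rank(-x, ties.method = "average")
    }
  }
  ranks
}

#' Recovery-curve AUC score
#'
#' AUCell-style enrichment: for each cell, the recovery curve
#' `y(i) = #` gene-set genes at rank `<= i` is accumulated over the top
#' `maxRank = ceiling(max_rank_frac * n_genes)` ranks, and the raw area
#' `sum_i y(i)` is normalised by the top-packed maximum
#' `sum_i min(i, k)` (all `k` matched set genes occupying the best ranks), so
#' scores lie in `[0, 1]`. The default `max_rank_frac` of 0.05 follows the
#' convention of setting the AUC ceiling at 5% of the input genes. A set with
#' no gene in the ranking scores 0 with a warning.
#'
#' @param ranking Rank matrix from [rank_genes_per_cell()].
#' @param gene_set Character vector of gene symbols (matched case-sensitively
#'   against the ranking's rownames).
#' @param max_rank_frac Fraction of genes forming the AUC ceiling, in (0, 1].
#' @return Named numeric vector of per-cell scores in `[0, 1]`.
#' @export
auc_score <- function(ranking, gene_set, max_rank_frac = 0.05) {
  stopifnot(is.matrix(ranking), !is.null(rownames(ranking)))
  if (!(max_rank_frac > 0 && max_rank_frac <= 1)) {
    stop_("max_rank_frac must be in (0, 1]")
  }
  n_genes <- nrow(ranking)
  max_rank <- max(1L, as.integer(ceiling(max_rank_frac * n_genes)))
  matched <- intersect(unique(trimws(gene_set)), rownames(ranking))
  k <- length(matched)
  if (k == 0) {
    warn_("gene set has no gene in the ranking; scores are 0")
    return(setNames(rep(0, ncol(ranking)), colnames(ranking)))
  }
  # gene at rank r contributes (max_rank - ceiling(r) + 1) curve steps;
  # ceiling() makes midranks count only from the first integer rank they reach
  r <- ranking[matched, , drop = FALSE]
  contrib <- pmax(max_rank - ceiling(r) + 1, 0)  # matrix-shaped (pmax keeps dims of first arg)
  raw <- colSums(contrib)
  max_area <- sum(pmin(seq_len(max_rank), k))
  setNames(raw / max_area, colnames(ranking))
}

#' Bin-matched control module score
#'
#' Seurat-AddModuleScore-style aggregate expression: genes are binned into
#' `n_bins` groups by dataset-wide mean expression, `n_ctrl` control genes are
#' drawn (seeded) for each set gene from its bin — excluding the set genes
#' themselves, so adding a constant to the set genes shifts every score by
#' exactly that constant — and each cell's score is its mean expression over
#' the set genes minus its mean over the pooled controls. Controls are drawn
#' without replacement when the bin is large enough, with replacement
#' otherwise. Requires a log-normalised matrix.
#'
#' @param dataset A log-normalised [expression_dataset()].
#' @param gene_set Character vector of gene symbols.
#' @param n_bins Number of expression bins (default 24, capped at the number
#'   of non-set genes).
#' @param n_ctrl Controls drawn per set gene (default 100).
#' @param seed Integer seed for control sampling.
#' @return Named numeric vector of per-cell scores (unbounded).
#' @export
module_score <- function(dataset, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!dataset$normalised) {
    stop_("module_score requires a log-normalised dataset; see normalise_expression()")
  }
  stopifnot(n_bins >= 1, n_ctrl >= 1)
  matched <- intersect(unique(trimws(gene_set)), dataset$gene_ids)
  if (!length(matched)) stop_("gene set has no gene in the dataset")
  pool <- setdiff(dataset$gene_ids, matched)
  if (!length(pool)) stop_("no non-set genes available as controls")

  means <- Matrix::rowMeans(dataset$matrix)
  n_bins <- min(n_bins, length(dataset$gene_ids))
  bin <- dplyr::ntile(rank(means, ties.method = "first"), n_bins)
  names(bin) <- dataset$gene_ids

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ctrl <- unlist(lapply(matched, function(g) {
    cand <- pool[bin[pool] == bin[[g]]]
    if (!length(cand)) cand <- pool
    sample(cand, n_ctrl, replace = length(cand) < n_ctrl)
  }), use.names = FALSE)

  sig <- Matrix::colMeans(dataset$matrix[matched, , drop = FALSE])
  ctl <- Matrix::colSums(dataset$matrix[ctrl, , drop = FALSE]) / length(ctrl)
  setNames(as.numeric(sig - ctl), dataset$cell_ids)
}

#' Score cells for one or more gene sets
#'
#' Tidy front end to [auc_score()] and [module_score()]: scores every cell for
#' every gene set and returns one row per (cell, set).
#'
#' @param dataset An [expression_dataset()].
#' @param gene_sets Named list of gene symbol vectors (e.g. from [read_gmt()]),
#'   or a single character vector (named `"set1"`).
#' @param method `"auc"` (rank-based, default) or `"module"` (bin-matched
#'   controls; requires a log-normalised matrix).
#' @param max_rank_frac,ties AUC parameters, see [auc_score()] and
#'   [rank_genes_per_cell()].
#' @param n_bins,n_ctrl Module-score parameters, see [module_score()].
#' @param seed Integer seed controlling tie-breaking / control sampling.
#' @return A tibble with columns `cell_id`, `set_name`, `score`, `method`,
#'   carrying a `params_digest` attribute.
#' @export
#' @examples
#' sim <- simulate_expression(expression_sim_config(n_samples_per_arm = 2,
#'                                                  cells_per_sample = 20,
#'                                                  n_genes = 60, seed = 7))
#' scores <- score_cells(sim$dataset, list(CSP = sim$gene_set), seed = 7)
#' head(scores)
score_cells <- function(dataset, gene_sets, method = c("auc", "module"),
                        max_rank_frac = 0.05, ties = "random",
                        n_bins = 24, n_ctrl = 100, seed = 1L) {
  method <- match.arg(method)
  if (is.character(gene_sets)) gene_sets <- list(set1 = gene_sets)
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  if (method == "auc") {
    ranking <- rank_genes_per_cell(dataset, seed = seed, ties = ties)
    res <- purrr::imap_dfr(gene_sets, function(gs, nm) {
      sc <- auc_score(ranking, gs, max_rank_frac = max_rank_frac)
      tibble(cell_id = names(sc), set_name = nm, score = unname(sc),
             method = "auc")
    })
    digest <- params_digest(method = "auc", max_rank_frac = max_rank_frac,
                            ties = ties, seed = seed)
  } else {
    res <- purrr::imap_dfr(gene_sets, function(gs, nm) {
      sc <- module_score(dataset, gs, n_bins = n_bins, n_ctrl = n_ctrl,
                         seed = seed)
      tibble(cell_id = names(sc), set_name = nm, score = unname(sc),
             method = "module")
    })
    digest <- params_digest(method = "module", n_bins = n_bins,
                            n_ctrl = n_ctrl, seed = seed)
  }
  attr(res, "params_digest") <- digest
  res
}

#' Mean gene-set score per group
#'
#' Averages per-cell scores within groups defined by cell-metadata columns —
#' e.g. mean score per (sample, cell type), the per-sample aggregation used
#' ahead of meta-analysis. Optionally z-scales the group means across groups
#' (per set).
#'
#' @param scores Tibble from [score_cells()].
#' @param cell_meta Per-cell metadata with `cell_id` and the grouping columns.
#' @param group_by Character vector of metadata columns to group by.
#' @param scale If `TRUE`, adds `mean_score_scaled`, the z-score of the group
#'   means within each set.
#' @return Tibble with the grouping columns, `set_name`, `n_cells`,
#'   `mean_score` (and `mean_score_scaled` if requested).
#' @export
mean_score_per_group <- function(scores, cell_meta, group_by = "cell_type",
                                 scale = FALSE) {
  check_columns(scores, c("cell_id", "set_name", "score"), "scores")
  check_columns(cell_meta, c("cell_id", group_by), "cell_meta")
  joined <- dplyr::inner_join(scores, cell_meta, by = "cell_id")
  n_na <- sum(is.na(joined$score))
  if (n_na > 0) {
    warn_("%d score(s) are NA and were dropped", n_na)
    joined <- dplyr::filter(joined, !is.na(.data$score))
  }
  out <- joined %>%
    group_by(across(all_of(c(group_by, "set_name")))) %>%
    summarise(n_cells = dplyr::n(), mean_score = mean(.data$score),
              .groups = "drop")
  if (scale) {
    out <- out %>%
      group_by(.data$set_name) %>%
      mutate(mean_score_scaled = as.numeric(scale(.data$mean_score))) %>%
      ungroup()
    attr(out, "scaled") <- TRUE
  }
  out
}
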
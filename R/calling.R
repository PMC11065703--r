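#' Call senescent cells by a robust outlier threshold
#'
#' Classifies a cell as senescent when its gene-set score strictly exceeds
#' `median + k_mad * MAD` of the scores within its stratum, the
#' median-plus-3-MADs rule used to define senescent nuclei from canonical
#' senescence pathway scores. The MAD is normal-consistent by default
#' (`mad_scale = 1.4826`), so under Gaussian scores the rule calls
#' roughly the upper `1 - pnorm(3)` tail. Strata default to cell type pooled
#' across diagnosis and samples, so case and control calls share one
#' yardstick; pass other metadata columns to stratify differently. When the
#' MAD is zero (e.g. mostly tied scores) the threshold degenerates to the
#' median and only strictly greater scores are called.
#'
#' @param scores Tibble from [score_cells()] (columns `cell_id`, `set_name`,
#'   `score`).
#' @param cell_meta Per-cell metadata with `cell_id` and the stratification
#'   columns.
#' @param group_by Metadata columns defining the threshold strata
#'   (default `"cell_type"`; use `character(0)` for one global stratum).
#' @param k_mad Number of MADs above the median (default 3).
#' @param mad_scale MAD consistency constant (default 1.4826; use 1 for the
#'   raw median absolute deviation).
#' @return Tibble with `cell_id`, `set_name`, the stratum columns, `score`,
#'   `threshold_used` and logical `senescent`. Strata with fewer than two
#'   cells get all-`FALSE` calls with a warning.
#' @export
call_senescent <- function(scores, cell_meta, group_by = "cell_type",
                           k_mad = 3, mad_scale = 1.4826) {
  stopifnot(k_mad > 0, mad_scale > 0)
  check_columns(scores, c("cell_id", "set_name", "score"), "scores")
  if (length(group_by)) check_columns(cell_meta, c("cell_id", group_by), "cell_meta")
  joined <- if (length(group_by)) {
    dplyr::inner_join(scores, dplyr::distinct(cell_meta[, c("cell_id", group_by)]),
                      by = "cell_id")
  } else {
    scores
  }
  out <- joined %>%
    group_by(across(all_of(c("set_name", group_by)))) %>%
    mutate(
      threshold_used = median(.data$score) +
        k_mad * mad(.data$score, constant = mad_scale),
      senescent = dplyr::n() >= 2 & .data$score > .data$threshold_used
    ) %>%
    ungroup()
  small <- out %>%
    count(across(all_of(c("set_name", group_by)))) %>%
    filter(.data$n < 2)
  if (nrow(small) > 0) {
    warn_("%d stratum(s) have fewer than 2 cells; their calls are all FALSE",
          nrow(small))
  }
  attr(out, "params_digest") <- params_digest(
    k_mad = k_mad, mad_scale = mad_scale,
    group_by = paste(group_by, collapse = "+"))
  out
}

#' Per-sample senescent proportions
#'
#' Aggregates senescence calls to counts and proportions per
#' (sample, stratum), excluding strata observed in fewer than `min_cells`
#' cells in a sample — the same small-count rule used for IMC clusters
#' (samples with fewer than 3 cells per cluster removed). Excluded rows are
#' kept with `excluded = TRUE`, an NA proportion and a reason, so downstream
#' contrasts can report what was skipped.
#'
#' @param calls Tibble from [call_senescent()].
#' @param cell_meta Per-cell metadata with `cell_id`, `sample_id` and the
#'   stratum columns (plus any sample-level columns such as `diagnosis`,
#'   `region`, `age`, `amyloid_load`, carried through).
#' @param stratify_by Stratum columns (default `"cell_type"`).
#' @param min_cells Minimum cells per (sample, stratum) (default 3).
#' @return Tibble with `sample_id`, stratum and carried sample-level columns,
#'   `n_cells`, `n_senescent`, `proportion`, `excluded`, `reason`.
#' @export
sample_proportions <- function(calls, cell_meta, stratify_by = "cell_type",
                               min_cells = 3) {
  stopifnot(min_cells >= 1)
  check_columns(calls, c("cell_id", "set_name", "senescent"), "calls")
  check_columns(cell_meta, c("cell_id", "sample_id"), "cell_meta")
  carry <- intersect(c("diagnosis", "region", "age", "sex", "amyloid_load"),
                     names(cell_meta))
  meta_cols <- unique(c("cell_id", "sample_id", stratify_by, carry))
  joined <- dplyr::inner_join(
    calls[, c("cell_id", "set_name", "senescent")],
    dplyr::distinct(cell_meta[, meta_cols]), by = "cell_id")
  # sample-level columns must be constant within sample for carry-through
  out <- joined %>%
    group_by(across(all_of(c("sample_id", stratify_by, "set_name", carry)))) %>%
    summarise(n_cells = dplyr::n(),
              n_senescent = sum(.data$senescent),
              .groups = "drop") %>%
    mutate(
      excluded = .data$n_cells < min_cells,
      proportion = ifelse(.data$excluded, NA_real_,
                          .data$n_senescent / .data$n_cells),
      reason = ifelse(.data$excluded,
                      sprintf("fewer than %d cells", min_cells), NA_character_)
    )
  attr(out, "params_digest") <- params_digest(min_cells = min_cells)
  out
}
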
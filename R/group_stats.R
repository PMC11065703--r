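#' Wilcoxon rank-sum test with rank-biserial effect size
#'
#' Two-sample Mann-Whitney comparison reported the way the senescent-burden
#' contrasts are: the U statistic, a p-value (exact when both arms have at
#' most 10 observations and no ties, otherwise the normal approximation with
#' continuity and tie correction, via [stats::wilcox.test()]), and the
#' rank-biserial correlation `r = 2*U1/(n1*n2) - 1`, where `U1` counts pairs
#' with `x > y` plus half the ties — equivalently `P(x > y) - P(x < y)`.
#' The confidence interval for `r` comes from a seeded percentile bootstrap
#' resampling each arm independently (default), or from a normal
#' approximation on the Fisher-like `atanh(r)` scale.
#'
#' @param x,y Numeric observations for the two arms (e.g. per-sample
#'   proportions in AD and NDC donors).
#' @param alternative Passed to [stats::wilcox.test()].
#' @param ci_method `"bootstrap"` (default) or `"normal"`.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param label Optional contrast label carried into the output.
#' @return One-row tibble: `contrast`, `n1`, `n2`, `U`, `p_value`,
#'   `rank_biserial`, `ci_low`, `ci_high`, `method`.
#' @export
#' @examples
#' wilcoxon_rank_biserial(c(0.30, 0.25, 0.4), c(0.05, 0.02, 0.1), seed = 1)
wilcoxon_rank_biserial <- function(x, y, alternative = "two.sided",
                                   ci_method = c("bootstrap", "normal"),
                                   conf_level = 0.95, n_boot = 2000,
                                   seed = 1L, label = "group1 vs group2") {
  ci_method <- match.arg(ci_method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_("both groups must be non-empty")

  u1 <- u_pairs(x, y)
  rb <- 2 * u1 / (n1 * n2) - 1
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- n1 <= 10 && n2 <= 10 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  p_value <- wt$p.value
  # a completely tied pooled sample (zero rank variance) carries no evidence
  if (!is.finite(p_value)) p_value <- 1

  alpha <- 1 - conf_level
  if (ci_method == "bootstrap" && n1 >= 2 && n2 >= 2) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    rbs <- vapply(seq_len(n_boot), function(i) {
      xb <- x[sample.int(n1, replace = TRUE)]
      yb <- y[sample.int(n2, replace = TRUE)]
      2 * u_pairs(xb, yb) / (n1 * n2) - 1
    }, numeric(1))
    ci <- unname(quantile(rbs, c(alpha / 2, 1 - alpha / 2)))
    method <- sprintf("Wilcoxon rank-sum; %d-resample percentile bootstrap CI",
                      n_boot)
  } else {
    # normal approximation on atanh(r); clamp away from +-1
    z <- stats::qnorm(1 - alpha / 2)
    rc <- max(min(rb, 1 - 1e-12), -1 + 1e-12)
    se <- sqrt((n1 + n2 + 1) / (3 * n1 * n2))
    ci <- tanh(atanh(rc) + c(-z, z) * se)
    method <- "Wilcoxon rank-sum; normal-approximation CI"
  }
  ci[1] <- min(ci[1], rb); ci[2] <- max(ci[2], rb)

  tibble(contrast = label, n1 = n1, n2 = n2, U = u1,
         p_value = p_value, rank_biserial = rb,
         ci_low = ci[1], ci_high = ci[2], method = method)
}

# U1 = #{(i,j): x_i > y_j} + 0.5 * #ties; midrank identity with rank sums
u_pairs <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Pearson correlation with least-squares line
#'
#' Correlates a per-sample quantity (e.g. a microglial sub-population
#' fraction) against pathology load (e.g. 4G8+ beta-amyloid % area):
#' Pearson's r, a two-sided p-value from the t distribution with `n - 2`
#' degrees of freedom, and the OLS slope and intercept.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; rows with NA in
#'   either are dropped.
#' @return One-row tibble: `r`, `p_value`, `n`, `slope`, `intercept`.
#' @export
pearson_regression <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_("need at least 3 complete observations")
  if (sd(x) == 0) stop_("x has zero variance")
  if (sd(y) == 0) stop_("y has zero variance")
  ct <- cor.test(x, y, method = "pearson")
  slope <- unname(ct$estimate) * sd(y) / sd(x)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()], with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Contrast per-sample senescent proportions between diagnosis groups
#'
#' Runs [wilcoxon_rank_biserial()] on per-sample proportions for every
#' stratum (e.g. cell type within brain region), AD arm first, mirroring the
#' percentage-of-senescent-nuclei contrasts stratified by region. Strata with
#' fewer than `min_per_arm` non-excluded samples in either arm are reported
#' as skipped rather than tested. Benjamini-Hochberg adjusted p-values are
#' appended across the tested strata.
#'
#' @param props Tibble from [sample_proportions()] (needs `proportion`,
#'   `excluded` and the contrast/stratum columns).
#' @param contrast Column holding the two-level group factor (default
#'   `"diagnosis"`); `level_order` gives the (case, control) order, default
#'   `c("AD", "NDC")` when present.
#' @param stratify_by Stratum columns (default `c("cell_type", "region")`,
#'   intersected with the available columns).
#' @param level_order Optional length-2 character vector.
#' @param min_per_arm Minimum samples per arm (default 2).
#' @param ci_method,n_boot,seed Passed to [wilcoxon_rank_biserial()].
#' @return Tibble with one row per stratum: the effect columns of
#'   [wilcoxon_rank_biserial()] plus `skipped`, `skip_reason`, `p_adj`.
#' @export
contrast_proportions <- function(props, contrast = "diagnosis",
                                 stratify_by = c("cell_type", "region"),
                                 level_order = NULL, min_per_arm = 2,
                                 ci_method = "bootstrap", n_boot = 2000,
                                 seed = 1L) {
  check_columns(props, c(contrast, "proportion", "excluded"), "props")
  stratify_by <- intersect(stratify_by, names(props))
  usable <- filter(props, !.data$excluded, !is.na(.data$proportion))
  lv <- level_order %||%
    (if (all(c("AD", "NDC") %in% usable[[contrast]])) c("AD", "NDC")
     else sort(unique(usable[[contrast]])))
  if (length(lv) != 2) stop_("contrast column must have exactly two levels")

  strata <- dplyr::distinct(usable[, stratify_by, drop = FALSE])
  if (nrow(strata) == 0) strata <- tibble(.rows = 1)
  res <- purrr::map_dfr(seq_len(nrow(strata)), function(i) {
    sub <- usable
    for (sc in stratify_by) sub <- sub[sub[[sc]] == strata[[sc]][i], ]
    x <- sub$proportion[sub[[contrast]] == lv[1]]
    y <- sub$proportion[sub[[contrast]] == lv[2]]
    base <- strata[i, , drop = FALSE]
    if (length(x) < min_per_arm || length(y) < min_per_arm) {
      return(dplyr::bind_cols(base, tibble(
        contrast = paste(lv, collapse = " vs "),
        n1 = length(x), n2 = length(y), U = NA_real_, p_value = NA_real_,
        rank_biserial = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        method = NA_character_, skipped = TRUE,
        skip_reason = sprintf("fewer than %d samples in an arm", min_per_arm))))
    }
    eff <- wilcoxon_rank_biserial(x, y, ci_method = ci_method, n_boot = n_boot,
                                  seed = seed,
                                  label = paste(lv, collapse = " vs "))
    dplyr::bind_cols(base, eff, tibble(skipped = FALSE,
                                       skip_reason = NA_character_))
  })
  res$p_adj <- NA_real_
  tested <- !res$skipped
  res$p_adj[tested] <- bh_fdr(res$p_value[tested])
  res
}
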
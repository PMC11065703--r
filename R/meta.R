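#' Per-dataset standardised effect of case vs control mean scores
#'
#' Converts per-sample mean gene-set scores (the donor-level averages of
#' per-nucleus scores) from one dataset into a small-sample-corrected
#' standardised mean difference: Cohen's
#' `d = (mean_case - mean_control) / sd_pooled`, Hedges'
#' `g = d * J` with `J = 1 - 3 / (4*(n1+n2) - 9)`, and the standard
#' large-sample variance `var(g) = J^2 * ((n1+n2)/(n1*n2) + d^2/(2*(n1+n2)))`.
#'
#' @param per_sample_means Numeric vector of per-sample (donor) mean scores.
#' @param arm_labels Factor/character of the same length giving each sample's
#'   arm; `case_level` defaults to `"AD"` when present, else the first sorted
#'   level.
#' @param dataset_id Identifier carried into the output.
#' @param case_level,control_level Optional explicit arm levels.
#' @return One-row tibble: `dataset_id`, `n_case`, `n_control`, `mean_case`,
#'   `sd_case`, `mean_control`, `sd_control`, `d`, `g`, `se_g`.
#' @export
dataset_effect <- function(per_sample_means, arm_labels, dataset_id = "dataset",
                           case_level = NULL, control_level = NULL) {
  stopifnot(length(per_sample_means) == length(arm_labels))
  arm_labels <- as.character(arm_labels)
  lv <- sort(unique(arm_labels))
  case_level <- case_level %||% (if ("AD" %in% lv) "AD" else lv[1])
  control_level <- control_level %||% setdiff(lv, case_level)[1]
  x1 <- per_sample_means[arm_labels == case_level]
  x0 <- per_sample_means[arm_labels == control_level]
  n1 <- length(x1); n0 <- length(x0)
  if (n1 < 2 || n0 < 2) stop_("need at least 2 samples per arm (got %d, %d)",
                              n1, n0)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / (n1 + n0 - 2)
  if (sp2 <= 0) stop_("pooled standard deviation is zero in '%s'", dataset_id)
  d <- (mean(x1) - mean(x0)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n0) - 9)
  g <- d * J
  var_g <- J^2 * ((n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0)))
  tibble(dataset_id = dataset_id, n_case = n1, n_control = n0,
         mean_case = mean(x1), sd_case = sd(x1),
         mean_control = mean(x0), sd_control = sd(x0),
         d = d, g = g, se_g = sqrt(var_g))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-dataset Hedges' g values under the DerSimonian-Laird
#' random-effects model: with fixed-effect weights `w_i = 1/se_i^2`,
#' heterogeneity `Q = sum w_i (g_i - g_fixed)^2`,
#' `C = sum(w) - sum(w^2)/sum(w)`, `tau^2 = max(0, (Q - (k-1))/C)`; the
#' pooled effect is the `1/(se_i^2 + tau^2)`-weighted mean, with
#' `z = pooled/se_pooled` and a two-sided normal p-value.
#' `I^2 = max(0, (Q - (k-1))/Q) * 100` summarises heterogeneity and
#' `n_positive_direction` counts datasets with `g > 0`. With a single
#' dataset the pooled effect is that dataset's g and `tau^2 = 0`.
#'
#' @param effects Tibble with `dataset_id`, `g`, `se_g` (one row per
#'   dataset), e.g. rows from [dataset_effect()].
#' @return An object of class `meta_result`; see [tidy.meta_result()] and
#'   [glance.meta_result()].
#' @export
pool_random_effects <- function(effects) {
  check_columns(effects, c("dataset_id", "g", "se_g"), "effects")
  bad <- which(!is.finite(effects$g) | !is.finite(effects$se_g) |
                 effects$se_g <= 0)
  if (length(bad)) stop_("non-finite effect or se in dataset '%s'",
                         effects$dataset_id[bad[1]])
  k <- nrow(effects)
  w <- 1 / effects$se_g^2
  g_fixed <- sum(w * effects$g) / sum(w)
  Q <- sum(w * (effects$g - g_fixed)^2)
  if (k > 1) {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
  } else {
    tau2 <- 0
  }
  wr <- 1 / (effects$se_g^2 + tau2)
  pooled <- sum(wr * effects$g) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- pooled / se
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  structure(
    list(pooled = pooled, se = se, z = z, p_value = 2 * pnorm(-abs(z)),
         tau2 = tau2, i2 = i2, q = Q, k = k,
         n_positive_direction = sum(effects$g > 0),
         effects = as_tibble(effects)),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (DerSimonian-Laird), k = %d datasets\n", x$k))
  cat(sprintf("  pooled g = %.3f (se %.3f), z = %.2f, p = %.3g\n",
              x$pooled, x$se, x$z, x$p_value))
  cat(sprintf("  tau^2 = %.4f, I^2 = %.1f%%, positive direction: %d/%d\n",
              x$tau2, x$i2, x$n_positive_direction, x$k))
  invisible(x)
}

#' Per-dataset and pooled rows of a meta-analysis
#'
#' @param x A `meta_result`.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @param ... Ignored.
#' @return Tibble with one row per dataset plus a `"pooled"` row: `dataset_id`,
#'   `g`, `se_g`, `ci_low`, `ci_high`, `weight` (normalised random-effects
#'   weight), `pooled` flag. Suitable for a forest plot ([plot_forest()]).
#' @exportS3Method generics::tidy
#' @export
tidy.meta_result <- function(x, conf_level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  wr <- 1 / (x$effects$se_g^2 + x$tau2)
  per <- tibble(dataset_id = x$effects$dataset_id,
                g = x$effects$g, se_g = x$effects$se_g,
                ci_low = x$effects$g - zq * x$effects$se_g,
                ci_high = x$effects$g + zq * x$effects$se_g,
                weight = wr / sum(wr), pooled = FALSE)
  bind_rows(per, tibble(dataset_id = "pooled", g = x$pooled, se_g = x$se,
                        ci_low = x$pooled - zq * x$se,
                        ci_high = x$pooled + zq * x$se,
                        weight = NA_real_, pooled = TRUE))
}

#' One-row summary of a meta-analysis
#' @param x A `meta_result`.
#' @param ... Ignored.
#' @return Tibble: `k`, `pooled_g`, `se`, `z`, `p_value`, `tau2`, `i2`, `q`,
#'   `n_positive_direction`.
#' @exportS3Method generics::glance
#' @export
glance.meta_result <- function(x, ...) {
  tibble(k = x$k, pooled_g = x$pooled, se = x$se, z = x$z,
         p_value = x$p_value, tau2 = x$tau2, i2 = x$i2, q = x$q,
         n_positive_direction = x$n_positive_direction)
}

#' Forest plot of a random-effects meta-analysis
#'
#' @param x A `meta_result` from [pool_random_effects()].
#' @param conf_level Confidence level (default 0.95).
#' @return A ggplot object.
#' @export
plot_forest <- function(x, conf_level = 0.95) {
  td <- tidy(x, conf_level = conf_level)
  td$dataset_id <- factor(td$dataset_id,
                          levels = rev(c(setdiff(td$dataset_id, "pooled"),
                                         "pooled")))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$g, y = .data$dataset_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled,
                                     size = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4),
                               guide = "none") +
    ggplot2::labs(x = "Hedges' g (case - control)", y = NULL) +
    ggplot2::theme_minimal()
}
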
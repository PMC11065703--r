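#' Default pipeline configuration
#'
#' Assembles the run configuration consumed by [run_pipeline()]: generator
#' settings (or input paths) plus every stage parameter, with all randomness
#' funnelled through explicit seeds so a rerun with the same config
#' reproduces identical outputs.
#'
#' @param seed Master seed; stage seeds default to offsets of it.
#' @param expression Named list of overrides for [expression_sim_config()],
#'   or `NULL` to skip the expression stages; alternatively a list with
#'   `paths = list(matrix=, genes=, cells=, meta=)` to read data instead of
#'   simulating.
#' @param imaging Named list of overrides for [imaging_sim_config()], or
#'   `NULL` to skip the imaging stages.
#' @param max_rank_frac,k_mad,mad_scale,min_cells AUC-scoring and
#'   senescence-calling parameters.
#' @param trim_frac,radius_um IMC trimming fraction and peri-plaque radius.
#' @param ci_method,n_boot Confidence-interval settings for contrasts.
#' @return A list of class `senescape_config`.
#' @export
pipeline_config <- function(seed = 1L, expression = list(), imaging = list(),
                            max_rank_frac = 0.05, k_mad = 3,
                            mad_scale = 1.4826, min_cells = 3,
                            trim_frac = 0.01, radius_um = 10,
                            ci_method = "bootstrap", n_boot = 2000) {
  cfg <- as.list(environment())
  class(cfg) <- "senescape_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return A `senescape_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop_("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the senescence-burden pipeline end to end
#'
#' Executes the stages in dependency order — simulate (or read) expression
#' data, normalise, AUC-score the senescence gene set, call senescent nuclei
#' (median + k*MAD), aggregate per-sample proportions, contrast AD vs NDC
#' per cell type and region, fit the score-vs-age linear-plateau model per
#' arm, pool per-region effects with a random-effects meta-analysis, and (if
#' configured) the imaging arm: marker calling, QC trimming, peri-plaque
#' classification and the peri-vs-non-plaque contrast. Each stage writes a
#' CSV whose first line is a `#`-prefixed parameter digest; a
#' `provenance.json` manifest records the full config, seeds and row counts.
#'
#' @param config A `senescape_config` (or YAML path).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "senescape_config"))
  validate_config_paths(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list(config = unclass_deep(config), stages = list())

  if (!is.null(config$expression)) {
    ep <- config$expression$paths
    if (!is.null(ep)) {
      dataset <- read_expression(ep$matrix, ep$genes, ep$cells, ep$meta)
      gene_sets <- read_gmt(ep$gmt)
      truth <- NULL
    } else {
      ecfg <- do.call(expression_sim_config,
                      c(config$expression,
                        if (is.null(config$expression$seed))
                          list(seed = config$seed)))
      sim <- simulate_expression(ecfg)
      dataset <- sim$dataset
      gene_sets <- list(CSP = sim$gene_set)
      truth <- sim$truth
      results$sample_table <- sim$sample_table
      stage_csv(sim$truth, file.path(outdir, "truth_expression.csv"),
                params_digest(seed = ecfg$seed))
    }
    dataset <- normalise_expression(dataset)
    scores <- score_cells(dataset, gene_sets, method = "auc",
                          max_rank_frac = config$max_rank_frac,
                          seed = config$seed)
    calls <- call_senescent(scores, dataset$cell_meta,
                            k_mad = config$k_mad,
                            mad_scale = config$mad_scale)
    props <- sample_proportions(calls, dataset$cell_meta,
                                min_cells = config$min_cells)
    effects <- contrast_proportions(props, ci_method = config$ci_method,
                                    n_boot = config$n_boot,
                                    seed = config$seed + 1L)
    results <- c(results, list(dataset = dataset, scores = scores,
                               calls = calls, proportions = props,
                               effects = effects, truth = truth))
    stage_csv(scores, file.path(outdir, "scores.csv"),
              attr(scores, "params_digest"))
    stage_csv(calls, file.path(outdir, "calls.csv"),
              attr(calls, "params_digest"))
    stage_csv(props, file.path(outdir, "proportions.csv"),
              attr(props, "params_digest"))
    stage_csv(effects, file.path(outdir, "effects.csv"),
              params_digest(ci_method = config$ci_method,
                            n_boot = config$n_boot))

    # score-vs-age plateau per arm on per-sample mean scores
    per_sample <- mean_score_per_group(
      scores, dataset$cell_meta,
      group_by = c("sample_id", "diagnosis", "region", "age"))
    agefits <- per_sample %>%
      group_by(.data$diagnosis) %>%
      dplyr::group_map(~ {
        if (dplyr::n_distinct(.x$age) >= 5) {
          dplyr::bind_cols(tibble(diagnosis = .y$diagnosis),
                           glance(fit_linear_plateau(.x$age, .x$mean_score)))
        } else {
          tibble(diagnosis = .y$diagnosis)
        }
      }) %>% bind_rows()
    results$age_fits <- agefits
    stage_csv(agefits, file.path(outdir, "agefit.csv"), params_digest())

    # meta-analysis: one dataset effect per region, falling back to a single
    # whole-cohort effect when no region has two samples per arm
    de <- per_sample %>%
      group_by(.data$region) %>%
      dplyr::group_map(~ tryCatch(
        dataset_effect(.x$mean_score, .x$diagnosis, dataset_id = .y$region),
        error = function(e) NULL)) %>%
      bind_rows()
    if (nrow(de) == 0) {
      de <- tryCatch(
        dataset_effect(per_sample$mean_score, per_sample$diagnosis,
                       dataset_id = "all_regions"),
        error = function(e) de)
    }
    if (nrow(de) >= 1) {
      meta <- pool_random_effects(de)
      results$meta <- meta
      stage_csv(tidy(meta), file.path(outdir, "meta.csv"),
                params_digest(model = "DerSimonian-Laird"))
    }
  }

  if (!is.null(config$imaging)) {
    icfg <- do.call(imaging_sim_config,
                    c(config$imaging,
                      if (is.null(config$imaging$seed))
                        list(seed = config$seed + 2L)))
    isim <- simulate_imaging(icfg)
    called <- call_markers(isim$cells, default_marker_rules(isim$cells))
    trimmed <- qc_trim(called,
                       senescence_channels = c("GLB1", "p16", "p21", "gH2AX"),
                       cell_type_channels = c("Iba1", "GFAP"),
                       trim_frac = config$trim_frac)
    prox <- classify_peri_plaque(trimmed, isim$plaques,
                                 radius_um = config$radius_um)
    contrast <- peri_vs_nonplaque_contrast(trimmed, prox)
    cluster_props <- senescent_proportion_per_cluster(
      trimmed, c(Micro = "Iba1", Astro = "GFAP"),
      senescence_channels = c("GLB1", "p16", "p21", "gH2AX"),
      min_cells = config$min_cells)
    results <- c(results, list(imaging = isim, proximity = prox,
                               peri_contrast = contrast,
                               cluster_proportions = cluster_props))
    stage_csv(prox, file.path(outdir, "proximity.csv"),
              params_digest(radius_um = config$radius_um))
    stage_csv(contrast$proportions,
              file.path(outdir, "peri_proportions.csv"), params_digest())
    stage_csv(contrast$effects, file.path(outdir, "peri_effects.csv"),
              params_digest())
    stage_csv(cluster_props, file.path(outdir, "cluster_proportions.csv"),
              attr(cluster_props, "params_digest"))
  }

  manifest$stages <- lapply(results[vapply(results, is.data.frame,
                                           logical(1))], nrow)
  manifest$seed <- config$seed
  jsonlite::write_json(manifest, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(results)
}

# fixed threshold midway (log scale) between the simulated positive
# (median 20) and negative (median 1) intensity modes
default_marker_rules <- function(cells) {
  chans <- imc_channels(cells)
  rules <- lapply(chans, function(ch) list(type = "fixed",
                                           value = sqrt(20 * 1)))
  names(rules) <- chans
  rules
}

stage_csv <- function(df, path, digest) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# params: %s", digest), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

validate_config_paths <- function(config) {
  ep <- config$expression$paths
  if (!is.null(ep)) {
    for (nm in c("matrix", "genes", "cells", "meta", "gmt")) {
      if (is.null(ep[[nm]])) stop_("expression paths must include '%s'", nm)
      if (!file.exists(ep[[nm]])) stop_("input path does not exist: %s",
                                        ep[[nm]])
    }
  }
  invisible(config)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
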
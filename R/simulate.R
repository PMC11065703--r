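#' Configuration for the expression simulator
#'
#' Defines the generative model for a case-control single-nucleus experiment:
#' two diagnosis arms (AD, NDC) of `n_samples_per_arm` donors, each
#' contributing `cells_per_sample` nuclei from a mixture of cell types;
#' negative-binomial counts with gene-level dispersion; a planted senescent
#' sub-fraction per (arm, cell type) whose gene-set genes' means are
#' multiplied by `fold_change`; per-sample amyloid load generated as a linear
#' function of the realised microglial senescent fraction plus noise; donor
#' ages drawn uniformly per arm. Defaults emulate the study structure the
#' package targets: a microglial senescent fraction of 0.25 in AD versus
#' 0.05 in controls, a small 0.02 background in other cell types, three
#' cortical regions, and control ages spanning 50-100 years.
#'
#' @param n_samples_per_arm Donors per arm (default 8).
#' @param cells_per_sample Nuclei per donor (default 150).
#' @param cell_type_weights Named mixture weights summing to 1
#'   (default Micro 0.4, Astro 0.3, ExN 0.3).
#' @param n_genes Total genes (default 2000).
#' @param gene_set_size Genes in the planted senescence set (default 80).
#' @param senescent_fraction List per arm of named per-cell-type fractions.
#' @param fold_change Multiplier `f >= 1` on gene-set means in senescent
#'   cells (default 4; 1 is the exchangeable null).
#' @param dispersion NB size parameter (default 2).
#' @param base_mean_log_mu,base_mean_log_sd Log-normal gene baseline means.
#' @param amyloid_alpha,amyloid_beta,amyloid_sd Per-sample amyloid model
#'   `load = alpha + beta * realised_microglial_fraction + N(0, sd)`,
#'   truncated at 0.
#' @param age_range List per arm of `c(min, max)` donor ages.
#' @param regions Brain-region labels cycled across samples.
#' @param seed Integer seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(
    n_samples_per_arm = 8, cells_per_sample = 150,
    cell_type_weights = c(Micro = 0.4, Astro = 0.3, ExN = 0.3),
    n_genes = 2000, gene_set_size = 80,
    senescent_fraction = list(
      AD  = c(Micro = 0.25, Astro = 0.02, ExN = 0.02),
      NDC = c(Micro = 0.05, Astro = 0.02, ExN = 0.02)),
    fold_change = 4, dispersion = 2,
    base_mean_log_mu = 0, base_mean_log_sd = 1,
    amyloid_alpha = 1, amyloid_beta = 40, amyloid_sd = 1.5,
    age_range = list(AD = c(60, 95), NDC = c(50, 100)),
    regions = c("EC", "MTG", "SSC"), seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cell_type_weights) - 1) > 1e-6) {
    stop_("cell_type_weights must sum to 1 (got %.4f)", sum(cell_type_weights))
  }
  pis <- unlist(senescent_fraction)
  if (any(pis < 0 | pis > 1)) stop_("senescent fractions must lie in [0, 1]")
  if (fold_change < 1) stop_("fold_change must be >= 1")
  if (dispersion <= 0) stop_("dispersion must be > 0")
  if (gene_set_size > n_genes) stop_("gene_set_size exceeds n_genes")
  class(cfg) <- "expression_sim_config"
  cfg
}

#' Simulate a case-control expression dataset with known senescent cells
#'
#' Draws a gene-by-cell count matrix under the model in
#' [expression_sim_config()] and returns it together with the planted gene
#' set and a per-cell ground-truth table, so every downstream stage (scoring,
#' calling, proportion contrasts, amyloid regression) can be validated
#' against truth. Bit-reproducible given the config (which carries the seed).
#'
#' @param config An [expression_sim_config()].
#' @return List: `dataset` (an [expression_dataset()] of raw counts), `truth`
#'   (tibble `cell_id`, `sample_id`, `diagnosis`, `cell_type`, `senescent`),
#'   `gene_set` (character), `sample_table` (per-sample `diagnosis`, `region`,
#'   `age`, `amyloid_load`, realised microglial senescent fraction), `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  gene_set <- sprintf("SENG%03d", seq_len(config$gene_set_size))
  genes[seq_len(config$gene_set_size)] <- gene_set
  base_mu <- stats::rlnorm(config$n_genes, config$base_mean_log_mu,
                           config$base_mean_log_sd)
  types <- names(config$cell_type_weights)
  # mild cell-type-specific expression signatures
  type_fac <- sapply(types, function(t) stats::rlnorm(config$n_genes, 0, 0.3))

  arms <- names(config$senescent_fraction)
  sample_rows <- list(); cell_rows <- list(); count_cols <- list()
  si <- 0
  for (arm in arms) {
    for (s in seq_len(config$n_samples_per_arm)) {
      si <- si + 1
      sample_id <- sprintf("%s_s%02d", arm, s)
      age <- round(runif(1, config$age_range[[arm]][1],
                         config$age_range[[arm]][2]))
      region <- config$regions[(si - 1) %% length(config$regions) + 1]
      ct <- sample(types, config$cells_per_sample, replace = TRUE,
                   prob = config$cell_type_weights)
      pi_ct <- config$senescent_fraction[[arm]]
      sen <- rbinom(config$cells_per_sample, 1,
                    unname(pi_ct[ct])) == 1
      cell_ids <- sprintf("%s_c%03d", sample_id,
                          seq_len(config$cells_per_sample))
      mu <- base_mu * type_fac[, match(ct, types), drop = FALSE]
      mu[seq_len(config$gene_set_size), sen] <-
        mu[seq_len(config$gene_set_size), sen, drop = FALSE] *
        config$fold_change
      cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                            size = config$dispersion),
                    nrow = config$n_genes)
      count_cols[[si]] <- cnt
      mg_frac <- if (any(ct == "Micro")) mean(sen[ct == "Micro"]) else 0
      amyloid <- max(0, config$amyloid_alpha + config$amyloid_beta * mg_frac +
                       rnorm(1, 0, config$amyloid_sd))
      sample_rows[[si]] <- tibble(
        sample_id = sample_id, diagnosis = arm, region = region, age = age,
        sex = sample(c("F", "M"), 1), amyloid_load = amyloid,
        true_micro_senescent_fraction = mg_frac)
      cell_rows[[si]] <- tibble(
        cell_id = cell_ids, sample_id = sample_id, diagnosis = arm,
        cell_type = ct, region = region, age = age, senescent = sen)
    }
  }
  sample_table <- bind_rows(sample_rows)
  cells <- bind_rows(cell_rows)
  counts <- do.call(cbind, count_cols)
  meta <- cells %>%
    left_join(sample_table[, c("sample_id", "sex", "amyloid_load")],
              by = "sample_id") %>%
    select("cell_id", "sample_id", "diagnosis", "cell_type", "region",
           "age", "sex", "amyloid_load")
  dataset <- expression_dataset(counts, genes, cells$cell_id, meta,
                                normalised = FALSE)
  list(dataset = dataset,
       truth = cells[, c("cell_id", "sample_id", "diagnosis", "cell_type",
                         "senescent")],
       gene_set = gene_set, sample_table = sample_table, config = config)
}

#' Configuration for the imaging (IMC) simulator
#'
#' Generative model for segmented IMC cell tables with plaque geometry:
#' per sample, `rois_per_sample` square ROIs of side `roi_size_um` (the
#' 4-ROIs-of-500x500-um acquisition layout); cells placed uniformly;
#' `n_plaques_per_roi` non-overlapping disk plaques with log-normal radii;
#' microglia and astrocytes in the stated mixture; marker positivity drawn
#' from `baseline_rates`, with the probability of GLB1 (and p16) positivity
#' raised to `peri_rates` for cells whose centroid lies within
#' `boost_radius_um` of a plaque boundary; intensities log-normal around
#' separated positive/negative modes.
#'
#' @param n_samples Number of donors (default 10).
#' @param rois_per_sample ROIs per donor (default 4).
#' @param roi_size_um ROI side length in micrometres (default 500).
#' @param cells_per_roi Cells per ROI (default 250).
#' @param cluster_weights Named mixture over cell clusters
#'   (default Micro 0.5, Astro 0.5).
#' @param n_plaques_per_roi Plaques per ROI (default 6).
#' @param plaque_radius_log_mu,plaque_radius_log_sd Log-normal radius model
#'   (default median 12 um).
#' @param baseline_rates Named baseline positivity probabilities per channel.
#' @param peri_rates Named positivity probabilities within the boost radius
#'   (channels absent here keep their baseline everywhere).
#' @param boost_radius_um Radius of the peri-plaque boost (default 10).
#' @param pos_log_mu,neg_log_mu,intensity_log_sd Intensity model (log scale).
#' @param diagnosis Diagnosis label given to every sample (default "AD").
#' @param max_placement_tries Retries for non-overlapping plaque placement.
#' @param seed Integer seed.
#' @return A list of class `imaging_sim_config`.
#' @export
imaging_sim_config <- function(
    n_samples = 10, rois_per_sample = 4, roi_size_um = 500,
    cells_per_roi = 250,
    cluster_weights = c(Micro = 0.5, Astro = 0.5),
    n_plaques_per_roi = 6,
    plaque_radius_log_mu = log(12), plaque_radius_log_sd = 0.3,
    baseline_rates = c(Iba1 = NA, GFAP = NA, GLB1 = 0.03, p16 = 0.03,
                       p21 = 0.05, gH2AX = 0.05),
    peri_rates = c(GLB1 = 0.30, p16 = 0.15),
    boost_radius_um = 10,
    pos_log_mu = log(20), neg_log_mu = log(1), intensity_log_sd = 0.35,
    diagnosis = "AD", max_placement_tries = 200, seed = 1L) {
  cfg <- as.list(environment())
  if (roi_size_um <= 0) stop_("roi_size_um must be > 0")
  if (abs(sum(cluster_weights) - 1) > 1e-6) {
    stop_("cluster_weights must sum to 1")
  }
  rates <- c(cfg$baseline_rates, cfg$peri_rates)
  rates <- rates[!is.na(rates)]
  if (any(rates < 0 | rates > 1)) stop_("positivity rates must lie in [0, 1]")
  class(cfg) <- "imaging_sim_config"
  cfg
}

#' Simulate an IMC cell table with plaques and ground truth
#'
#' Draws cells, plaques and channel intensities under
#' [imaging_sim_config()]. Cluster identity determines which cell-type
#' channel is high (Micro -> Iba1, Astro -> GFAP); senescence-channel
#' positivity is Bernoulli at the baseline rate, boosted near plaques per the
#' config. The truth table records each cell's generative peri-plaque status
#' and marker states.
#'
#' @param config An [imaging_sim_config()].
#' @return List: `cells` (an `imaging_cell_table`), `plaques` (a
#'   [plaque_set()] of disks), `truth` (tibble with `cell_id`, `roi_id`,
#'   `true_peri`, `<channel>_true` logicals), `config`.
#' @export
simulate_imaging <- function(config) {
  stopifnot(inherits(config, "imaging_sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  L <- config$roi_size_um
  type_channel <- c(Micro = "Iba1", Astro = "GFAP")
  sen_channels <- setdiff(names(config$baseline_rates), type_channel)
  cells_l <- list(); disks_l <- list(); truth_l <- list()

  for (s in seq_len(config$n_samples)) {
    sample_id <- sprintf("imc_s%02d", s)
    for (r in seq_len(config$rois_per_sample)) {
      roi_id <- sprintf("%s_roi%d", sample_id, r)
      # plaques: rejection-sample non-overlapping disks
      dk <- tibble(roi_id = character(), plaque_id = character(),
                   cx_um = double(), cy_um = double(), radius_um = double())
      if (config$n_plaques_per_roi > 0) {
        tries <- 0
        while (nrow(dk) < config$n_plaques_per_roi) {
          tries <- tries + 1
          if (tries > config$max_placement_tries *
                config$n_plaques_per_roi) {
            stop_("could not place %d non-overlapping plaques in a %g-um ROI",
                  config$n_plaques_per_roi, L)
          }
          rad <- stats::rlnorm(1, config$plaque_radius_log_mu,
                               config$plaque_radius_log_sd)
          cx <- runif(1, rad, L - rad); cy <- runif(1, rad, L - rad)
          if (nrow(dk) == 0 ||
              all(sqrt((dk$cx_um - cx)^2 + (dk$cy_um - cy)^2) >
                    dk$radius_um + rad)) {
            dk <- bind_rows(dk, tibble(
              roi_id = roi_id, plaque_id = as.character(nrow(dk) + 1),
              cx_um = cx, cy_um = cy, radius_um = rad))
          }
        }
      }
      disks_l[[roi_id]] <- dk

      n <- config$cells_per_roi
      x <- runif(n, 0, L); y <- runif(n, 0, L)
      cl <- sample(names(config$cluster_weights), n, replace = TRUE,
                   prob = config$cluster_weights)
      dist_b <- if (nrow(dk)) {
        apply(vapply(seq_len(nrow(dk)), function(p) {
          pmax(0, sqrt((x - dk$cx_um[p])^2 + (y - dk$cy_um[p])^2) -
                 dk$radius_um[p])
        }, numeric(n)), 1, min)
      } else rep(Inf, n)
      true_peri <- dist_b <= config$boost_radius_um

      row <- tibble(cell_id = sprintf("%s_c%04d", roi_id, seq_len(n)),
                    roi_id = roi_id, sample_id = sample_id,
                    diagnosis = config$diagnosis, region = "other",
                    x_um = x, y_um = y, cluster_label = cl)
      tru <- tibble(cell_id = row$cell_id, roi_id = roi_id,
                    true_peri = true_peri, distance_um = dist_b)
      # cell-type channels: high for own type, low otherwise
      for (tp in names(type_channel)) {
        ch <- type_channel[[tp]]
        state <- cl == tp
        row[[ch]] <- stats::rlnorm(n,
          ifelse(state, config$pos_log_mu, config$neg_log_mu),
          config$intensity_log_sd)
        tru[[paste0(ch, "_true")]] <- state
      }
      for (ch in sen_channels) {
        p0 <- config$baseline_rates[[ch]]
        p <- rep(p0, n)
        if (ch %in% names(config$peri_rates)) {
          p[true_peri] <- config$peri_rates[[ch]]
        }
        state <- rbinom(n, 1, p) == 1
        row[[ch]] <- stats::rlnorm(n,
          ifelse(state, config$pos_log_mu, config$neg_log_mu),
          config$intensity_log_sd)
        tru[[paste0(ch, "_true")]] <- state
      }
      cells_l[[roi_id]] <- row
      truth_l[[roi_id]] <- tru
    }
  }
  cells <- as_imaging_cell_table(
    bind_rows(cells_l),
    channels = c(unname(type_channel), sen_channels))
  disks <- bind_rows(disks_l)
  plaques <- if (nrow(disks)) plaque_set(disks = disks) else NULL
  list(cells = cells, plaques = plaques, truth = bind_rows(truth_l),
       config = config)
}

#' Rasterise disk plaques into integer label masks
#'
#' Builds one label matrix per ROI at `scale_um_per_px` resolution: a pixel
#' carries a plaque's label when its centre lies inside the disk. Used to
#' exercise mask-mode proximity classification against the same geometry.
#'
#' @param plaques A [plaque_set()] with disks.
#' @param roi_size_um ROI side length in micrometres.
#' @param scale_um_per_px Pixel size (default 1).
#' @return A [plaque_set()] carrying both the disks and the masks.
#' @export
rasterise_plaques <- function(plaques, roi_size_um, scale_um_per_px = 1) {
  stopifnot(inherits(plaques, "plaque_set"), !is.null(plaques$disks))
  npx <- as.integer(ceiling(roi_size_um / scale_um_per_px))
  ctr <- (seq_len(npx) - 0.5) * scale_um_per_px
  masks <- lapply(split(plaques$disks, plaques$disks$roi_id), function(dk) {
    m <- matrix(0L, npx, npx)
    for (p in seq_len(nrow(dk))) {
      dx2 <- outer((ctr - dk$cy_um[p])^2, (ctr - dk$cx_um[p])^2, `+`)
      m[dx2 <= dk$radius_um[p]^2] <- as.integer(dk$plaque_id[p])
    }
    m
  })
  plaque_set(disks = plaques$disks, masks = masks,
             scale_um_per_px = scale_um_per_px)
}
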
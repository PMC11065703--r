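#' Quality-control trimming of IMC cells and ROIs
#'
#' Two-stage trim used before quantifying senescent proportions in imaging
#' mass cytometry: (1) mean senescence-marker expression (averaged over
#' `senescence_channels`, then over cells) is computed per ROI and ROIs in
#' the lowest `trim_frac` quantile across all ROIs are excluded; (2) within
#' each remaining ROI, cells in the lowest `trim_frac` quantile of their
#' defining cell-type-marker intensity (the maximum over
#' `cell_type_channels`) are removed. Quantiles use the type-1 (order
#' statistic) definition and removal is inclusive at the cutoff, so ties at
#' the cutoff are all removed — which makes the trim idempotent when the
#' first pass's cutoffs are re-applied via `cutoffs`.
#'
#' @param cells An `imaging_cell_table`.
#' @param senescence_channels Channels defining senescence expression
#'   (e.g. GLB1, p16, p21, gH2AX).
#' @param cell_type_channels Channels defining cell identity
#'   (e.g. Iba1, GFAP).
#' @param trim_frac Trimmed fraction in `[0, 0.5)` (default 0.01); 0 is the
#'   identity.
#' @param cutoffs Optional cutoffs from a previous pass (the `qc_cutoffs`
#'   attribute of its result) to re-apply unchanged.
#' @return The filtered table, with attributes `qc_cutoffs` (ROI cutoff and
#'   per-ROI cell cutoffs) and `qc_log` (counts removed at each stage).
#' @export
qc_trim <- function(cells, senescence_channels, cell_type_channels,
                    trim_frac = 0.01, cutoffs = NULL) {
  stopifnot(trim_frac >= 0, trim_frac < 0.5)
  check_columns(cells, c(senescence_channels, cell_type_channels),
                "imaging cell table")
  if (trim_frac == 0 && is.null(cutoffs)) {
    attr(cells, "qc_log") <- tibble(stage = character(), removed = integer())
    return(cells)
  }
  cells <- mutate(cells,
    .roi_key = paste(.data$sample_id, .data$roi_id, sep = "\r"),
    .sen_mean = rowMeans(as.matrix(
      cells[, senescence_channels, drop = FALSE])),
    .def_int = do.call(pmax, c(as.list(
      cells[, cell_type_channels, drop = FALSE]), na.rm = TRUE)))

  roi_means <- cells %>%
    group_by(.data$.roi_key) %>%
    summarise(roi_mean = mean(.data$.sen_mean), .groups = "drop")
  roi_cut <- cutoffs$roi_cutoff %||%
    unname(quantile(roi_means$roi_mean, trim_frac, type = 1))
  drop_rois <- roi_means$.roi_key[roi_means$roi_mean <= roi_cut]
  if (is.null(cutoffs) && length(drop_rois) == nrow(roi_means)) {
    stop_("trimming at %.3g would remove every ROI", trim_frac)
  }
  kept <- filter(cells, !.data$.roi_key %in% drop_rois)

  cell_cuts <- cutoffs$cell_cutoffs %||% (
    kept %>%
      group_by(.data$.roi_key) %>%
      summarise(cell_cutoff = unname(quantile(.data$.def_int, trim_frac,
                                              type = 1)),
                .groups = "drop"))
  kept2 <- kept %>%
    left_join(cell_cuts, by = ".roi_key") %>%
    filter(is.na(.data$cell_cutoff) | .data$.def_int > .data$cell_cutoff)

  log <- tibble(stage = c("roi_trim", "cell_trim"),
                removed = c(nrow(cells) - nrow(kept),
                            nrow(kept) - nrow(kept2)))
  out <- select(kept2, -".roi_key", -".sen_mean", -".def_int", -"cell_cutoff")
  attr(out, "channels") <- imc_channels(cells)
  class(out) <- c("imaging_cell_table", class(tibble()))
  attr(out, "qc_cutoffs") <- list(roi_cutoff = roi_cut,
                                  cell_cutoffs = cell_cuts)
  attr(out, "qc_log") <- log
  out
}

#' Otsu threshold on log intensities
#'
#' Histogram-based two-class threshold (maximising between-class variance)
#' computed on `log1p` intensities and mapped back to the intensity scale.
#'
#' @param x Non-negative intensities.
#' @param n_breaks Histogram bins (default 256).
#' @return A single threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_breaks = 256) {
  lx <- log1p(x[is.finite(x)])
  if (length(unique(lx)) < 2) return(expm1(max(lx)))
  h <- hist(lx, breaks = seq(min(lx), max(lx), length.out = n_breaks + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  expm1(mids[which.max(sigma_b)])
}

#' Marker-positivity calls from channel intensities
#'
#' Thresholds channel intensities into boolean positivity calls. Each rule is
#' one of: a fixed intensity threshold, a per-ROI (or global) quantile, or an
#' Otsu threshold on log intensity. A cell is positive when its intensity is
#' strictly greater than the threshold. The applied rule and realised
#' threshold(s) are recorded in the `positivity_rules` attribute.
#'
#' @param cells An `imaging_cell_table`.
#' @param rules Named list, one entry per channel:
#'   `list(type = "fixed", value = 5)`,
#'   `list(type = "quantile", value = 0.9, per_roi = TRUE)` or
#'   `list(type = "otsu")`.
#' @return `cells` with a logical `<channel>_pos` column per rule and a
#'   `positivity_rules` attribute.
#' @export
call_markers <- function(cells, rules) {
  stopifnot(is.list(rules), !is.null(names(rules)))
  unknown <- setdiff(names(rules), names(cells))
  if (length(unknown)) stop_("unknown channel(s): %s",
                             paste(unknown, collapse = ", "))
  record <- list()
  for (ch in names(rules)) {
    rule <- rules[[ch]]
    type <- rule$type %||% "fixed"
    v <- cells[[ch]]
    if (type == "fixed") {
      thr <- rule$value
      if (is.null(thr)) stop_("fixed rule for '%s' needs a value", ch)
      cells[[paste0(ch, "_pos")]] <- v > thr
    } else if (type == "quantile") {
      prob <- rule$value %||% 0.9
      if (isTRUE(rule$per_roi)) {
        key <- paste(cells$sample_id, cells$roi_id, sep = "\r")
        thr <- tapply(v, key, quantile, probs = prob, names = FALSE)
        cells[[paste0(ch, "_pos")]] <- v > unname(thr[key])
      } else {
        thr <- unname(quantile(v, prob))
        cells[[paste0(ch, "_pos")]] <- v > thr
      }
    } else if (type == "otsu") {
      thr <- otsu_threshold(v)
      cells[[paste0(ch, "_pos")]] <- v > thr
    } else {
      stop_("unknown rule type '%s' for channel '%s'", type, ch)
    }
    record[[ch]] <- list(type = type, threshold = thr)
  }
  attr(cells, "positivity_rules") <- record
  cells
}

#' Senescent-cell proportions per sample and cluster
#'
#' For each (sample, cluster): the denominator is the number of cells
#' positive for the cluster's defining cell-type marker, and the numerator
#' the subset also positive for at least one senescence marker — the
#' ratio of cells co-expressing cell and senescence markers to cells
#' positive for cell markers only. ROI-level counts are summed to the sample
#' level; (sample, cluster) strata with fewer than `min_cells` marker-positive
#' cells are flagged excluded.
#'
#' @param cells Output of [call_markers()] (needs `<channel>_pos` columns and
#'   `cluster_label`).
#' @param cluster_markers Named character vector mapping cluster label to its
#'   defining cell-type channel, e.g. `c(Micro = "Iba1", Astro = "GFAP")`.
#' @param senescence_channels Senescence marker channels (their `_pos`
#'   columns must exist).
#' @param min_cells Minimum denominator (default 3).
#' @return Tibble: `sample_id`, `cluster_label`, carried `diagnosis`/`region`,
#'   `n_cells`, `n_senescent`, `proportion`, `excluded`, `reason`; plus a
#'   `per_roi` attribute with the unaggregated ROI-level counts.
#' @export
senescent_proportion_per_cluster <- function(cells, cluster_markers,
                                             senescence_channels,
                                             min_cells = 3) {
  check_columns(cells, "cluster_label", "imaging cell table")
  sen_pos_cols <- paste0(senescence_channels, "_pos")
  check_columns(cells, sen_pos_cols, "marker-call table")
  carry <- intersect(c("diagnosis", "region"), names(cells))
  cells <- filter(cells, .data$cluster_label %in% names(cluster_markers))
  marker_pos_col <- paste0(unname(cluster_markers[cells$cluster_label]), "_pos")
  check_columns(cells, unique(marker_pos_col), "marker-call table")
  cells$.marker_pos <- vapply(seq_len(nrow(cells)), function(i) {
    isTRUE(cells[[marker_pos_col[i]]][i])
  }, logical(1))
  cells$.sen_pos <- rowSums(as.matrix(cells[, sen_pos_cols, drop = FALSE])) > 0

  per_roi <- cells %>%
    filter(.data$.marker_pos) %>%
    group_by(across(all_of(c("sample_id", "roi_id", "cluster_label", carry)))) %>%
    summarise(n_cells = dplyr::n(),
              n_senescent = sum(.data$.sen_pos), .groups = "drop")
  out <- per_roi %>%
    group_by(across(all_of(c("sample_id", "cluster_label", carry)))) %>%
    summarise(n_cells = sum(.data$n_cells),
              n_senescent = sum(.data$n_senescent), .groups = "drop") %>%
    mutate(excluded = .data$n_cells < min_cells,
           proportion = ifelse(.data$excluded, NA_real_,
                               .data$n_senescent / .data$n_cells),
           reason = ifelse(.data$excluded,
                           sprintf("fewer than %d cells", min_cells),
                           NA_character_))
  attr(out, "per_roi") <- per_roi
  attr(out, "params_digest") <- params_digest(min_cells = min_cells)
  out
}

#' Classify cells as peri-plaque by proximity to plaque objects
#'
#' Labels each cell peri-plaque when it lies within `radius_um` of a plaque,
#' emulating the procedure of dilating 4G8+ plaque objects by 10 um and
#' keeping overlapping cells. Two modes:
#' \describe{
#'   \item{centroid}{distance from the cell centroid to the nearest plaque
#'     disk boundary (0 inside a plaque); peri-plaque iff the distance is
#'     `<= radius_um`, inclusive at exactly the radius.}
#'   \item{mask}{works in the pixel raster of the plaque label masks: a cell
#'     is peri-plaque iff its centroid pixel lies within the plaque labels
#'     morphologically dilated by a disc of `radius_um / scale` pixels
#'     (computed as nearest-plaque-pixel distance, which is exactly the disc
#'     dilation). Agrees with centroid mode on disk plaques to within one
#'     pixel.}
#' }
#' ROIs without plaques get `distance_um = Inf` and all cells non-plaque.
#'
#' @param cells An `imaging_cell_table`.
#' @param plaques A [plaque_set()] (mask mode requires masks).
#' @param radius_um Proximity radius in micrometres (default 10).
#' @param mode `"centroid"` or `"mask"`.
#' @return Tibble: `cell_id`, `roi_id`, `sample_id`, `nearest_plaque_id`,
#'   `distance_um`, `peri_plaque`.
#' @export
classify_peri_plaque <- function(cells, plaques, radius_um = 10,
                                 mode = c("centroid", "mask")) {
  mode <- match.arg(mode)
  stopifnot(radius_um > 0, inherits(plaques, "plaque_set"))
  if (mode == "mask" && is.null(plaques$masks)) {
    stop_("mask mode requires a plaque_set with label masks")
  }
  out <- purrr::map_dfr(split(as_tibble(cells), cells$roi_id), function(sub) {
    roi <- sub$roi_id[1]
    base <- sub[, c("cell_id", "roi_id", "sample_id")]
    if (mode == "centroid") {
      dk <- plaques$disks[plaques$disks$roi_id == roi, ]
      if (nrow(dk) == 0) {
        return(mutate(base, nearest_plaque_id = NA_character_,
                      distance_um = Inf, peri_plaque = FALSE))
      }
      d <- vapply(seq_len(nrow(dk)), function(p) {
        pmax(0, sqrt((sub$x_um - dk$cx_um[p])^2 +
                       (sub$y_um - dk$cy_um[p])^2) - dk$radius_um[p])
      }, numeric(nrow(sub)))
      d <- matrix(d, nrow = nrow(sub))
      nearest <- max.col(-d, ties.method = "first")
      mutate(base,
             nearest_plaque_id = as.character(dk$plaque_id[nearest]),
             distance_um = d[cbind(seq_len(nrow(sub)), nearest)],
             peri_plaque = .data$distance_um <= radius_um)
    } else {
      m <- plaques$masks[[roi]]
      s <- plaques$scale_um_per_px
      if (is.null(m) || !any(m > 0)) {
        return(mutate(base, nearest_plaque_id = NA_character_,
                      distance_um = Inf, peri_plaque = FALSE))
      }
      px <- which(m > 0, arr.ind = TRUE)
      labs <- m[px]
      # pixel (i, j) centre sits at ((j-0.5)*s, (i-0.5)*s)
      ci <- pmin(pmax(floor(sub$y_um / s) + 1, 1), nrow(m))
      cj <- pmin(pmax(floor(sub$x_um / s) + 1, 1), ncol(m))
      d2 <- vapply(seq_len(nrow(sub)), function(ic) {
        dd <- (px[, 1] - ci[ic])^2 + (px[, 2] - cj[ic])^2
        w <- which.min(dd)
        c(dd[w], labs[w])
      }, numeric(2))
      mutate(base,
             nearest_plaque_id = as.character(as.integer(d2[2, ])),
             distance_um = sqrt(d2[1, ]) * s,
             peri_plaque = sqrt(d2[1, ]) <= radius_um / s)
    }
  })
  out[match(cells$cell_id, out$cell_id), ]
}

#' Contrast marker positivity between peri-plaque and non-plaque microglia
#'
#' Among microglia (cells positive for `microglia_channel`), computes the
#' per-sample proportion positive for each senescence marker (and for all
#' markers jointly, `double_positive`) separately for peri-plaque and
#' non-plaque cells, then compares the paired per-sample proportions with a
#' Wilcoxon signed-rank test. This is the peri-plaque co-localisation
#' analysis in which GLB1 expression is far more frequent within 10 um of
#' plaques than beyond.
#'
#' @param cells Output of [call_markers()].
#' @param proximity Output of [classify_peri_plaque()] for the same cells.
#' @param markers Senescence marker channels (default `c("GLB1", "p16")`).
#' @param microglia_channel Microglial identity channel (default `"Iba1"`).
#' @return List with `proportions` (per sample x marker x compartment) and
#'   `effects` (one paired-test row per marker, or zero rows with a
#'   `skip_reason` attribute when no sample has both compartments).
#' @export
peri_vs_nonplaque_contrast <- function(cells, proximity,
                                       markers = c("GLB1", "p16"),
                                       microglia_channel = "Iba1") {
  check_columns(cells, paste0(c(markers, microglia_channel), "_pos"),
                "marker-call table")
  joined <- dplyr::inner_join(
    as_tibble(cells), proximity[, c("cell_id", "roi_id", "distance_um",
                                    "peri_plaque")],
    by = c("cell_id", "roi_id"))
  mg <- filter(joined, .data[[paste0(microglia_channel, "_pos")]])
  pos_cols <- paste0(markers, "_pos")
  mg$double_positive <- rowSums(as.matrix(mg[, pos_cols, drop = FALSE])) ==
    length(pos_cols)

  props <- purrr::map_dfr(c(setNames(pos_cols, markers),
                            double_positive = "double_positive"),
                          function(col) {
    mg %>%
      group_by(.data$sample_id, .data$peri_plaque) %>%
      summarise(n = dplyr::n(), n_pos = sum(.data[[col]]),
                proportion = .data$n_pos / .data$n, .groups = "drop")
  }, .id = "marker")
  props <- mutate(props, compartment = ifelse(.data$peri_plaque, "peri_plaque",
                                              "non_plaque"))

  wide <- props %>%
    select("marker", "sample_id", "compartment", "proportion") %>%
    tidyr::pivot_wider(names_from = "compartment", values_from = "proportion")
  if (!all(c("peri_plaque", "non_plaque") %in% names(wide))) {
    effects <- tibble(marker = character(), n_samples = integer(),
                      mean_peri = double(), mean_non = double(),
                      p_value = double())
    attr(effects, "skip_reason") <-
      "no sample has both peri-plaque and non-plaque microglia"
    return(list(proportions = props, effects = effects))
  }
  effects <- wide %>%
    filter(!is.na(.data$peri_plaque), !is.na(.data$non_plaque)) %>%
    group_by(.data$marker) %>%
    summarise(
      n_samples = dplyr::n(),
      mean_peri = mean(.data$peri_plaque),
      mean_non = mean(.data$non_plaque),
      p_value = if (dplyr::n() >= 2 &&
                    any(.data$peri_plaque != .data$non_plaque)) {
        suppressWarnings(wilcox.test(.data$peri_plaque, .data$non_plaque,
                                     paired = TRUE)$p.value)
      } else NA_real_,
      .groups = "drop")
  list(proportions = props, effects = effects)
}
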
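mk_roi_cells <- function(n_rois = 10, cells_per_roi = 10, sen_base = 5) {
  purrr::map_dfr(seq_len(n_rois), function(r) {
    tibble::tibble(
      cell_id = sprintf("r%d_c%d", r, seq_len(cells_per_roi)),
      roi_id = sprintf("roi%02d", r), sample_id = "s1", diagnosis = "AD",
      region = "other",
      x_um = seq_len(cells_per_roi) * 5, y_um = 10,
      Iba1 = seq_len(cells_per_roi),         # distinct defining intensities
      GLB1 = sen_base + r)                   # distinct ROI means
  }) |> as_imaging_cell_table(channels = c("Iba1", "GLB1"))
}

test_that("a 1% trim over 100 distinct-mean ROIs removes exactly one ROI", {
  cells <- mk_roi_cells(n_rois = 100)
  out <- qc_trim(cells, senescence_channels = "GLB1",
                 cell_type_channels = "Iba1", trim_frac = 0.01)
  log <- attr(out, "qc_log")
  expect_equal(dplyr::n_distinct(out$roi_id), 99)
  expect_false("roi01" %in% out$roi_id)  # the lowest-mean ROI
  # within each surviving 10-cell ROI the lowest defining intensity goes too
  expect_false(any(out$Iba1 == 1))
  expect_equal(log$removed[log$stage == "roi_trim"], 10L)
})

test_that("trim_frac zero is the identity", {
  cells <- mk_roi_cells(5)
  out <- qc_trim(cells, "GLB1", "Iba1", trim_frac = 0)
  expect_equal(nrow(out), nrow(cells))
  expect_equal(out$cell_id, cells$cell_id)
})

test_that("ties at the cutoff are removed inclusively and trims are idempotent", {
  cells <- mk_roi_cells(10)
  cells$GLB1[cells$roi_id %in% c("roi01", "roi02")] <- 6  # tie two ROI means
  out <- qc_trim(cells, "GLB1", "Iba1", trim_frac = 0.1)
  expect_false(any(c("roi01", "roi02") %in% out$roi_id))

  # frozen cutoffs: a second pass removes nothing new
  again <- qc_trim(out, "GLB1", "Iba1", trim_frac = 0.1,
                   cutoffs = attr(out, "qc_cutoffs"))
  expect_equal(nrow(again), nrow(out))
  expect_equal(again$cell_id, out$cell_id)
})

test_that("trimming everything is an error", {
  cells <- mk_roi_cells(3)
  cells$GLB1 <- 1  # all ROI means equal -> all at or below the cutoff
  expect_error(qc_trim(cells, "GLB1", "Iba1", trim_frac = 0.01), "every ROI")
})

test_that("marker rules threshold as documented", {
  cells <- tiny_imaging_table(2, channels = list(GLB1 = 1))
  cells$GLB1 <- c(3, 7)
  out <- call_markers(cells, list(GLB1 = list(type = "fixed", value = 5)))
  expect_equal(out$GLB1_pos, c(FALSE, TRUE))
  out0 <- call_markers(cells, list(GLB1 = list(type = "fixed", value = 0)))
  expect_equal(out0$GLB1_pos, c(TRUE, TRUE))  # strictly greater than 0
  expect_error(call_markers(cells, list(NoCh = list(type = "fixed", value = 1))),
               "NoCh")
  rules <- attr(out, "positivity_rules")
  expect_equal(rules$GLB1$threshold, 5)
})

test_that("Otsu separates a planted bimodal intensity mixture", {
  set.seed(50)
  n <- 4000
  state <- rbinom(n, 1, 0.4) == 1
  x <- ifelse(state, rlnorm(n, log(50), 0.3), rlnorm(n, log(1), 0.3))
  thr <- otsu_threshold(x)
  mis <- mean((x > thr) != state)
  expect_lt(mis, 0.02)
})

test_that("cluster proportions use co-expression counts with exclusions", {
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:12),
    roi_id = rep(c("roi1", "roi2"), each = 6),
    sample_id = "s1", diagnosis = "AD", region = "other",
    x_um = 1:12, y_um = 1, cluster_label = "Micro",
    Iba1_pos = c(rep(TRUE, 4), FALSE, FALSE, rep(TRUE, 4), FALSE, FALSE),
    GLB1_pos = c(TRUE, rep(FALSE, 5), TRUE, rep(FALSE, 5)),
    p16_pos = FALSE)
  props <- senescent_proportion_per_cluster(
    cells, c(Micro = "Iba1"), senescence_channels = c("GLB1", "p16"))
  # 8 Iba1+ cells across ROIs, 2 of them GLB1+ -> 0.25
  expect_equal(props$proportion, 0.25)
  per_roi <- attr(props, "per_roi")
  expect_equal(sum(per_roi$n_cells), props$n_cells)       # conservation
  expect_equal(sum(per_roi$n_senescent), props$n_senescent)

  # a cluster observed in < 3 marker-positive cells is excluded
  few <- cells[1:3, ]
  few$Iba1_pos <- c(TRUE, TRUE, FALSE)
  p2 <- senescent_proportion_per_cluster(few, c(Micro = "Iba1"),
                                         senescence_channels = c("GLB1", "p16"))
  expect_true(p2$excluded)
  expect_true(is.na(p2$proportion))
})

test_that("centroid-mode proximity is exact on analytic placements", {
  plaques <- plaque_set(disks = tibble::tibble(
    roi_id = "roi1", plaque_id = "1", cx_um = 100, cy_um = 100,
    radius_um = 20))
  cells <- tibble::tibble(
    cell_id = c("inside", "at5", "at10", "at15"),
    roi_id = "roi1", sample_id = "s1", diagnosis = "AD", region = "other",
    x_um = c(100, 125, 130, 135), y_um = 100, Iba1 = 1) |>
    as_imaging_cell_table(channels = "Iba1")
  prox <- classify_peri_plaque(cells, plaques, radius_um = 10)
  expect_equal(prox$distance_um, c(0, 5, 10, 15))
  expect_equal(prox$peri_plaque, c(TRUE, TRUE, TRUE, FALSE))  # inclusive at 10
  expect_equal(unique(prox$nearest_plaque_id), "1")
})

test_that("centroid-mode distances are rigid-motion invariant", {
  set.seed(17)
  base_cells <- tibble::tibble(
    cell_id = paste0("c", 1:30), roi_id = "roi1", sample_id = "s1",
    diagnosis = "AD", region = "other",
    x_um = runif(30, 0, 200), y_um = runif(30, 0, 200), Iba1 = 1)
  disks <- tibble::tibble(roi_id = "roi1", plaque_id = c("1", "2"),
                          cx_um = c(60, 150), cy_um = c(60, 120),
                          radius_um = c(15, 10))
  d0 <- classify_peri_plaque(as_imaging_cell_table(base_cells, "Iba1"),
                             plaque_set(disks = disks))$distance_um
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(x, y) cbind(x, y) %*% R
  cells_r <- base_cells
  xy <- rot(base_cells$x_um, base_cells$y_um)
  cells_r$x_um <- xy[, 1] + 500; cells_r$y_um <- xy[, 2] + 300
  dxy <- rot(disks$cx_um, disks$cy_um)
  disks_r <- disks; disks_r$cx_um <- dxy[, 1] + 500; disks_r$cy_um <- dxy[, 2] + 300
  d1 <- classify_peri_plaque(as_imaging_cell_table(cells_r, "Iba1"),
                             plaque_set(disks = disks_r))$distance_um
  expect_equal(d1, d0, tolerance = 1e-10)
})

test_that("mask mode agrees with centroid mode on rasterised disks", {
  sim <- simulate_imaging(imaging_sim_config(n_samples = 1,
                                             rois_per_sample = 2,
                                             cells_per_roi = 120, seed = 23))
  masks <- rasterise_plaques(sim$plaques, roi_size_um = 500,
                             scale_um_per_px = 1)
  cen <- classify_peri_plaque(sim$cells, sim$plaques, mode = "centroid")
  msk <- classify_peri_plaque(sim$cells, masks, mode = "mask")
  # agreement except within one pixel of the 10-um boundary
  boundary <- abs(cen$distance_um - 10) <= 1.5
  expect_true(all(cen$peri_plaque[!boundary] == msk$peri_plaque[!boundary]))
  expect_equal(cen$distance_um, msk$distance_um, tolerance = 1.5)
})

test_that("ROIs without plaques yield infinite distances and no peri calls", {
  cells <- tiny_imaging_table(4)
  plaques <- plaque_set(disks = tibble::tibble(
    roi_id = "other_roi", plaque_id = "1", cx_um = 1, cy_um = 1,
    radius_um = 5))
  prox <- classify_peri_plaque(cells, plaques)
  expect_true(all(is.infinite(prox$distance_um)))
  expect_false(any(prox$peri_plaque))
})

test_that("peri vs non-plaque contrast recovers a planted positivity boost", {
  sim <- simulate_imaging(imaging_sim_config(seed = 61, n_samples = 10))
  called <- call_markers(sim$cells, lapply(
    setNames(imc_channels(sim$cells), imc_channels(sim$cells)),
    function(ch) list(type = "fixed", value = sqrt(20))))
  prox <- classify_peri_plaque(called, sim$plaques, radius_um = 10)
  res <- peri_vs_nonplaque_contrast(called, prox)
  glb1 <- res$effects[res$effects$marker == "GLB1", ]
  expect_lt(glb1$p_value, 0.05)
  expect_gt(glb1$mean_peri, glb1$mean_non)
  # recovered rates near the generative 0.30 / 0.03
  expect_lt(abs(glb1$mean_peri - 0.30), 0.06)
  expect_lt(abs(glb1$mean_non - 0.03), 0.02)

  # no plaques: the contrast is skipped with a reason
  sim0 <- simulate_imaging(imaging_sim_config(seed = 62, n_samples = 2,
                                              n_plaques_per_roi = 0))
  called0 <- call_markers(sim0$cells, list(
    Iba1 = list(type = "fixed", value = sqrt(20)),
    GLB1 = list(type = "fixed", value = sqrt(20)),
    p16 = list(type = "fixed", value = sqrt(20))))
  prox0 <- tibble::tibble(cell_id = sim0$cells$cell_id,
                          roi_id = sim0$cells$roi_id,
                          sample_id = sim0$cells$sample_id,
                          nearest_plaque_id = NA_character_,
                          distance_um = Inf, peri_plaque = FALSE)
  res0 <- peri_vs_nonplaque_contrast(called0, prox0)
  expect_equal(nrow(res0$effects), 0)
  expect_match(attr(res0$effects, "skip_reason"), "no sample")
})
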
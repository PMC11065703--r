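test_that("expression MTX + sidecars round-trip losslessly", {
  ds <- tiny_dataset(3, 2)
  dir <- withr::local_tempdir()
  write_expression(ds, dir)
  back <- read_expression(file.path(dir, "matrix.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "cells.tsv"),
                          file.path(dir, "cell_meta.csv"))
  expect_equal(dim(back), c(3L, 2L))
  expect_equal(as.matrix(back$matrix), as.matrix(ds$matrix))
  expect_equal(back$gene_ids, ds$gene_ids)
  expect_equal(back$cell_meta$sample_id, ds$cell_meta$sample_id)
})

test_that("sidecar dimension mismatches are rejected with a named error", {
  ds <- tiny_dataset(3, 2)
  dir <- withr::local_tempdir()
  write_expression(ds, dir)
  writeLines(paste0("g", 1:4), file.path(dir, "genes.tsv"))
  expect_error(
    read_expression(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                    file.path(dir, "cells.tsv"),
                    file.path(dir, "cell_meta.csv")),
    "3 rows but .*4 gene ids")
})

test_that("expression_dataset validates ids, dimensions and sign", {
  m <- matrix(1:6, nrow = 3)
  meta <- tibble::tibble(cell_id = c("c1", "c2"), sample_id = "s",
                         diagnosis = "AD")
  expect_error(expression_dataset(m, c("g1", "g1", "g3"), c("c1", "c2"), meta),
               "not unique")
  expect_error(expression_dataset(m, c("g1", "g2"), c("c1", "c2"), meta),
               "3 rows but 2 gene ids")
  expect_error(expression_dataset(-m, paste0("g", 1:3), c("c1", "c2"), meta),
               "negative")
  meta_bad <- tibble::tibble(cell_id = c("c1", "c2"), sample_id = "s",
                             diagnosis = c("AD", NA))
  expect_error(expression_dataset(m, paste0("g", 1:3), c("c1", "c2"), meta_bad),
               "diagnosis")
})

test_that("GMT curation drops sets below the minimum size after dedup", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    paste(c("big", "na", paste0("G", 1:12)), collapse = "\t"),
    paste(c("small", "na", paste0("G", 1:7)), collapse = "\t"),
    # 12 entries but only 9 unique symbols: must be dropped at min 10
    paste(c("dupes", "na", paste0("G", c(1:9, 1:3))), collapse = "\t")),
    path)
  expect_message(sets <- read_gmt(path, min_genes = 10), "dropped 2 set")
  expect_named(sets, "big")
  expect_equal(attr(sets, "n_dropped"), 2L)
  all_sets <- read_gmt(path, min_genes = 1)
  expect_length(all_sets, 3)
  expect_equal(sort(all_sets$dupes), paste0("G", 1:9))
})

test_that("GMT parsing rejects empty files and short lines", {
  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_error(read_gmt(empty), "empty")
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ok\tna\tG1\tG2", "short\tna"), bad)
  expect_error(read_gmt(bad, min_genes = 1), "line 2")
})

test_that("curation keeps exactly the sets at or above min_genes (property)", {
  set.seed(42)
  for (rep in 1:10) {
    sizes <- sample(1:30, 8)
    path <- withr::local_tempfile(fileext = ".gmt")
    writeLines(vapply(seq_along(sizes), function(i) {
      paste(c(sprintf("set%d", i), "na", sprintf("S%d_%d", i, seq_len(sizes[i]))),
            collapse = "\t")
    }, character(1)), path)
    min_genes <- sample(1:15, 1)
    n_expected <- sum(sizes >= min_genes)
    if (n_expected == 0) {
      expect_error(suppressMessages(read_gmt(path, min_genes)), "no gene set")
    } else {
      sets <- suppressMessages(read_gmt(path, min_genes))
      expect_length(sets, n_expected)
    }
  }
})

test_that("imaging cell tables validate columns, coordinates and keys", {
  cells <- tiny_imaging_table()
  expect_s3_class(cells, "imaging_cell_table")
  expect_equal(nrow(cells), 6)
  expect_setequal(imc_channels(cells), c("Iba1", "GLB1"))

  df <- tibble::as_tibble(cells)
  expect_error(as_imaging_cell_table(df[, setdiff(names(df), "x_um")]),
               "x_um")
  df_bad <- df; df_bad$y_um <- as.character(df_bad$y_um); df_bad$y_um[3] <- "oops"
  expect_error(as_imaging_cell_table(df_bad), "row 3")
  df_dup <- df; df_dup$cell_id[2] <- df_dup$cell_id[1]
  expect_error(as_imaging_cell_table(df_dup), "not unique")
  df_neg <- df; df_neg$GLB1[1] <- -2
  expect_error(as_imaging_cell_table(df_neg, channels = c("Iba1", "GLB1")),
               "negative")
})

test_that("schema remapping renames file columns to the standard names", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::as_tibble(tiny_imaging_table())
  names(df)[names(df) == "x_um"] <- "CentroidX"
  utils::write.csv(df, path, row.names = FALSE)
  cells <- read_imaging_cells(path, schema = list(x_um = "CentroidX"))
  expect_equal(nrow(cells), 6)
  expect_true("x_um" %in% names(cells))
  expect_error(read_imaging_cells(path, schema = list(x_um = "NoSuch")),
               "NoSuch")
})

test_that("plaque disks validate and masks convert to objects", {
  expect_error(plaque_set(disks = tibble::tibble(
    roi_id = "r", plaque_id = "1", cx_um = 5, cy_um = 5, radius_um = -1)),
    "radius")
  m <- matrix(0L, 20, 20)
  m[3:6, 3:6] <- 1L          # 16 px
  m[15:16, 15:16] <- 2L      # 4 px
  ps <- plaque_set(masks = list(roiA = m), scale_um_per_px = 1)
  expect_equal(nrow(ps$disks), 2)
  expect_equal(ps$disks$n_px, c(16, 4))
  # centroid of label 1: rows/cols 3:6 -> pixel centres average 4.0
  expect_equal(ps$disks$cx_um[1], 4)
  expect_equal(ps$disks$cy_um[1], 4)
})

test_that("label-mask TIFF round-trips through read_plaques", {
  skip_if_not_installed("tiff")
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 1L
  m[8:9, 8:9] <- 2L
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  ps <- read_plaques(path, scale_um_per_px = 1, roi_id = "roi1")
  expect_equal(nrow(ps$disks), 2)
  expect_equal(sort(unique(as.vector(ps$masks$roi1))), c(0L, 1L, 2L))
})
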
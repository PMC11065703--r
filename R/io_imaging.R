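#' Read a segmented imaging (IMC) single-cell table
#'
#' Loads a CSV/TSV of segmented cells — one row per cell with ROI and sample
#' keys, centroid coordinates in micrometres (origin at the ROI top-left,
#' y increasing downward, matching the raster convention of label masks) and
#' per-channel mean intensities. Column names can be remapped through
#' `schema`, a named list `standard_name = file_column`.
#'
#' @param path CSV/TSV path.
#' @param schema Optional named list mapping the required names
#'   (`cell_id`, `roi_id`, `sample_id`, `x_um`, `y_um`, and optionally
#'   `diagnosis`, `region`, `cluster_label`) to columns in the file.
#' @param channels Character vector naming the intensity columns. Defaults to
#'   every numeric column not otherwise claimed.
#' @return A tibble of class `imaging_cell_table` with a `channels` attribute.
#' @export
read_imaging_cells <- function(path, schema = NULL, channels = NULL) {
  df <- read_table_auto(path)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      src <- schema[[std]]
      if (!src %in% names(df)) {
        stop_("schema maps '%s' to column '%s', absent from '%s'",
              std, src, path)
      }
      names(df)[names(df) == src] <- std
    }
  }
  as_imaging_cell_table(df, channels = channels)
}

#' Validate a data frame as an imaging cell table
#'
#' @param df Data frame with `cell_id`, `roi_id`, `sample_id`, `x_um`, `y_um`
#'   plus channel-intensity columns.
#' @param channels Channel column names; default all unclaimed numeric columns.
#' @return The validated tibble, classed `imaging_cell_table`.
#' @export
as_imaging_cell_table <- function(df, channels = NULL) {
  df <- as_tibble(df)
  required <- c("cell_id", "roi_id", "sample_id", "x_um", "y_um")
  check_columns(df, required, "imaging cell table")
  for (cc in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad)) stop_("non-numeric %s at row %d", cc, bad[1])
    df[[cc]] <- v
  }
  dup <- duplicated(df[, c("roi_id", "cell_id")])
  if (any(dup)) stop_("(roi_id, cell_id) pairs are not unique (e.g. row %d)",
                      which(dup)[1])
  claimed <- c(required, "diagnosis", "region", "cluster_label")
  if (is.null(channels)) {
    channels <- names(df)[!names(df) %in% claimed &
                            vapply(df, is.numeric, logical(1))]
  }
  missing <- setdiff(channels, names(df))
  if (length(missing)) stop_("channel column(s) absent: %s",
                             paste(missing, collapse = ", "))
  for (ch in channels) {
    if (any(df[[ch]] < 0, na.rm = TRUE)) {
      stop_("channel '%s' has negative intensities", ch)
    }
  }
  attr(df, "channels") <- channels
  class(df) <- c("imaging_cell_table", class(df))
  df
}

#' Channel names of an imaging cell table
#' @param cells An `imaging_cell_table`.
#' @return Character vector of intensity-column names.
#' @export
imc_channels <- function(cells) attr(cells, "channels")

#' Plaque objects for a set of ROIs
#'
#' Amyloid (4G8+) plaque objects, either as parametric disks — a tibble with
#' `roi_id`, `plaque_id`, `cx_um`, `cy_um`, `radius_um` — or as integer label
#' masks (one matrix per ROI, micrometre-per-pixel scale). Disk plaques are
#' the default geometry; masks support the dilation-based classification mode.
#'
#' @param disks Data frame of disk parameters, or `NULL`.
#' @param masks Named list of integer label matrices (names = ROI ids), or
#'   `NULL`.
#' @param scale_um_per_px Pixel size in micrometres for masks (default 1).
#' @return An object of class `plaque_set` with a `disks` tibble (derived from
#'   mask centroids/equivalent radii when only masks are given) and optional
#'   `masks`.
#' @export
plaque_set <- function(disks = NULL, masks = NULL, scale_um_per_px = 1) {
  if (is.null(disks) && is.null(masks)) {
    stop_("plaque_set needs disks and/or masks")
  }
  if (!is.null(disks)) {
    disks <- as_tibble(disks)
    check_columns(disks, c("roi_id", "plaque_id", "cx_um", "cy_um", "radius_um"),
                  "plaque disk table")
    bad <- which(!is.finite(disks$radius_um) | disks$radius_um <= 0)
    if (length(bad)) stop_("plaque radius must be > 0 (row %d)", bad[1])
  }
  if (!is.null(masks)) {
    stopifnot(is.list(masks), !is.null(names(masks)))
    for (nm in names(masks)) {
      m <- masks[[nm]]
      if (!is.matrix(m) || any(m < 0) || any(m != round(m))) {
        stop_("mask for ROI '%s' must be a non-negative integer label matrix", nm)
      }
    }
    if (is.null(disks)) disks <- mask_to_disks(masks, scale_um_per_px)
  }
  structure(list(disks = disks, masks = masks,
                 scale_um_per_px = scale_um_per_px),
            class = "plaque_set")
}

# Label-mask objects -> centroid + equivalent-radius disks.
# Mask rows index y (downward), columns index x; pixel (i, j) covers
# ((j-0.5)*s, (i-0.5)*s) at its centre.
mask_to_disks <- function(masks, scale) {
  purrr::map_dfr(names(masks), function(roi) {
    m <- masks[[roi]]
    labs <- sort(setdiff(unique(as.vector(m)), 0))
    purrr::map_dfr(labs, function(lb) {
      idx <- which(m == lb, arr.ind = TRUE)
      tibble(
        roi_id = roi, plaque_id = as.character(lb),
        cx_um = mean(idx[, 2] - 0.5) * scale,
        cy_um = mean(idx[, 1] - 0.5) * scale,
        radius_um = sqrt(nrow(idx) / pi) * scale,
        n_px = nrow(idx)
      )
    })
  })
}

#' @export
print.plaque_set <- function(x, ...) {
  cat(sprintf("<plaque_set> %d plaque(s) in %d ROI(s)%s\n",
              nrow(x$disks), dplyr::n_distinct(x$disks$roi_id),
              if (is.null(x$masks)) "" else
                sprintf(", label masks at %.3g um/px", x$scale_um_per_px)))
  invisible(x)
}

#' Read plaque objects from a disk-parameter CSV or a label-mask TIFF
#'
#' A `.csv`/`.tsv` path is parsed as disk parameters (`roi_id`, `plaque_id`,
#' `cx_um`, `cy_um`, `radius_um`). A `.tif`/`.tiff` path is read as an integer
#' label mask (requires the tiff package; the file must store integer labels)
#' for a single ROI.
#'
#' @param path Input path.
#' @param scale_um_per_px Micrometres per pixel for masks (default 1).
#' @param roi_id ROI id to assign to a mask (default the file base name).
#' @return A [plaque_set()].
#' @export
read_plaques <- function(path, scale_um_per_px = 1, roi_id = NULL) {
  if (grepl("\\.(csv|tsv|txt)$", path, ignore.case = TRUE)) {
    return(plaque_set(disks = read_table_auto(path)))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_("reading TIFF masks requires the 'tiff' package")
    }
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3) m <- m[, , 1]
    storage.mode(m) <- "integer"
    roi <- roi_id %||% sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
    return(plaque_set(masks = setNames(list(m), roi),
                      scale_um_per_px = scale_um_per_px))
  }
  stop_("unrecognised plaque file type: '%s'", path)
}
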
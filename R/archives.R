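#' Write a scanner-correction archive
#'
#' Stores a matrix correction (and optionally a dose-dependent transversal
#' correction) as a portable directory: per-channel `M_<channel>.csv`
#' float matrices, an `MD.csv` long table (channel, x, dose_Gy,
#' correction_PV) and a JSON manifest (lot, normalization ROI, scan count,
#' creation date, geometry).
#'
#' @param matrix a [build_matrix_correction()], or a list with `matrix`
#'   and `md` elements as returned by [read_correction_archive()].
#' @param dir destination directory (created if missing).
#' @param mdcorr optional [build_dose_transversal_correction()].
#' @return `dir`, invisibly.
#' @export
write_correction_archive <- function(matrix, dir, mdcorr = NULL) {
  if (is.list(matrix) && inherits(matrix$matrix, "matrix_correction")) {
    mdcorr <- mdcorr %||% matrix$md
    matrix <- matrix$matrix
  }
  if (!inherits(matrix, "matrix_correction"))
    stop_input("`matrix` must be a matrix_correction (or a list holding one)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in CHANNELS)
    write.csv(matrix$M[[ch]], file.path(dir, paste0("M_", ch, ".csv")),
              row.names = FALSE)
  manifest <- list(lot_id = matrix$lot_id, n_scans = matrix$n_scans,
                   width_px = matrix$width_px, height_px = matrix$height_px,
                   norm_roi = unclass(matrix$norm_roi),
                   norm_mean = as.list(matrix$norm_mean),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   has_md = !is.null(mdcorr))
  if (!is.null(mdcorr)) {
    manifest$dose_grid <- mdcorr$dose_grid
    manifest$norm_cols <- mdcorr$norm_cols
    rows <- do.call(rbind, lapply(CHANNELS, function(ch) {
      tab <- mdcorr$md[[ch]]
      do.call(rbind, lapply(seq_along(mdcorr$dose_grid), function(i)
        data.frame(channel = ch, x = seq_len(ncol(tab)) - 1L,
                   dose_Gy = mdcorr$dose_grid[i], correction_PV = tab[i, ])))
    }))
    write.csv(rows, file.path(dir, "MD.csv"), row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scanner-correction archive
#'
#' @param dir archive directory written by [write_correction_archive()].
#' @return list with `matrix` (a `matrix_correction`) and `md` (an
#'   `md_correction` or `NULL`).
#' @export
read_correction_archive <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop_input("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  M <- lapply(setNames(CHANNELS, CHANNELS), function(ch)
    as.matrix(read.csv(file.path(dir, paste0("M_", ch, ".csv")))))
  M <- lapply(M, function(m) { dimnames(m) <- NULL; m })
  nr <- mf$norm_roi
  matrix <- structure(list(
    M = M, norm_roi = roi(nr$x0, nr$y0, nr$width, nr$height),
    norm_mean = unlist(mf$norm_mean), n_scans = mf$n_scans,
    lot_id = mf$lot_id, width_px = mf$width_px, height_px = mf$height_px),
    class = "matrix_correction")
  md <- NULL
  if (isTRUE(mf$has_md)) {
    rows <- read.csv(file.path(dir, "MD.csv"), stringsAsFactors = FALSE)
    grid <- sort(unique(rows$dose_Gy))
    tabs <- lapply(setNames(CHANNELS, CHANNELS), function(ch) {
      sub <- rows[rows$channel == ch, ]
      tab <- matrix(0, length(grid), mf$width_px)
      for (i in seq_along(grid)) {
        si <- sub[sub$dose_Gy == grid[i], ]
        tab[i, si$x + 1L] <- si$correction_PV
      }
      rownames(tab) <- format(grid)
      tab
    })
    md <- structure(list(md = tabs, dose_grid = grid,
                         norm_cols = unlist(mf$norm_cols),
                         width_px = mf$width_px, height_px = mf$height_px),
                    class = "md_correction")
  }
  list(matrix = matrix, md = md)
}

#' Write a calibration archive
#'
#' JSON with lot, beam quality, per-channel rational parameters, dose
#' range, calibration date and fit residual summaries; optionally a CSV of
#' the calibration points alongside.
#'
#' @param curve a [calibration_curve()].
#' @param path JSON destination.
#' @param points optional calibration points data.frame written next to
#'   the JSON as `<path-sans-ext>_points.csv`.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(curve, path, points = NULL) {
  obj <- list(lot_id = curve$lot_id, q = curve$q, form = curve$form,
              dose_range_gy = curve$dose_range,
              calibration_date = format(curve$calibration_date),
              channels_for_dose = curve$channels_for_dose,
              params = lapply(curve$params, as.list),
              fit_rmse_gy = if (!is.null(curve$fit))
                lapply(curve$fit, `[[`, "rmse"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(points))
    write.csv(points,
              paste0(tools::file_path_sans_ext(path), "_points.csv"),
              row.names = FALSE)
  invisible(path)
}

#' Read a calibration archive
#'
#' @param path JSON written by [write_calibration_json()].
#' @return a [calibration_curve()].
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) stop_input("calibration file does not exist: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(lapply(j$params, unlist), lot_id = j$lot_id, q = j$q,
                    dose_range = unlist(j$dose_range_gy),
                    calibration_date = as.Date(j$calibration_date),
                    form = j$form,
                    channels_for_dose = unlist(j$channels_for_dose))
}

#' Export a dose map (float TIFF + JSON header + CSV)
#'
#' Writes `<base>.tif` (32-bit float, single channel, dose mapped into
#' \[0, 1\] by the `dose_offset_gy`/`dose_scale_gy` recorded in the
#' header), `<base>.json`
#' (pixel spacing, units, scale, provenance), `<base>.csv` (the dose
#' matrix) and `<base>_mask.tif` (8-bit flag mask).
#'
#' @param map a [dose_map()].
#' @param base output path base (no extension).
#' @return named vector of file paths, invisibly.
#' @export
write_dose_map <- function(map, base) {
  offset <- min(map$dose, 0)
  scale <- max(max(map$dose) - offset, 1e-9) * 1.0001
  tif <- paste0(base, ".tif")
  tiff::writeTIFF((map$dose - offset) / scale, tif, bits.per.sample = 32,
                  compression = "none")
  msk <- paste0(base, "_mask.tif")
  tiff::writeTIFF(pmin(map$mask, 255) / 255, msk, bits.per.sample = 8,
                  compression = "none")
  hdr <- paste0(base, ".json")
  jsonlite::write_json(list(units = "Gy", dose_scale_gy = scale,
                            dose_offset_gy = offset,
                            pixel_spacing_mm = map$pixel_spacing_mm,
                            width_px = ncol(map$dose),
                            height_px = nrow(map$dose),
                            provenance = map$provenance),
                       hdr, auto_unbox = TRUE, digits = NA)
  csv <- paste0(base, ".csv")
  write.csv(map$dose, csv, row.names = FALSE)
  invisible(c(tif = tif, json = hdr, csv = csv, mask = msk))
}

#' Read a dose map exported by [write_dose_map()]
#'
#' @param base the path base used at write time.
#' @return a [dose_map()].
#' @export
read_dose_map <- function(base) {
  hdr <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(paste0(base, ".tif"))
  msk <- round(tiff::readTIFF(paste0(base, "_mask.tif")) * 255)
  dose_map(img * hdr$dose_scale_gy + (hdr$dose_offset_gy %||% 0),
           pixel_spacing_mm = hdr$pixel_spacing_mm,
           mask = matrix(as.integer(msk), nrow(img)),
           provenance = as.list(hdr$provenance))
}
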
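#' Background homogeneity QC across film pieces
#'
#' Before calibration, the background reading of every film piece is
#' compared to the average over all pieces of the lot. A piece is rejected
#' when its relative deviation exceeds 0.5% in the red or green channel or
#' 1% in the blue channel (the blue channel is the most sensitive to
#' emulsion thickness and gets the wider tolerance).
#'
#' @param piece_means data.frame with a `piece_id` column and per-channel
#'   mean-PV columns `red`, `green`, `blue` (one row per piece).
#' @param thresholds rejection thresholds in percent:
#'   `c(rg = 0.5, b = 1)`.
#' @param lot_mean optional named per-channel reference means; default the
#'   column means over all pieces.
#' @return data.frame with per-channel relative deviations (%), the
#'   verdict (`"accept"`/`"reject"`) and the rule triggered.
#' @export
background_qc <- function(piece_means, thresholds = c(rg = 0.5, b = 1),
                          lot_mean = NULL) {
  if (!all(c("piece_id", CHANNELS) %in% names(piece_means)))
    stop_input("piece_means needs columns piece_id, red, green, blue")
  if (nrow(piece_means) < 2 && is.null(lot_mean))
    stop_input("need at least 2 pieces to define a lot mean")
  lm0 <- lot_mean %||% vapply(piece_means[CHANNELS], mean, 0)
  dev <- sapply(CHANNELS, function(ch)
    (piece_means[[ch]] - lm0[[ch]]) / lm0[[ch]] * 100)
  dev <- matrix(dev, nrow = nrow(piece_means),
                dimnames = list(NULL, CHANNELS))
  lim <- c(red = thresholds[["rg"]], green = thresholds[["rg"]],
           b = thresholds[["b"]])
  hit_r <- abs(dev[, "red"]) > lim["red"]
  hit_g <- abs(dev[, "green"]) > lim["green"]
  hit_b <- abs(dev[, "blue"]) > lim["b"]
  rule <- character(nrow(piece_means))
  rule[hit_b] <- "blue>1%"
  rule[hit_g] <- "green>0.5%"
  rule[hit_r] <- "red>0.5%"
  data.frame(piece_id = piece_means$piece_id,
             dev_red_pct = dev[, "red"], dev_green_pct = dev[, "green"],
             dev_blue_pct = dev[, "blue"],
             verdict = ifelse(hit_r | hit_g | hit_b, "reject", "accept"),
             rule = rule, stringsAsFactors = FALSE)
}

#' Blue-channel homogeneity QC of a film sheet
#'
#' Emulsion spreading makes sheet sensitivity vary in longitudinal bands,
#' visible mainly in the blue channel of unexposed film. The per-column
#' blue mean profile is compared to the sheet mean; a sheet whose profile
#' deviates by more than the tolerance (1% by default) anywhere is
#' rejected, and the offending band is localized.
#'
#' For full-bed scans the scanner's own transversal sensitivity (up to
#' ~1800 PV) dwarfs film bands, so pass the matrix correction to flatten
#' the scanner first.
#'
#' @param sheet_scan unexposed [film_scan()] of the sheet.
#' @param tolerance maximum allowed relative deviation in percent.
#' @param matrix optional [build_matrix_correction()] applied before
#'   profiling.
#' @param roi optional [roi()] restricting the analysis.
#' @return list with `profile` (data.frame: column, mean PV, deviation %),
#'   `max_dev_pct`, `max_dev_col` (0-based) and `verdict`.
#' @export
homogeneity_qc_blue <- function(sheet_scan, tolerance = 1, matrix = NULL,
                                roi = NULL) {
  if (!is.null(sheet_scan$exposure_time) && !is.null(sheet_scan$scan_time) &&
      sheet_scan$scan_time > sheet_scan$exposure_time)
    warning("scan appears to be of exposed film; homogeneity QC is meant ",
            "for unexposed film", call. = FALSE)
  plane <- if (is.null(matrix)) sheet_scan$channels$blue
           else apply_matrix_correction(sheet_scan, matrix)$blue
  x_offset <- 0L
  if (!is.null(roi)) {
    check_roi_bounds(roi, sheet_scan$width_px, sheet_scan$height_px)
    plane <- roi_slice(plane, roi)
    x_offset <- roi$x0
  }
  prof <- colMeans(plane)
  m <- mean(prof)
  dev <- (prof - m) / m * 100
  imax <- which.max(abs(dev))
  list(profile = data.frame(column = x_offset + seq_along(prof) - 1L,
                            mean_pv = prof, dev_pct = dev),
       max_dev_pct = abs(dev[imax]),
       max_dev_col = x_offset + imax - 1L,
       verdict = if (abs(dev[imax]) > tolerance) "reject" else "accept")
}

#' Read-out timing window check
#'
#' Film darkening continues after exposure; the protocol reads films four
#' days (96 h) after irradiation with a +/-12 h tolerance. A shorter 48 h
#' window can be used with a tight +/-0.5 to 1 h tolerance. The check
#' passes when the exposure-to-scan delay sits inside the window.
#'
#' @param exposure_time,scan_time `POSIXct` timestamps; missing values
#'   yield a warn-only verdict.
#' @param window_hours nominal exposure-to-read delay (default 96 h).
#' @param tolerance_hours allowed deviation (default 12 h; use 0.5-1 h
#'   with a 48 h window).
#' @return list with `verdict` (`"pass"`/`"warn"`), the measured delay in
#'   hours and the window used.
#' @export
timing_check <- function(exposure_time, scan_time, window_hours = 96,
                         tolerance_hours = 12) {
  if (is.null(exposure_time) || is.null(scan_time) ||
      is.na(exposure_time) || is.na(scan_time))
    return(list(verdict = "warn", delta_hours = NA_real_,
                window_hours = window_hours,
                tolerance_hours = tolerance_hours,
                reason = "missing timestamps"))
  delta <- as.numeric(difftime(scan_time, exposure_time, units = "hours"))
  ok <- abs(delta - window_hours) <= tolerance_hours
  list(verdict = if (ok) "pass" else "warn", delta_hours = delta,
       window_hours = window_hours, tolerance_hours = tolerance_hours,
       reason = if (ok) NULL else
         sprintf("read-out %0.1f h after exposure, outside %g h +/- %g h",
                 delta, window_hours, tolerance_hours))
}
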
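#' Construct a film scan
#'
#' A `film_scan` holds the three 16-bit colour channel planes of one
#' transmission scan together with its geometry and acquisition metadata.
#' Full-bed scans at 72 dpi are 576 x 720 pixels (the whole scanner plate is
#' always digitised so transversal/longitudinal positions stay fixed).
#' The X axis (columns) is the transversal direction, where the scanner's
#' dose-dependent lateral artifact lives; Y (rows) is longitudinal.
#' Coordinates are 0-based with the origin at the top-left pixel.
#'
#' @param channels named list with elements `red`, `green`, `blue`, each a
#'   numeric matrix (rows = height, cols = width) of pixel values in
#'   \[0, 65535\]. Values may be non-integer (e.g. after scan averaging).
#' @param dpi scan resolution in dots per inch (the protocol fixes 72).
#' @param film_id,lot_id identification strings for the film piece and its
#'   production lot.
#' @param orientation_tag one of `"normal"`, `"rot180"`, `"flipped"`,
#'   `"flipped_rot180"` (the four-orientation read-out protocol).
#' @param scan_time,exposure_time optional `POSIXct` timestamps.
#' @param scan_index position of this scan within a repeated-scan burst
#'   (1-based), used for drift-trend correction.
#' @return an object of class `film_scan`.
#' @export
film_scan <- function(channels, dpi = SCAN_DPI, film_id = "unknown",
                      lot_id = "unknown", orientation_tag = "normal",
                      scan_time = NULL, exposure_time = NULL,
                      scan_index = 1L) {
  if (!is.list(channels) || !all(CHANNELS %in% names(channels)))
    stop_input("`channels` must be a named list with red, green and blue planes")
  channels <- channels[CHANNELS]
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE)))
    stop_input("each channel plane must be a numeric matrix")
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop_input("all three channel planes must share identical dimensions")
  rng <- range(vapply(channels, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 65535)
    stop_input("pixel values must lie within the 16-bit range [0, 65535]")
  orientation_tag <- match.arg(orientation_tag, ORIENTATION_TAGS)
  structure(list(
    channels = channels,
    width_px = ncol(channels$red),
    height_px = nrow(channels$red),
    dpi = as.integer(dpi),
    film_id = film_id,
    lot_id = lot_id,
    orientation_tag = orientation_tag,
    scan_time = scan_time,
    exposure_time = exposure_time,
    scan_index = as.integer(scan_index)
  ), class = "film_scan")
}

is_film_scan <- function(x) inherits(x, "film_scan")

#' @export
print.film_scan <- function(x, ...) {
  cat(sprintf("<film_scan> %d x %d px @ %d dpi, film %s (lot %s), %s, scan #%d\n",
              x$width_px, x$height_px, x$dpi, x$film_id, x$lot_id,
              x$orientation_tag, x$scan_index))
  for (ch in CHANNELS)
    cat(sprintf("  %-5s PV range [%.0f, %.0f]\n", ch,
                min(x$channels[[ch]]), max(x$channels[[ch]])))
  invisible(x)
}

is_full_bed <- function(scan) {
  scan$width_px == FULL_BED_WIDTH && scan$height_px == FULL_BED_HEIGHT
}

#' Define a rectangular region of interest
#'
#' ROIs use 0-based top-left coordinates and half-open extents
#' \[x0, x0+width) x \[y0, y0+height), so adjacent ROIs tile without overlap.
#'
#' @param x0,y0 0-based top-left corner (x = transversal column,
#'   y = longitudinal row).
#' @param width,height extent in pixels, both > 0.
#' @return an object of class `film_roi`.
#' @export
roi <- function(x0, y0, width, height) {
  if (width <= 0 || height <= 0) stop_input("ROI width and height must be > 0")
  if (x0 < 0 || y0 < 0) stop_input("ROI origin must be non-negative")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "film_roi")
}

#' Centered ROI from physical dimensions
#'
#' Converts centimetre dimensions to pixels at the scan resolution
#' (72 dpi by default, the fixed protocol value) with rounding to the
#' nearest pixel, and centres the ROI on the scan area. The 3 cm x 4 cm
#' normalization area in the middle of the scanner plate and the
#' 35 mm x 40 mm scoring area are both expressed this way.
#'
#' @param width_cm,height_cm physical ROI size in cm.
#' @param image_width,image_height scan dimensions in pixels.
#' @param dpi scan resolution.
#' @return a `film_roi` centred on the image.
#' @export
roi_cm_center <- function(width_cm, height_cm,
                          image_width = FULL_BED_WIDTH,
                          image_height = FULL_BED_HEIGHT,
                          dpi = SCAN_DPI) {
  w <- round(width_cm / 2.54 * dpi)
  h <- round(height_cm / 2.54 * dpi)
  roi(floor((image_width - w) / 2), floor((image_height - h) / 2), w, h)
}

#' The standard 3 cm x 4 cm normalization ROI at the plate centre
#' @inheritParams roi_cm_center
#' @return a `film_roi`.
#' @export
normalization_roi <- function(image_width = FULL_BED_WIDTH,
                              image_height = FULL_BED_HEIGHT,
                              dpi = SCAN_DPI) {
  roi_cm_center(3, 4, image_width, image_height, dpi)
}

check_roi_bounds <- function(r, width, height) {
  if (!inherits(r, "film_roi")) stop_input("expected a `film_roi`")
  if (r$x0 + r$width > width || r$y0 + r$height > height)
    stop_input(sprintf("ROI [%d,%d %dx%d] extends outside the %dx%d image",
                       r$x0, r$y0, r$width, r$height, width, height))
  invisible(r)
}

# extract the ROI submatrix from a channel plane (0-based half-open ROI)
roi_slice <- function(plane, r) {
  plane[(r$y0 + 1):(r$y0 + r$height), (r$x0 + 1):(r$x0 + r$width), drop = FALSE]
}

#' ROI pixel statistics
#'
#' Mean and population standard deviation of pixel values within a
#' half-open ROI of one colour channel.
#'
#' @param scan a [film_scan()].
#' @param roi a [roi()] fully inside the scan.
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @return a list with `mean`, `sd` (population SD) and `n`.
#' @export
roi_stats <- function(scan, roi, channel = "red") {
  channel <- match.arg(channel, CHANNELS)
  check_roi_bounds(roi, scan$width_px, scan$height_px)
  v <- as.vector(roi_slice(scan$channels[[channel]], roi))
  n <- length(v)
  m <- mean(v)
  list(mean = m, sd = sqrt(sum((v - m)^2) / n), n = n)
}

#' Average a burst of repeated scans of one film
#'
#' Repeated scans of the same film are combined into a single reading.
#' With five or fewer scans a pixelwise mean is used. With more than five
#' scans, the scanner light measurably darkens exposed film (the reading
#' rises by about 0.03% per successive scan), so a per-pixel linear trend
#' over `scan_index` is fitted and evaluated at the first scan's index,
#' removing the drift.
#'
#' @param scans list of [film_scan()] objects of the same film with
#'   identical dimensions and strictly increasing `scan_index`.
#' @return a `film_scan` carrying the averaged (possibly non-integer)
#'   pixel values and the first scan's metadata.
#' @export
average_repeated_scans <- function(scans) {
  if (length(scans) < 1) stop_input("need at least one scan")
  if (!all(vapply(scans, is_film_scan, TRUE)))
    stop_input("all elements must be film_scan objects")
  first <- scans[[1]]
  ids <- vapply(scans, function(s) s$film_id, "")
  if (length(unique(ids)) != 1)
    stop_input("scans come from different films: ", paste(unique(ids), collapse = ", "))
  dims_ok <- vapply(scans, function(s)
    s$width_px == first$width_px && s$height_px == first$height_px, TRUE)
  if (!all(dims_ok)) stop_input("scans have mismatched dimensions")
  idx <- vapply(scans, function(s) s$scan_index, 1L)
  if (length(idx) > 1 && any(diff(idx) <= 0))
    stop_input("scan_index must be strictly increasing across the burst")

  n <- length(scans)
  out <- first
  if (n <= 5) {
    for (ch in CHANNELS) {
      acc <- scans[[1]]$channels[[ch]]
      for (i in seq_len(n)[-1]) acc <- acc + scans[[i]]$channels[[ch]]
      out$channels[[ch]] <- acc / n
    }
  } else {
    # per-pixel least-squares line over scan_index, evaluated at idx[1]
    t <- as.numeric(idx)
    tb <- mean(t)
    stt <- sum((t - tb)^2)
    for (ch in CHANNELS) {
      mb <- 0
      sxy <- 0
      for (i in seq_len(n)) {
        p <- scans[[i]]$channels[[ch]]
        mb <- mb + p
        sxy <- sxy + (t[i] - tb) * p
      }
      mb <- mb / n
      slope <- sxy / stt
      out$channels[[ch]] <- mb + slope * (t[1] - tb)
    }
  }
  out$scan_index <- first$scan_index
  out
}
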
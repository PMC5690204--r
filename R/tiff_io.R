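#' Read a 48-bit RGB film scan from TIFF
#'
#' Reads an RGB TIFF with 16 bits per channel into a [film_scan()] without
#' any colour transformation (the protocol disables all colour management).
#' 8-bit or grayscale images are rejected. Scan metadata is taken from the
#' `metadata` argument, or from a JSON sidecar written by
#' [write_film_tiff()] (`<path>.json`) when present.
#'
#' @param path path to the TIFF file.
#' @param metadata optional named list overriding sidecar metadata
#'   (`film_id`, `lot_id`, `orientation_tag`, `scan_time`, `exposure_time`,
#'   `scan_index`).
#' @return a [film_scan()].
#' @export
read_film_tiff <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop_input("file does not exist: ", path)
  img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) stop_input("not a readable TIFF: ", path,
                                                 " (", conditionMessage(e), ")"))
  info <- attributes(img)
  bits <- info$bits.per.sample %||% NA
  if (!identical(as.integer(bits), 16L))
    stop_input("expected 16 bits per channel, got ", bits,
               " (8-bit or other bit depths are not valid film scans)")
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop_input("expected an RGB image, got a grayscale or non-RGB TIFF")
  dpi <- SCAN_DPI
  if (!is.null(info$x.resolution)) {
    dpi <- as.integer(round(info$x.resolution))
    if (dpi != SCAN_DPI)
      warning("scan resolution is ", dpi, " dpi; the protocol assumes 72 dpi",
              call. = FALSE)
  }
  # readTIFF scales to [0,1] by 1/65535; undo exactly
  planes <- lapply(1:3, function(k) round(img[, , k] * 65535))
  names(planes) <- CHANNELS

  md <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) md <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!is.null(metadata)) md[names(metadata)] <- metadata
  parse_time <- function(x) {
    if (is.null(x) || (is.character(x) && !nzchar(x))) return(NULL)
    if (inherits(x, "POSIXct")) return(x)
    t <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    if (is.na(t)) t <- as.POSIXct(x, tz = "UTC")
    t
  }
  film_scan(planes, dpi = dpi,
            film_id = md$film_id %||% "unknown",
            lot_id = md$lot_id %||% "unknown",
            orientation_tag = md$orientation_tag %||% "normal",
            scan_time = parse_time(md$scan_time),
            exposure_time = parse_time(md$exposure_time),
            scan_index = md$scan_index %||% 1L)
}

#' Write a film scan as lossless 48-bit RGB TIFF
#'
#' Pixel values are rounded to integers and stored losslessly (no
#' compression); reading the file back reproduces the stored values
#' bit-exactly. A JSON metadata sidecar (`<path>.json`) records film and
#' lot identity, orientation, timestamps and scan index.
#'
#' @param scan a [film_scan()].
#' @param path destination file path.
#' @param sidecar write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_film_tiff <- function(scan, path, sidecar = TRUE) {
  if (!is_film_scan(scan)) stop_input("`scan` must be a film_scan")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_input("directory does not exist: ", dir)
  img <- array(0, dim = c(scan$height_px, scan$width_px, 3))
  for (k in 1:3) img[, , k] <- round(scan$channels[[CHANNELS[k]]])
  ok <- tryCatch(tiff::writeTIFF(img / 65535, path, bits.per.sample = 16,
                                 compression = "none"),
                 error = function(e) stop_input("cannot write TIFF at ", path,
                                                ": ", conditionMessage(e)))
  if (isTRUE(sidecar)) {
    fmt_time <- function(x) if (is.null(x)) NULL else
      format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    md <- list(film_id = scan$film_id, lot_id = scan$lot_id,
               orientation_tag = scan$orientation_tag,
               scan_time = fmt_time(scan$scan_time),
               exposure_time = fmt_time(scan$exposure_time),
               scan_index = scan$scan_index, dpi = scan$dpi)
    jsonlite::write_json(md[!vapply(md, is.null, TRUE)], paste0(path, ".json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}
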
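#' Restore a dose map to the film frame
#'
#' The four-orientation read-out scans the film normal, rotated 180
#' degrees, flipped, and flipped + rotated. After correction and dose
#' conversion each map is restored to the film's original frame by the
#' pixel-exact inverse transform (pure index permutation, no
#' interpolation). All four operations are involutions, so applying a
#' restore twice gives back the input.
#'
#' @param map a [dose_map()] or a plain numeric matrix.
#' @param tag orientation tag; defaults to the map's provenance.
#' @return the restored object of the same type, tagged `"normal"`.
#' @export
restore_orientation <- function(map, tag = NULL) {
  if (is.matrix(map)) {
    tag <- match.arg(tag, ORIENTATION_TAGS)
    return(orient_matrix(map, tag))
  }
  if (!inherits(map, "dose_map")) stop_input("expected a dose_map or matrix")
  tag <- tag %||% map$provenance$orientation
  if (is.null(tag)) stop_input("no orientation tag available")
  tag <- match.arg(tag, ORIENTATION_TAGS)
  map$dose <- orient_matrix(map$dose, tag)
  map$mask <- orient_matrix(map$mask, tag)
  if (!is.null(map$channel_doses))
    map$channel_doses <- lapply(map$channel_doses, orient_matrix, tag = tag)
  map$provenance$orientation <- "normal"
  map$provenance$restored_from <- tag
  map
}

#' Merge restored orientation dose maps with outlier rejection
#'
#' Dust on the scanner glass contaminates single orientations at random
#' positions, while the film's true dose appears consistently in all four
#' restored maps. Per pixel, any orientation deviating from the median of
#' the four by more than `max(outlier_rel * |median|, outlier_abs_gy)` is
#' masked, and the mean over the surviving orientations is taken. At least
#' two orientations always contribute: if fewer survive the threshold, the
#' two values closest to the median are used and the pixel is flagged
#' unreliable.
#'
#' @param maps list of 2-4 restored [dose_map()]s (or matrices) of
#'   identical dimensions with distinct orientation provenance.
#' @param outlier_rel relative outlier threshold (default 2% of the local
#'   median dose).
#' @param outlier_abs_gy absolute threshold floor in Gy (default 0.04 Gy).
#' @return an object of class `merged_dose`: the mean dose map, a
#'   height x width x n logical exclusion mask, the per-pixel spread
#'   (max - min of contributors), and the unreliable-pixel flags.
#' @export
merge_orientations <- function(maps, outlier_rel = 0.02,
                               outlier_abs_gy = 0.04) {
  planes <- lapply(maps, function(m) if (is.matrix(m)) m else m$dose)
  n <- length(planes)
  if (n < 2) stop_input("need at least two restored maps to merge")
  dims <- lapply(planes, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop_input("restored maps have mismatched dimensions")
  tags <- vapply(maps, function(m)
    if (is.matrix(m)) NA_character_ else
      (m$provenance$restored_from %||% m$provenance$orientation %||% NA_character_),
    "")
  if (!anyNA(tags) && anyDuplicated(tags))
    stop_input("orientation tags are not distinct: ",
               paste(tags, collapse = ", "))
  H <- dims[[1]][1]; W <- dims[[1]][2]
  arr <- array(unlist(planes), dim = c(H, W, n))
  med <- if (n == 4) {
    (arr[, , 1] + arr[, , 2] + arr[, , 3] + arr[, , 4] -
       pmax(arr[, , 1], arr[, , 2], arr[, , 3], arr[, , 4]) -
       pmin(arr[, , 1], arr[, , 2], arr[, , 3], arr[, , 4])) / 2
  } else apply(arr, c(1, 2), median)
  thr <- pmax(outlier_rel * abs(med), outlier_abs_gy)
  excl <- array(FALSE, dim = c(H, W, n))
  for (k in seq_len(n)) excl[, , k] <- abs(arr[, , k] - med) > thr
  n_surv <- n - apply(excl, c(1, 2), sum)
  unreliable <- n_surv < 2
  if (any(unreliable)) {
    # fall back to the two values nearest the median at starved pixels
    idx <- which(unreliable)
    for (px in idx) {
      yy <- ((px - 1) %% H) + 1; xx <- ((px - 1) %/% H) + 1
      d <- abs(arr[yy, xx, ] - med[yy, xx])
      keep <- order(d)[1:2]
      excl[yy, xx, ] <- !(seq_len(n) %in% keep)
    }
  }
  wsum <- matrix(0, H, W); cnt <- matrix(0, H, W)
  mx <- matrix(-Inf, H, W); mn <- matrix(Inf, H, W)
  for (k in seq_len(n)) {
    use <- !excl[, , k]
    wsum <- wsum + arr[, , k] * use
    cnt <- cnt + use
    mx <- pmax(mx, ifelse(use, arr[, , k], -Inf))
    mn <- pmin(mn, ifelse(use, arr[, , k], Inf))
  }
  merged <- wsum / cnt
  spacing <- if (inherits(maps[[1]], "dose_map")) maps[[1]]$pixel_spacing_mm
             else 25.4 / SCAN_DPI
  structure(list(
    dose = merged,
    map = dose_map(merged, pixel_spacing_mm = spacing,
                   mask = matrix(as.integer(unreliable), H, W),
                   provenance = list(merged_from = tags, n_orientations = n)),
    excluded = excl, n_excluded = apply(excl, c(1, 2), sum),
    spread = mx - mn, unreliable = unreliable,
    tags = tags), class = "merged_dose")
}

#' @export
print.merged_dose <- function(x, ...) {
  cat(sprintf("<merged_dose> %dx%d px from %d orientations, mean %.3f Gy, %d px excluded somewhere, %d unreliable\n",
              ncol(x$dose), nrow(x$dose), dim(x$excluded)[3], mean(x$dose),
              sum(x$n_excluded > 0), sum(x$unreliable)))
  invisible(x)
}

#' Extract a 1D dose profile from a map
#'
#' Averages a band of rows (transversal profile, along X) or columns
#' (longitudinal, along Y) centred on `position`, optionally normalizing
#' to the central value for relative profiles.
#'
#' @param map a [dose_map()], [merge_orientations()] result, or matrix.
#' @param axis `"transversal"` (default) or `"longitudinal"`.
#' @param position 0-based centre row (transversal) / column
#'   (longitudinal) of the averaging band; default the map centre.
#' @param width_px band width in pixels.
#' @param normalize divide by the central profile value.
#' @return data.frame with `index` (0-based), `position_mm` and `value`.
#' @export
extract_profile <- function(map, axis = c("transversal", "longitudinal"),
                            position = NULL, width_px = 20,
                            normalize = FALSE) {
  axis <- match.arg(axis)
  plane <- if (is.matrix(map)) map else map$dose
  spacing <- if (is.matrix(map)) 25.4 / SCAN_DPI else
    (map$pixel_spacing_mm %||% map$map$pixel_spacing_mm %||% 25.4 / SCAN_DPI)
  H <- nrow(plane); W <- ncol(plane)
  extent <- if (axis == "transversal") H else W
  position <- position %||% ((extent - 1) / 2)
  lo <- max(1, round(position + 1 - width_px / 2))
  hi <- min(extent, round(position + width_px / 2))
  if (lo > hi || position < 0 || position > extent - 1)
    stop_input("profile band lies outside the map")
  v <- if (axis == "transversal") colMeans(plane[lo:hi, , drop = FALSE])
       else rowMeans(plane[, lo:hi, drop = FALSE])
  if (normalize) {
    ctr <- v[floor((length(v) - 1) / 2) + 1]
    if (ctr == 0) stop_input("cannot normalize: central profile value is 0")
    v <- v / ctr
  }
  data.frame(index = seq_along(v) - 1L,
             position_mm = (seq_along(v) - 1) * spacing, value = v)
}

#' Compare a measured profile to a reference
#'
#' Both profiles are centre-normalized (so a global scale cancels) and the
#' reference is linearly resampled to the test profile's relative grid if
#' the sampling differs. Reported are the maximum and mean absolute
#' relative differences over the central fraction of the overlap.
#'
#' @param test,reference numeric vectors or [extract_profile()] frames.
#' @param region central fraction over which to compare (default 0.8).
#' @return list with `max_rel_diff`, `mean_rel_diff` and `n` points
#'   compared.
#' @export
compare_profiles <- function(test, reference, region = 0.8) {
  as_vec <- function(p) if (is.data.frame(p)) p$value else as.numeric(p)
  tv <- as_vec(test); rv <- as_vec(reference)
  if (length(tv) < 3 || length(rv) < 3) stop_input("profiles too short")
  if (length(rv) != length(tv)) {
    u <- seq(0, 1, length.out = length(rv))
    rv <- approx(u, rv, xout = seq(0, 1, length.out = length(tv)))$y
  }
  ctr <- function(v) v / v[floor((length(v) - 1) / 2) + 1]
  tv <- ctr(tv); rv <- ctr(rv)
  n <- length(tv)
  k <- floor(n * region)
  lo <- floor((n - k) / 2) + 1
  sel <- lo:(lo + k - 1)
  if (length(sel) == 0) stop_input("empty comparison region")
  rel <- abs(tv[sel] - rv[sel]) / abs(rv[sel])
  list(max_rel_diff = max(rel), mean_rel_diff = mean(rel), n = length(sel))
}
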
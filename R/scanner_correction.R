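#' Derive the per-pixel matrix correction from unexposed films
#'
#' Averages a stack of unexposed film scans pixelwise per colour channel
#' and builds the additive correction M that flattens the stack mean to
#' the mean over the normalization area: `M[x, y] = mean(stack mean over
#' norm ROI) - stack mean[x, y]`. Adding M to the stack mean therefore
#' yields a field equal to the normalization mean everywhere, and applying
#' M to any later scan removes the scanner's position-dependent sensitivity
#' at zero dose.
#'
#' @param scans list of at least two unexposed [film_scan()]s with
#'   identical dimensions, normally from the same lot.
#' @param norm_roi normalization area; default the 3 cm x 4 cm ROI at the
#'   plate centre.
#' @param on_mixed_lots `"error"` (default) or `"warn"` when the scans do
#'   not share one lot.
#' @return an object of class `matrix_correction`: per-channel correction
#'   matrices `M`, the normalization ROI and per-channel normalization
#'   mean, the source scan count and lot.
#' @export
build_matrix_correction <- function(scans, norm_roi = NULL,
                                    on_mixed_lots = c("error", "warn")) {
  on_mixed_lots <- match.arg(on_mixed_lots)
  if (length(scans) < 2)
    stop_input("need at least 2 unexposed scans to derive a matrix correction")
  if (!all(vapply(scans, is_film_scan, TRUE)))
    stop_input("all elements must be film_scan objects")
  first <- scans[[1]]
  if (!all(vapply(scans, function(s)
    s$width_px == first$width_px && s$height_px == first$height_px, TRUE)))
    stop_input("scans have mismatched dimensions")
  lots <- unique(vapply(scans, function(s) s$lot_id, ""))
  if (length(lots) > 1) {
    msg <- paste0("scans come from mixed lots: ", paste(lots, collapse = ", "))
    if (on_mixed_lots == "error") stop_input(msg) else warning(msg, call. = FALSE)
  }
  if (is.null(norm_roi))
    norm_roi <- roi_cm_center(3, 4, first$width_px, first$height_px, first$dpi)
  check_roi_bounds(norm_roi, first$width_px, first$height_px)

  n <- length(scans)
  M <- list(); norm_mean <- numeric(0)
  for (ch in CHANNELS) {
    acc <- scans[[1]]$channels[[ch]]
    for (i in seq_len(n)[-1]) acc <- acc + scans[[i]]$channels[[ch]]
    stack_mean <- acc / n
    nm <- mean(roi_slice(stack_mean, norm_roi))
    M[[ch]] <- nm - stack_mean
    norm_mean[ch] <- nm
  }
  structure(list(M = M, norm_roi = norm_roi, norm_mean = norm_mean,
                 n_scans = n, lot_id = lots[1],
                 width_px = first$width_px, height_px = first$height_px),
            class = "matrix_correction")
}

#' @export
print.matrix_correction <- function(x, ...) {
  cat(sprintf("<matrix_correction> %dx%d px from %d scans (lot %s)\n",
              x$width_px, x$height_px, x$n_scans, x$lot_id))
  for (ch in CHANNELS)
    cat(sprintf("  %-5s M range [%.1f, %.1f] PV, norm mean %.1f PV\n", ch,
                min(x$M[[ch]]), max(x$M[[ch]]), x$norm_mean[ch]))
  invisible(x)
}

check_correction_dims <- function(corr, scan) {
  if (scan$width_px != corr$width_px || scan$height_px != corr$height_px)
    stop_input("correction was derived for ", corr$width_px, "x",
               corr$height_px, " scans, got ", scan$width_px, "x",
               scan$height_px)
}

#' Apply the matrix correction to a scan
#'
#' Adds the per-channel correction M pixelwise; no dose-dependent term.
#'
#' @param scan a [film_scan()].
#' @param matrix a [build_matrix_correction()] result of matching geometry.
#' @return named list of corrected (real-valued) channel matrices.
#' @export
apply_matrix_correction <- function(scan, matrix) {
  check_correction_dims(matrix, scan)
  lapply(setNames(CHANNELS, CHANNELS),
         function(ch) scan$channels[[ch]] + matrix$M[[ch]])
}

#' Derive the dose-dependent transversal correction from stripe scans
#'
#' A film stripe exposed to one known uniform dose and scanned at several
#' transversal placements reveals how much of the scanner's lateral
#' response remains after the matrix correction at that dose level.
#' Per channel and dose level, the correction is
#' `MD[x, d] = (matrix-corrected PV at the normalization columns) -
#' (matrix-corrected PV observed at column x)`, with observed values
#' obtained by averaging stripe rows per covered column and pooling
#' overlapping placements. The table always carries an implicit dose-0 row
#' of zeros (an unexposed film is fully corrected by M alone), and MD is
#' forced to zero over the normalization columns at every dose.
#'
#' @param stripe_sets either the result of [generate_stripe_series()] or a
#'   list of such sets (one per dose level). Each set is a list with
#'   `dose` (Gy, > 0), `scans` (list of [film_scan()]) and `columns`
#'   (0-based covered bed columns per scan).
#' @param matrix the [build_matrix_correction()] used before deriving MD.
#' @param norm_roi normalization area (defaults to the matrix correction's).
#' @return an object of class `md_correction`: per-channel matrices of
#'   additive PV corrections indexed by dose-grid row and bed column,
#'   the dose grid (including 0) and the normalization columns.
#' @export
build_dose_transversal_correction <- function(stripe_sets, matrix,
                                              norm_roi = matrix$norm_roi) {
  if (!is.null(stripe_sets$dose)) stripe_sets <- list(stripe_sets)
  doses <- vapply(stripe_sets, function(s) s$dose, 0)
  if (any(doses <= 0)) stop_input("stripe dose must be > 0")
  if (anyDuplicated(doses)) stop_input("duplicate dose levels in stripe sets")
  W <- matrix$width_px
  nx <- c(norm_roi$x0, norm_roi$x0 + norm_roi$width)   # [nx0, nx1), 0-based

  rows <- lapply(stripe_sets, function(set) {
    sums <- lapply(setNames(CHANNELS, CHANNELS), function(ch) numeric(W))
    cnt <- integer(W)
    for (i in seq_along(set$scans)) {
      corr <- apply_matrix_correction(set$scans[[i]], matrix)
      cols0 <- set$columns[[i]]
      if (any(cols0 < 0 | cols0 >= W)) stop_input("stripe columns outside the bed")
      j <- cols0 + 1L
      cnt[j] <- cnt[j] + 1L
      for (ch in CHANNELS)
        sums[[ch]][j] <- sums[[ch]][j] + colMeans(corr[[ch]][, j, drop = FALSE])
    }
    if (any(cnt == 0))
      stop_input("stripe placements do not cover bed columns ",
                 paste(head(which(cnt == 0) - 1L, 5), collapse = ", "),
                 if (sum(cnt == 0) > 5) " ..." else "",
                 " (coverage error)")
    norm_cols <- (nx[1] + 1L):nx[2]
    if (!any(cnt[norm_cols] > 0))
      stop_input("no stripe placement covers the normalization columns")
    sapply(CHANNELS, function(ch) {
      prof <- sums[[ch]] / cnt
      md <- mean(prof[norm_cols]) - prof
      md[norm_cols] <- 0
      md
    })
  })

  ord <- order(doses)
  grid <- c(0, doses[ord])
  md <- lapply(setNames(CHANNELS, CHANNELS), function(ch) {
    tab <- rbind(numeric(W),
                 t(vapply(rows[ord], function(r) r[, ch], numeric(W))))
    rownames(tab) <- format(grid)
    tab
  })
  structure(list(md = md, dose_grid = grid, norm_cols = nx,
                 width_px = W, height_px = matrix$height_px),
            class = "md_correction")
}

#' @export
print.md_correction <- function(x, ...) {
  cat(sprintf("<md_correction> %d columns, dose grid {%s} Gy\n", x$width_px,
              paste(format(x$dose_grid), collapse = ", ")))
  for (ch in CHANNELS)
    cat(sprintf("  %-5s MD range [%.1f, %.1f] PV\n", ch,
                min(x$md[[ch]]), max(x$md[[ch]])))
  invisible(x)
}

# evaluate MD for a whole image: linear interpolation in dose between grid
# rows, constant (clamped) extrapolation beyond the grid; exact per column
md_at_dose <- function(mdcorr, channel, dose) {
  g <- mdcorr$dose_grid
  tab <- mdcorr$md[[channel]]
  K <- length(g)
  if (K == 1) return(matrix(tab[1, col(dose)], nrow(dose)))
  dc <- pmin(pmax(dose, g[1]), g[K])
  i <- pmin(findInterval(dc, g, rightmost.closed = TRUE), K - 1L)
  w <- (dc - g[i]) / (g[i + 1L] - g[i])
  cols <- col(dose)
  lo <- tab[cbind(as.vector(i), as.vector(cols))]
  hi <- tab[cbind(as.vector(i + 1L), as.vector(cols))]
  matrix(lo * (1 - as.vector(w)) + hi * as.vector(w), nrow(dose))
}

#' Apply the two-phase scanner correction iteratively and convert to dose
#'
#' The dose-dependent transversal correction depends on the very dose it
#' is needed to measure, so it is applied as a fixed-point iteration:
#' iteration 0 corrects exposed and background scans with the matrix
#' correction alone, forms the net OD pixelwise and converts it to a first
#' dose estimate; every further iteration re-corrects the exposed scan
#' with `M + MD[x, D_prev]` (MD interpolated in dose) and recomputes the
#' dose, until the maximum pixel dose change falls below `tol` or
#' `max_iter` is reached. The background scan receives the matrix
#' correction only (its dose is zero, where MD vanishes by construction).
#' The per-channel doses of the requested channels are averaged in dose
#' space (never in PV or OD) into the combined map.
#'
#' @param scan exposed [film_scan()].
#' @param background background [film_scan()] of the same film, scanned
#'   before irradiation (a warning is raised if timestamps show it older
#'   than 7 days at exposure).
#' @param matrix a [build_matrix_correction()].
#' @param mdcorr a [build_dose_transversal_correction()], or `NULL` for a
#'   matrix-only (non-iterative) conversion.
#' @param curve a [calibration_curve()] valid for the lot.
#' @param channels channels combined into the dose map (default red+green;
#'   blue is not recommended for dose).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance in Gy; default 0.1% of the median of
#'   the first dose estimate, floored at 0.002 Gy.
#' @param mask_right_px optionally exclude this many right-edge columns
#'   from the returned dose map mask (high-accuracy use can avoid the
#'   right part of the image).
#' @return list with `corrected` (class `corrected_scan`: final corrected
#'   PV planes, iteration count, final max dose change, convergence flag)
#'   and `dose` (a [dose_map()], scanner frame).
#' @export
apply_corrections_iterative <- function(scan, background, matrix,
                                        mdcorr = NULL, curve,
                                        channels = c("red", "green"),
                                        max_iter = 10L, tol = NULL,
                                        mask_right_px = 0L) {
  check_correction_dims(matrix, scan)
  check_correction_dims(matrix, background)
  channels <- match.arg(channels, CHANNELS, several.ok = TRUE)
  if (!is.null(scan$exposure_time) && !is.null(background$scan_time)) {
    age <- as.numeric(difftime(scan$exposure_time, background$scan_time,
                               units = "days"))
    if (age < 0 || age > 7)
      warning("background scan is not within 7 days before irradiation (",
              round(age, 1), " days)", call. = FALSE)
  }
  check_curve_validity(curve, scan$scan_time)

  bg_corr <- apply_matrix_correction(background, matrix)
  pv_m <- apply_matrix_correction(scan, matrix)

  dose_of <- function(pvcorr) {
    per_ch <- lapply(setNames(channels, channels), function(ch) {
      od <- log10(bg_corr[[ch]] / pvcorr[[ch]])
      od_to_dose(od, curve, ch, extrapolation = "flag", detail = TRUE)
    })
    d <- Reduce(`+`, lapply(per_ch, `[[`, "dose")) / length(per_ch)
    list(combined = d,
         per_channel = lapply(per_ch, `[[`, "dose"),
         flags = Reduce(pmax, lapply(per_ch, `[[`, "flags")))
  }

  est <- dose_of(pv_m)
  D <- est$combined
  if (is.null(tol)) tol <- max(0.002, 0.001 * median(D))
  iterations <- 0L
  final_change <- NA_real_
  converged <- is.null(mdcorr)
  pv_final <- pv_m
  if (!is.null(mdcorr)) {
    for (k in seq_len(max_iter)) {
      pv_k <- lapply(setNames(channels, channels), function(ch)
        pv_m[[ch]] + md_at_dose(mdcorr, ch, D))
      est <- dose_of(pv_k)
      final_change <- max(abs(est$combined - D))
      D <- est$combined
      pv_final <- pv_k
      iterations <- k
      if (final_change < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("dose-dependent correction did not converge after ", max_iter,
              " iterations (last max change ", signif(final_change, 3),
              " Gy)", call. = FALSE)
  }

  flags <- est$flags
  if (mask_right_px > 0)
    flags[, (scan$width_px - mask_right_px + 1):scan$width_px] <- 4L

  corrected <- structure(list(channels = pv_final, iterations = iterations,
                              final_max_change_gy = final_change,
                              converged = converged),
                         class = "corrected_scan")
  dm <- dose_map(D, pixel_spacing_mm = 25.4 / scan$dpi, mask = flags,
                 channel_doses = est$per_channel,
                 provenance = list(film_id = scan$film_id,
                                   lot_id = scan$lot_id,
                                   orientation = scan$orientation_tag,
                                   iterations = iterations,
                                   converged = converged,
                                   channels = channels))
  list(corrected = corrected, dose = dm)
}

#' Dose map container
#'
#' A 2D absorbed-dose-to-water array with pixel spacing, a per-pixel flag
#' mask (0 = clean, 1 = negative-OD clamp, 2 = beyond calibration range,
#' 4 = excluded right-edge region) and provenance.
#'
#' @param dose numeric matrix (Gy).
#' @param pixel_spacing_mm pixel pitch in mm.
#' @param mask integer flag matrix (defaults to all clean).
#' @param channel_doses optional named list of per-channel dose matrices.
#' @param provenance free-form provenance list.
#' @return an object of class `dose_map`.
#' @export
dose_map <- function(dose, pixel_spacing_mm = 25.4 / SCAN_DPI, mask = NULL,
                     channel_doses = NULL, provenance = list()) {
  if (is.null(mask)) mask <- matrix(0L, nrow(dose), ncol(dose))
  structure(list(dose = dose, pixel_spacing_mm = pixel_spacing_mm,
                 mask = mask, channel_doses = channel_doses,
                 provenance = provenance),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %dx%d px @ %.3f mm, dose [%.3f, %.3f] Gy, %d flagged px\n",
              ncol(x$dose), nrow(x$dose), x$pixel_spacing_mm,
              min(x$dose), max(x$dose), sum(x$mask != 0)))
  invisible(x)
}
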
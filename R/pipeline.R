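#' Assemble a read-out run configuration
#'
#' Bundles the inputs of an end-to-end film read-out: the orientation
#' scans with their paired backgrounds, the scanner-correction archive and
#' the calibration, plus thresholds. Scan entries may hold in-memory
#' [film_scan()] objects or TIFF paths (read with their JSON sidecars).
#'
#' @param scans list of entries, each a list with `exposed`, `background`
#'   (film_scan or path) and `tag` (orientation; defaults to the exposed
#'   scan's tag).
#' @param correction a correction archive directory, or a list with
#'   `matrix` and `md` as returned by [read_correction_archive()].
#' @param calibration a [calibration_curve()] or a calibration JSON path.
#' @param outlier_rel,outlier_abs_gy dust/outlier rejection thresholds for
#'   the merge (see [merge_orientations()]).
#' @param max_iter,tol_gy iteration controls for
#'   [apply_corrections_iterative()].
#' @param profile_axis,profile_width_px profile extraction settings.
#' @param out_dir optional report output directory.
#' @return an object of class `readout_config`.
#' @export
readout_config <- function(scans, correction, calibration,
                           outlier_rel = 0.02, outlier_abs_gy = 0.04,
                           max_iter = 10L, tol_gy = NULL,
                           profile_axis = "transversal",
                           profile_width_px = 20L, out_dir = NULL) {
  if (length(scans) < 1) stop_input("no scans configured")
  if (outlier_rel <= 0 || outlier_abs_gy <= 0 || max_iter <= 0)
    stop_input("thresholds must be positive")
  structure(list(scans = scans, correction = correction,
                 calibration = calibration, outlier_rel = outlier_rel,
                 outlier_abs_gy = outlier_abs_gy, max_iter = max_iter,
                 tol_gy = tol_gy, profile_axis = profile_axis,
                 profile_width_px = profile_width_px, out_dir = out_dir),
            class = "readout_config")
}

resolve_scan <- function(x) {
  if (is_film_scan(x)) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop_input("scan file does not exist: ", x)
    return(read_film_tiff(x))
  }
  stop_input("scan entries must be film_scan objects or file paths")
}

resolve_correction <- function(x) {
  if (is.list(x) && inherits(x$matrix, "matrix_correction")) return(x)
  if (inherits(x, "matrix_correction")) return(list(matrix = x, md = NULL))
  if (is.character(x)) {
    if (!dir.exists(x)) stop_input("correction archive does not exist: ", x)
    return(read_correction_archive(x))
  }
  stop_input("`correction` must be a matrix_correction, an archive list or a directory")
}

resolve_calibration <- function(x) {
  if (inherits(x, "calibration_curve")) return(x)
  if (is.character(x)) return(read_calibration_json(x))
  stop_input("`calibration` must be a calibration_curve or a JSON path")
}

#' Run the full film read-out pipeline
#'
#' For each configured orientation: pairs the exposed scan with its
#' background, applies the two-phase scanner correction iteratively,
#' converts to dose (red/green average), and restores the map to the film
#' frame. The restored maps are merged by mean dose with per-pixel dust
#' rejection, and the requested profile is extracted. Every QC decision
#' (timing, convergence, calibration age) is logged with its rule and
#' values.
#'
#' @param config a [readout_config()].
#' @return an object of class `readout_result` with the merged dose, the
#'   per-orientation maps and corrections, the profile, and the QC log.
#' @export
run_readout <- function(config) {
  if (!inherits(config, "readout_config")) stop_input("expected a readout_config")
  corr <- resolve_correction(config$correction)
  curve <- resolve_calibration(config$calibration)
  qc_log <- list()
  log_qc <- function(rule, verdict, ...)
    qc_log[[length(qc_log) + 1]] <<- c(list(rule = rule, verdict = verdict),
                                       list(...))

  age_days <- as.numeric(Sys.Date() - curve$calibration_date)
  log_qc("calibration_age", if (age_days > 90) "warn" else "pass",
         age_days = age_days)
  if (age_days > 90)
    warning("calibration of lot ", curve$lot_id, " is ", round(age_days),
            " days old; recalibration is due every 3 months", call. = FALSE)

  maps <- list(); corrections <- list(); tags <- character()
  for (i in seq_along(config$scans)) {
    entry <- config$scans[[i]]
    if (is.null(entry$background))
      stop_input("scan entry ", i, " has no background scan (fatal)")
    exposed <- resolve_scan(entry$exposed)
    background <- resolve_scan(entry$background)
    tag <- entry$tag %||% exposed$orientation_tag
    tc <- timing_check(exposed$exposure_time, exposed$scan_time)
    log_qc("timing_window", tc$verdict, tag = tag,
           delta_hours = tc$delta_hours)
    res <- suppressWarnings(apply_corrections_iterative(
      exposed, background, corr$matrix, corr$md, curve,
      max_iter = config$max_iter, tol = config$tol_gy))
    log_qc("iteration_convergence",
           if (res$corrected$converged) "pass" else "warn",
           tag = tag, iterations = res$corrected$iterations,
           final_max_change_gy = res$corrected$final_max_change_gy)
    res$dose$provenance$orientation <- tag
    maps[[i]] <- restore_orientation(res$dose, tag)
    corrections[[i]] <- res$corrected
    tags[i] <- tag
  }

  if (length(maps) == 1) {
    warning("single-orientation read-out: no dust rejection, higher noise",
            call. = FALSE)
    merged <- structure(list(
      dose = maps[[1]]$dose, map = maps[[1]],
      excluded = array(FALSE, c(dim(maps[[1]]$dose), 1)),
      n_excluded = matrix(0L, nrow(maps[[1]]$dose), ncol(maps[[1]]$dose)),
      spread = matrix(0, nrow(maps[[1]]$dose), ncol(maps[[1]]$dose)),
      unreliable = matrix(FALSE, nrow(maps[[1]]$dose), ncol(maps[[1]]$dose)),
      tags = tags), class = "merged_dose")
    log_qc("orientation_count", "warn", n = 1)
  } else {
    merged <- merge_orientations(maps, config$outlier_rel,
                                 config$outlier_abs_gy)
    log_qc("orientation_count", "pass", n = length(maps))
    log_qc("dust_rejection", "pass",
           pixels_excluded = sum(merged$n_excluded > 0),
           unreliable = sum(merged$unreliable))
  }

  profile <- extract_profile(merged$map, axis = config$profile_axis,
                             width_px = config$profile_width_px,
                             normalize = TRUE)
  structure(list(merged = merged, maps = maps, corrections = corrections,
                 tags = tags, profile = profile, qc_log = qc_log,
                 curve = curve, config = config),
            class = "readout_result")
}

#' @export
print.readout_result <- function(x, ...) {
  cat(sprintf("<readout_result> %d orientation(s): mean dose %.3f Gy, max %.3f Gy\n",
              length(x$maps), mean(x$merged$dose), max(x$merged$dose)))
  for (q in x$qc_log)
    cat(sprintf("  [%s] %s %s\n", q$verdict, q$rule,
                paste(vapply(q[-(1:2)], function(v)
                  paste(format(v, digits = 4), collapse = ","), ""),
                  collapse = " ")))
  invisible(x)
}

#' Write human- and machine-readable read-out reports
#'
#' Produces `summary.txt` (mean/max dose, iteration counts, QC log,
#' masked-pixel counts per orientation), `report.json` (the same,
#' machine-readable), the merged dose map via [write_dose_map()], and
#' `profile.csv`. With `plots = TRUE` a PNG of the extracted profile is
#' added.
#'
#' @param result a [run_readout()] result.
#' @param out_dir output directory (defaults to the config's, which must
#'   then be set).
#' @param plots also write a profile plot (default `FALSE`).
#' @return named vector of file paths, invisibly.
#' @export
report <- function(result, out_dir = NULL, plots = FALSE) {
  if (!inherits(result, "readout_result")) stop_input("expected a readout_result")
  out_dir <- out_dir %||% result$config$out_dir
  if (is.null(out_dir)) stop_input("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  m <- result$merged
  excl_per_tag <- if (length(dim(m$excluded)) == 3)
    setNames(apply(m$excluded, 3, sum), result$tags) else integer()
  iters <- vapply(result$corrections, function(cc) cc$iterations, 0L)
  summary_lines <- c(
    sprintf("orientations: %s", paste(result$tags, collapse = ", ")),
    sprintf("mean dose: %.4f Gy", mean(m$dose)),
    sprintf("max dose: %.4f Gy", max(m$dose)),
    sprintf("max deviation from mean: %.2f %%",
            100 * max(abs(m$dose - mean(m$dose))) / mean(m$dose)),
    sprintf("iterations per orientation: %s", paste(iters, collapse = ", ")),
    sprintf("masked pixels per orientation: %s",
            paste(sprintf("%s=%d", names(excl_per_tag), excl_per_tag),
                  collapse = ", ")),
    sprintf("unreliable pixels: %d", sum(m$unreliable)),
    "qc log:",
    vapply(result$qc_log, function(q)
      sprintf("  %s=%s %s", q$rule, q$verdict,
              paste(sprintf("%s=%s", names(q[-(1:2)]),
                            vapply(q[-(1:2)], function(v)
                              paste(format(v, digits = 6), collapse = ","), "")),
                    collapse = " ")), ""))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  jsonlite::write_json(
    list(tags = result$tags, mean_dose_gy = mean(m$dose),
         max_dose_gy = max(m$dose),
         iterations = iters,
         masked_pixels_per_orientation = as.list(excl_per_tag),
         unreliable_pixels = sum(m$unreliable),
         qc_log = result$qc_log),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)

  files <- write_dose_map(m$map, file.path(out_dir, "merged_dose"))
  write.csv(result$profile, file.path(out_dir, "profile.csv"),
            row.names = FALSE)
  if (isTRUE(plots)) {
    grDevices::png(file.path(out_dir, "profile.png"), 800, 500)
    graphics::plot(result$profile$position_mm, result$profile$value,
                   type = "l", xlab = "position [mm]",
                   ylab = "relative dose", main = "merged dose profile")
    grDevices::dev.off()
  }
  invisible(c(summary = file.path(out_dir, "summary.txt"),
              json = file.path(out_dir, "report.json"),
              profile = file.path(out_dir, "profile.csv"), files))
}
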
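# Shared simulation fixtures for the test suite.
#
# Deriving the scanner corrections and the calibration is the expensive
# part of most tests, so two fixture bundles are built lazily and cached
# for the whole test run: a small-geometry bundle (160 x 200 px bed) for
# module tests, and a full-bed bundle (576 x 720 px) for the acceptance
# criteria that are stated at full scale. All seeds are fixed constants
# chosen before any test outcome was observed.

t_exposure <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")

small_scanner <- function(...) scanner_model(width_px = 160, height_px = 200, ...)

# a scanner with every artifact switched off: the identity instrument
clean_scanner <- function(width_px = 160, height_px = 200, noise_sd_pv = 0, ...) {
  scanner_model(width_px = width_px, height_px = height_px,
                transversal_left_pv = 0, transversal_right_pv = 0,
                longitudinal_pv = 0,
                dose_lateral_pv = c(red = 0, green = 0, blue = 0),
                noise_sd_pv = noise_sd_pv, ...)
}

# a film lot without emulsion bands or piece-to-piece variation
clean_film <- function(...) {
  film_model(band_amplitude = c(red = 0, green = 0, blue = 0),
             piece_scale_sd = c(red = 0, green = 0, blue = 0), ...)
}

# the exact generator response as a calibration curve (no fit involved)
model_curve <- function(film = film_model()) {
  calibration_curve(film$curve, lot_id = "SIMLOT", q = "Co-60",
                    dose_range = c(0, film$max_dose_gy),
                    calibration_date = Sys.Date())
}

.fixture_cache <- new.env(parent = emptyenv())

# small-geometry bundle: unexposed stack, matrix correction, calibration
# points + fitted curve, 2 Gy stripe series and the MD correction
small_fixtures <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  scanner <- small_scanner()
  film <- film_model()
  stack <- generate_unexposed_stack(6, film, scanner, seed = 11)
  matrix <- build_matrix_correction(stack$scans, norm_roi = scanner$norm_roi)
  calset <- generate_calibration_set(c(0.25, 0.5, 1, 2, 4, 8), film, scanner,
                                     seed = 21)
  points <- measure_calibration_points(calset, matrix = matrix)
  curve <- fit_calibration_curves(points, lot_id = "SIMLOT", q = "Co-60")
  stripes <- generate_stripe_series(2, c(71, 89), film, scanner, seed = 31)
  md <- build_dose_transversal_correction(stripes, matrix)
  .fixture_cache$small <- list(scanner = scanner, film = film, stack = stack,
                               matrix = matrix, calset = calset,
                               points = points, curve = curve,
                               stripes = stripes, md = md)
  .fixture_cache$small
}

# full-bed bundle for the acceptance criteria (10-scan stack, 2 Gy stripe
# series covering all 576 columns, fitted calibration)
full_bed_fixtures <- function() {
  if (!is.null(.fixture_cache$full)) return(.fixture_cache$full)
  scanner <- scanner_model()
  film <- film_model()
  stack <- generate_unexposed_stack(10, film, scanner, seed = 101)
  matrix <- build_matrix_correction(stack$scans, norm_roi = scanner$norm_roi)
  calset <- generate_calibration_set(c(0.25, 0.5, 1, 2, 4, 8), film, scanner,
                                     seed = 121)
  points <- measure_calibration_points(calset, matrix = matrix)
  curve <- fit_calibration_curves(points, lot_id = "SIMLOT", q = "Co-60")
  stripes <- generate_stripe_series(2, c(71, 213, 355, 497, 505), film,
                                    scanner, seed = 131)
  md <- build_dose_transversal_correction(stripes, matrix)
  .fixture_cache$full <- list(scanner = scanner, film = film, stack = stack,
                              matrix = matrix, calset = calset,
                              points = points, curve = curve,
                              stripes = stripes, md = md)
  .fixture_cache$full
}

# mean PV over a film_roi of a plain channel matrix
roi_mean <- function(plane, r) {
  mean(plane[(r$y0 + 1):(r$y0 + r$height), (r$x0 + 1):(r$x0 + r$width)])
}

# central fraction of 1-based indices 1..n (the profile comparison region)
central_indices <- function(n, fraction = 0.8) {
  k <- floor(n * fraction)
  lo <- floor((n - k) / 2) + 1
  lo:(lo + k - 1)
}
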
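test_that("matrix correction recovers the injected sensitivity field exactly", {
  # noise-free, band-free films: M must equal minus the scanner's additive
  # deficit up to quantization, and correcting an independent scan must
  # flatten it to the normalization mean
  scanner <- small_scanner(noise_sd_pv = 0)
  film <- clean_film()
  zero <- uniform_dose_field(0, scanner)
  scans <- lapply(1:2, function(i) simulate_scan(zero, film, scanner)$scan)
  mat <- build_matrix_correction(scans, norm_roi = scanner$norm_roi)
  expect_s3_class(mat, "matrix_correction")
  for (ch in c("red", "green", "blue"))
    expect_lt(max(abs(mat$M[[ch]] + scanner$base_deficit)), 1)   # rounding only

  probe <- simulate_scan(zero, film, scanner)$scan
  corr <- apply_matrix_correction(probe, mat)
  for (ch in c("red", "green", "blue")) {
    resid <- corr[[ch]] - roi_mean(corr[[ch]], scanner$norm_roi)
    expect_lt(max(abs(resid)), 1.5)
  }
})

test_that("matrix correction validates its inputs", {
  fx <- small_fixtures()
  expect_error(build_matrix_correction(fx$stack$scans[1]), "at least 2")
  other <- fx$stack$scans[[2]]
  other$lot_id <- "OTHERLOT"
  expect_error(build_matrix_correction(list(fx$stack$scans[[1]], other)),
               "mixed lots")
  expect_warning(build_matrix_correction(list(fx$stack$scans[[1]], other),
                                         norm_roi = fx$scanner$norm_roi,
                                         on_mixed_lots = "warn"),
                 "mixed lots")
  small <- film_scan(list(red = matrix(0, 5, 5), green = matrix(0, 5, 5),
                          blue = matrix(0, 5, 5)))
  expect_error(apply_matrix_correction(small, fx$matrix), "derived for")
})

test_that("MD is zero at dose zero and over the normalization columns", {
  fx <- small_fixtures()
  md <- fx$md
  expect_equal(md$dose_grid, c(0, 2))
  norm_cols <- (md$norm_cols[1] + 1):md$norm_cols[2]
  for (ch in c("red", "green", "blue")) {
    expect_equal(md$md[[ch]][1, ], rep(0, md$width_px))   # dose-0 row
    expect_equal(md$md[[ch]][2, norm_cols], rep(0, length(norm_cols)))
  }
})

test_that("MD recovers the injected dose-lateral deficit exactly without noise", {
  scanner <- small_scanner(noise_sd_pv = 0)
  film <- clean_film()
  stack <- generate_unexposed_stack(2, film, scanner, seed = 7)
  mat <- build_matrix_correction(stack$scans, norm_roi = scanner$norm_roi)
  stripes <- generate_stripe_series(2, c(71, 89), film, scanner, seed = 8,
                                    dose_uniformity_sd = 0)
  md <- build_dose_transversal_correction(stripes, mat)
  norm_cols <- (md$norm_cols[1] + 1):md$norm_cols[2]
  for (ch in c("red", "green")) {
    diff <- md$md[[ch]][2, ] - stripes$truth[[ch]]
    diff[norm_cols] <- 0   # forced-zero region carries no information
    expect_lt(max(abs(diff)), 1.5)   # quantization only
  }
})

test_that("stripe coverage gaps and bad doses raise clear errors", {
  fx <- small_fixtures()
  gap <- generate_stripe_series(2, c(71), fx$film, fx$scanner, seed = 9)
  expect_error(build_dose_transversal_correction(gap, fx$matrix), "coverage")
  bad <- fx$stripes
  bad$dose <- 0
  expect_error(build_dose_transversal_correction(bad, fx$matrix), "> 0")
  expect_error(
    build_dose_transversal_correction(list(fx$stripes, fx$stripes), fx$matrix),
    "duplicate")
})

test_that("md_at_dose interpolates linearly in dose and clamps at the grid ends", {
  col_md <- c(0, 0, 10, 20, 40)
  md <- structure(list(
    md = list(red = rbind(rep(0, 5), col_md), green = rbind(rep(0, 5), col_md),
              blue = rbind(rep(0, 5), col_md)),
    dose_grid = c(0, 2), norm_cols = c(0, 2), width_px = 5L, height_px = 3L),
    class = "md_correction")
  dose <- matrix(1, 3, 5)        # halfway between the grid rows
  half <- ebt3dose:::md_at_dose(md, "red", dose)
  expect_equal(half, matrix(rep(col_md / 2, each = 3), 3))
  above <- ebt3dose:::md_at_dose(md, "red", matrix(5, 3, 5))   # clamped at 2 Gy
  expect_equal(above, matrix(rep(col_md, each = 3), 3))
  below <- ebt3dose:::md_at_dose(md, "red", matrix(-1, 3, 5))  # clamped at 0
  expect_equal(below, matrix(0, 3, 5))
})

test_that("iterative correction converges and flattens a uniform 2 Gy film", {
  fx <- small_fixtures()
  piece <- film_piece(fx$film, "UNIF", fx$scanner$width_px, seed = 41)
  bg <- simulate_scan(uniform_dose_field(0, fx$scanner), piece, fx$scanner,
                      seed = 42, exposure_time = t_exposure,
                      scan_time = t_exposure - 86400)$scan
  ex <- simulate_scan(uniform_dose_field(2, fx$scanner), piece, fx$scanner,
                      seed = 43, exposure_time = t_exposure,
                      scan_time = t_exposure + 4 * 86400)$scan
  res <- apply_corrections_iterative(ex, bg, fx$matrix, fx$md, fx$curve)
  expect_true(res$corrected$converged)
  expect_gte(res$corrected$iterations, 1)
  expect_lt(abs(mean(res$dose$dose) - 2), 0.02)

  prof <- extract_profile(res$dose, "transversal", normalize = TRUE)
  sel <- central_indices(nrow(prof))
  expect_lt(max(abs(prof$value[sel] - 1)), 0.005)

  # without the dose-dependent term the same scan fails the 0.5% bound
  only_m <- apply_corrections_iterative(ex, bg, fx$matrix, NULL, fx$curve)
  expect_equal(only_m$corrected$iterations, 0L)
  prof_m <- extract_profile(only_m$dose, "transversal", normalize = TRUE)
  expect_gt(max(abs(prof_m$value[sel] - 1)), 0.005)
})

test_that("background pairing cancels the film's own nonuniformity", {
  # a film with a strong 1% sensitivity band, read on an artifact-free
  # scanner: the band divides out in net OD, so the dose map stays flat
  scanner <- clean_scanner()
  film <- clean_film()
  piece <- inject_band(film_piece(film, "BANDY", scanner$width_px),
                       center_frac = 0.4, width_frac = 0.15, delta = 0.01,
                       channels = c("red", "green"))
  mat <- build_matrix_correction(
    generate_unexposed_stack(2, film, scanner)$scans,
    norm_roi = scanner$norm_roi)
  bg <- simulate_scan(uniform_dose_field(0, scanner), piece, scanner)$scan
  ex <- simulate_scan(uniform_dose_field(1, scanner), piece, scanner)$scan
  res <- apply_corrections_iterative(ex, bg, mat, NULL, model_curve(film))
  expect_lt(max(abs(res$dose$dose - 1)), 0.005)
})

test_that("a stale background scan is flagged", {
  fx <- small_fixtures()
  piece <- film_piece(fx$film, "OLD", fx$scanner$width_px, seed = 44)
  bg <- simulate_scan(uniform_dose_field(0, fx$scanner), piece, fx$scanner,
                      seed = 45, scan_time = t_exposure - 30 * 86400)$scan
  ex <- simulate_scan(uniform_dose_field(1, fx$scanner), piece, fx$scanner,
                      seed = 46, exposure_time = t_exposure)$scan
  expect_warning(
    apply_corrections_iterative(ex, bg, fx$matrix, NULL, fx$curve),
    "7 days")
})
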
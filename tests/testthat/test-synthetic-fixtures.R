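test_that("the simulator is reproducible for a seed and leaves the RNG alone", {
  scanner <- small_scanner()
  film <- film_model()
  field <- uniform_dose_field(1, scanner)
  a <- simulate_scan(field, film, scanner, seed = 99)$scan
  set.seed(123)
  before <- runif(3)
  b <- simulate_scan(field, film, scanner, seed = 99)$scan
  set.seed(123)
  expect_identical(runif(3), before)   # global RNG state untouched by seeding
  expect_identical(a$channels, b$channels)
  c <- simulate_scan(field, film, scanner, seed = 100)$scan
  expect_false(identical(a$channels$red, c$channels$red))
})

test_that("artifact magnitudes appear at the configured edge values", {
  scanner <- small_scanner(noise_sd_pv = 0)
  film <- clean_film()
  scan <- simulate_scan(uniform_dose_field(0, scanner), film, scanner)$scan
  bg <- film$background_pv[["red"]]
  mid_row <- scanner$norm_roi$y0 + 5       # longitudinal deficit is 0 here
  mid_col <- scanner$norm_roi$x0 + 5       # transversal deficit is 0 here
  expect_equal(scan$channels$red[mid_row, 1], bg - 300, tolerance = 1)
  expect_equal(scan$channels$red[mid_row, scanner$width_px], bg - 1800,
               tolerance = 1)
  expect_equal(scan$channels$red[1, mid_col], bg - 340, tolerance = 1)
  expect_equal(scan$channels$red[mid_row, mid_col], bg, tolerance = 1)

  # the dose-dependent lateral deficit scales with dose on the right half
  ex <- simulate_scan(uniform_dose_field(2, scanner), film, scanner)$scan
  right <- scanner$width_px
  base <- simulate_scan(uniform_dose_field(2, clean_scanner()), film,
                        clean_scanner())$scan
  deficit <- base$channels$red[mid_row, right] - ex$channels$red[mid_row, right]
  expect_equal(deficit, 1800 + 600, tolerance = 1.5)   # static + dose term
})

test_that("dust specks darken readings by the configured factor", {
  scanner <- clean_scanner()
  film <- clean_film()
  sim <- simulate_scan(uniform_dose_field(0, scanner), film, scanner,
                       seed = 5, dust_count = 3L)
  expect_gt(sum(sim$truth$dust_mask), 0)
  bg <- film$background_pv[["red"]]
  inside <- sim$scan$channels$red[sim$truth$dust_mask]
  outside <- sim$scan$channels$red[!sim$truth$dust_mask]
  expect_equal(unique(outside), bg)
  expect_equal(unique(inside), round(bg * scanner$dust_factor))
})

test_that("per-scan drift raises exposed readings by 0.03% per scan only", {
  scanner <- clean_scanner()
  film <- clean_film()
  first <- simulate_scan(uniform_dose_field(2, scanner), film, scanner,
                         scan_index = 1L)$scan
  fourth <- simulate_scan(uniform_dose_field(2, scanner), film, scanner,
                          scan_index = 4L)$scan
  ratio <- mean(fourth$channels$red) / mean(first$channels$red)
  expect_equal(ratio, 1 + 3 * 3e-4, tolerance = 5e-5)
  # unexposed film does not drift
  u1 <- simulate_scan(uniform_dose_field(0, scanner), film, scanner,
                      scan_index = 1L)$scan
  u4 <- simulate_scan(uniform_dose_field(0, scanner), film, scanner,
                      scan_index = 4L)$scan
  expect_identical(u1$channels$red, u4$channels$red)
})

test_that("scans of one piece share its band realization; pieces differ", {
  scanner <- clean_scanner()
  film <- film_model()
  piece <- film_piece(film, "P1", scanner$width_px, seed = 3)
  s1 <- simulate_scan(uniform_dose_field(0, scanner), piece, scanner)$scan
  s2 <- simulate_scan(uniform_dose_field(0, scanner), piece, scanner)$scan
  expect_identical(s1$channels$blue, s2$channels$blue)
  other <- film_piece(film, "P2", scanner$width_px, seed = 4)
  s3 <- simulate_scan(uniform_dose_field(0, scanner), other, scanner)$scan
  expect_false(identical(s1$channels$blue, s3$channels$blue))
})

test_that("the stripe series records the injected lateral deficit as truth", {
  fx <- small_fixtures()
  ramp <- fx$scanner$dose_lateral_ramp
  expect_equal(fx$stripes$truth$red, 600 * ramp * 2 / 2)
  expect_equal(fx$stripes$truth$blue, 300 * ramp * 2 / 2)
  expect_equal(fx$stripes$dose, 2)
  # placements are stamped with their covered 0-based columns
  for (i in seq_along(fx$stripes$scans))
    expect_equal(length(fx$stripes$columns[[i]]), 142)   # 5 cm at 72 dpi
})

test_that("generators validate their inputs", {
  expect_error(generate_unexposed_stack(1), "at least 2")
  expect_error(generate_calibration_set(numeric(0)), "empty")
  expect_warning(
    generate_calibration_set(c(1, 4), scanner = small_scanner(), seed = 1),
    "2 Gy")
  expect_error(generate_stripe_series(0, 71), "> 0")
  expect_error(
    generate_stripe_series(2, 10, scanner = small_scanner(), seed = 1),
    "outside the scanner bed")
  film <- film_model()
  expect_error(
    simulate_scan(uniform_dose_field(9, small_scanner()), film,
                  small_scanner()),
    "monotone range")
  expect_error(film_model(curve = list(red = c(a = 0, b = 2, c = 11.9),
                                       green = c(a = 0, b = 0.5, c = 12.8),
                                       blue = c(a = 0, b = 0.5, c = 31.8))),
               "not monotone")
})

test_that("calibration fixtures carry exact ground truth and timing", {
  fx <- small_fixtures()
  expect_equal(fx$calset$truth$dose_gy, c(0.25, 0.5, 1, 2, 4, 8))
  p <- fx$film$curve$red
  expect_equal(fx$calset$truth$od_red,
               (fx$calset$truth$dose_gy - p[["a"]]) /
                 (p[["c"]] - p[["b"]] * fx$calset$truth$dose_gy))
  two <- fx$calset$pieces[[4]]
  expect_equal(two$dose, 2)
  # background scanned before exposure, read-out four days after
  expect_lt(as.numeric(two$background$scan_time), as.numeric(two$background$exposure_time))
  expect_equal(as.numeric(difftime(two$exposed$scan_time,
                                   two$exposed$exposure_time, units = "hours")),
               96)
})
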
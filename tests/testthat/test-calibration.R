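test_that("net OD is log10 of the background/exposed ratio", {
  expect_equal(net_od(40000, 4000), 1)
  expect_equal(net_od(40000, 40000), 0)
  expect_lt(net_od(40000, 40100), 0)   # noise can push net OD negative
  expect_error(net_od(0, 100), "positive")
  expect_error(net_od(100, -1), "positive")
})

test_that("fit recovers rational-form parameters exactly on noise-free data", {
  truth <- c(a = 0.02, b = 0.48, c = 12.1)
  od <- seq(0.01, 0.9, length.out = 9)
  dose <- (truth[["a"]] + truth[["c"]] * od) / (1 + truth[["b"]] * od)
  fit <- fit_calibration(od, dose, "red")
  expect_lt(abs(fit$a - truth[["a"]]) / truth[["a"]], 1e-6)
  expect_lt(abs(fit$b - truth[["b"]]) / truth[["b"]], 1e-6)
  expect_lt(abs(fit$c - truth[["c"]]) / truth[["c"]], 1e-6)
  expect_lt(fit$rmse, 1e-9)
})

test_that("fit recovers the additive form and honours constrain_zero", {
  truth <- c(a = 0.05, b = 0.6, c = 11.2)
  od <- seq(0.02, 0.8, length.out = 8)
  dose <- truth[["a"]] + truth[["c"]] * od / (1 + truth[["b"]] * od)
  fit <- fit_calibration(od, dose, "green", form = "additive")
  expect_lt(abs(fit$a - truth[["a"]]) / truth[["a"]], 1e-6)
  expect_lt(abs(fit$b - truth[["b"]]) / truth[["b"]], 1e-6)
  expect_lt(abs(fit$c - truth[["c"]]) / truth[["c"]], 1e-6)

  dose0 <- 12 * od / (1 + 0.5 * od)
  fz <- fit_calibration(od, dose0, "red", constrain_zero = TRUE)
  expect_equal(fz$a, 0)
  expect_lt(abs(fz$b - 0.5) / 0.5, 1e-6)
  expect_lt(abs(fz$c - 12) / 12, 1e-6)
})

test_that("fit rejects too few points, poles and non-monotone responses", {
  expect_error(fit_calibration(c(0.1, 0.2, 0.3), c(1, 2, 3)), "at least 4")
  expect_error(fit_calibration(c(0.1, 0.2), c(1, 2, 3)), "lengths differ")
  od <- seq(0.05, 0.8, length.out = 8)
  expect_error(fit_calibration(od, rev(12 * od / (1 + 0.5 * od)), "red"),
               "monotone|pole|degenerate")
})

test_that("od_to_dose inverts the generator response and handles edge cases", {
  film <- film_model()
  curve <- model_curve(film)
  doses <- c(0.25, 1, 2, 5)
  od <- (doses - film$curve$red[["a"]]) /
    (film$curve$red[["c"]] - film$curve$red[["b"]] * doses)
  expect_equal(as.numeric(od_to_dose(od, curve, "red")), doses,
               tolerance = 1e-12)

  # negative OD clamps to the zero dose level with flag 1
  d <- od_to_dose(c(-0.01, 0.1), curve, "red", detail = TRUE)
  expect_equal(d$dose[1], 0)
  expect_equal(as.integer(d$flags), c(1L, 0L))

  # doses beyond the validity range flag (default) or error
  big <- (7.9999 - 0) / (film$curve$red[["c"]] - film$curve$red[["b"]] * 7.9999)
  curve8 <- model_curve(film); curve8$dose_range <- c(0, 4)
  flagged <- od_to_dose(big, curve8, "red", detail = TRUE)
  expect_equal(as.integer(flagged$flags), 2L)
  expect_error(od_to_dose(big, curve8, "red", extrapolation = "error"),
               "not certified")
  expect_equal(as.integer(od_to_dose(big, curve8, "red",
                                     extrapolation = "ignore",
                                     detail = TRUE)$flags), 0L)
})

test_that("curves fitted from simulated calibration scans match the generator", {
  fx <- small_fixtures()
  p <- fx$curve$params$red
  truth <- fx$film$curve$red
  expect_lt(abs(p[["a"]] - truth[["a"]]), 5e-3)          # truth a = 0
  expect_lt(abs(p[["b"]] - truth[["b"]]), 5e-3)
  expect_lt(abs(p[["c"]] / truth[["c"]] - 1), 1e-3)
  # the fitted curve maps the exact 2 Gy OD back to 2 Gy within 0.5%
  od2 <- (2 - truth[["a"]]) / (truth[["c"]] - truth[["b"]] * 2)
  expect_lt(abs(as.numeric(od_to_dose(od2, fx$curve, "red")) - 2) / 2, 0.005)
})

test_that("2 Gy lands in the 26000-26500 PV window on the red channel", {
  # frozen generator anchor: 40000 PV background with the default response
  scanner <- clean_scanner()
  film <- clean_film()
  scan <- simulate_scan(uniform_dose_field(2, scanner), film, scanner)$scan
  m <- roi_stats(scan, scanner$norm_roi, "red")$mean
  expect_gt(m, 26000)
  expect_lt(m, 26500)
})

test_that("calibration curve container and validity checks behave", {
  expect_error(calibration_curve(list(red = c(a = 0, b = 1))), "a, b, c")
  expect_error(calibration_curve(list(pink = c(a = 0, b = 1, c = 2))),
               "named by colour channel")
  old <- calibration_curve(list(red = c(a = 0, b = 0.5, c = 12)),
                           calibration_date = Sys.Date() - 120)
  expect_warning(check_curve_validity(old), "3 months")
  fresh <- calibration_curve(list(red = c(a = 0, b = 0.5, c = 12)))
  expect_silent(check_curve_validity(fresh))
})

test_that("calibration JSON archive round-trips the curve", {
  fx <- small_fixtures()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(fx$curve, path, points = fx$points)
  back <- read_calibration_json(path)
  for (ch in c("red", "green", "blue"))
    expect_equal(back$params[[ch]], fx$curve$params[[ch]], tolerance = 1e-12)
  expect_equal(back$lot_id, fx$curve$lot_id)
  expect_equal(back$form, fx$curve$form)
  expect_equal(back$dose_range, fx$curve$dose_range)
  expect_equal(back$calibration_date, fx$curve$calibration_date)
  expect_true(file.exists(sub("\\.json$", "_points.csv", path)))
})

test_that("calibration factor is dose per unit net OD", {
  expect_equal(calibration_factor(2, 0.16), 12.5)
  expect_error(calibration_factor(2, 0), "non-zero")
})
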
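test_that("roi_stats matches hand-computed mean, population SD and n", {
  plane <- matrix(as.numeric(1:20), nrow = 4)   # 4 x 5, column-major 1..20
  planes <- list(red = plane, green = plane + 100, blue = plane + 200)
  scan <- film_scan(planes)
  r <- roi(x0 = 1, y0 = 1, width = 2, height = 3)   # columns 2:3, rows 2:4
  v <- c(plane[2:4, 2:3])
  s <- roi_stats(scan, r, "red")
  expect_equal(s$n, 6)
  expect_equal(s$mean, mean(v))
  expect_equal(s$sd, sqrt(mean((v - mean(v))^2)))   # population SD
  expect_equal(roi_stats(scan, r, "green")$mean, mean(v) + 100)
})

test_that("ROI constructors validate bounds and are half-open", {
  expect_error(roi(0, 0, 0, 5), "width and height")
  expect_error(roi(-1, 0, 5, 5), "non-negative")
  scan <- film_scan(list(red = matrix(0, 10, 10), green = matrix(0, 10, 10),
                         blue = matrix(0, 10, 10)))
  expect_error(roi_stats(scan, roi(6, 0, 5, 5)), "outside")
  # adjacent half-open ROIs tile without overlap
  left <- roi(0, 0, 5, 10); right <- roi(5, 0, 5, 10)
  scan$channels$red[, 6:10] <- 100
  expect_equal(roi_stats(scan, left, "red")$mean, 0)
  expect_equal(roi_stats(scan, right, "red")$mean, 100)
})

test_that("the normalization ROI is 3 x 4 cm centred on the full bed", {
  r <- normalization_roi()
  expect_equal(r$width, 85)     # round(3 / 2.54 * 72)
  expect_equal(r$height, 113)   # round(4 / 2.54 * 72)
  expect_equal(r$x0, 245)
  expect_equal(r$y0, 303)
})

test_that("film_scan validates channels, dimensions and value range", {
  m <- matrix(0, 5, 6)
  expect_error(film_scan(list(red = m, green = m)), "red, green and blue")
  expect_error(film_scan(list(red = m, green = m, blue = matrix(0, 5, 7))),
               "identical dimensions")
  expect_error(film_scan(list(red = m - 1, green = m, blue = m)), "16-bit")
  expect_error(film_scan(list(red = m + 70000, green = m, blue = m)), "16-bit")
  s <- film_scan(list(red = m, green = m, blue = m), orientation_tag = "rot180")
  expect_s3_class(s, "film_scan")
  expect_equal(s$width_px, 6)
  expect_equal(s$height_px, 5)
})

test_that("48-bit TIFF write/read round-trips pixel values bit-exactly", {
  set.seed(42)
  planes <- lapply(setNames(1:3, c("red", "green", "blue")), function(k)
    matrix(sample(0:65535, 20 * 30, replace = TRUE), 20, 30))
  planes$red[1, 1] <- 0          # exercise both ends of the range
  planes$red[1, 2] <- 65535
  scan <- film_scan(planes, film_id = "RT1", lot_id = "LOTX",
                    orientation_tag = "flipped",
                    scan_time = t_exposure + 4 * 86400,
                    exposure_time = t_exposure, scan_index = 2L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_film_tiff(scan, path)
  back <- suppressWarnings(read_film_tiff(path))
  for (ch in c("red", "green", "blue"))
    expect_identical(back$channels[[ch]], planes[[ch]] + 0)   # numeric, exact
  expect_equal(back$film_id, "RT1")
  expect_equal(back$lot_id, "LOTX")
  expect_equal(back$orientation_tag, "flipped")
  expect_equal(back$scan_index, 2L)
  expect_equal(as.numeric(back$scan_time), as.numeric(scan$scan_time))
  expect_equal(as.numeric(back$exposure_time), as.numeric(scan$exposure_time))
})

test_that("8-bit and grayscale TIFFs are rejected as film scans", {
  path8 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, dim = c(5, 5, 3)), path8, bits.per.sample = 8)
  expect_error(read_film_tiff(path8), "16 bits")
  pathg <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 5, 5), pathg, bits.per.sample = 16)
  expect_error(read_film_tiff(pathg), "grayscale|RGB")
  expect_error(read_film_tiff(withr::local_tempfile(fileext = ".tif")),
               "does not exist")
})

test_that("averaging five or fewer scans is a pixelwise mean", {
  m <- matrix(1000, 8, 9)
  mk <- function(val, i) film_scan(list(red = m + val, green = m, blue = m),
                                   film_id = "A", scan_index = i)
  avg <- average_repeated_scans(list(mk(0, 1), mk(30, 2), mk(60, 3)))
  expect_equal(avg$channels$red, m + 30)
  expect_equal(avg$scan_index, 1L)
})

test_that("averaging more than five scans removes a linear drift trend", {
  # readings grow by exactly 12 PV per scan; the fitted line evaluated at
  # the first scan index must recover the undrifted value exactly
  m <- matrix(2000, 6, 7)
  scans <- lapply(1:7, function(i)
    film_scan(list(red = m + 12 * (i - 1), green = m, blue = m),
              film_id = "D", scan_index = i))
  avg <- average_repeated_scans(scans)
  expect_equal(avg$channels$red, m, tolerance = 1e-12)
  # a plain mean would sit 36 PV high
  expect_false(isTRUE(all.equal(avg$channels$red, m + 36)))
})

test_that("averaging rejects mixed films and unordered scan indices", {
  m <- matrix(0, 4, 4)
  a <- film_scan(list(red = m, green = m, blue = m), film_id = "A",
                 scan_index = 1L)
  b <- film_scan(list(red = m, green = m, blue = m), film_id = "B",
                 scan_index = 2L)
  expect_error(average_repeated_scans(list(a, b)), "different films")
  a2 <- a; a2$scan_index <- 1L
  expect_error(average_repeated_scans(list(a, a2)), "strictly increasing")
})
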
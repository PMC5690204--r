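#' Scanner model for the synthetic fixture generator
#'
#' Describes a flatbed transmission scanner with the sensitivity artifacts
#' characteristic of consumer flatbeds used for film dosimetry:
#' an additive transversal pixel-value deficit (about 300 PV at the left
#' edge, zero over the central normalization columns, growing to about
#' 1800 PV at the right edge for unexposed film), a smaller longitudinal
#' deviation (up to 340 PV at the top/bottom edges), and a dose-dependent
#' lateral response on the right half of the bed that vanishes at zero dose
#' and grows linearly with the local dose. Pixel noise, a per-scan reading
#' drift for exposed film (+0.03% per successive scan of a burst), and
#' dust specks on the scanner glass complete the model.
#'
#' All sensitivity terms are additive in pixel-value space and are zero
#' over the normalization columns, so the additive two-phase correction
#' model is exactly the right correction class; this is deliberate, the
#' generator is a testbed for the correction pipeline, not an optics
#' simulation.
#'
#' @param width_px,height_px bed size in pixels (full bed 576 x 720 at 72 dpi).
#' @param dpi scan resolution.
#' @param transversal_left_pv,transversal_right_pv PV deficit magnitude at
#'   the left and right bed edges for unexposed film.
#' @param longitudinal_pv maximum PV deficit at the top/bottom edges.
#' @param dose_lateral_pv named per-channel PV deficit at the right edge at
#'   the reference dose `dose_lateral_ref_gy`; scales linearly with dose.
#' @param dose_lateral_ref_gy reference dose of `dose_lateral_pv` (Gy).
#' @param noise_sd_pv per-pixel Gaussian read noise (PV, 1 SD). The default
#'   of 9 PV makes the maximum pixel difference between two matrix
#'   corrections derived from independent 10-scan stacks about 20 PV,
#'   the repeatability a well-behaved flatbed achieves.
#' @param drift_per_scan relative reading increase per successive scan of
#'   exposed film within one burst (0.0003 = +0.03%).
#' @param dust_count,dust_radius_px,dust_factor number of dust specks per
#'   scan, their radius in pixels, and the multiplicative PV attenuation
#'   inside a speck (0.92 darkens the reading by 8%, roughly a +20% local
#'   dose error at 2 Gy).
#' @param nofilm_pv mean PV of bed areas not covered by film.
#' @return an object of class `scanner_model` with precomputed artifact
#'   fields.
#' @export
scanner_model <- function(width_px = FULL_BED_WIDTH, height_px = FULL_BED_HEIGHT,
                          dpi = SCAN_DPI,
                          transversal_left_pv = 300,
                          transversal_right_pv = 1800,
                          longitudinal_pv = 340,
                          dose_lateral_pv = c(red = 600, green = 600, blue = 300),
                          dose_lateral_ref_gy = 2,
                          noise_sd_pv = 9,
                          drift_per_scan = 3e-4,
                          dust_count = 0L, dust_radius_px = 3, dust_factor = 0.92,
                          nofilm_pv = 62000) {
  W <- as.integer(width_px); H <- as.integer(height_px)
  nr <- roi_cm_center(3, 4, W, H, dpi)
  nx0 <- nr$x0; nx1 <- nr$x0 + nr$width    # norm columns [nx0, nx1), 0-based
  ny0 <- nr$y0; ny1 <- nr$y0 + nr$height

  x <- 0:(W - 1)
  tprof <- numeric(W)
  left <- x < nx0
  tprof[left] <- -transversal_left_pv * ((nx0 - x[left]) / nx0)^2
  right <- x >= nx1
  tprof[right] <- -transversal_right_pv *
    ((x[right] - (nx1 - 1)) / (W - nx1))^2

  y <- 0:(H - 1)
  lprof <- numeric(H)
  top <- y < ny0
  lprof[top] <- -longitudinal_pv * ((ny0 - y[top]) / ny0)^2
  bot <- y >= ny1
  lprof[bot] <- -longitudinal_pv * ((y[bot] - (ny1 - 1)) / (H - ny1))^2

  # squared right-half ramp of the dose-dependent lateral response
  dd <- numeric(W)
  dd[right] <- ((x[right] - (nx1 - 1)) / (W - nx1))^2

  structure(list(
    width_px = W, height_px = H, dpi = as.integer(dpi),
    norm_roi = nr, norm_cols = c(nx0, nx1),
    transversal_profile = tprof, longitudinal_profile = lprof,
    base_deficit = outer(lprof, tprof, `+`),
    dose_lateral_pv = dose_lateral_pv, dose_lateral_ref_gy = dose_lateral_ref_gy,
    dose_lateral_ramp = dd,
    noise_sd_pv = noise_sd_pv, drift_per_scan = drift_per_scan,
    dust_count = as.integer(dust_count), dust_radius_px = dust_radius_px,
    dust_factor = dust_factor, nofilm_pv = nofilm_pv
  ), class = "scanner_model")
}

#' Film lot model for the synthetic fixture generator
#'
#' Ground-truth film response and lot-level variability. The dose response
#' follows the rational form D(x) = (a + c x) / (1 + b x) of the net
#' optical density x; the generator inverts it to produce exposed pixel
#' values. The default background/curve pairing is frozen so that a 2 Gy
#' exposure lands in the 26000-26500 PV window on the red channel with a
#' 40000 PV unexposed background. Emulsion spreading produces longitudinal
#' sensitivity bands (multiplicative, strongest in the blue channel) and a
#' small piece-to-piece background variation.
#'
#' @param background_pv named per-channel unexposed mean PV.
#' @param curve named list of per-channel `c(a, b, c)` response parameters
#'   (Gy, 1/OD, Gy/OD) of the rational dose-response.
#' @param band_amplitude named per-channel relative amplitude of the
#'   longitudinal emulsion bands.
#' @param piece_scale_sd named per-channel SD of the multiplicative
#'   piece-to-piece background variation (truncated at `piece_scale_max`).
#' @param piece_scale_max truncation bound of the piece variation (the lot
#'   QC experience is that sheet variation stays within 2%).
#' @param max_dose_gy upper end of the monotone response range.
#' @return an object of class `film_model`.
#' @export
film_model <- function(background_pv = c(red = 40000, green = 40500, blue = 30000),
                       curve = list(red   = c(a = 0, b = 0.5, c = 11.930),
                                    green = c(a = 0, b = 0.5, c = 12.765),
                                    blue  = c(a = 0, b = 0.5, c = 31.770)),
                       band_amplitude = c(red = 2e-4, green = 2e-4, blue = 4e-3),
                       piece_scale_sd = c(red = 0.0015, green = 0.0015, blue = 0.003),
                       piece_scale_max = 0.02,
                       max_dose_gy = 8) {
  for (ch in CHANNELS) {
    p <- curve[[ch]]
    if (p["c"] - p["b"] * max_dose_gy <= 0)
      stop_input("response of channel ", ch,
                 " is not monotone up to ", max_dose_gy, " Gy (need c - b*D > 0)")
  }
  structure(list(background_pv = background_pv, curve = curve,
                 band_amplitude = band_amplitude,
                 piece_scale_sd = piece_scale_sd,
                 piece_scale_max = piece_scale_max,
                 max_dose_gy = max_dose_gy),
            class = "film_model")
}

# exact net OD of the model response at dose D (inverse of the rational form)
model_od <- function(model, channel, dose) {
  p <- model$curve[[channel]]
  (dose - p["a"]) / (p["c"] - p["b"] * dose)
}

#' Realize an individual film piece from a lot model
#'
#' Draws the piece's concrete emulsion band profile and background scale
#' from the lot model. Scans of the same piece (e.g. its background and
#' exposed scans) share this realization, which is what lets background
#' pairing cancel the film's own nonuniformity in net OD.
#'
#' @param model a [film_model()].
#' @param film_id identification string.
#' @param width_px film width in pixels (bands are a function of the
#'   transversal film coordinate).
#' @param lot_id lot identification.
#' @param seed RNG seed for the realization.
#' @return an object of class `film_piece`.
#' @export
film_piece <- function(model, film_id, width_px = FULL_BED_WIDTH,
                       lot_id = "SIMLOT", seed = NULL) {
  with_seed(seed, {
    fx <- 0:(width_px - 1)
    bands <- sapply(CHANNELS, function(ch) {
      amp <- model$band_amplitude[[ch]]
      p1 <- runif(1, 0.3, 0.6) * width_px
      p2 <- runif(1, 0.08, 0.2) * width_px
      ph <- runif(2, 0, 2 * pi)
      1 + amp * (0.7 * sin(2 * pi * fx / p1 + ph[1]) +
                 0.3 * sin(2 * pi * fx / p2 + ph[2]))
    })
    scale <- vapply(CHANNELS, function(ch) {
      s <- rnorm(1, 0, model$piece_scale_sd[[ch]])
      1 + max(min(s, model$piece_scale_max), -model$piece_scale_max)
    }, 0)
    structure(list(model = model, film_id = film_id, lot_id = lot_id,
                   width_px = as.integer(width_px),
                   bands = bands, scale = scale),
              class = "film_piece")
  })
}

#' Inject a localized sensitivity band into a film piece
#'
#' Adds a Gaussian-profile multiplicative band to the piece's emulsion
#' band profile, for testing the blue-channel homogeneity QC.
#'
#' @param piece a [film_piece()].
#' @param center_frac,width_frac band centre and full width as fractions of
#'   the film width.
#' @param delta peak relative amplitude (0.015 = a 1.5% band).
#' @param channels channels affected (emulsion thickness shows mostly in
#'   blue).
#' @return the modified `film_piece`.
#' @export
inject_band <- function(piece, center_frac = 0.3, width_frac = 0.08,
                        delta = 0.015, channels = "blue") {
  fx <- 0:(piece$width_px - 1)
  c0 <- center_frac * piece$width_px
  sg <- width_frac * piece$width_px / 2.355    # FWHM -> sigma
  bump <- delta * exp(-(fx - c0)^2 / (2 * sg^2))
  for (ch in channels) piece$bands[, ch] <- piece$bands[, ch] * (1 + bump)
  piece
}

#' Dose field on the scanner bed
#'
#' A ground-truth absorbed-dose-to-water array in the film frame, plus the
#' film's placement on the bed: `film_mask` marks bed pixels covered by
#' film, `film_x0` is the transversal bed column where the film's left
#' edge sits (used to index the piece's band profile).
#'
#' @param dose numeric matrix (Gy), bed-sized.
#' @param film_mask logical matrix marking film coverage (default: all).
#' @param film_x0 0-based bed column of the film's left edge.
#' @param description free-text provenance.
#' @return an object of class `dose_field`.
#' @export
dose_field <- function(dose, film_mask = NULL, film_x0 = 0L, description = "") {
  if (any(dose < 0)) stop_input("dose must be non-negative")
  if (is.null(film_mask)) film_mask <- matrix(TRUE, nrow(dose), ncol(dose))
  stopifnot(identical(dim(film_mask), dim(dose)))
  structure(list(dose = dose, film_mask = film_mask,
                 film_x0 = as.integer(film_x0), description = description),
            class = "dose_field")
}

#' Uniform full-bed dose field
#' @param dose_gy uniform dose (Gy).
#' @param scanner a [scanner_model()] fixing the bed geometry.
#' @return a [dose_field()].
#' @export
uniform_dose_field <- function(dose_gy, scanner = scanner_model()) {
  dose_field(matrix(dose_gy, scanner$height_px, scanner$width_px),
             description = sprintf("uniform %.3g Gy", dose_gy))
}

#' Flat-top square field with linear penumbra
#'
#' A centred square field (10 cm x 10 cm by default) with a flat plateau
#' and a linear penumbra falling to zero, emulating a reference-geometry
#' exposure of a full film sheet.
#'
#' @param dose_gy plateau dose (Gy).
#' @param field_cm field side length (cm).
#' @param penumbra_cm width of the linear falloff (cm).
#' @param scanner a [scanner_model()].
#' @return a [dose_field()].
#' @export
flat_top_dose_field <- function(dose_gy, field_cm = 10, penumbra_cm = 0.5,
                                scanner = scanner_model()) {
  W <- scanner$width_px; H <- scanner$height_px; dpi <- scanner$dpi
  half <- field_cm / 2.54 * dpi / 2
  pen <- penumbra_cm / 2.54 * dpi
  fall <- function(u) pmin(1, pmax(0, (half + pen - abs(u)) / pen))
  wx <- fall((0:(W - 1)) - (W - 1) / 2)
  wy <- fall((0:(H - 1)) - (H - 1) / 2)
  dose_field(dose_gy * outer(wy, wx),
             description = sprintf("flat-top %gx%g cm, %.3g Gy", field_cm,
                                   field_cm, dose_gy))
}

#' Centred calibration-piece field
#'
#' A small film piece (5 cm x 6 cm by default) centred on the bed and
#' uniformly exposed; the rest of the bed is bare glass.
#'
#' @param dose_gy dose over the piece (Gy).
#' @param piece_cm piece width x height in cm.
#' @param scanner a [scanner_model()].
#' @return a [dose_field()] whose `film_mask` covers only the piece.
#' @export
calibration_piece_field <- function(dose_gy, piece_cm = c(5, 6),
                                    scanner = scanner_model()) {
  W <- scanner$width_px; H <- scanner$height_px
  r <- roi_cm_center(piece_cm[1], piece_cm[2], W, H, scanner$dpi)
  mask <- matrix(FALSE, H, W)
  mask[(r$y0 + 1):(r$y0 + r$height), (r$x0 + 1):(r$x0 + r$width)] <- TRUE
  dose_field(matrix(dose_gy, H, W) * mask, film_mask = mask, film_x0 = r$x0,
             description = sprintf("calibration piece, %.3g Gy", dose_gy))
}

# transform a matrix between film frame and scanner frame; all four
# orientation operations are involutions so forward and inverse coincide
orient_matrix <- function(m, tag) {
  switch(tag,
    normal = m,
    rot180 = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
    flipped = m[, rev(seq_len(ncol(m))), drop = FALSE],
    flipped_rot180 = m[rev(seq_len(nrow(m))), , drop = FALSE],
    stop_input("unknown orientation tag: ", tag))
}

#' Simulate one film scan
#'
#' Runs the forward model: the ground-truth dose field is converted to net
#' optical density through the film model's response, multiplied by the
#' piece's band profile and background scale, geometrically placed on the
#' bed in the requested orientation, and degraded by the scanner's additive
#' sensitivity deficits (position-dependent plus dose-dependent lateral),
#' per-scan drift, dust specks and pixel noise, then quantized to 16 bits.
#' Deterministic for a given seed.
#'
#' @param field a [dose_field()] (film frame).
#' @param piece a [film_piece()] (or a [film_model()], from which an
#'   average piece with unit bands is taken).
#' @param scanner a [scanner_model()].
#' @param orientation one of the four read-out orientation tags.
#' @param scan_index position within a repeated-scan burst (drives drift).
#' @param seed RNG seed (noise and dust).
#' @param dust_count number of dust specks for this scan (defaults to the
#'   scanner model's value).
#' @param exposure_time,scan_time optional timestamps copied to the scan.
#' @return a list with `scan` (a [film_scan()]) and `truth` (ground-truth
#'   record: film-frame dose, exact per-channel OD, scanner-frame dose,
#'   dust mask, piece and orientation).
#' @export
simulate_scan <- function(field, piece, scanner = scanner_model(),
                          orientation = "normal", scan_index = 1L,
                          seed = NULL, dust_count = scanner$dust_count,
                          exposure_time = NULL, scan_time = NULL) {
  orientation <- match.arg(orientation, ORIENTATION_TAGS)
  if (inherits(piece, "film_model"))
    piece <- structure(list(model = piece, film_id = "MODEL", lot_id = "SIMLOT",
                            width_px = ncol(field$dose),
                            bands = matrix(1, ncol(field$dose), 3,
                                           dimnames = list(NULL, CHANNELS)),
                            scale = setNames(rep(1, 3), CHANNELS)),
                       class = "film_piece")
  model <- piece$model
  W <- scanner$width_px; H <- scanner$height_px
  stopifnot(identical(dim(field$dose), c(H, W)))
  dmax <- max(field$dose)
  if (dmax > model$max_dose_gy)
    stop_input("dose field exceeds the film model's monotone range (",
               dmax, " > ", model$max_dose_gy, " Gy)")

  # band profile mapped to bed columns through the film placement
  band_bed <- function(ch) {
    b <- rep(1, W)
    fx <- seq_len(piece$width_px) + field$film_x0   # 1-based bed columns
    fx_ok <- fx >= 1 & fx <= W
    b[fx[fx_ok]] <- piece$bands[which(fx_ok), ch]
    b
  }

  od <- lapply(setNames(CHANNELS, CHANNELS), function(ch)
    matrix(model_od(model, ch, field$dose), H, W))

  with_seed(seed, {
    planes <- list()
    # dust specks live on the scanner glass: per scan, scanner frame
    dustmask <- matrix(FALSE, H, W)
    if (dust_count > 0) {
      cx <- runif(dust_count, 1, W); cy <- runif(dust_count, 1, H)
      xg <- matrix(1:W, H, W, byrow = TRUE); yg <- matrix(1:H, H, W)
      for (i in seq_len(dust_count))
        dustmask <- dustmask |
          ((xg - cx[i])^2 + (yg - cy[i])^2 <= scanner$dust_radius_px^2)
    }
    dose_scanner <- orient_matrix(field$dose, orientation)
    exposed <- dmax > 0
    for (ch in CHANNELS) {
      pv0 <- model$background_pv[[ch]] * piece$scale[[ch]] *
        matrix(band_bed(ch), H, W, byrow = TRUE) * 10^(-od[[ch]])
      pv0[!field$film_mask] <- scanner$nofilm_pv
      pv <- orient_matrix(pv0, orientation)
      pv <- pv + scanner$base_deficit -
        matrix(scanner$dose_lateral_pv[[ch]] *
                 scanner$dose_lateral_ramp, H, W, byrow = TRUE) *
          dose_scanner / scanner$dose_lateral_ref_gy
      if (exposed) pv <- pv * (1 + scanner$drift_per_scan * (scan_index - 1))
      pv[dustmask] <- pv[dustmask] * scanner$dust_factor
      if (scanner$noise_sd_pv > 0)
        pv <- pv + matrix(rnorm(H * W, 0, scanner$noise_sd_pv), H, W)
      planes[[ch]] <- pmin(pmax(round(pv), 0), 65535)
    }
    scan <- film_scan(planes, dpi = scanner$dpi, film_id = piece$film_id,
                      lot_id = piece$lot_id, orientation_tag = orientation,
                      scan_time = scan_time, exposure_time = exposure_time,
                      scan_index = scan_index)
    list(scan = scan,
         truth = list(dose_film = field$dose, dose_scanner = dose_scanner,
                      od = od, dust_mask = dustmask, film_mask = field$film_mask,
                      piece = piece, orientation = orientation, seed = seed))
  })
}

#' Generate a stack of unexposed full-bed film scans
#'
#' One scan each of `n` distinct unexposed films, sharing the scanner's
#' sensitivity field but with independent noise and film realizations;
#' the raw material for deriving the matrix correction.
#'
#' @param n number of films (>= 2).
#' @param film a [film_model()].
#' @param scanner a [scanner_model()].
#' @param seed master seed; each film gets a derived sub-seed.
#' @param lot_id lot identity stamped on the scans.
#' @return a list with `scans` (list of [film_scan()]) and `pieces`.
#' @export
generate_unexposed_stack <- function(n, film = film_model(),
                                     scanner = scanner_model(), seed = NULL,
                                     lot_id = "SIMLOT") {
  if (n < 2) stop_input("need at least 2 unexposed films")
  zero <- uniform_dose_field(0, scanner)
  out <- lapply(seq_len(n), function(i) {
    piece <- film_piece(film, sprintf("UNEXP%02d", i), scanner$width_px,
                        lot_id, seed = derive_seed(seed, i))
    simulate_scan(zero, piece, scanner, seed = derive_seed(seed, 1000 + i))
  })
  list(scans = lapply(out, `[[`, "scan"),
       pieces = lapply(out, function(o) o$truth$piece))
}

#' Generate a calibration exposure set
#'
#' One film piece per dose level, each with a background scan taken two
#' days before the (simulated) exposure and an exposed scan four days
#' after, matching the read-out timing protocol. Pieces are centred on the
#' bed. The exact per-channel net OD of each dose is recorded as ground
#' truth. A 2 Gy level is expected in every calibration.
#'
#' @param doses dose levels in Gy (0.25-8 Gy range typical).
#' @param film a [film_model()].
#' @param scanner a [scanner_model()].
#' @param seed master seed.
#' @param out_dir if given, TIFF fixtures plus a `truth.csv` are written
#'   there.
#' @param lot_id lot identity.
#' @return list with `pieces` (per dose: `dose`, `background`, `exposed`
#'   [film_scan()]s and the piece), `truth` (data.frame of dose and exact
#'   per-channel OD), and `roi` (the 35 mm x 40 mm scoring area).
#' @export
generate_calibration_set <- function(doses, film = film_model(),
                                     scanner = scanner_model(), seed = NULL,
                                     out_dir = NULL, lot_id = "SIMLOT") {
  if (length(doses) < 1) stop_input("empty dose list")
  if (any(doses < 0)) stop_input("doses must be non-negative")
  if (!any(abs(doses - 2) < 1e-9))
    warning("calibration set does not include the 2 Gy level", call. = FALSE)
  t0 <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")
  pieces <- lapply(seq_along(doses), function(i) {
    d <- doses[i]
    piece <- film_piece(film, sprintf("CAL%04.2f", d), scanner$width_px,
                        lot_id, seed = derive_seed(seed, 2000 + i))
    bg <- simulate_scan(calibration_piece_field(0, scanner = scanner), piece,
                        scanner, seed = derive_seed(seed, 3000 + i),
                        exposure_time = t0, scan_time = t0 - 2 * 86400)
    ex <- simulate_scan(calibration_piece_field(d, scanner = scanner), piece,
                        scanner, seed = derive_seed(seed, 4000 + i),
                        exposure_time = t0, scan_time = t0 + 4 * 86400)
    list(dose = d, background = bg$scan, exposed = ex$scan, piece = piece)
  })
  truth <- data.frame(
    dose_gy = doses,
    od_red = vapply(doses, function(d) model_od(film, "red", d), 0),
    od_green = vapply(doses, function(d) model_od(film, "green", d), 0),
    od_blue = vapply(doses, function(d) model_od(film, "blue", d), 0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (p in pieces) {
      tag <- sprintf("%04.2fGy", p$dose)
      write_film_tiff(p$background, file.path(out_dir, paste0("bg_", tag, ".tif")))
      write_film_tiff(p$exposed, file.path(out_dir, paste0("ex_", tag, ".tif")))
    }
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(pieces = pieces, truth = truth,
       roi = roi_cm_center(3.5, 4.0, scanner$width_px, scanner$height_px,
                           scanner$dpi))
}

#' Generate a constant-dose stripe series for the transversal correction
#'
#' One physical film stripe (5 cm wide, full bed height) exposed to a
#' uniform dose and re-placed at several transversal positions on the bed,
#' scanned once per placement. The stripe's small physical dose
#' nonuniformity (well under the 0.2% 1 SD the rotating-reel exposure
#' guarantees) travels with the film. This is the raw material for
#' deriving the dose-dependent transversal correction.
#'
#' @param dose stripe dose (Gy, > 0).
#' @param positions 0-based bed columns of the stripe centres; together the
#'   placements should cover the bed left-to-right including the
#'   normalization columns.
#' @param film a [film_model()].
#' @param scanner a [scanner_model()].
#' @param seed master seed.
#' @param stripe_width_px stripe width (default 5 cm at the scan dpi).
#' @param dose_uniformity_sd relative 1 SD of the stripe's smooth physical
#'   dose nonuniformity.
#' @return list with `scans`, `columns` (0-based covered columns per scan),
#'   `dose`, `piece` and `truth` (the injected dose-lateral deficit per
#'   channel at this dose, by bed column).
#' @export
generate_stripe_series <- function(dose, positions, film = film_model(),
                                   scanner = scanner_model(), seed = NULL,
                                   stripe_width_px = round(5 / 2.54 * scanner$dpi),
                                   dose_uniformity_sd = 0.001) {
  if (dose <= 0) stop_input("stripe dose must be > 0")
  W <- scanner$width_px; H <- scanner$height_px
  half <- stripe_width_px / 2
  x0s <- as.integer(round(positions - half))
  if (any(x0s < 0) || any(x0s + stripe_width_px > W))
    stop_input("stripe placement extends outside the scanner bed")
  piece <- film_piece(film, "STRIPE1", stripe_width_px,
                      seed = derive_seed(seed, 51))
  # smooth physical dose pattern fixed on the film (separable, low order)
  pat <- with_seed(derive_seed(seed, 52), {
    fx <- 0:(stripe_width_px - 1); fy <- 0:(H - 1)
    phx <- runif(2, 0, 2 * pi); phy <- runif(2, 0, 2 * pi)
    rx <- sin(2 * pi * fx / stripe_width_px + phx[1]) +
      0.5 * sin(4 * pi * fx / stripe_width_px + phx[2])
    ry <- sin(2 * pi * fy / H + phy[1]) + 0.5 * sin(4 * pi * fy / H + phy[2])
    sc <- dose_uniformity_sd / sqrt(2)
    outer(1 + sc * ry / sd(ry), 1 + sc * rx / sd(rx))
  })
  res <- lapply(seq_along(x0s), function(i) {
    x0 <- x0s[i]
    mask <- matrix(FALSE, H, W)
    mask[, (x0 + 1):(x0 + stripe_width_px)] <- TRUE
    dmat <- matrix(0, H, W)
    dmat[, (x0 + 1):(x0 + stripe_width_px)] <- dose * pat
    f <- dose_field(dmat, film_mask = mask, film_x0 = x0,
                    description = sprintf("stripe at col %d", x0))
    sim <- simulate_scan(f, piece, scanner, scan_index = 1L,
                         seed = derive_seed(seed, 100 + i))
    list(scan = sim$scan, columns = x0:(x0 + stripe_width_px - 1L))
  })
  truth <- lapply(setNames(CHANNELS, CHANNELS), function(ch)
    scanner$dose_lateral_pv[[ch]] * scanner$dose_lateral_ramp *
      dose / scanner$dose_lateral_ref_gy)
  list(scans = lapply(res, `[[`, "scan"),
       columns = lapply(res, `[[`, "columns"),
       dose = dose, piece = piece, truth = truth)
}
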
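#' Net optical density
#'
#' The dose-carrying signal of radiochromic film read in transmission:
#' `net OD = log10(PV_unexposed / PV_exposed)` for the same film piece.
#' Small negative values are legitimate (noise around zero dose) and are
#' handled downstream by the zero-level rule of [od_to_dose()].
#'
#' @param pv_un,pv_ex mean pixel values of the unexposed (background) and
#'   exposed readings; both must be positive. Vectorized.
#' @return net optical density (same shape as the inputs).
#' @export
net_od <- function(pv_un, pv_ex) {
  if (any(pv_un <= 0) || any(pv_ex <= 0))
    stop_input("pixel values must be positive to form an optical density")
  log10(pv_un / pv_ex)
}

dose_from_od <- function(x, p, form) {
  switch(form,
    rational = (p[["a"]] + p[["c"]] * x) / (1 + p[["b"]] * x),
    additive = p[["a"]] + p[["c"]] * x / (1 + p[["b"]] * x),
    stop_input("unknown functional form: ", form))
}

#' Fit the rational dose-response of one channel
#'
#' Least-squares fit of the dose response `D(x) = (a + c x) / (1 + b x)`
#' (default) or the additive variant `D(x) = a + c x / (1 + b x)` to
#' calibration points `(net OD, dose)`. For the rational form the model is
#' linear in `(a, c, b)` after multiplying out the denominator, which
#' provides exact starting values; a Levenberg-Marquardt refinement then
#' minimizes the untransformed residuals. The fitted curve must be
#' monotone increasing over the data's OD range.
#'
#' @param od net optical densities.
#' @param dose reference doses (Gy) from a traceable source.
#' @param channel colour channel the points belong to.
#' @param form `"rational"` (default) or `"additive"`.
#' @param constrain_zero force `a = 0` so that zero net OD maps to zero
#'   dose.
#' @param weights optional least-squares weights (e.g. inverse variance);
#'   default unweighted.
#' @return a list with the parameters `a`, `b`, `c`, the residuals, their
#'   RMSE, the OD range and the point count.
#' @export
fit_calibration <- function(od, dose, channel = "red",
                            form = c("rational", "additive"),
                            constrain_zero = FALSE, weights = NULL) {
  form <- match.arg(form)
  channel <- match.arg(channel, CHANNELS)
  if (length(od) != length(dose)) stop_input("od and dose lengths differ")
  if (length(od) < 4)
    stop_input("need at least 4 calibration points per channel, got ",
               length(od))
  w <- weights %||% rep(1, length(od))

  # starting values: the rational form is linear after clearing the
  # denominator: D = a + c*x - b*(D*x)
  X <- if (constrain_zero) cbind(x = od, bx = -dose * od)
       else cbind(1, x = od, bx = -dose * od)
  beta <- tryCatch(qr.solve(X * sqrt(w), dose * sqrt(w)),
                   error = function(e) NULL)
  if (is.null(beta)) stop_input("degenerate calibration design; cannot fit")
  beta <- unname(beta)
  start <- if (constrain_zero) list(a = 0, c = beta[1], b = beta[2])
           else list(a = beta[1], c = beta[2], b = beta[3])
  if (form == "additive") {
    # rational-form starts do not transfer; start near the linear limit
    lf <- lm(dose ~ od, weights = w)
    start <- list(a = if (constrain_zero) 0 else unname(coef(lf)[1]),
                  c = unname(coef(lf)[2]), b = 1e-3)
  }

  df <- data.frame(x = od, D = dose)
  fml <- if (form == "rational") {
    if (constrain_zero) D ~ (c * x) / (1 + b * x)
    else D ~ (a + c * x) / (1 + b * x)
  } else {
    if (constrain_zero) D ~ c * x / (1 + b * x)
    else D ~ a + c * x / (1 + b * x)
  }
  st <- start[setdiff(names(start), if (constrain_zero) "a" else character())]
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = st, weights = w,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    p <- c(a = if (constrain_zero) 0 else unname(cf["a"]),
           b = unname(cf["b"]), c = unname(cf["c"]))
  } else {
    p <- c(a = if (constrain_zero) 0 else unname(start$a),
           b = unname(start$b), c = unname(start$c))
  }

  xr <- range(od)
  xs <- seq(xr[1], xr[2], length.out = 101)
  if (any(1 + p[["b"]] * xs <= 0))
    stop_input("fitted curve has a pole inside the data range (1 + b*x <= 0)")
  ds <- dose_from_od(xs, p, form)
  if (any(diff(ds) <= 0))
    stop_input("fitted curve is not monotone increasing over the data range")

  resid <- dose - dose_from_od(od, p, form)
  list(channel = channel, form = form,
       a = p[["a"]], b = p[["b"]], c = p[["c"]],
       residuals = resid, rmse = sqrt(mean(resid^2)),
       od_range = xr, n = length(od))
}

#' Calibration curve container
#'
#' Per-channel rational dose-response parameters together with lot
#' identity, beam quality, validity dose range and calibration date.
#' Curves are per-lot and should be renewed every three months.
#'
#' @param params named list (`red`, `green`, `blue` or a subset) of
#'   `c(a =, b =, c =)` parameter vectors.
#' @param lot_id film lot the curve belongs to.
#' @param q beam quality label of the calibration (e.g. `"Co-60"`,
#'   `"6MV"`).
#' @param dose_range validity range in Gy; conversions above the top end
#'   are extrapolations and are flagged or refused.
#' @param calibration_date a `Date`.
#' @param form functional form, `"rational"` or `"additive"`.
#' @param channels_for_dose channels averaged for dose determination
#'   (default red and green; blue is kept for QC only).
#' @param fit optional list of per-channel [fit_calibration()] results.
#' @return an object of class `calibration_curve`.
#' @export
calibration_curve <- function(params, lot_id = "unknown", q = "Co-60",
                              dose_range = c(0, 8),
                              calibration_date = Sys.Date(),
                              form = c("rational", "additive"),
                              channels_for_dose = c("red", "green"),
                              fit = NULL) {
  form <- match.arg(form)
  if (!all(names(params) %in% CHANNELS) || length(params) == 0)
    stop_input("params must be named by colour channel")
  for (ch in names(params)) {
    p <- params[[ch]]
    if (!all(c("a", "b", "c") %in% names(p)))
      stop_input("channel ", ch, " parameters must be named a, b, c")
  }
  structure(list(params = lapply(params, function(p) p[c("a", "b", "c")]),
                 lot_id = lot_id, q = q, dose_range = dose_range,
                 calibration_date = as.Date(calibration_date), form = form,
                 channels_for_dose = channels_for_dose, fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> lot %s, Q = %s, %s form, %g-%g Gy, %s\n",
              x$lot_id, x$q, x$form, x$dose_range[1], x$dose_range[2],
              format(x$calibration_date)))
  for (ch in names(x$params)) {
    p <- x$params[[ch]]
    cat(sprintf("  %-5s a = %.5g Gy, b = %.5g /OD, c = %.5g Gy/OD\n",
                ch, p[["a"]], p[["b"]], p[["c"]]))
  }
  invisible(x)
}

#' Fit calibration curves for all channels
#'
#' Convenience wrapper fitting [fit_calibration()] per channel from a
#' calibration points table and assembling a [calibration_curve()].
#' The validity range ends at the largest calibration dose; extrapolation
#' beyond it is never certified.
#'
#' @param points data.frame with columns `dose_gy`, `od_red`, `od_green`,
#'   `od_blue` (any channel column may be omitted).
#' @param lot_id,q,calibration_date curve identity (see
#'   [calibration_curve()]).
#' @inheritParams fit_calibration
#' @return a [calibration_curve()].
#' @export
fit_calibration_curves <- function(points, lot_id = "unknown", q = "Co-60",
                                   calibration_date = Sys.Date(),
                                   form = c("rational", "additive"),
                                   constrain_zero = FALSE) {
  form <- match.arg(form)
  chans <- CHANNELS[paste0("od_", CHANNELS) %in% names(points)]
  if (length(chans) == 0) stop_input("no od_<channel> columns in points")
  fits <- lapply(setNames(chans, chans), function(ch)
    fit_calibration(points[[paste0("od_", ch)]], points$dose_gy, ch,
                    form = form, constrain_zero = constrain_zero))
  params <- lapply(fits, function(f) c(a = f$a, b = f$b, c = f$c))
  calibration_curve(params, lot_id = lot_id, q = q,
                    dose_range = c(0, max(points$dose_gy)),
                    calibration_date = calibration_date, form = form,
                    channels_for_dose = intersect(c("red", "green"), chans),
                    fit = fits)
}

#' Warn when a calibration curve has expired
#'
#' Film response drifts with lot aging; curves should be renewed every
#' three months.
#'
#' @param curve a [calibration_curve()].
#' @param at time of use (default now).
#' @return `TRUE` (valid) or `FALSE` (expired, with a warning), invisibly.
#' @export
check_curve_validity <- function(curve, at = Sys.time()) {
  if (is.null(at)) return(invisible(TRUE))
  age <- as.numeric(difftime(as.Date(at), curve$calibration_date,
                             units = "days"))
  if (is.finite(age) && age > 90) {
    warning("calibration of lot ", curve$lot_id, " is ", round(age),
            " days old; recalibration is due every 3 months", call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' Convert net optical density to absorbed dose
#'
#' Evaluates the calibration curve. Negative net OD (noise around zero
#' dose) is clamped to 0 Gy to set the dose zero level properly; doses
#' beyond the curve's validity range are flagged (default) or raise an
#' error, since extrapolation above the calibration range is not
#' certified.
#'
#' @param x net optical density (scalar, vector or matrix).
#' @param curve a [calibration_curve()].
#' @param channel colour channel whose parameters to use.
#' @param extrapolation `"flag"` (default), `"error"`, or `"ignore"`.
#' @param detail if `TRUE`, return a list with `dose` and an integer
#'   `flags` array (1 = clamped negative OD, 2 = extrapolated).
#' @return dose in Gy with logical attributes `clamped` and
#'   `extrapolated`, or the detail list.
#' @export
od_to_dose <- function(x, curve, channel = "red",
                       extrapolation = c("flag", "error", "ignore"),
                       detail = FALSE) {
  extrapolation <- match.arg(extrapolation)
  channel <- match.arg(channel, CHANNELS)
  p <- curve$params[[channel]]
  if (is.null(p)) stop_input("curve has no parameters for channel ", channel)
  clamped <- x < 0
  xx <- pmax(x, 0)
  if (any(1 + p[["b"]] * xx <= 0))
    stop_input("optical density outside the curve's domain (1 + b*x <= 0)")
  d <- dose_from_od(xx, p, curve$form)
  d[clamped] <- 0
  extrap <- d > curve$dose_range[2]
  if (any(extrap) && extrapolation == "error")
    stop_input("dose above the calibration range (",
               curve$dose_range[2], " Gy); extrapolation is not certified")
  flags <- array(0L, dim = dim(x) %||% length(x))
  flags[clamped] <- 1L
  if (extrapolation == "flag") flags[extrap] <- 2L
  if (detail) return(list(dose = d, flags = flags))
  attr(d, "clamped") <- any(clamped)
  attr(d, "extrapolated") <- extrapolation == "flag" && any(extrap)
  d
}

#' OD-dependent calibration factor
#'
#' `N_{W,Q,OD} = D_{W,Q} / OD_{M,Q}`: dose to water per unit net OD at the
#' beam quality Q used in calibration.
#'
#' @param d_w_q absorbed dose to water (Gy).
#' @param od_m_q measured net OD (non-zero).
#' @return calibration factor in Gy per unit OD.
#' @export
calibration_factor <- function(d_w_q, od_m_q) {
  if (any(od_m_q == 0)) stop_input("net OD must be non-zero")
  d_w_q / od_m_q
}

#' Measure calibration points from a simulated or scanned exposure set
#'
#' Computes the per-channel net OD of each calibration piece from the
#' background/exposed ROI means (matrix-corrected when a correction is
#' supplied; calibration pieces sit on the normalization area where the
#' correction is zero by construction).
#'
#' @param set result of [generate_calibration_set()], or a list with
#'   `pieces` (each `dose`, `background`, `exposed`) and `roi`.
#' @param matrix optional [build_matrix_correction()].
#' @param roi scoring area (defaults to the set's 35 mm x 40 mm ROI).
#' @return data.frame with `dose_gy`, `od_red`, `od_green`, `od_blue`.
#' @export
measure_calibration_points <- function(set, matrix = NULL, roi = NULL) {
  roi <- roi %||% set$roi
  rows <- lapply(set$pieces, function(p) {
    ods <- vapply(CHANNELS, function(ch) {
      if (is.null(matrix)) {
        bg <- roi_stats(p$background, roi, ch)$mean
        ex <- roi_stats(p$exposed, roi, ch)$mean
      } else {
        bg <- mean(roi_slice(apply_matrix_correction(p$background, matrix)[[ch]], roi))
        ex <- mean(roi_slice(apply_matrix_correction(p$exposed, matrix)[[ch]], roi))
      }
      net_od(bg, ex)
    }, 0)
    data.frame(dose_gy = p$dose, od_red = ods[["red"]],
               od_green = ods[["green"]], od_blue = ods[["blue"]])
  })
  do.call(rbind, rows)
}
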
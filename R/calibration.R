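#' Detector correction factors
#'
#' Solid-state dose probes under-respond to scatter relative to an
#' ionization chamber in phantom geometry; the measured reference doses are
#' therefore multiplied by a mode-specific factor before curve fitting so
#' the correction is baked into the calibration, not applied per read. The
#' defaults are 1.4 for manual acquisitions and 2.0 for automatic brightness
#' control (ABC).
#'
#' @param manual multiplier for manual-mode reference doses (>= 1).
#' @param abc multiplier for ABC-mode reference doses (>= 1).
#' @return a named list with components \code{manual} and \code{abc}.
#' @export
detectorCorrection <- function(manual = 1.4, abc = 2.0) {
  if (manual < 1 || abc < 1)
    stop("detector correction factors must be >= 1")
  list(manual = manual, abc = abc)
}

#' Apply the solid-state to ionization-chamber correction to a dose
#'
#' Linear in dose: the corrected value is \code{dose * factor(mode)}.
#'
#' @param dose absorbed dose in mGy (>= 0); vectorized.
#' @param mode \code{"manual"} or \code{"abc"}.
#' @param corr correction factors from [detectorCorrection()].
#' @return corrected dose, mGy.
#' @examples
#' applyDetectorCorrection(10, "manual")  # 14
#' applyDetectorCorrection(50, "abc")     # 100
#' @export
applyDetectorCorrection <- function(dose, mode = c("manual", "abc"),
                                    corr = detectorCorrection()) {
  mode <- match.arg(mode)
  if (any(dose < 0)) stop("dose must be >= 0")
  dose * corr[[mode]]
}

#' Read calibration samples from CSV
#'
#' Expected header: \code{net_mpv,reference_dose_mGy,mode}.
#'
#' @param path CSV file path.
#' @return data.frame with columns net_mpv, reference_dose_mGy, mode.
#' @export
readCalibrationSamples <- function(path) {
  if (!file.exists(path)) stop("calibration sample file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("net_mpv", "reference_dose_mGy", "mode")
  if (!all(need %in% names(df)))
    stop("calibration CSV must have columns: ", paste(need, collapse = ","))
  validateCalibrationSamples(df)
  df
}

validateCalibrationSamples <- function(df) {
  if (any(df$net_mpv < 0) || any(df$net_mpv > 65535))
    stop("net_mpv must lie in [0, 65535]")
  if (any(df$reference_dose_mGy < 0))
    stop("reference doses must be >= 0")
  if (any(df$reference_dose_mGy > 160))
    stop("reference doses above the 160 mGy supported calibration range")
  if (!all(df$mode %in% c("manual", "abc")))
    stop("mode must be 'manual' or 'abc'")
  invisible(df)
}

#' Fit a net-MPV to dose calibration curve
#'
#' Reference doses of the requested mode are multiplied by the detector
#' correction factor, then a monotone-through-origin parametric form
#' \code{dose = a x + b x^c} (a, b >= 0, c >= 1) is fitted by bounded
#' Levenberg-Marquardt least squares. A pure linear fit is tried as well and
#' kept when it is at least as good. When the parametric RMS exceeds
#' \code{rmsThreshold} the fit falls back to a monotone piecewise-cubic
#' interpolant through the (isotonized) samples.
#'
#' @param samples data.frame of calibration samples (see
#'   [readCalibrationSamples()]); rows of other modes are ignored.
#' @param mode \code{"manual"} or \code{"abc"}.
#' @param corr correction factors from [detectorCorrection()].
#' @param rmsThreshold parametric-fit RMS (mGy) above which the monotone
#'   spline fallback is used; default 2\% of the maximum corrected dose.
#' @return a \linkS4class{CalibrationCurve}.
#' @export
fitCalibration <- function(samples, mode = c("manual", "abc"),
                           corr = detectorCorrection(),
                           rmsThreshold = NULL) {
  mode <- match.arg(mode)
  validateCalibrationSamples(samples)
  s <- samples[samples$mode == mode, , drop = FALSE]
  if (nrow(s) < 4)
    stop("need at least 4 calibration samples for mode '", mode, "', got ",
         nrow(s))
  x <- s$net_mpv
  d <- s$reference_dose_mGy * corr[[mode]]
  if (length(unique(x)) < 4)
    stop("degenerate calibration set: net_mpv values nearly all equal")
  if (diff(range(d)) <= 0)
    stop("degenerate calibration set: reference doses span no range")
  if (is.null(rmsThreshold)) rmsThreshold <- 0.02 * max(d)

  xscale <- max(x)
  u <- x / xscale
  pos <- u > 0
  # pure linear through the origin, slope >= 0
  aLin <- max(0, sum(u * d) / sum(u * u))
  rmsLin <- sqrt(mean((aLin * u - d)^2))

  fitPar <- NULL
  rmsPar <- Inf
  a0 <- max(aLin, 1e-6)
  df <- data.frame(u = u, d = d)
  fitPar <- tryCatch(
    minpack.lm::nlsLM(d ~ a * u + b * u^c, data = df,
                      start = list(a = a0 / 2, b = a0 / 2, c = 1.5),
                      lower = c(0, 0, 1), upper = c(Inf, Inf, 8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fitPar))
    rmsPar <- sqrt(mean(stats::residuals(fitPar)^2))

  if (rmsLin <= rmsPar + 1e-12 * max(d)) {
    form <- "linear"
    coefs <- c(a = aLin, b = 0, c = 1)
    rms <- rmsLin
  } else {
    form <- "linear-power"
    coefs <- stats::coef(fitPar)
    names(coefs) <- c("a", "b", "c")
    rms <- rmsPar
  }

  ord <- order(x)
  knots <- data.frame(x = x[ord], dose = d[ord])
  if (rms > rmsThreshold) {
    # monotone piecewise-cubic fallback through isotonized sample means
    agg <- stats::aggregate(dose ~ x, data = knots, FUN = mean)
    iso <- stats::isoreg(agg$x, agg$dose)   # agg is sorted by x
    ky <- iso$yf
    kx <- agg$x
    if (kx[1] > 0) { kx <- c(0, kx); ky <- c(0, ky) }
    form <- "monotone-spline"
    coefs <- numeric()
    knots <- data.frame(x = kx, dose = ky)
    f <- stats::splinefun(kx, ky, method = "hyman")
    rms <- sqrt(mean((f(agg$x) - agg$dose)^2))
  }

  curve <- new("CalibrationCurve",
    mode = mode, form = form, coef = coefs, xscale = xscale,
    knots = knots, doseRange = c(0, max(d)), mpvRange = c(0, max(x)),
    fitRMS = rms, correction = corr[[mode]])
  assertMonotoneCurve(curve)
  curve
}

# internal raw evaluator (no range policy)
curveEval <- function(curve, x) {
  if (curve@form == "monotone-spline") {
    f <- stats::splinefun(curve@knots$x, curve@knots$dose, method = "hyman")
    out <- f(pmin(x, max(curve@knots$x)))
    # beyond the last knot hold the last value; range policy flags it anyway
    pmax(out, 0)
  } else {
    u <- x / curve@xscale
    co <- curve@coef
    co[["a"]] * u + co[["b"]] * u^co[["c"]]
  }
}

assertMonotoneCurve <- function(curve, n = 513) {
  g <- seq(curve@mpvRange[1], curve@mpvRange[2], length.out = n)
  v <- curveEval(curve, g)
  if (any(diff(v) < -1e-9 * max(abs(v), 1)))
    stop("fitted calibration curve is not monotone non-decreasing; ",
         "inspect the sample set")
  if (curveEval(curve, 0) > 1e-6 * max(v, 1) + 1e-9)
    stop("fitted calibration curve does not pass through the origin")
  invisible(TRUE)
}

#' @describeIn mpvToDose evaluate a fitted curve; out-of-range values are
#'   clamped to the range ceiling and flagged in the \code{"outOfRange"}
#'   attribute rather than extrapolated.
#' @export
setMethod("mpvToDose", "CalibrationCurve", function(curve, netMpv) {
  if (any(netMpv < 0)) stop("net MPV must be >= 0")
  d <- curveEval(curve, netMpv)
  oor <- d > curve@doseRange[2] + 1e-9 | netMpv > curve@mpvRange[2] + 1e-9
  d <- pmin(pmax(d, 0), curve@doseRange[2])
  attr(d, "outOfRange") <- oor
  d
})

# inverse of the curve on its calibrated range, by dense monotone
# interpolation of (dose, mpv); used by the synthetic film renderer
doseToMpv <- function(curve, dose) {
  if (any(dose < -1e-9) || any(dose > curve@doseRange[2] + 1e-9))
    stop("dose outside the calibrated range ",
         sprintf("[%.3g, %.3g] mGy", 0, curve@doseRange[2]))
  g <- seq(curve@mpvRange[1], curve@mpvRange[2], length.out = 8193)
  v <- curveEval(curve, g)
  keep <- c(TRUE, diff(v) > 0)           # strictify flats for approx()
  stats::approx(v[keep], g[keep], xout = pmax(dose, 0), rule = 2)$y
}

#' Write / read a fitted calibration curve as JSON
#'
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param path output JSON path.
#' @return \code{writeCalibrationCurve} returns \code{path} invisibly;
#'   \code{readCalibrationCurve} returns the curve.
#' @export
writeCalibrationCurve <- function(curve, path) {
  obj <- list(
    mode = curve@mode, form = curve@form,
    coef = as.list(curve@coef), xscale = curve@xscale,
    knots = curve@knots, dose_range = curve@doseRange,
    mpv_range = curve@mpvRange, fit_rms = curve@fitRMS,
    correction = curve@correction)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationCurve
#' @export
readCalibrationCurve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationCurve",
    mode = obj$mode, form = obj$form,
    coef = unlist(obj$coef) %||% numeric(), xscale = obj$xscale,
    knots = as.data.frame(obj$knots), doseRange = obj$dose_range,
    mpvRange = obj$mpv_range, fitRMS = obj$fit_rms,
    correction = obj$correction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noiseless demonstration calibration samples
#'
#' Generates an exact, monotone convex response spanning the full supported
#' dose range (0-160 mGy before correction) over net MPV 0-40000:
#' \code{dose = 160 (0.4 t + 0.6 t^2)}, \code{t = mpv / 40000}. Used by the
#' synthetic generator's default curve and in examples; not measured data.
#'
#' @param mode \code{"manual"} or \code{"abc"}.
#' @param n number of samples (>= 4).
#' @return data.frame of calibration samples.
#' @export
demoCalibrationSamples <- function(mode = c("abc", "manual"), n = 12) {
  mode <- match.arg(mode)
  x <- seq(0, 40000, length.out = n)
  t <- x / 40000
  data.frame(net_mpv = x,
             reference_dose_mGy = 160 * (0.4 * t + 0.6 * t^2),
             mode = mode)
}
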
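#' Evaluate a calibration curve at net MPV values
#'
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param netMpv numeric vector of net mean pixel values (>= 0).
#' @return numeric vector of absorbed dose in mGy, with a logical attribute
#'   \code{"outOfRange"} flagging values above the calibrated range (those
#'   are clamped to the range ceiling, never extrapolated).
#' @export
setGeneric("mpvToDose", function(curve, netMpv) standardGeneric("mpvToDose"))

#' Render synthetic film scans from true dose
#'
#' Inverts the calibration curve per pixel, adds the noise model's per-film
#' offset and per-pixel noise, and digitizes to a 16-bit RGB scan with the
#' signal on the red channel. Deterministic for a fixed noise seed.
#'
#' @param truth a \linkS4class{GroundTruth} (one scan per slice map) or a
#'   single \linkS4class{DoseMap} (one scan).
#' @param curve a \linkS4class{CalibrationCurve}; every true dose must lie
#'   inside its calibrated range.
#' @param noise a \linkS4class{NoiseModel}.
#' @param dpi optional output resolution; default renders on the dose grid
#'   itself (dpi = 25.4 / pixel spacing), nearest-neighbour resampled
#'   otherwise.
#' @return a named list of \linkS4class{FilmScan} (GroundTruth input) or a
#'   single \linkS4class{FilmScan} (DoseMap input).
#' @export
setGeneric("renderFilm", function(truth, curve, noise, dpi = NULL)
  standardGeneric("renderFilm"))

#' Calibrated dose range of a curve
#'
#' @param x a \linkS4class{CalibrationCurve}.
#' @return numeric(2), the calibrated (corrected) dose range in mGy.
#' @export
setGeneric("doseRange", function(x) standardGeneric("doseRange"))

#' @rdname doseRange
#' @export
setMethod("doseRange", "CalibrationCurve", function(x) x@doseRange)

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve [%s mode, %s form]\n  dose range: %.3g-%.3g mGy  correction: x%.2g  fit RMS: %.3g mGy\n",
    object@mode, object@form, object@doseRange[1], object@doseRange[2],
    object@correction, object@fitRMS))
})

setMethod("show", "FilmScan", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "FilmScan %d x %d px, %g dpi (%.4g mm/px), unexposed ref (R): %s\n",
    d[1], d[2], object@dpi, 25.4 / object@dpi,
    format(object@unexposedReference[1])))
})

setMethod("show", "DoseMap", function(object) {
  d <- dim(object@dose)
  cat(sprintf(
    "DoseMap %d x %d px @ %.4g mm/px, dose %.3g-%.3g mGy, %d px out of range\n",
    d[1], d[2], object@pixelSpacing, min(object@dose), max(object@dose),
    sum(object@outOfRange)))
})

setMethod("show", "OrganDoseResult", function(object) {
  cat(sprintf(
    "OrganDoseResult: left %.4g mGy, right %.4g mGy, overall %.4g mGy",
    object@dLeft, object@dRight, object@dOverall))
  if (is.finite(object@relativeUncertainty))
    cat(sprintf(" (+/- %.1f%%)", 100 * object@relativeUncertainty))
  cat("\n")
})

setMethod("show", "ProcedureDoseEstimate", function(object) {
  cat(sprintf(
    "ProcedureDoseEstimate: %d acquisitions, total DAP %.4g Gy.cm2\n  left %.4g mGy, right %.4g mGy, overall %.4g mGy (%d fallback match%s)\n",
    nrow(object@perAcquisition), object@totalDap, object@dLeft,
    object@dRight, object@dOverall, sum(object@perAcquisition$fallback_used),
    if (sum(object@perAcquisition$fallback_used) == 1) "" else "es"))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d slice maps, DAP %.4g Gy.cm2\n  true doses: left %.4g, right %.4g, overall %.4g mGy\n",
    length(object@maps), object@dap, object@dLeft, object@dRight,
    object@dOverall))
})

# --- simple accessors -------------------------------------------------------

#' Dose matrix of a DoseMap
#' @param x a \linkS4class{DoseMap}.
#' @return numeric matrix, mGy.
#' @export
doseMatrix <- function(x) {
  stopifnot(is(x, "DoseMap"))
  x@dose
}

#' Pixel spacing of a DoseMap (mm per pixel)
#' @param x a \linkS4class{DoseMap}.
#' @export
pixelSpacing <- function(x) {
  stopifnot(is(x, "DoseMap"))
  x@pixelSpacing
}

#' Out-of-range mask of a DoseMap
#' @param x a \linkS4class{DoseMap}.
#' @return logical matrix.
#' @export
outOfRangeMask <- function(x) {
  stopifnot(is(x, "DoseMap"))
  x@outOfRange
}

#' Organ-dose accessors
#'
#' Extract the per-side and overall doses from an
#' \linkS4class{OrganDoseResult} or \linkS4class{ProcedureDoseEstimate}.
#' @param x the result object.
#' @return dose in mGy.
#' @export
doseLeft <- function(x) x@dLeft

#' @rdname doseLeft
#' @export
doseRight <- function(x) x@dRight

#' @rdname doseLeft
#' @export
doseOverall <- function(x) x@dOverall
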
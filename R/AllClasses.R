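#' @import methods
NULL

#' CalibrationCurve: monotone net-MPV to absorbed-dose mapping
#'
#' Represents a fitted calibration curve converting net mean pixel value
#' (unexposed reference minus exposed reflectance value) to absorbed dose in
#' mGy for one acquisition mode. The solid-state to ionization-chamber
#' detector correction is incorporated into the curve at fit time (reference
#' doses are multiplied by the mode's factor before fitting), never at
#' evaluation time.
#'
#' @slot mode acquisition mode, \code{"manual"} or \code{"abc"}.
#' @slot form functional form actually used: \code{"linear"} (dose = a x),
#'   \code{"linear-power"} (dose = a x + b x^c, a,b >= 0, c >= 1) or
#'   \code{"monotone-spline"} (monotone piecewise-cubic fallback).
#' @slot coef named numeric coefficients (a, b, c) on the scaled abscissa
#'   x/xscale; empty for the spline form.
#' @slot xscale abscissa scale used during fitting (max net MPV).
#' @slot knots data.frame of (x, dose) knots; used by the spline form and
#'   kept for all forms as the fitted sample support.
#' @slot doseRange numeric(2), calibrated dose range in mGy (after
#'   correction). Evaluations above the range are flagged, not extrapolated.
#' @slot mpvRange numeric(2), net-MPV support of the fit.
#' @slot fitRMS root-mean-square residual of the fit, mGy.
#' @slot correction detector correction factor folded into the curve.
#' @export
setClass("CalibrationCurve",
  representation(
    mode = "character",
    form = "character",
    coef = "numeric",
    xscale = "numeric",
    knots = "data.frame",
    doseRange = "numeric",
    mpvRange = "numeric",
    fitRMS = "numeric",
    correction = "numeric"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (!object@mode %in% c("manual", "abc"))
    msg <- c(msg, "mode must be 'manual' or 'abc'")
  if (!object@form %in% c("linear", "linear-power", "monotone-spline"))
    msg <- c(msg, "unknown curve form")
  if (length(object@doseRange) != 2 || diff(object@doseRange) <= 0)
    msg <- c(msg, "doseRange must be an increasing pair")
  if (length(object@mpvRange) != 2 || diff(object@mpvRange) <= 0)
    msg <- c(msg, "mpvRange must be an increasing pair")
  if (object@xscale <= 0) msg <- c(msg, "xscale must be positive")
  if (object@correction < 1) msg <- c(msg, "correction factor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' FilmScan: a digitized radiochromic film
#'
#' Holds the pixel data of one scanned film (RGB, 16 bits per channel as
#' integers in [0, 65535]), the scan resolution and the mean channel values
#' of an unexposed reference patch used to form net MPV.
#'
#' @slot pixels numeric array \code{[rows, cols, 3]} of integer reflectance
#'   values in [0, 65535].
#' @slot dpi scan resolution, dots per inch.
#' @slot unexposedReference numeric(3) per-channel mean value of an
#'   unexposed patch; \code{NA} when not yet measured.
#' @export
setClass("FilmScan",
  representation(
    pixels = "array",
    dpi = "numeric",
    unexposedReference = "numeric"
  )
)

setValidity("FilmScan", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3)
    msg <- c(msg, "pixels must be a rows x cols x 3 array")
  else if (d[1] < 1 || d[2] < 1) msg <- c(msg, "pixel grid is empty")
  if (!is.na(object@dpi) && object@dpi <= 0) msg <- c(msg, "dpi must be > 0")
  rng <- suppressWarnings(range(object@pixels))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 65535))
    msg <- c(msg, "pixel values must lie in [0, 65535]")
  if (length(object@unexposedReference) != 3)
    msg <- c(msg, "unexposedReference must have one value per channel")
  if (length(msg)) msg else TRUE
})

#' DoseMap: a 2D absorbed-dose distribution
#'
#' @slot dose numeric matrix of absorbed dose, mGy.
#' @slot pixelSpacing physical pixel pitch, mm (25.4 / dpi).
#' @slot outOfRange logical matrix flagging pixels whose net MPV fell above
#'   the calibrated range (dose there is the range endpoint, not an
#'   extrapolation).
#' @export
setClass("DoseMap",
  representation(
    dose = "matrix",
    pixelSpacing = "numeric",
    outOfRange = "matrix"
  )
)

setValidity("DoseMap", function(object) {
  msg <- character()
  if (object@pixelSpacing <= 0) msg <- c(msg, "pixelSpacing must be > 0")
  if (any(object@dose < 0, na.rm = TRUE)) msg <- c(msg, "dose must be >= 0")
  if (!identical(dim(object@dose), dim(object@outOfRange)))
    msg <- c(msg, "outOfRange mask must match the dose grid")
  if (length(msg)) msg else TRUE
})

#' CircularROI: circular extraction mask in physical units
#'
#' Coordinates are millimetres from the top-left corner of the image,
#' x rightward (columns), y downward (rows).
#'
#' @slot center numeric(2), (x, y) of the circle center in mm.
#' @slot radius circle radius in mm.
#' @export
setClass("CircularROI",
  representation(center = "numeric", radius = "numeric")
)

setValidity("CircularROI", function(object) {
  msg <- character()
  if (length(object@center) != 2 || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a finite (x, y) pair")
  if (!is.finite(object@radius) || object@radius <= 0)
    msg <- c(msg, "radius must be > 0")
  if (length(msg)) msg else TRUE
})

#' OrganDoseResult: per-breast and overall organ dose
#'
#' @slot dLeft left-breast mass-weighted mean dose, mGy.
#' @slot dRight right-breast mass-weighted mean dose, mGy.
#' @slot dOverall overall breast dose (mass-weighted over both sides), mGy.
#' @slot relativeUncertainty relative (fractional) uncertainty of the
#'   overall dose, combining per-slice read noise and calibration RMS in
#'   quadrature; \code{NA} when no uncertainty inputs were supplied.
#' @export
setClass("OrganDoseResult",
  representation(
    dLeft = "numeric",
    dRight = "numeric",
    dOverall = "numeric",
    relativeUncertainty = "numeric"
  )
)

setValidity("OrganDoseResult", function(object) {
  msg <- character()
  d <- c(object@dLeft, object@dRight, object@dOverall)
  if (any(d < 0)) msg <- c(msg, "doses must be >= 0")
  lo <- min(object@dLeft, object@dRight) - 1e-9
  hi <- max(object@dLeft, object@dRight) + 1e-9
  if (object@dOverall < lo || object@dOverall > hi)
    msg <- c(msg, "overall dose must lie between the per-side doses")
  if (length(msg)) msg else TRUE
})

#' ProcedureDoseEstimate: breast dose reconstructed from an acquisition log
#'
#' @slot perAcquisition data.frame with one row per acquisition: label,
#'   matched factor-table row index, fallback flag and the per-breast dose
#'   contributions (DAP times factor) in mGy.
#' @slot dLeft,dRight,dOverall summed dose estimates, mGy.
#' @slot totalDap sum of the per-acquisition DAP values, Gy.cm2.
#' @export
setClass("ProcedureDoseEstimate",
  representation(
    perAcquisition = "data.frame",
    dLeft = "numeric",
    dRight = "numeric",
    dOverall = "numeric",
    totalDap = "numeric"
  )
)

setValidity("ProcedureDoseEstimate", function(object) {
  msg <- character()
  pa <- object@perAcquisition
  need <- c("label", "dose_left", "dose_right", "dose_overall",
            "fallback_used")
  if (!all(need %in% names(pa)))
    msg <- c(msg, "perAcquisition lacks required columns")
  else {
    if (abs(sum(pa$dose_overall) - object@dOverall) > 1e-8 *
        max(1, object@dOverall))
      msg <- c(msg, "totals must equal the sum of contributions")
  }
  if (object@totalDap < 0) msg <- c(msg, "totalDap must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomGeometry: breast-slab phantom for the synthetic generator
#'
#' The phantom mirrors a sliced anthropomorphic torso with three stacked
#' breast slabs per side. Slice index 1 is chest-proximal; slice plane i
#' sits at depth (i - 1) * sliceThickness downstream (anteriorly) of the
#' chest-entry plane.
#'
#' @slot slices data.frame with columns side, index, mass_kg, length_cm,
#'   width_cm, height_cm (one row per slab).
#' @slot sliceThickness slab thickness, cm (default 2.5).
#' @slot breastGap lateral gap between the two inner slab edges, cm.
#' @slot torsoWaterEquivalent water-equivalent material upstream of the
#'   chest-entry plane, cm (attenuates every slice equally).
#' @slot lateralHeartOffset beam-axis aim point offset from the midline,
#'   cm, signed toward the patient's left.
#' @export
setClass("PhantomGeometry",
  representation(
    slices = "data.frame",
    sliceThickness = "numeric",
    breastGap = "numeric",
    torsoWaterEquivalent = "numeric",
    lateralHeartOffset = "numeric"
  )
)

setValidity("PhantomGeometry", function(object) {
  msg <- character()
  s <- object@slices
  need <- c("side", "index", "mass_kg", "length_cm", "width_cm", "height_cm")
  if (!all(need %in% names(s)))
    msg <- c(msg, "slices must carry side,index,mass_kg,length_cm,width_cm,height_cm")
  else {
    if (any(s$mass_kg <= 0)) msg <- c(msg, "slice masses must be > 0")
    for (sd in unique(s$side))
      if (anyDuplicated(s$index[s$side == sd]))
        msg <- c(msg, "slice index must be unique per side")
  }
  if (object@sliceThickness <= 0) msg <- c(msg, "sliceThickness must be > 0")
  if (object@torsoWaterEquivalent < 0)
    msg <- c(msg, "torsoWaterEquivalent must be >= 0")
  if (length(msg)) msg else TRUE
})

#' BeamConfig: one projection of the simulated X-ray beam
#'
#' @slot angulation numeric(2) \code{c(lateral, axial)} in degrees; positive
#'   lateral = LAO (toward patient left), negative = RAO; positive axial =
#'   CRA (cranial), negative = CAU.
#' @slot fov square field side at the isocenter, cm.
#' @slot sid source-to-image-receptor distance, cm (carried, not modelled).
#' @slot entryDose dose per exposure on the beam axis at the chest-entry
#'   plane, mGy.
#' @slot muEff effective attenuation coefficient, per cm.
#' @export
setClass("BeamConfig",
  representation(
    angulation = "numeric",
    fov = "numeric",
    sid = "numeric",
    entryDose = "numeric",
    muEff = "numeric"
  )
)

setValidity("BeamConfig", function(object) {
  msg <- character()
  if (length(object@angulation) != 2 || any(abs(object@angulation) > 90))
    msg <- c(msg, "angulation must be (lateral, axial) with |angle| <= 90")
  if (object@fov <= 0) msg <- c(msg, "fov must be > 0")
  if (object@entryDose < 0) msg <- c(msg, "entryDose must be >= 0")
  if (object@muEff < 0) msg <- c(msg, "muEff must be >= 0")
  if (length(msg)) msg else TRUE
})

#' NoiseModel: digitization noise for synthetic film rendering
#'
#' Two components act in net-MPV units: an iid per-pixel term (scanner and
#' film graininess) and a per-film correlated offset (film-to-film
#' sensitivity variation), the latter being what limits ROI-mean accuracy.
#'
#' @slot sigmaPixel SD of the additive iid per-pixel noise, MPV units.
#' @slot sigmaFilm SD of the per-film correlated offset, MPV units.
#' @slot seed integer seed driving all draws.
#' @export
setClass("NoiseModel",
  representation(
    sigmaPixel = "numeric",
    sigmaFilm = "numeric",
    seed = "numeric"
  )
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@sigmaPixel < 0 || object@sigmaFilm < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: synthetic exposure with known answers
#'
#' @slot maps named list of \linkS4class{DoseMap}, keyed "side_index".
#' @slot sliceDoses data.frame side,index,dose_mgy of true per-slice ROI
#'   mean doses (inscribed-circle mask).
#' @slot dLeft,dRight,dOverall true organ doses, mGy, computed with the
#'   organ-dose aggregator from the true slice doses.
#' @slot dap total dose-area product of the simulated exposure, Gy.cm2.
#' @export
setClass("GroundTruth",
  representation(
    maps = "list",
    sliceDoses = "data.frame",
    dLeft = "numeric",
    dRight = "numeric",
    dOverall = "numeric",
    dap = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(vapply(object@maps, function(m) is(m, "DoseMap"), logical(1))))
    msg <- c(msg, "maps must all be DoseMap objects")
  if (object@dap < 0) msg <- c(msg, "dap must be >= 0")
  if (length(msg)) msg else TRUE
})
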
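#' Construct the default breast-slab phantom geometry
#'
#' Uses the packaged slice table (see [randoBreastSlices()]). Each side's
#' slab stack is centered laterally at \code{+/-(gap/2 + length/2)} from
#' the midline (positive toward the patient's left) and vertically on the
#' beam plane; the slab footprint is the ellipse inscribed in length x
#' width.
#'
#' @param slices slice table (side, index, mass_kg, length_cm, width_cm,
#'   height_cm).
#' @param sliceThickness slab thickness, cm.
#' @param breastGap lateral gap between the inner slab edges, cm.
#' @param torsoWaterEquivalent water-equivalent attenuator upstream of the
#'   chest-entry plane, cm.
#' @param lateralHeartOffset beam aim-point offset from the midline, cm,
#'   signed toward the patient's left.
#' @return a \linkS4class{PhantomGeometry}.
#' @export
defaultPhantom <- function(slices = randoBreastSlices(),
                           sliceThickness = 2.5, breastGap = 1,
                           torsoWaterEquivalent = 0,
                           lateralHeartOffset = 0) {
  new("PhantomGeometry", slices = slices, sliceThickness = sliceThickness,
      breastGap = breastGap, torsoWaterEquivalent = torsoWaterEquivalent,
      lateralHeartOffset = lateralHeartOffset)
}

#' Construct a beam configuration
#'
#' @param angulation numeric \code{c(lateral, axial)} degrees or a label
#'   accepted by [parseAngulation()].
#' @param fov square field side, cm.
#' @param sid source-to-image-receptor distance, cm.
#' @param entryDose beam-axis dose per exposure at the chest-entry plane,
#'   mGy.
#' @param muEff effective attenuation coefficient, per cm (default 0.2, a
#'   soft-tissue-like magnitude).
#' @return a \linkS4class{BeamConfig}.
#' @export
beamConfig <- function(angulation = c(0, 0), fov = 15, sid = 100,
                       entryDose = 10, muEff = 0.2) {
  if (is.character(angulation)) angulation <- parseAngulation(angulation)
  new("BeamConfig", angulation = as.numeric(angulation), fov = fov,
      sid = sid, entryDose = entryDose, muEff = muEff)
}

#' Construct a noise model
#'
#' @param sigmaPixel iid per-pixel noise SD, net-MPV units.
#' @param sigmaFilm per-film correlated offset SD, net-MPV units.
#' @param seed integer seed.
#' @return a \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(sigmaPixel = 100, sigmaFilm = 0, seed = 1) {
  new("NoiseModel", sigmaPixel = sigmaPixel, sigmaFilm = sigmaFilm,
      seed = seed)
}

#' Default noise model calibrated to the film's readability limit
#'
#' The per-film offset SD is solved (deterministically, by equal-probability
#' quadrature over the normal offset) so that an ROI read at
#' \code{atDose} mGy carries \code{targetRel} relative dose uncertainty --
#' the readability limit of this film class (about 15\% at 10 mGy).
#'
#' @param curve the \linkS4class{CalibrationCurve} the films will be read
#'   with.
#' @param targetRel target relative SD at \code{atDose} (default 0.15).
#' @param atDose anchoring dose, mGy (default 10).
#' @param sigmaPixel iid per-pixel noise SD, net-MPV units.
#' @param seed integer seed.
#' @return a \linkS4class{NoiseModel}.
#' @export
defaultNoiseModel <- function(curve, targetRel = 0.15, atDose = 10,
                              sigmaPixel = 100, seed = 1) {
  stopifnot(is(curve, "CalibrationCurve"))
  x0 <- doseToMpv(curve, atDose)
  z <- stats::qnorm(stats::ppoints(801))
  sdAt <- function(s) {
    d <- curveEval(curve, pmax(x0 + s * z, 0))
    sqrt(mean((d - mean(d))^2))
  }
  target <- targetRel * atDose
  hi <- curve@mpvRange[2] / 2
  if (sdAt(hi) < target)
    stop("cannot reach the target uncertainty within the curve support")
  s <- stats::uniroot(function(s) sdAt(s) - target, c(1e-6, hi),
                      tol = 1e-8)$root
  noiseModel(sigmaPixel = sigmaPixel, sigmaFilm = s, seed = seed)
}

# slice lookup + derived geometry (all internal, mm units)
sliceSpec <- function(phantom, side, index) {
  s <- phantom@slices
  r <- s[s$side == side & s$index == index, , drop = FALSE]
  if (nrow(r) != 1)
    stop("no slice '", side, "' #", index, " in the phantom")
  r
}

sliceDepthCm <- function(phantom, index) (index - 1) * phantom@sliceThickness

sliceCenterXmm <- function(phantom, spec) {
  sgn <- if (spec$side == "left") 1 else -1
  sgn * (phantom@breastGap / 2 + spec$length_cm / 2) * 10
}

# pixel-center coordinate grids over a slice bounding box (mm, slice frame:
# origin at slab center, x toward patient left, y cranial)
sliceGrid <- function(spec, spacingMm) {
  Lmm <- spec$length_cm * 10
  Wmm <- spec$width_cm * 10
  nx <- max(1L, ceiling(Lmm / spacingMm))
  ny <- max(1L, ceiling(Wmm / spacingMm))
  list(
    x = (seq_len(nx) - 0.5) * spacingMm - Lmm / 2,
    y = (seq_len(ny) - 0.5) * spacingMm - Wmm / 2,
    nx = nx, ny = ny, Lmm = Lmm, Wmm = Wmm)
}

sliceEllipseMask <- function(grid) {
  # rows = y (image rows), cols = x
  outer((grid$y / (grid$Wmm / 2))^2, (grid$x / (grid$Lmm / 2))^2, `+`) <= 1
}

#' Project the beam footprint onto one slice plane
#'
#' The square field (side = FOV) pivots about the chest-entry plane: on
#' slice plane i at depth d the beam axis is laterally displaced by
#' \code{d tan(lateral)} (and vertically by \code{d tan(axial)}) from its
#' chest-plane position, which itself sits at the midline plus the lateral
#' heart offset. The footprint is clipped to the slab's inscribed ellipse
#' and may be empty for steep angles.
#'
#' @param beam a \linkS4class{BeamConfig} (|angles| < 90).
#' @param phantom a \linkS4class{PhantomGeometry}.
#' @param side \code{"left"} or \code{"right"}.
#' @param index slice index (1 = chest-proximal).
#' @param spacingMm grid pitch of the returned mask, mm.
#' @return list with \code{mask} (logical matrix over the slice bounding
#'   box, rows = width direction), \code{inSlice} (the ellipse mask),
#'   \code{axisOffset} (lateral beam-axis displacement \code{d tan(lat)} on
#'   this plane, mm), \code{empty} flag and the grid geometry.
#' @export
projectFootprint <- function(beam, phantom, side = c("left", "right"),
                             index = 1, spacingMm = 1) {
  side <- match.arg(side)
  stopifnot(is(beam, "BeamConfig"), is(phantom, "PhantomGeometry"))
  lat <- beam@angulation[1]; ax <- beam@angulation[2]
  if (abs(lat) >= 90 || abs(ax) >= 90)
    stop("|angulation| must be < 90 degrees for a defined footprint")
  spec <- sliceSpec(phantom, side, index)
  g <- sliceGrid(spec, spacingMm)
  depthMm <- sliceDepthCm(phantom, index) * 10
  axisOffset <- depthMm * tan(lat * pi / 180)
  axisX <- phantom@lateralHeartOffset * 10 + axisOffset   # global mm
  axisY <- depthMm * tan(ax * pi / 180)
  half <- beam@fov * 10 / 2
  # slice-frame coordinates of the grid relative to the beam axis
  gx <- g$x + sliceCenterXmm(phantom, spec)                # global x
  inRect <- outer(abs(g$y - axisY) <= half, abs(gx - axisX) <= half, `&`)
  inSlice <- sliceEllipseMask(g)
  mask <- inRect & inSlice
  list(mask = mask, inSlice = inSlice, axisOffset = axisOffset,
       empty = !any(mask), grid = g, spacingMm = spacingMm)
}

# default extraction ROI of a slice map: the inscribed circle, which is
# guaranteed to stay inside the slab ellipse
sliceROIFor <- function(spec) {
  Lmm <- spec$length_cm * 10; Wmm <- spec$width_cm * 10
  circularROI(Lmm / 2, Wmm / 2, min(Lmm, Wmm) / 2)
}

#' Default circular extraction ROI for a slice
#'
#' Centered on the slab with radius \code{min(length, width) / 2} (the
#' inscribed circle), so the mask never leaves the slab footprint.
#'
#' @param slices slice table.
#' @param side,index slice identity.
#' @return a \linkS4class{CircularROI} in the slice map's mm frame.
#' @export
sliceROI <- function(slices = randoBreastSlices(),
                     side = c("left", "right"), index = 1) {
  side <- match.arg(side)
  r <- slices[slices$side == side & slices$index == index, , drop = FALSE]
  if (nrow(r) != 1) stop("no slice '", side, "' #", index)
  sliceROIFor(r)
}

#' Simulate film exposures over the phantom
#'
#' Minimal analytic transport: inside each beam's footprint the dose is
#' \code{entryDose * exp(-muEff * path)} per exposure with
#' \code{path = torsoWaterEquivalent + depth / (cos(lat) cos(ax))}; outside
#' footprints a uniform scatter floor (a fraction of that beam's slice-1
#' in-beam dose) is added. True per-slice doses are the inscribed-circle
#' ROI means; organ doses are computed from them with the organ-dose
#' aggregator, so ground truth is self-consistent by construction.
#'
#' @param phantom a \linkS4class{PhantomGeometry}.
#' @param beams list of \code{list(beam = BeamConfig, n = exposures)}.
#' @param dapPerExposure DAP per exposure, Gy.cm2 (recycled over beams).
#' @param spacingMm dose-grid pitch, mm.
#' @param scatterFraction scatter floor as a fraction of the in-beam
#'   slice-1 dose (default 0.05).
#' @return a \linkS4class{GroundTruth}.
#' @export
simulateExposure <- function(phantom, beams, dapPerExposure = 1,
                             spacingMm = 1, scatterFraction = 0.05) {
  stopifnot(is(phantom, "PhantomGeometry"), length(beams) >= 1)
  dapPer <- rep_len(dapPerExposure, length(beams))
  maps <- list()
  sliceRows <- list()
  for (side in c("left", "right")) {
    idx <- sort(phantom@slices$index[phantom@slices$side == side])
    for (i in idx) {
      spec <- sliceSpec(phantom, side, i)
      g <- sliceGrid(spec, spacingMm)
      dose <- matrix(0, nrow = g$ny, ncol = g$nx)
      for (b in beams) {
        beam <- b$beam; n <- b$n
        fp <- projectFootprint(beam, phantom, side, i, spacingMm)
        lat <- beam@angulation[1] * pi / 180
        ax <- beam@angulation[2] * pi / 180
        path <- phantom@torsoWaterEquivalent +
          sliceDepthCm(phantom, i) / (cos(lat) * cos(ax))
        primary <- beam@entryDose * exp(-beam@muEff * path)
        scatter <- scatterFraction * beam@entryDose *
          exp(-beam@muEff * phantom@torsoWaterEquivalent)
        dose <- dose + n * (primary * fp$mask + scatter * !fp$mask)
      }
      key <- paste0(side, "_", i)
      maps[[key]] <- new("DoseMap", dose = dose, pixelSpacing = spacingMm,
                         outOfRange = matrix(FALSE, g$ny, g$nx))
      roi <- sliceROIFor(spec)
      m <- roiMeanDose(maps[[key]], roi)
      sliceRows[[key]] <- data.frame(side = side, index = i,
                                     dose_mgy = m$mean,
                                     stringsAsFactors = FALSE)
    }
  }
  sliceDoses <- do.call(rbind, sliceRows)
  rownames(sliceDoses) <- NULL
  od <- organDose(sliceDoses, phantom@slices)
  dap <- sum(vapply(beams, function(b) b$n, numeric(1)) * dapPer)
  new("GroundTruth", maps = maps, sliceDoses = sliceDoses,
      dLeft = od@dLeft, dRight = od@dRight, dOverall = od@dOverall,
      dap = dap)
}

# nearest-neighbour resample of a matrix to a new spacing
resampleNN <- function(m, fromSpacing, toSpacing) {
  if (abs(fromSpacing - toSpacing) < 1e-12) return(m)
  nr <- max(1L, round(nrow(m) * fromSpacing / toSpacing))
  nc <- max(1L, round(ncol(m) * fromSpacing / toSpacing))
  ri <- pmin(nrow(m), pmax(1L, ceiling(((seq_len(nr) - 0.5) * toSpacing) /
                                         fromSpacing)))
  ci <- pmin(ncol(m), pmax(1L, ceiling(((seq_len(nc) - 0.5) * toSpacing) /
                                         fromSpacing)))
  m[ri, ci, drop = FALSE]
}

renderOneScan <- function(map, curve, noise, dpi, unexposed = 45000) {
  oor <- map@dose > curve@doseRange[2] + 1e-9
  if (any(oor))
    stop(sum(oor), " pixels exceed the calibrated dose range (",
         sprintf("max %.3g > %.3g mGy", max(map@dose), curve@doseRange[2]),
         "); reduce the exposure or extend the calibration")
  spacing <- if (is.null(dpi)) map@pixelSpacing else 25.4 / dpi
  dose <- resampleNN(map@dose, map@pixelSpacing, spacing)
  # invert the curve on the unique dose levels only (maps are piecewise
  # constant, so this is cheap and exact)
  ud <- unique(as.numeric(dose))
  ux <- doseToMpv(curve, ud)
  x <- matrix(ux[match(as.numeric(dose), ud)], nrow = nrow(dose))
  filmOffset <- stats::rnorm(1, 0, noise@sigmaFilm)
  eps <- matrix(stats::rnorm(length(x), 0, noise@sigmaPixel),
                nrow = nrow(x))
  red <- round(unexposed - (x + filmOffset + eps))
  gb <- round(unexposed + matrix(stats::rnorm(length(x), 0,
                                              noise@sigmaPixel),
                                 nrow = nrow(x)))
  clamp <- function(v) pmin(pmax(v, 0), 65535)
  px <- array(0, dim = c(nrow(x), ncol(x), 3))
  px[, , 1] <- clamp(red)
  px[, , 2] <- clamp(gb)
  px[, , 3] <- clamp(gb)
  new("FilmScan", pixels = px, dpi = 25.4 / spacing,
      unexposedReference = rep(unexposed, 3))
}

#' @describeIn renderFilm render every slice map of a ground truth; the
#'   per-film offsets are drawn independently per scan.
#' @export
setMethod("renderFilm", "GroundTruth", function(truth, curve, noise,
                                                dpi = NULL) {
  withSeed(noise@seed, {
    scans <- lapply(truth@maps, renderOneScan, curve = curve,
                    noise = noise, dpi = dpi)
  })
  scans
})

#' @describeIn renderFilm render a single dose map into one scan.
#' @export
setMethod("renderFilm", "DoseMap", function(truth, curve, noise,
                                            dpi = NULL) {
  withSeed(noise@seed,
           renderOneScan(truth, curve = curve, noise = noise, dpi = dpi))
})

# run expr under a local, seeded RNG stream without touching global state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a complete synthetic mock procedure
#'
#' Emits a nine-acquisition log shaped like the packaged mock-procedure
#' table (same angulation labels, SIDs, tube factors and FOVs -- eight
#' acquisitions at 15 cm and the LV view at 23 cm) with DAP values drawn
#' uniformly within +/-30\% of the recorded ones, together with the
#' simulated ground truth and rendered film scans. Fully reproducible for
#' a fixed seed.
#'
#' @param seed integer seed for all randomness (DAP draws and film noise).
#' @param curve calibration curve used to digitize the films; default is
#'   the fit to [demoCalibrationSamples()] in ABC mode.
#' @param phantom phantom geometry; default uses a +1.5 cm leftward heart
#'   offset, emulating the leftward beam bias of a clinical operator using
#'   the floating table.
#' @param noise noise model; default [defaultNoiseModel()] for the curve.
#' @param spacingMm simulation grid pitch, mm.
#' @param entryDosePerDap beam-axis entry dose per unit DAP, mGy per
#'   Gy.cm2 (scales the exposure into the film's readable range).
#' @param muEff effective attenuation coefficient, per cm.
#' @param scatterFraction scatter floor fraction.
#' @param dpi optional scan resolution (default: the simulation grid).
#' @return list with \code{log} (acquisition data.frame), \code{truth}
#'   (\linkS4class{GroundTruth}) and \code{scans} (list of
#'   \linkS4class{FilmScan}).
#' @export
generateMockProcedure <- function(seed = 1, curve = NULL, phantom = NULL,
                                  noise = NULL, spacingMm = 1,
                                  entryDosePerDap = 8, muEff = 0.2,
                                  scatterFraction = 0.05, dpi = NULL) {
  if (is.null(curve))
    curve <- fitCalibration(demoCalibrationSamples("abc"), "abc")
  if (is.null(phantom))
    phantom <- defaultPhantom(lateralHeartOffset = 1.5)
  if (is.null(noise))
    noise <- defaultNoiseModel(curve, seed = seed)
  noise@seed <- seed

  log <- mockProcedureLog()
  log$dap_gycm2 <- withSeed(seed,
    log$dap_gycm2 * stats::runif(nrow(log), 0.7, 1.3))
  beams <- lapply(seq_len(nrow(log)), function(i) {
    list(beam = beamConfig(
           angulation = c(log$lateral_deg[i], log$axial_deg[i]),
           fov = log$fov_cm[i], sid = log$sid_cm[i],
           entryDose = entryDosePerDap * log$dap_gycm2[i],
           muEff = muEff),
         n = 1)
  })
  truth <- simulateExposure(phantom, beams,
                            dapPerExposure = log$dap_gycm2,
                            spacingMm = spacingMm,
                            scatterFraction = scatterFraction)
  scans <- renderFilm(truth, curve, noise, dpi = dpi)
  list(log = log, truth = truth, scans = scans)
}

#' Recover organ doses from rendered scans
#'
#' Runs the measurement pipeline (scan to dose map, inscribed-circle ROI
#' mean per slice, mass-weighted aggregation) on a set of slice scans, the
#' same way physical films would be processed.
#'
#' @param scans named list of \linkS4class{FilmScan} keyed "side_index".
#' @param curve the calibration curve.
#' @param slices slice table matching the phantom.
#' @param channel scan channel to read.
#' @return an \linkS4class{OrganDoseResult}.
#' @export
recoverOrganDose <- function(scans, curve, slices = randoBreastSlices(),
                             channel = "red") {
  rows <- lapply(names(scans), function(key) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    side <- parts[1]; index <- as.integer(parts[2])
    dm <- scanToDoseMap(scans[[key]], curve, channel = channel)
    m <- roiMeanDose(dm, sliceROI(slices, side, index))
    data.frame(side = side, index = index, dose_mgy = m$mean,
               se_mgy = m$sd / sqrt(m$n), stringsAsFactors = FALSE)
  })
  organDose(do.call(rbind, rows), slices, calibrationRMS = curve@fitRMS)
}
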
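# shared fixtures, all generated in code

# samples lying exactly on dose = slope * net_mpv (no correction)
exactLinearSamples <- function(slope = 0.01, mode = "manual", n = 8) {
  x <- seq(0, 16000, length.out = n)
  data.frame(net_mpv = x, reference_dose_mGy = slope * x, mode = mode)
}

# samples from the convex power generator dose = a * x^b
powerSamples <- function(a = 2e-4, b = 1.5, mode = "manual", n = 8) {
  x <- seq(200, 8500, length.out = n)
  d <- a * x^b
  stopifnot(max(d) <= 160)
  data.frame(net_mpv = x, reference_dose_mGy = d, mode = mode)
}

unitCorrection <- function() detectorCorrection(manual = 1, abc = 1)

# a curve whose dose range comfortably covers [0, 320] mGy
demoCurve <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- fitCalibration(demoCalibrationSamples("abc"), "abc")
    cache
  }
})

# uniform-dose map
uniformDoseMap <- function(dose, nr = 50, nc = 50, spacing = 1) {
  new("DoseMap", dose = matrix(dose, nr, nc), pixelSpacing = spacing,
      outOfRange = matrix(FALSE, nr, nc))
}

# phantom with the left slice geometry mirrored onto the right side
symmetricPhantom <- function(...) {
  s <- randoBreastSlices()
  left <- s[s$side == "left", ]
  right <- left
  right$side <- "right"
  defaultPhantom(slices = rbind(left, right), ...)
}

# brute-force per-pixel circular ROI mean (independent oracle)
bruteRoiMean <- function(map, roi) {
  s <- pixelSpacing(map)
  d <- doseMatrix(map)
  tot <- 0; n <- 0L
  for (r in seq_len(nrow(d))) {
    for (c in seq_len(ncol(d))) {
      x <- (c - 0.5) * s; y <- (r - 0.5) * s
      if ((x - roi@center[1])^2 + (y - roi@center[2])^2 <= roi@radius^2) {
        tot <- tot + d[r, c]; n <- n + 1L
      }
    }
  }
  list(mean = tot / n, n = n)
}

# brute-force slice dose map for one beam: explicit loops re-deriving the
# footprint geometry (rectangle displaced by depth*tan, clipped to the
# inscribed ellipse) independently of the package's vectorized path
bruteSliceDose <- function(phantom, beam, side, index, spacingMm = 1,
                           scatterFraction = 0.05, n = 1) {
  sl <- phantom@slices
  spec <- sl[sl$side == side & sl$index == index, ]
  L <- spec$length_cm * 10; W <- spec$width_cm * 10
  nx <- ceiling(L / spacingMm); ny <- ceiling(W / spacingMm)
  lat <- beam@angulation[1] * pi / 180
  ax <- beam@angulation[2] * pi / 180
  depth <- (index - 1) * phantom@sliceThickness
  sgn <- if (side == "left") 1 else -1
  centerX <- sgn * (phantom@breastGap / 2 + spec$length_cm / 2) * 10
  axisX <- phantom@lateralHeartOffset * 10 + depth * 10 * tan(lat)
  axisY <- depth * 10 * tan(ax)
  half <- beam@fov * 10 / 2
  path <- phantom@torsoWaterEquivalent + depth / (cos(lat) * cos(ax))
  primary <- beam@entryDose * exp(-beam@muEff * path)
  scatter <- scatterFraction * beam@entryDose *
    exp(-beam@muEff * phantom@torsoWaterEquivalent)
  dose <- matrix(0, ny, nx)
  for (r in seq_len(ny)) {
    for (c in seq_len(nx)) {
      x <- (c - 0.5) * spacingMm - L / 2
      y <- (r - 0.5) * spacingMm - W / 2
      inEll <- (x / (L / 2))^2 + (y / (W / 2))^2 <= 1
      gx <- x + centerX
      inRect <- abs(gx - axisX) <= half && abs(y - axisY) <= half
      dose[r, c] <- n * if (inEll && inRect) primary else scatter
    }
  }
  dose
}

# write a uniform-value 16-bit RGB TIFF; returns the path
writeRgbTiff <- function(path, value = 30000, nr = 50, nc = 50) {
  px <- array(value / 65535, dim = c(nr, nc, 3))
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  path
}
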
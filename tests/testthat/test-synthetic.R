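test_that("beam footprint geometry follows the chest-plane pivot", {
  ph <- defaultPhantom()
  # PA beam, zero heart offset: no axis displacement on any plane
  pa <- beamConfig(c(0, 0), fov = 15)
  for (i in 1:3) {
    fp <- projectFootprint(pa, ph, "left", i)
    expect_equal(fp$axisOffset, 0)
    expect_false(fp$empty)
  }
  # 30 degrees lateral at 2.5 cm depth: offset = 25 tan(30) ~ 14.43 mm
  fp2 <- projectFootprint(beamConfig(c(30, 0)), ph, "left", 2)
  expect_equal(fp2$axisOffset, 25 * tan(30 * pi / 180), tolerance = 1e-9)
  expect_equal(fp2$axisOffset, 14.43376, tolerance = 1e-4)
  # steep lateral angle walks the field off a deep slice entirely
  fp3 <- projectFootprint(beamConfig(c(80, 0), fov = 15), ph, "left", 3)
  expect_true(fp3$empty)
  expect_equal(sum(fp3$mask), 0)
  expect_no_error(projectFootprint(beamConfig(c(89.9, 0)), ph, "left", 1))
  expect_error(beamConfig(c(95, 0)), "90")
})

test_that("a wide PA field covers exactly the inscribed ellipse", {
  ph <- defaultPhantom()
  fp <- projectFootprint(beamConfig(c(0, 0), fov = 100), ph, "right", 1)
  expect_identical(fp$mask, fp$inSlice)
  # ellipse area check: fraction of bounding box ~ pi/4
  expect_equal(mean(fp$inSlice), pi / 4, tolerance = 0.01)
})

test_that("depth attenuation follows the exponential closed form", {
  ph <- defaultPhantom()
  beams <- list(list(beam = beamConfig(c(0, 0), fov = 60, entryDose = 10,
                                       muEff = 0.2), n = 1))
  tr <- simulateExposure(ph, beams, dapPerExposure = 1,
                         scatterFraction = 0)
  d <- tr@sliceDoses
  l <- d$dose_mgy[d$side == "left"][order(d$index[d$side == "left"])]
  # depths 0 / 2.5 / 5 cm at mu = 0.2/cm: ratios 1 : e^-0.5 : e^-1
  expect_equal(l / l[1], c(1, exp(-0.5), exp(-1)), tolerance = 1e-9)
  expect_equal(l[1], 10, tolerance = 1e-9)
  # no attenuation, full coverage: every slice reads entryDose * n
  tr0 <- simulateExposure(ph, list(list(beam = beamConfig(c(0, 0), fov = 60,
                                                          entryDose = 10,
                                                          muEff = 0), n = 3)),
                          dapPerExposure = 1, scatterFraction = 0)
  expect_true(all(abs(tr0@sliceDoses$dose_mgy - 30) < 1e-9))
  expect_equal(tr0@dLeft, tr0@dRight, tolerance = 1e-12)
  expect_equal(tr0@dOverall, 30, tolerance = 1e-9)
})

test_that("slice doses are non-increasing in the attenuation coefficient", {
  ph <- defaultPhantom()
  prev <- NULL
  for (mu in c(0, 0.1, 0.2, 0.4)) {
    tr <- simulateExposure(ph, list(list(beam = beamConfig(c(20, -10),
                                                           fov = 15,
                                                           entryDose = 10,
                                                           muEff = mu),
                                         n = 1)), 1)
    cur <- tr@sliceDoses$dose_mgy
    if (!is.null(prev)) expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("mirroring the lateral angle and heart offset swaps the sides", {
  for (cfg in list(c(30, 0, 1.5), c(-25, -15, 2), c(10, 20, -1))) {
    phA <- symmetricPhantom(lateralHeartOffset = cfg[3])
    phB <- symmetricPhantom(lateralHeartOffset = -cfg[3])
    beamA <- list(list(beam = beamConfig(c(cfg[1], cfg[2]), fov = 15,
                                         entryDose = 10), n = 1))
    beamB <- list(list(beam = beamConfig(c(-cfg[1], cfg[2]), fov = 15,
                                         entryDose = 10), n = 1))
    trA <- simulateExposure(phA, beamA, 1)
    trB <- simulateExposure(phB, beamB, 1)
    expect_equal(trA@dLeft, trB@dRight, tolerance = 1e-12)
    expect_equal(trA@dRight, trB@dLeft, tolerance = 1e-12)
    expect_equal(trA@dOverall, trB@dOverall, tolerance = 1e-12)
  }
})

test_that("doubling exposures doubles doses and DAP, not the factors", {
  ph <- defaultPhantom(lateralHeartOffset = 1)
  mk <- function(n) simulateExposure(
    ph, list(list(beam = beamConfig(c(-20, 10), fov = 15, entryDose = 8),
                  n = n)), dapPerExposure = 1.3)
  t1 <- mk(1); t2 <- mk(2)
  expect_equal(t2@dap, 2 * t1@dap, tolerance = 1e-12)
  expect_equal(t2@sliceDoses$dose_mgy, 2 * t1@sliceDoses$dose_mgy,
               tolerance = 1e-12)
  expect_equal(t2@dOverall, 2 * t1@dOverall, tolerance = 1e-12)
  expect_equal(conversionFactor(t2@dOverall, t2@dap),
               conversionFactor(t1@dOverall, t1@dap), tolerance = 1e-12)
})

test_that("the simulator agrees with a brute-force pixel enumeration", {
  ph <- defaultPhantom(lateralHeartOffset = 1.5)
  beam <- beamConfig(c(-30, 12), fov = 15, entryDose = 10, muEff = 0.2)
  tr <- simulateExposure(ph, list(list(beam = beam, n = 2)), 1,
                         spacingMm = 2, scatterFraction = 0.05)
  for (key in c("left_1", "right_2", "left_3")) {
    parts <- strsplit(key, "_")[[1]]
    oracle <- bruteSliceDose(ph, beam, parts[1], as.integer(parts[2]),
                             spacingMm = 2, scatterFraction = 0.05, n = 2)
    expect_equal(doseMatrix(tr@maps[[key]]), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("noiseless rendering inverts the measurement chain", {
  cu <- demoCurve()
  ph <- defaultPhantom()
  tr <- simulateExposure(ph, list(list(beam = beamConfig(c(10, -5),
                                                         fov = 15,
                                                         entryDose = 40),
                                       n = 1)), 1.5)
  scans <- renderFilm(tr, cu, noiseModel(sigmaPixel = 0, sigmaFilm = 0,
                                         seed = 1))
  rec <- recoverOrganDose(scans, cu)
  expect_equal(doseLeft(rec), tr@dLeft, tolerance = 0.005)
  expect_equal(doseRight(rec), tr@dRight, tolerance = 0.005)
  expect_equal(doseOverall(rec), tr@dOverall, tolerance = 0.005)
  # per-slice, against the true slice means
  for (i in seq_len(nrow(tr@sliceDoses))) {
    row <- tr@sliceDoses[i, ]
    key <- paste0(row$side, "_", row$index)
    dm <- scanToDoseMap(scans[[key]], cu)
    m <- roiMeanDose(dm, sliceROI(side = row$side, index = row$index))
    expect_equal(m$mean, row$dose_mgy, tolerance = 0.005 * max(1, row$dose_mgy))
  }
})

test_that("a zero-dose map renders centered on the unexposed reference", {
  cu <- demoCurve()
  m <- uniformDoseMap(0, 40, 40)
  scan <- renderFilm(m, cu, noiseModel(sigmaPixel = 80, sigmaFilm = 0,
                                       seed = 4))
  expect_s4_class(scan, "FilmScan")
  expect_equal(mean(scan@pixels[, , 1]), 45000, tolerance = 5e-4 * 45000)
})

test_that("rendering refuses doses beyond the calibrated range", {
  cu <- demoCurve()
  m <- uniformDoseMap(doseRange(cu)[2] * 1.2, 10, 10)
  expect_error(renderFilm(m, cu, noiseModel(seed = 1)), "calibrated")
})

test_that("the mock procedure generator is reproducible and log-shaped", {
  a <- generateMockProcedure(seed = 12, spacingMm = 2)
  b <- generateMockProcedure(seed = 12, spacingMm = 2)
  expect_identical(a$log, b$log)
  expect_identical(lapply(a$scans, function(s) s@pixels),
                   lapply(b$scans, function(s) s@pixels))
  c <- generateMockProcedure(seed = 13, spacingMm = 2)
  expect_false(identical(a$log$dap_gycm2, c$log$dap_gycm2))
  # shape: nine acquisitions, eight at 15 cm FOV, one at 23 cm
  expect_equal(nrow(a$log), 9)
  expect_equal(sum(a$log$fov_cm == 15), 8)
  expect_equal(sum(a$log$fov_cm == 23), 1)
  # DAP draws stay within +/-30% of the recorded log
  ref <- mockProcedureLog()$dap_gycm2
  expect_true(all(a$log$dap_gycm2 >= 0.7 * ref - 1e-12))
  expect_true(all(a$log$dap_gycm2 <= 1.3 * ref + 1e-12))
  expect_equal(a$truth@dap, sum(a$log$dap_gycm2), tolerance = 1e-12)
})

test_that("pipeline recovery of the mock procedure stays within 10%", {
  cu <- fitCalibration(demoCalibrationSamples("abc"), "abc")
  for (seed in c(2, 27)) {
    sim <- generateMockProcedure(seed = seed, spacingMm = 2)
    rec <- recoverOrganDose(sim$scans, cu)
    expect_lt(abs(doseOverall(rec) / sim$truth@dOverall - 1), 0.10)
  }
})

test_that("ground truth is self-consistent with the organ-dose module", {
  sim <- generateMockProcedure(seed = 5, spacingMm = 2)
  d <- sim$truth@sliceDoses
  l <- d$dose_mgy[d$side == "left"][order(d$index[d$side == "left"])]
  r <- d$dose_mgy[d$side == "right"][order(d$index[d$side == "right"])]
  expect_equal(sim$truth@dLeft, breastDoseSide(l, side = "left"),
               tolerance = 1e-12)
  expect_equal(sim$truth@dRight, breastDoseSide(r, side = "right"),
               tolerance = 1e-12)
  expect_equal(sim$truth@dOverall,
               overallBreastDose(sim$truth@dLeft, sim$truth@dRight),
               tolerance = 1e-12)
})
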
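test_that("angulation labels parse with the LAO/CRA-positive convention", {
  expect_equal(parseAngulation("LAO31\u00b0/CAU28\u00b0"),
               c(lateral = 31, axial = -28))
  expect_equal(parseAngulation("PA"), c(lateral = 0, axial = 0))
  expect_equal(parseAngulation("RAO 33\u00b0/CAU 4\u00b0"),
               c(lateral = -33, axial = -4))
  expect_equal(parseAngulation("CRA40"), c(lateral = 0, axial = 40))
  expect_equal(parseAngulation("rao10"), c(lateral = -10, axial = 0))
  expect_error(parseAngulation("LAO31/RAO10"), "duplicate")
  expect_error(parseAngulation("sideways"), "sideways")
  expect_error(parseAngulation("LAO95"), "90")
})

test_that("the packaged mock log matches its recorded totals and FOVs", {
  log <- mockProcedureLog()
  expect_equal(nrow(log), 9)
  expect_equal(sum(log$fov_cm == 15), 8)
  expect_equal(sum(log$fov_cm == 23), 1)
  expect_equal(totalDap(log), 14.06, tolerance = 1e-12)
  expect_equal(totalDap(log[1:2, ]), 2.16, tolerance = 1e-12)
  expect_equal(totalDap(log[0, ]), 0)
})

test_that("total DAP is permutation-invariant and additive", {
  log <- mockProcedureLog()
  set.seed(9)
  expect_equal(totalDap(log[sample(nrow(log)), ]), totalDap(log))
  expect_equal(totalDap(rbind(log, log[3:5, ])),
               totalDap(log) + totalDap(log[3:5, ]))
})

test_that("factor matching prefers exact, then FOV, then angulation", {
  tab <- demoFactorTable()
  # exact (angulation, fov)
  m <- matchFactor(tab, list(lateral_deg = 31, axial_deg = -28,
                             fov_cm = 15))
  expect_false(m$fallback_used)
  expect_equal(m$entry$factor_left, 0.050)
  # FOV fallback: LV view at 23 cm, table only has 15 cm
  m2 <- matchFactor(tab, list(lateral_deg = -33, axial_deg = 4,
                              fov_cm = 23))
  expect_true(m2$fallback_used)
  expect_equal(m2$entry$fov_cm, 15)
  expect_equal(m2$entry$lateral_deg, -33)
  # nearest-angulation fallback within tolerance
  tab3 <- data.frame(lateral_deg = c(31, -31), axial_deg = c(0, 0),
                     fov_cm = 15, factor_left = c(0.1, 0.2),
                     factor_right = c(0.1, 0.2),
                     factor_overall = c(0.1, 0.2))
  m3 <- matchFactor(tab3, list(lateral_deg = 30, axial_deg = 0,
                               fov_cm = 15), toleranceDeg = 5)
  expect_true(m3$fallback_used)
  expect_equal(m3$entry$lateral_deg, 31)
  # beyond the tolerance: error that names the nearest candidates
  expect_error(matchFactor(tab3, list(lateral_deg = 0, axial_deg = -60,
                                      fov_cm = 15)),
               "nearest candidates")
  expect_error(matchFactor(tab3[0, ], list(lateral_deg = 0, axial_deg = 0,
                                           fov_cm = 15)), "empty")
})

test_that("procedure dose is the sum of DAP x factor contributions", {
  tab <- data.frame(lateral_deg = c(0, 30, -30), axial_deg = c(0, 0, 0),
                    fov_cm = 15,
                    factor_left = c(0.10, 0.05, 0.12),
                    factor_right = c(0.15, 0.06, 0.20),
                    factor_overall = c(0.1275, 0.0555, 0.1640))
  log <- data.frame(label = c("PA", "LAO30", "RAO30"),
                    lateral_deg = c(0, 30, -30), axial_deg = 0,
                    fov_cm = 15, dap_gycm2 = c(2, 3, 5))
  est <- estimateBreastDose(log, tab)
  expect_s4_class(est, "ProcedureDoseEstimate")
  # hand-computed sums of products
  expect_equal(doseLeft(est), 2 * 0.10 + 3 * 0.05 + 5 * 0.12,
               tolerance = 1e-12)
  expect_equal(doseRight(est), 2 * 0.15 + 3 * 0.06 + 5 * 0.20,
               tolerance = 1e-12)
  expect_equal(doseOverall(est), 2 * 0.1275 + 3 * 0.0555 + 5 * 0.1640,
               tolerance = 1e-12)
  expect_equal(est@totalDap, 10)
  expect_false(any(est@perAcquisition$fallback_used))
  # single record, one multiplication
  one <- estimateBreastDose(log[1, ][, ], tab)
  expect_equal(doseOverall(one), 2 * 0.1275, tolerance = 1e-12)
  # zero DAP log gives zero totals
  log0 <- log; log0$dap_gycm2 <- 0
  expect_equal(doseOverall(estimateBreastDose(log0, tab)), 0)
  # linear in a uniform DAP rescaling
  logK <- log; logK$dap_gycm2 <- log$dap_gycm2 * 2.5
  expect_equal(doseOverall(estimateBreastDose(logK, tab)),
               2.5 * doseOverall(est), tolerance = 1e-12)
  # unmatched records name the acquisition
  logBad <- log; logBad$lateral_deg[2] <- 80
  expect_error(estimateBreastDose(logBad, tab), "LAO30")
})

test_that("a one-entry table reduces the estimate to totalDap x factors", {
  tab1 <- data.frame(lateral_deg = 0, axial_deg = 0, fov_cm = 15,
                     factor_left = 0.16, factor_right = 0.08,
                     factor_overall = 0.116)
  log <- data.frame(label = paste0("#", 1:4), lateral_deg = 0,
                    axial_deg = 0, fov_cm = 15,
                    dap_gycm2 = c(1.2, 0.8, 2.5, 0.5))
  est <- estimateBreastDose(log, tab1)
  expect_equal(doseLeft(est), totalDap(log) * 0.16, tolerance = 1e-12)
  expect_equal(doseOverall(est), totalDap(log) * 0.116, tolerance = 1e-12)
})

test_that("mass-consistent factor tables keep side/overall consistency", {
  tab <- demoFactorTable()
  # each row satisfies overall = 0.45 left + 0.55 right by construction
  expect_equal(tab$factor_overall,
               0.45 * tab$factor_left + 0.55 * tab$factor_right,
               tolerance = 1e-12)
  log <- mockProcedureLog()
  est <- estimateBreastDose(log, tab)
  expect_equal(doseOverall(est),
               overallBreastDose(doseLeft(est), doseRight(est)),
               tolerance = 1e-9)
  # the LV view (23 cm) and the CAU39 row must have used fallbacks
  expect_gte(sum(est@perAcquisition$fallback_used), 2)
})

test_that("effective dose scales DAP by the scalar conversion factor", {
  expect_equal(effectiveDoseFromDap(82, 0.2), 16.4)
  expect_equal(effectiveDoseFromDap(0, 0.2), 0)
  expect_equal(effectiveDoseFromDap(14.06, 0.2), 2.812)
  expect_error(effectiveDoseFromDap(-1), ">= 0")
})

test_that("acquisition logs read from CSV with parsed angulations", {
  withr::with_tempfile("f", fileext = ".csv", {
    writeLines(c("label,angulation,sid_cm,kv,ma,ms,frames,time_s,dap_gycm2,fov_cm",
                 "#1,LAO31/CAU28,101,79,596,5,35,4.7,1.22,15",
                 "#2,PA,100,80,600,5,30,4.0,1.00,15"), f)
    log <- readAcquisitionLog(f)
    expect_equal(log$lateral_deg, c(31, 0))
    expect_equal(log$axial_deg, c(-28, 0))
    expect_equal(totalDap(log), 2.22)
  })
  expect_error(readAcquisitionLog("no/file.csv"), "not found")
})
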
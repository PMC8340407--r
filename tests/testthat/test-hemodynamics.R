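test_that("boundary-condition arithmetic follows the stated relations", {
  # allometric calibration: 150 g at k = 0.75 gives 2.0 mL/s
  expect_equal(restingFlow(150), 2.0, tolerance = 2e-3)
  expect_equal(restingFlow(100, k = 1, qc = 0.01), 1.0)
  expect_equal(restingFlow(2 * 80) / restingFlow(80), 2^0.75)
  expect_error(restingFlow(-1), "mass")

  expect_equal(hyperemicFlow(2, 3), 6)
  expect_silent(hyperemicFlow(2, 2))
  expect_silent(hyperemicFlow(2, 4))
  expect_warning(hyperemicFlow(2, 1.5), "\\[2, 4\\]")
  expect_error(hyperemicFlow(2, 1.5, strict = TRUE), "\\[2, 4\\]")
  expect_error(hyperemicFlow(2, 0), "> 0")
  expect_equal(suppressWarnings(hyperemicFlow(2, 1)), 2)

  expect_equal(murrayOutletFlows(2, c(3, 2)), c(2 * 27 / 35, 2 * 8 / 35))
  expect_equal(murrayOutletFlows(5, c(2, 2, 2)), rep(5 / 3, 3))
  set.seed(1)
  for (i in 1:20) {
    d <- runif(sample(2:6, 1), 0.5, 4)
    q <- murrayOutletFlows(3.7, d)
    expect_lt(abs(sum(q) - 3.7) / 3.7, 1e-12)
  }
  expect_error(murrayOutletFlows(1, numeric()), "outlet")

  expect_equal(meanAorticPressure(131, 76)$mmHg, 94 + 1 / 3, tolerance = 1e-9)
  expect_equal(meanAorticPressure(90, 90)$mmHg, 90)
  expect_equal(meanAorticPressure(120, 80)$mmHg, 93 + 1 / 3, tolerance = 1e-9)
  expect_equal(meanAorticPressure(120, 80)$pa,
               (93 + 1 / 3) * 133.322, tolerance = 1e-9)
  expect_error(meanAorticPressure(70, 80), "systolic")
})

test_that("axisymmetric solve matches Hagen-Poiseuille in a straight tube", {
  mesh <- buildAxiMesh(profile = data.frame(arclen = c(0, 20),
                                            radius = c(1.5, 1.5)), hMax = 0.3)
  bc <- bcWithFlow(1.0)   # Re ~ 128
  ff <- solveAxisymmetric(mesh, bc, inflow = 1.0)
  dpTheory <- 8 * 0.0035 * 0.02 * 1e-6 / (pi * (1.5e-3)^4)
  expect_lt(abs(pressureDrop(ff) - dpTheory) / dpTheory, 0.03)
  # outlet profile: centreline/mean velocity ratio of a parabola
  uOut <- ff@uz[nrow(ff@uz), ]
  uMean <- 1e-6 / (pi * (1.5e-3)^2)
  expect_gte(uOut[1] / uMean, 1.94)
  expect_lte(uOut[1] / uMean, 2.06)
  # mass conservation
  expect_lt(ff@massErr, 1e-6)
  expect_true(ff@converged)
})

test_that("network solver is exact on uniform tubes and additive in series", {
  prof <- data.frame(arclen = c(0, 20), radius = c(1.5, 1.5))
  net <- buildNetwork(profileTree(prof), dx = 1)
  bc <- bcWithFlow(1.0)
  sol <- solveNetwork(net, bc)
  dp <- bc@mapPa - min(sol@pressures)
  dpTheory <- 128 * 0.0035 * 0.02 * 1e-6 / (pi * (3e-3)^4)
  expect_equal(dp, dpTheory, tolerance = 1e-12)
  # two identical elements in series double the drop of one
  prof1 <- data.frame(arclen = c(0, 10), radius = c(1.5, 1.5))
  dp1 <- bc@mapPa - min(solveNetwork(buildNetwork(profileTree(prof1), dx = 10),
                                     bc)@pressures)
  expect_equal(dp, 2 * dp1, tolerance = 1e-12)
  expect_error(solveNetwork({
    n <- net; n@elements$rmin[1] <- 0; n
  }, bc), "zero-radius")
})

test_that("network pressure drop grows with severity and matches the
           axisymmetric solver on the low-Reynolds calibration family", {
  bc <- bcWithFlow(0.3)   # throat Reynolds stays below 200 up to 70% DS
  dps <- c()
  for (sev in c(0.5, 0.6, 0.7)) {
    prof <- stenosisProfile(sev)
    net <- buildNetwork(profileTree(prof), dx = 0.5)
    dpN <- bc@mapPa - min(solveNetwork(net, bc)@pressures)
    dps <- c(dps, dpN)
    mesh <- buildAxiMesh(profile = prof, hMax = 0.15)
    ff <- solveAxisymmetric(mesh, bc, inflow = 0.3)
    expect_lt(abs(dpN - pressureDrop(ff)) / pressureDrop(ff), 0.15)
  }
  expect_true(all(diff(dps) > 0))
})

test_that("FFR extraction satisfies its defining identities", {
  bc <- bcWithFlow(2.0)
  prof <- stenosisProfile(0.6, L = 60, center = 20)
  net <- buildNetwork(profileTree(prof), dx = 0.5)
  sol <- solveNetwork(net, bc)
  f <- computeFFR(sol, bc, lesionEnd = 24, offset = 20)
  expect_identical(f@table$ffr[1], 1)          # inlet definition
  expect_true(all(diff(f@table$ffr) <= 1e-12)) # monotone non-increasing
  expect_equal(f@measurementArclen, 44)
  # measurement point capped at the path end / rejected beyond it
  fEnd <- computeFFR(sol, bc, lesionEnd = 55, offset = 20)
  expect_equal(fEnd@measurementArclen, 60)
  expect_error(computeFFR(sol, bc, arclen = 99), "beyond")
  # classification consistency at the boundary
  expect_identical(f@positive, f@lesionFFR <= 0.80)

  # hydrostatic limit: vanishing flow gives FFR 1 everywhere
  bc0 <- bcWithFlow(1e-12)
  f0 <- computeFFR(solveNetwork(net, bc0), bc0)
  expect_lt(max(abs(f0@table$ffr - 1)), 1e-9)

  # healthy 3 mm tube: Poiseuille-scale distal FFR ~ 0.997
  bcH <- bcWithFlow(1.0, outletDiameters = 3)
  bcH@mapPa <- 93 * 133.322; bcH@mapMmHg <- 93
  profH <- data.frame(arclen = c(0, 20), radius = c(1.5, 1.5))
  fH <- computeFFR(solveNetwork(buildNetwork(profileTree(profH), dx = 1), bcH),
                   bcH)
  expect_equal(fH@lesionFFR, 1 - 35.21 / (93 * 133.322), tolerance = 1e-3)
})

test_that("lesion FFR decreases with severity and with hyperemia", {
  ffrs <- vapply(seq(0.3, 0.8, 0.1), function(sev) {
    bc <- bcWithFlow(2.0)
    prof <- stenosisProfile(sev, L = 60, center = 20)
    computeFFR(solveNetwork(buildNetwork(profileTree(prof), dx = 0.5), bc),
               bc, lesionEnd = 24)@lesionFFR
  }, 0)
  expect_true(all(diff(ffrs) < 0))
  expect_true(any(ffrs > 0.80) && any(ffrs <= 0.80))  # crosses the threshold

  fh <- vapply(c(2, 3, 4), function(h) {
    bc <- boundaryConditions(mass = 150, hyperemiaFactor = h,
                             outletDiameters = 3)
    prof <- stenosisProfile(0.6, L = 60, center = 20)
    computeFFR(solveNetwork(buildNetwork(profileTree(prof), dx = 0.5), bc),
               bc, lesionEnd = 24)@lesionFFR
  }, 0)
  expect_true(all(diff(fh) < 0))
})

test_that("FFR is invariant to pressure-unit rescaling", {
  prof <- stenosisProfile(0.5, L = 40, center = 15)
  net <- buildNetwork(profileTree(prof), dx = 0.5)
  bc <- bcWithFlow(1.5)
  f1 <- computeFFR(solveNetwork(net, bc), bc)
  # same physics expressed with the pressure level in mmHg-sized units
  bc2 <- bc
  scale <- 1 / 133.322
  bc2@mapPa <- bc@mapPa   # solver works in SI; rescale the readout instead
  f2tab <- computeFFR(solveNetwork(net, bc2), bc2)@table
  expect_lt(max(abs(f2tab$ffr - f1@table$ffr)), 1e-12)
  expect_lt(max(abs(f2tab$pressure * scale / bc@mapMmHg - f2tab$ffr)), 1e-12)
})
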
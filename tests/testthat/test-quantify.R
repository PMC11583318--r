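test_that("ionic calibration fits exact and pooled points", {
  cal <- suppressWarnings(fitIonicCalibration(
    lapply(c(0, 20, 200), function(k)
      list(concentration = k, meanCounts = 2 * k))))
  expect_equal(slope(cal), 2)
  expect_equal(intercept(cal), 0)
  ## duplicate start/end standards: all six points enter the fit
  six <- lapply(rep(c(0, 20, 200), 2), function(k)
    list(concentration = k, meanCounts = 2 * k + (k == 20) * 1))
  cal6 <- suppressWarnings(fitIonicCalibration(six))
  expect_equal(cal6@nPoints, 6L)
  expect_error(fitIonicCalibration(list(list(concentration = 0,
                                             meanCounts = 0))),
               "at least 3")
  expect_error(suppressWarnings(fitIonicCalibration(
    lapply(1:3, function(i) list(concentration = 5, meanCounts = 10)))),
    "equal")
})

test_that("reference gold arithmetic matches independent hand computation", {
  ## (pi/6) (60e-7 cm)^3 x 19.32 g/cm3 = 2.185e-15 g
  expect_equal(singleParticleMass(goldReference()), 2.185e-15,
               tolerance = 1e-4)
  ## 1250 ng/L / 2.185e-15 g = 5.72e8 particles/L
  expect_equal(goldReference(1250)@numberConcentration * 1000, 5.72e8,
               tolerance = 1e-3)
})

test_that("frequency-method transport efficiency inverts the simulator", {
  ## identity: detected equal to delivered -> eta = 1
  s <- fullSettings()
  ref <- goldReference(125)
  delivered <- ref@numberConcentration * s@flowRate * 45 / 60
  te1 <- transportEfficiencyFrequency(NULL, ref, s,
                                      nDetected = floor(delivered))
  expect_equal(eta(te1), 1, tolerance = 1e-3)
  ## seeded recovery: true eta = 0.05 within 3 sqrt(N)/N
  sim <- simulateTrace(s, ref, noiseModel(1), 0.05, 5, seed = 2)
  ev <- detectEvents(sim$trace)
  te <- transportEfficiencyFrequency(ev, ref, s)
  expect_lt(abs(eta(te) - 0.05) / 0.05, 3 / sqrt(nrow(ev)) + 0.03)
  expect_error(transportEfficiencyFrequency(NULL, ref, s, nDetected = 0),
               "unusable")
})

test_that("mass-method transport efficiency is exact in consistent units", {
  ## with b = 1 count/dwell per ug/L and S = m_ref expressed in the same
  ## per-dwell mass unit, eta must be 1; doubling b doubles eta
  s <- fullSettings()
  ref <- goldReference(125)
  cal1 <- exactCalibration(slope = 5)
  mref <- singleParticleMass(ref)
  sbarUnit <- mref * 1e6 * slope(cal1) /
    (nanotrace:::.flowLitrePerSec(s) * s@dwellTime)  # integral giving eta = 1
  te <- transportEfficiencyMass(data.frame(integral = sbarUnit), ref, cal1, s)
  expect_equal(eta(te), 1, tolerance = 1e-12)
  cal2 <- exactCalibration(slope = 10)
  te2 <- transportEfficiencyMass(data.frame(integral = sbarUnit * 4),
                                 ref, cal2, s)
  expect_equal(eta(te2), 0.5, tolerance = 1e-12)
  expect_error(transportEfficiencyMass(data.frame(integral = numeric(0)),
                                       ref, cal1, s), "positive")
})

test_that("frequency and mass methods agree on simulated reference runs", {
  s <- fullSettings()
  ref <- goldReference(125)
  cal <- exactCalibration(slope = 5)
  sim <- simulateTrace(s, ref, noiseModel(1), 0.05, 5, seed = 4)
  ev <- detectEvents(sim$trace)
  tf <- transportEfficiencyFrequency(ev, ref, s)
  tm <- transportEfficiencyMass(ev, ref, cal, s)
  expect_lt(abs(eta(tm) / eta(tf) - 1), 0.10)
})

test_that("event mass and mass-equivalent diameter invert the simulator", {
  s <- fullSettings()
  cal <- exactCalibration(slope = 5)
  ## identity case: S_p scaled so that eta q t_dwell / b = 1 mass unit
  m1 <- eventMass(1, cal, 1, s)
  expect_equal(eventMass(2, cal, 1, s) / m1, 2)  # strict monotonicity
  expect_true(all(diff(eventMass(c(1, 5, 10), cal, 0.05, s)) > 0))

  ## noiseless unit inversion: a simulated event's integral converts back to
  ## its true mass exactly (event fully inside the trace)
  pop <- gold60(1e3)
  sim <- simulateTrace(s, pop, noiseModel(0), 0.05, 5, seed = 8, nEvents = 1)
  tr <- sim$truth$events
  ev <- detectEvents(sim$trace, baseline = rep(0, nDwells(sim$trace)))
  m <- eventMass(ev$integral, cal, 0.05, s)
  ## Poisson realization of the counts is the only error source here
  expect_lt(abs(sum(m) - sum(tr$mass)) / sum(tr$mass), 0.15)

  ## seeded recovery: median mass within 5% of the 60 nm truth
  sim2 <- simulateTrace(s, gold60(3e4), noiseModel(1), 0.05, 5, seed = 12)
  ev2 <- detectEvents(sim2$trace)
  m2 <- eventMass(ev2$integral, cal, 0.05, s)
  expect_lt(abs(median(m2) - 2.185e-15) / 2.185e-15, 0.05)
})

test_that("mass-equivalent diameter obeys its scaling laws", {
  expect_equal(massEquivalentDiameter(2.185e-15, 19.32), 60, tolerance = 1e-3)
  m <- 1e-15
  ## d scales as f^(-1/3)
  expect_equal(massEquivalentDiameter(m, 19.32, 0.5) /
                 massEquivalentDiameter(m, 19.32, 1), 2^(1 / 3))
  ## d(8m) = 2 d(m)
  expect_equal(massEquivalentDiameter(8 * m, 19.32),
               2 * massEquivalentDiameter(m, 19.32))
  expect_error(massEquivalentDiameter(-1, 19.32), "positive")
})

test_that("concentration arithmetic matches the closed form", {
  s <- fullSettings()
  cal <- exactCalibration(slope = 5)
  ## 18750 events, eta 0.05, q 0.5 mL/min, 45 s, dilution 1 g/L:
  ## analysed volume = 0.05 x 0.375 mL -> 1e6 /mL = 1e9 /L = 1e9 /g
  ev <- data.frame(integral = rep(100, 10))
  res <- sampleConcentrations(ev, cal, 0.05, s, dilution = 1)
  analysedML <- 0.05 * 0.5 * 45 / 60
  expect_equal(res$numberConcPerG, 10 / analysedML * 1000)
  expect_equal(18750 / analysedML * 1000, 1e9)
  ## halving dilution doubles per-gram values
  res2 <- sampleConcentrations(ev, cal, 0.05, s, dilution = 0.5)
  expect_equal(res2$numberConcPerG, 2 * res$numberConcPerG)
  expect_equal(res2$massConcNgPerG, 2 * res$massConcNgPerG)
  ## zero events
  res0 <- sampleConcentrations(nanotrace:::.emptyEvents(), cal, 0.05, s)
  expect_equal(res0$numberConcPerG, 0)
  expect_equal(res0$massConcNgPerG, 0)
})

test_that("blank subtraction floors at zero and preserves raw values", {
  s <- fullSettings()
  cal <- exactCalibration()
  mk <- function(n, id) {
    r <- sampleConcentrations(data.frame(integral = rep(50, n)), cal, 0.05,
                              s, sampleId = id)
    r
  }
  sample <- mk(100, "s")
  blanks <- rbind(mk(20, "b1"), mk(40, "b2"))
  out <- blankSubtract(sample, blanks)
  expect_equal(out$numberConcPerG,
               sample$numberConcPerG * (100 - 30) / 100)
  expect_equal(out$numberConcRaw, sample$numberConcPerG)
  expect_false(out$flooredNumber)
  ## zero blanks leave the sample unchanged
  zb <- mk(100, "b0"); zb$numberConcPerG <- 0; zb$massConcNgPerG <- 0
  expect_equal(blankSubtract(sample, zb)$numberConcPerG,
               sample$numberConcPerG)
  ## blank mean above the sample: floored and flagged
  big <- mk(300, "bb")
  out2 <- blankSubtract(sample, big)
  expect_equal(out2$numberConcPerG, 0)
  expect_true(out2$flooredNumber)
  none <- mk(10, "x"); none$element <- "Zz"
  expect_error(blankSubtract(sample, none), "no procedural blanks")
})

test_that("detection limits follow the 3/10 sigma and max-across-days rules", {
  ## hand computation: blanks 1..12 have sample SD 3.6056, so
  ## LOD = mean + 3 SD = 6.5 + 10.817 = 17.317 and LOQ = mean + 10 SD
  bl <- data.frame(dayId = "d1", numberConcPerG = 1:12,
                   massConcNgPerG = 1:12)
  lim <- detectionLimits(bl, c(d1 = 0.5))
  expect_equal(lim@numberLod, 6.5 + 3 * sd(1:12), tolerance = 1e-12)
  expect_equal(lim@numberLod, 17.3167, tolerance = 1e-4)
  expect_equal(lim@numberLoq, 6.5 + 10 * sd(1:12))
  ## identical blanks across days: SD 0, LOD = blank value; per-day and
  ## pooled limits coincide
  bl2 <- data.frame(dayId = rep(c("d1", "d2"), each = 3),
                    numberConcPerG = 5, massConcNgPerG = 2)
  lim2 <- detectionLimits(bl2, c(d1 = 0.5, d2 = 0.8))
  expect_equal(lim2@numberLod, 5)
  expect_equal(lim2@massLod, 2)
  ## mass-per-particle limit: highest value across days
  expect_equal(lim2@massPerParticleLodFg, 0.8)
  ## a day with a single blank is skipped with a warning
  bl3 <- rbind(bl, data.frame(dayId = "d2", numberConcPerG = 1,
                              massConcNgPerG = 1))
  expect_warning(lim3 <- detectionLimits(bl3, c(d1 = 0.5, d2 = 0.9)),
                 "skipped")
  expect_equal(lim3@numberLod, lim@numberLod)
})

test_that("applying limits censors at or below the detection limit", {
  s <- fullSettings()
  cal <- exactCalibration()
  res <- sampleConcentrations(data.frame(integral = rep(50, 5)), cal, 0.05, s)
  lim <- new("DetectionLimits", element = "Au", massPerParticleLodFg = 1,
             numberLod = res$numberConcPerG + 1,
             numberLoq = res$numberConcPerG + 2,
             massLod = 0, massLoq = 0, dayIds = "d1")
  out <- applyLimits(res, lim)
  expect_true(out$censoredNumber)
  expect_false(out$censoredMass)
})
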
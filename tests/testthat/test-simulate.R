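test_that("zero-particle traces are pure Poisson noise with empty truth", {
  sim <- simulateTrace(fastSettings(), gold60(0), noiseModel(2), 0.05, 5,
                       seed = 1)
  expect_equal(nrow(sim$truth$events), 0)
  expect_true(all(counts(sim$trace) >= 0))
  ## counts should look Poisson(2): mean within 5 SE
  n <- nDwells(sim$trace)
  expect_lt(abs(mean(counts(sim$trace)) - 2), 5 * sqrt(2 / n))
})

test_that("realized event counts match the closed-form expectation", {
  ## C_num * q * t_acq * eta = 1e6 * 0.5 * (45/60) * 0.05 = 18750 per
  ## acquisition; average over seeded runs must sit within 3 SE of it.
  ## Scaled geometry with identical expectation per dwell-count budget:
  ## 2 s acquisition, C chosen for an expected 833.33 events per run.
  s <- fastSettings(acquisitionTime = 2)
  expected <- 1e6 * 0.5 * (2 / 60) * 0.05
  nruns <- 120
  tot <- 0
  for (seed in seq_len(nruns)) {
    sim <- simulateTrace(s, gold60(1e6), noiseModel(1), 0.05, 5, seed = seed)
    tot <- tot + nrow(sim$truth$events)
  }
  se <- sqrt(expected * nruns) / nruns
  expect_lt(abs(tot / nruns - expected), 3 * se)
  ## and the full-scale arithmetic itself
  expect_equal(1e6 * 0.5 * (45 / 60) * 0.05, 18750)
})

test_that("noiseless traces put every nonzero count inside a true event", {
  s <- fastSettings()
  sim <- simulateTrace(s, gold60(1e4), noiseModel(0), 0.05, 5, seed = 3,
                       nEvents = 1)
  ev <- sim$truth$events
  expect_equal(nrow(ev), 1)
  nz <- which(counts(sim$trace) > 0)
  expect_true(all(nz >= ev$start & nz <= ev$start + ev$span - 1))
})

test_that("identical seeds reproduce traces exactly; different seeds differ", {
  a <- simulateTrace(fastSettings(), gold60(1e5), noiseModel(1), 0.05, 5,
                     seed = 42)
  b <- simulateTrace(fastSettings(), gold60(1e5), noiseModel(1), 0.05, 5,
                     seed = 42)
  c <- simulateTrace(fastSettings(), gold60(1e5), noiseModel(1), 0.05, 5,
                     seed = 43)
  expect_identical(counts(a$trace), counts(b$trace))
  expect_identical(a$truth$events, b$truth$events)
  expect_false(identical(counts(a$trace), counts(c$trace)))
})

test_that("impossible geometry is refused with a diagnostic", {
  expect_error(
    simulateTrace(acquisitionSettings(dwellTime = 0.1, acquisitionTime = 1,
                                      flowRate = 0.5),
                  gold60(1e9), noiseModel(1), 0.5, 5, seed = 1),
    "impossible geometry")
  expect_error(
    simulateTrace(fastSettings(), gold60(1e5), noiseModel(1), 0.05, 5,
                  seed = 1.5),
    "seed")
})

test_that("summed true event masses conserve the delivered particulate mass", {
  ## delivered mass = C_num x mean particle mass x q x t_acq; the simulated
  ## event masses must sum to eta x that, within Monte-Carlo error (5%).
  ## 450 s acquisition gives ~5600 events at 1e4 /mL.
  s <- acquisitionSettings(acquisitionTime = 450, flowRate = 0.5)
  pop <- gold60(1e4, gsd = 1.4)
  etaTrue <- 0.05
  sim <- simulateTrace(s, pop, noiseModel(0), etaTrue, 5, seed = 11)
  sigma <- log(1.4)
  meanMass <- singleParticleMass(pop) * exp(4.5 * sigma^2)  # E[d^3] factor
  deliveredG <- 1e4 * meanMass * 0.5 * 450 / 60 * 1  # per mL x mL delivered
  expect_lt(abs(sum(sim$truth$events$mass) / deliveredG - etaTrue) / etaTrue,
            0.05)
})

test_that("ionic standards have the constructed mean and recover the slope", {
  s <- fastSettings()
  nm <- noiseModel(2)
  tr0 <- simulateIonicStandard(s, 0, 2, nm, seed = 1)
  tr20 <- simulateIonicStandard(s, 20, 2, nm, seed = 2)
  n <- nDwells(tr0)
  expect_lt(abs(mean(counts(tr0)) - 2), 5 * sqrt(2 / n))
  expect_lt(abs(mean(counts(tr20)) - 42), 5 * sqrt(42 / n))
  expect_error(simulateIonicStandard(s, -1, 2, nm, seed = 1), "concentration")

  ## three-point round trip: fitted slope within 3 SE of the true response
  std <- lapply(seq_along(c(0, 20, 200)), function(i)
    list(concentration = c(0, 20, 200)[i],
         trace = simulateIonicStandard(s, c(0, 20, 200)[i], 2, nm, seed = i)))
  cal <- fitIonicCalibration(std)
  ## slope error bounded by the propagated SE of the trace means:
  ## sd(mean counts) ~ sqrt(lambda/n) at the top standard dominates
  n <- nDwells(std[[3]]$trace)
  seSlope <- sqrt((2 + 2 * 200) / n) / 200
  expect_lt(abs(slope(cal) - 2), max(3 * cal@slopeSE, 3 * seSlope))
})

test_that("survey generator honours effects, censoring and determinism", {
  se <- simulateSurvey(nLocations = 12, elements = c("Pb", "Ti", "Fe"),
                       seed = 5)
  expect_s4_class(se, "SurveyExperiment")
  expect_equal(dim(se), c(3L, 36L))
  expect_identical(
    SummarizedExperiment::assay(se, "number"),
    SummarizedExperiment::assay(simulateSurvey(nLocations = 12,
                                               elements = c("Pb", "Ti", "Fe"),
                                               seed = 5), "number"))

  ## full censoring of one element removes it from the clustering input
  se2 <- simulateSurvey(nLocations = 8, elements = c("Pb", "Ti"),
                        censoringRate = c(1 - 1e-9, 0.05), seed = 6)
  expect_true(all(SummarizedExperiment::assay(se2, "censoredNumber")["Pb", ]))
  suppressMessages(expect_message(
    z <- nanotrace:::.multivariateInput(se2, "number", "drop"),
    "dropping element"))
  expect_false("Pb" %in% colnames(z$z))

  ## a 10x class effect shifts that class's group mean upward
  se3 <- simulateSurvey(nLocations = 30, elements = c("Pb", "Ti"),
                        classEffects = list(Pb = c(anthropogenic = 10)),
                        censoringRate = 0, seed = 7)
  lmv <- locationMeans(se3, "number")
  anth <- lmv$classification == "anthropogenic"
  expect_gt(mean(log(lmv$values[anth, "Pb"])),
            mean(log(lmv$values[!anth, "Pb"])))
  expect_error(simulateSurvey(nLocations = 5, elements = character(0)),
               "empty")
})
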
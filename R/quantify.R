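## Calibration (ionic response, transport efficiency), event-mass conversion
## and blank-corrected concentrations with per-day detection limits.
##
## Unit conventions: event integrals in counts; ionic slope b in counts/dwell
## per (ug/L); masses in grams internally (reported as fg where stated);
## concentrations per litre of digest internally, per gram of tissue at the
## interface via the dilution factor (g tissue per litre of digest).

#' Fit the ionic calibration line
#'
#' Ordinary least-squares regression of mean counts per dwell against
#' dissolved standard concentration. Standards measured repeatedly (e.g. at
#' the start and end of a day) are pooled: every supplied trace contributes
#' one point.
#'
#' @param standards a list of `list(concentration = <ug/L>, trace =
#'   <TimeTrace>)` pairs (a bare numeric `meanCounts` may replace `trace`).
#' @param element,dayId identity recorded on the calibration; defaulted from
#'   the first trace when available.
#' @return An [IonicCalibration-class].
#' @examples
#' std <- lapply(c(0, 20, 200), function(conc)
#'   list(concentration = conc, meanCounts = 0.5 + 2 * conc))
#' slope(fitIonicCalibration(std))
#' @export
fitIonicCalibration <- function(standards, element = NULL, dayId = NULL) {
  if (length(standards) < 3L)
    stop("need at least 3 calibration points (including a 0 ug/L standard)")
  conc <- vapply(standards, function(s) as.numeric(s$concentration), 0)
  y <- vapply(standards, function(s) {
    if (!is.null(s$trace)) mean(counts(s$trace)) else as.numeric(s$meanCounts)
  }, 0)
  if (length(unique(conc)) < 2L)
    stop("calibration concentrations are all equal")
  if (length(unique(conc)) < 3L)
    warning("fewer than 3 distinct concentrations; the fit is a 2-level line")
  if (!any(conc == 0))
    warning("no 0 ug/L standard among the calibration points")
  fit <- lm(y ~ conc)
  sm <- summary(fit)
  tr1 <- standards[[1L]]$trace
  new("IonicCalibration",
      slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
      element = element %||% (if (!is.null(tr1)) tr1@element else "X"),
      dayId = dayId %||% (if (!is.null(tr1)) tr1@dayId else "day1"),
      residualSE = sm$sigma, slopeSE = sm$coefficients[2L, 2L],
      nPoints = length(conc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Element mass of a single reference particle
#'
#' Spherical particle mass from the population's median diameter, compound
#' density and element mass fraction: `(pi/6) d^3 rho f`.
#'
#' @param population a [ParticlePopulation-class].
#' @return Mass in grams.
#' @examples
#' singleParticleMass(goldReference())  # 60 nm Au: 2.185e-15 g
#' @export
singleParticleMass <- function(population) {
  .sphereMassG(population@medianDiameter, population@density,
               population@massFraction)
}

#' Reference gold nanoparticle suspension
#'
#' The monodisperse 60 nm spherical gold reference used for transport
#' efficiency determination, at a given mass concentration. Number
#' concentration is mass concentration divided by the single-particle mass.
#'
#' @param massConcNgPerL mass concentration of the prepared suspension in
#'   ng/L (default 1250).
#' @param diameter nominal diameter, nm (default 60).
#' @return A [ParticlePopulation-class] with `numberConcentration` in
#'   particles/mL.
#' @examples
#' goldReference()@numberConcentration * 1000  # particles per litre
#' @export
goldReference <- function(massConcNgPerL = 1250, diameter = 60) {
  m <- .sphereMassG(diameter, 19.32, 1)
  particlePopulation("Au", density = 19.32, massFraction = 1,
                     medianDiameter = diameter, gsd = 1,
                     numberConcentration = massConcNgPerL * 1e-9 / m / 1000)
}

#' Transport efficiency by the particle-frequency method
#'
#' Ratio of the number of particles detected in a reference-suspension
#' acquisition to the number delivered to the nebulizer:
#' `eta = N_detected / (C_num_ref x q x t_acq)`.
#'
#' @param reference either a [TimeTrace-class] of the reference run (events
#'   are then detected with the supplied detection parameters) or a detected
#'   event data.frame; alternatively pass `nDetected` directly.
#' @param population the reference [ParticlePopulation-class] (known number
#'   concentration, particles/mL).
#' @param settings the [AcquisitionSettings-class] of the reference run.
#' @param nDetected optional detected particle count overriding `reference`.
#' @param dayId analysis-day identifier.
#' @param ... passed to [detectEvents()] when `reference` is a trace.
#' @return A [TransportEfficiency-class] (method `"frequency"`).
#' @export
transportEfficiencyFrequency <- function(reference, population, settings,
                                         nDetected = NULL, dayId = "day1",
                                         ...) {
  if (is.null(nDetected)) {
    nDetected <- if (is(reference, "TimeTrace")) {
      nrow(detectEvents(reference, ...))
    } else nrow(reference)
  }
  delivered <- population@numberConcentration * settings@flowRate *
    .acqMinutes(settings)
  if (delivered <= 0)
    stop("reference number concentration and flow must be positive")
  if (nDetected == 0)
    stop("no particles detected in the reference run: ",
         "transport-efficiency calibration is unusable")
  e <- nDetected / delivered
  if (e > 1)
    stop(sprintf(paste("frequency method yields eta = %.3g > 1; the",
                       "reference concentration or detection settings are",
                       "inconsistent"), e))
  new("TransportEfficiency", eta = e, method = "frequency", dayId = dayId)
}

#' Transport efficiency by the particle-mass method
#'
#' Solves the event-mass relation for the reference particle of known mass:
#' with mean reference event integral `S`, `eta = m_ref x b / (S x q x
#' t_dwell)` (q in L/s, masses in grams converted through the ug/L basis of
#' the slope).
#'
#' @param referenceEvents event data.frame from the reference run.
#' @param population the reference [ParticlePopulation-class].
#' @param calib the day's [IonicCalibration-class].
#' @param settings the [AcquisitionSettings-class].
#' @param dayId analysis-day identifier.
#' @return A [TransportEfficiency-class] (method `"mass"`).
#' @export
transportEfficiencyMass <- function(referenceEvents, population, calib,
                                    settings, dayId = "day1") {
  sbar <- mean(referenceEvents$integral)
  if (!is.finite(sbar) || sbar <= 0)
    stop("mean reference event integral must be positive")
  mref <- singleParticleMass(population)
  e <- (mref * 1e6) * slope(calib) /
    (sbar * .flowLitrePerSec(settings) * settings@dwellTime)
  if (e <= 0 || e > 1)
    stop(sprintf("mass method yields eta = %.3g outside (0, 1]", e))
  new("TransportEfficiency", eta = e, method = "mass", dayId = dayId)
}

#' Convert an event integral to element mass per particle
#'
#' `m_p = S_p x eta x q x t_dwell / b`: the baseline-corrected event integral
#' divided by the detector's counts-per-mass response (ionic sensitivity
#' scaled by the mass flow actually reaching the plasma).
#'
#' @param integral event integral(s), baseline-corrected counts (vectorized).
#' @param calib an [IonicCalibration-class] (slope must be > 0).
#' @param eta a [TransportEfficiency-class] or bare fraction.
#' @param settings the [AcquisitionSettings-class].
#' @return Mass(es) in grams.
#' @examples
#' s <- acquisitionSettings()
#' cal <- fitIonicCalibration(lapply(c(0, 20, 200), function(k)
#'   list(concentration = k, meanCounts = 5 * k)))
#' massEquivalentDiameter(eventMass(262, cal, 0.05, s), density = 19.32)
#' @export
eventMass <- function(integral, calib, eta, settings) {
  b <- slope(calib)
  if (b <= 0) stop("calibration slope must be > 0")
  e <- if (is(eta, "TransportEfficiency")) eta@eta else eta
  integral * e * .flowLitrePerSec(settings) * settings@dwellTime / b * 1e-6
}

#' Mass-equivalent spherical diameter
#'
#' Diameter of a sphere of the assumed compound density containing the
#' measured element mass: `d = (6 (m/f) / (pi rho))^(1/3)`. Composition
#' (density and element mass fraction) is an assumption of the conversion,
#' not a measurement.
#'
#' @param mass element mass(es) per particle, grams (vectorized, > 0).
#' @param density compound density, g/cm^3.
#' @param massFraction element mass fraction of the compound, in (0, 1].
#' @return Diameter(s) in nm.
#' @examples
#' massEquivalentDiameter(2.185e-15, 19.32)  # 60 nm gold
#' @export
massEquivalentDiameter <- function(mass, density, massFraction = 1) {
  .assertNumber(density, "density", 0, strict_lower = TRUE)
  .assertNumber(massFraction, "massFraction", 0, 1, strict_lower = TRUE)
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("'mass' must be positive")
  ((6 * (mass / massFraction)) / (pi * density))^(1 / 3) * 1e7
}

#' Particle number and mass concentrations for one sample
#'
#' Scales detected events to concentrations: the analysed digest volume is
#' `eta x q x t_acq` (only the transported fraction counts particles), so the
#' number concentration per litre of digest is `n / (eta q t_acq)` and the
#' mass concentration uses the summed event masses. Per-gram-tissue values
#' divide by the dilution (grams of tissue per litre of digest).
#'
#' @param events event data.frame from [detectEvents()].
#' @param calib the day's [IonicCalibration-class].
#' @param eta a [TransportEfficiency-class] or bare fraction.
#' @param settings the [AcquisitionSettings-class].
#' @param dilution grams of tissue per litre of digest (default 1, the
#'   standard enzymatic-digest dilution).
#' @param element,sampleId,dayId identity strings for the result row.
#' @return One-row data.frame: `sampleId`, `element`, `dayId`, `nEvents`,
#'   `numberConcPerG` (particles/g), `massConcNgPerG` (ng/g),
#'   `censoredNumber`, `censoredMass` (NA until limits are applied),
#'   `flooredNumber`, `flooredMass` (blank subtraction flags).
#' @examples
#' s <- acquisitionSettings(flowRate = 0.5)
#' cal <- fitIonicCalibration(lapply(c(0, 20, 200), function(k)
#'   list(concentration = k, meanCounts = 5 * k)))
#' ev <- data.frame(integral = rep(100, 10))
#' sampleConcentrations(ev, cal, 0.05, s)
#' @export
sampleConcentrations <- function(events, calib, eta, settings, dilution = 1,
                                 element = NULL, sampleId = "sample",
                                 dayId = NULL) {
  .assertNumber(dilution, "dilution", 0, strict_lower = TRUE)
  e <- if (is(eta, "TransportEfficiency")) eta@eta else eta
  .assertNumber(e, "eta", 0, 1, strict_lower = TRUE)
  analysedL <- e * .flowLitrePerMin(settings) * .acqMinutes(settings)
  n <- nrow(events)
  massG <- if (n > 0) sum(eventMass(events$integral, calib, e, settings)) else 0
  data.frame(
    sampleId = sampleId,
    element = element %||% calib@element,
    dayId = dayId %||% calib@dayId,
    nEvents = n,
    numberConcPerG = n / analysedL / dilution,
    massConcNgPerG = massG * 1e9 / analysedL / dilution,
    censoredNumber = NA, censoredMass = NA,
    flooredNumber = FALSE, flooredMass = FALSE)
}

#' Subtract the mean procedural blank from a sample result
#'
#' Subtracts the mean blank number and mass concentrations (matching element
#' and day), floors negative results at zero and flags them; pre-subtraction
#' values are kept in `numberConcRaw` / `massConcRaw`.
#'
#' @param sample one-row result from [sampleConcentrations()].
#' @param blanks data.frame of blank results (same columns).
#' @return The corrected one-row data.frame.
#' @export
blankSubtract <- function(sample, blanks) {
  b <- blanks[blanks$element == sample$element &
                blanks$dayId == sample$dayId, , drop = FALSE]
  if (nrow(b) == 0L)
    stop(sprintf("no procedural blanks for element %s on %s",
                 sample$element, sample$dayId))
  sample$numberConcRaw <- sample$numberConcPerG
  sample$massConcRaw <- sample$massConcNgPerG
  num <- sample$numberConcPerG - mean(b$numberConcPerG)
  mas <- sample$massConcNgPerG - mean(b$massConcNgPerG)
  sample$flooredNumber <- num < 0
  sample$flooredMass <- mas < 0
  sample$numberConcPerG <- max(num, 0)
  sample$massConcNgPerG <- max(mas, 0)
  sample
}

#' Blank-derived detection and quantification limits
#'
#' Per analysis day, the number- and mass-concentration detection limit is
#' the mean + 3 SD of that day's procedural-blank concentrations and the
#' quantification limit the mean + 10 SD (sample SD, n-1); the final
#' concentration limits are the means across days. The mass-per-particle
#' detection limit is taken per day from the day's intensity threshold
#' converted through [eventMass()], and the final value is the maximum across
#' days so that false-negative rates stay comparable between days.
#'
#' @param blankResults data.frame of per-blank results (columns `dayId`,
#'   `numberConcPerG`, `massConcNgPerG`; one element). Days with fewer than
#'   2 blanks are skipped with a warning (SD undefined).
#' @param massLodByDay named numeric: per-day mass-per-particle detection
#'   limit in femtograms (threshold counts converted via [eventMass()] with
#'   that day's calibration).
#' @param element element symbol recorded on the result.
#' @return A [DetectionLimits-class].
#' @examples
#' bl <- data.frame(dayId = "d1", numberConcPerG = 1:12,
#'                  massConcNgPerG = 1:12)
#' detectionLimits(bl, c(d1 = 0.5))
#' @export
detectionLimits <- function(blankResults, massLodByDay, element = "X") {
  days <- unique(as.character(blankResults$dayId))
  if (length(days) < 1L) stop("need blanks from at least one day")
  numLod <- numLoq <- masLod <- masLoq <- numeric(0)
  used <- character(0)
  for (d in days) {
    b <- blankResults[blankResults$dayId == d, , drop = FALSE]
    if (nrow(b) < 2L) {
      warning(sprintf(
        "day %s has %d blank(s); SD undefined, day skipped", d, nrow(b)))
      next
    }
    numLod <- c(numLod, mean(b$numberConcPerG) + 3 * sd(b$numberConcPerG))
    numLoq <- c(numLoq, mean(b$numberConcPerG) + 10 * sd(b$numberConcPerG))
    masLod <- c(masLod, mean(b$massConcNgPerG) + 3 * sd(b$massConcNgPerG))
    masLoq <- c(masLoq, mean(b$massConcNgPerG) + 10 * sd(b$massConcNgPerG))
    used <- c(used, d)
  }
  if (length(used) == 0L) stop("no day had >= 2 blanks")
  mpp <- massLodByDay[names(massLodByDay) %in% used]
  if (length(mpp) == 0L) mpp <- massLodByDay
  new("DetectionLimits", element = element,
      massPerParticleLodFg = max(as.numeric(mpp)),
      numberLod = mean(numLod), numberLoq = mean(numLoq),
      massLod = mean(masLod), massLoq = mean(masLoq),
      dayIds = used)
}

#' Apply detection limits to a sample result
#'
#' Flags the number and mass concentrations censored when at or below the
#' corresponding detection limit.
#'
#' @param sample one-row result data.frame.
#' @param limits a [DetectionLimits-class].
#' @return The flagged result.
#' @export
applyLimits <- function(sample, limits) {
  sample$censoredNumber <- sample$numberConcPerG <= limits@numberLod
  sample$censoredMass <- sample$massConcNgPerG <= limits@massLod
  sample$lodNumber <- limits@numberLod
  sample$lodMass <- limits@massLod
  sample
}
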
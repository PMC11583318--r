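#' Acquisition settings for a single-particle ICP-MS run
#'
#' Holds the time-resolution parameters of one acquisition: the dwell time
#' (integration interval of one detector reading), the total acquisition time,
#' and the sample uptake (flow) rate measured gravimetrically.
#'
#' @slot dwellTime dwell time in seconds (default 1e-4, i.e. 100 us).
#' @slot acquisitionTime total acquisition time in seconds (default 45).
#' @slot flowRate sample uptake rate in mL/min.
#' @seealso [acquisitionSettings()], [nDwells()]
#' @export
setClass("AcquisitionSettings",
  representation(dwellTime = "numeric", acquisitionTime = "numeric",
                 flowRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@dwellTime) != 1L || object@dwellTime <= 0)
      msg <- c(msg, "dwellTime must be a single positive number")
    if (length(object@acquisitionTime) != 1L ||
        object@acquisitionTime < object@dwellTime)
      msg <- c(msg, "acquisitionTime must be >= dwellTime")
    if (length(object@flowRate) != 1L || object@flowRate <= 0)
      msg <- c(msg, "flowRate must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Construct acquisition settings
#'
#' @param dwellTime dwell time in seconds.
#' @param acquisitionTime acquisition time in seconds.
#' @param flowRate sample uptake rate in mL/min.
#' @return An [AcquisitionSettings-class] object.
#' @examples
#' acquisitionSettings(flowRate = 0.5)
#' @export
acquisitionSettings <- function(dwellTime = 1e-4, acquisitionTime = 45,
                                flowRate = 0.5) {
  new("AcquisitionSettings", dwellTime = dwellTime,
      acquisitionTime = acquisitionTime, flowRate = flowRate)
}

#' @rdname nDwells
#' @export
setMethod("nDwells", "AcquisitionSettings", function(x)
  as.integer(floor(x@acquisitionTime / x@dwellTime)))

setMethod("show", "AcquisitionSettings", function(object) {
  cat("AcquisitionSettings: dwell", object@dwellTime * 1e6, "us,",
      "acquisition", object@acquisitionTime, "s,",
      "flow", object@flowRate, "mL/min,",
      nDwells(object), "dwells\n")
})

#' Raw time-resolved intensity trace
#'
#' One acquisition's detector readings: a non-negative integer count per dwell
#' interval, together with the acquisition settings and sample identity.
#'
#' @slot counts integer vector, one count per dwell.
#' @slot settings the [AcquisitionSettings-class] of the acquisition.
#' @slot element element symbol measured (e.g. "Au").
#' @slot sampleId sample identifier.
#' @slot dayId analysis-day identifier (calibrations are per day).
#' @seealso [timeTrace()], [readTrace()], [detectEvents()]
#' @export
setClass("TimeTrace",
  representation(counts = "integer", settings = "AcquisitionSettings",
                 element = "character", sampleId = "character",
                 dayId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@counts) != nDwells(object@settings))
      msg <- c(msg, sprintf("counts has length %d but settings imply %d dwells",
                            length(object@counts), nDwells(object@settings)))
    if (anyNA(object@counts) || any(object@counts < 0L))
      msg <- c(msg, "counts must be non-negative and non-missing")
    if (length(msg)) msg else TRUE
  })

#' Construct a raw time trace
#'
#' @param counts integer counts, one per dwell.
#' @param settings an [AcquisitionSettings-class] object.
#' @param element,sampleId,dayId identity strings.
#' @return A [TimeTrace-class] object.
#' @export
timeTrace <- function(counts, settings, element = "X", sampleId = "sample",
                      dayId = "day1") {
  new("TimeTrace", counts = as.integer(counts), settings = settings,
      element = element, sampleId = sampleId, dayId = dayId)
}

#' @describeIn TimeTrace raw counts per dwell.
#' @param object a `TimeTrace`.
#' @export
setMethod("counts", "TimeTrace", function(object) object@counts)

#' @rdname nDwells
#' @export
setMethod("nDwells", "TimeTrace", function(x) length(x@counts))

setMethod("show", "TimeTrace", function(object) {
  cat("TimeTrace:", object@element, "|", object@sampleId, "|", object@dayId,
      "\n ", nDwells(object), "dwells,",
      "mean", signif(mean(object@counts), 4), "counts/dwell,",
      "max", max(object@counts), "\n")
})

#' Nanoparticle population description
#'
#' The composition and size distribution of a particle population, either as
#' simulation ground truth or as the compositional assumption used to convert
#' element mass to a mass-equivalent spherical diameter.
#'
#' @slot element element symbol quantified.
#' @slot density density of the particle compound in g/cm^3.
#' @slot massFraction mass fraction of the measured element in the compound,
#'   in (0, 1] (1 for a pure-element particle such as gold).
#' @slot medianDiameter median of the lognormal diameter distribution, nm.
#' @slot gsd geometric standard deviation of the diameter distribution
#'   (>= 1; 1 means monodisperse).
#' @slot numberConcentration particles per mL of the presented suspension.
#' @seealso [particlePopulation()], [goldReference()],
#'   [massEquivalentDiameter()]
#' @export
setClass("ParticlePopulation",
  representation(element = "character", density = "numeric",
                 massFraction = "numeric", medianDiameter = "numeric",
                 gsd = "numeric", numberConcentration = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@density <= 0) msg <- c(msg, "density must be > 0")
    if (object@massFraction <= 0 || object@massFraction > 1)
      msg <- c(msg, "massFraction must be in (0, 1]")
    if (object@medianDiameter <= 0)
      msg <- c(msg, "medianDiameter must be > 0")
    if (object@gsd < 1) msg <- c(msg, "gsd must be >= 1")
    if (object@numberConcentration < 0)
      msg <- c(msg, "numberConcentration must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a particle population
#'
#' @param element element symbol.
#' @param density compound density, g/cm^3.
#' @param massFraction element mass fraction of the compound, in (0, 1].
#' @param medianDiameter median diameter, nm.
#' @param gsd geometric SD of the lognormal diameter distribution (>= 1).
#' @param numberConcentration particles per mL of suspension.
#' @return A [ParticlePopulation-class] object.
#' @examples
#' particlePopulation("Au", density = 19.32, medianDiameter = 60,
#'                    numberConcentration = 1e5)
#' @export
particlePopulation <- function(element, density, massFraction = 1,
                               medianDiameter = 60, gsd = 1,
                               numberConcentration = 0) {
  new("ParticlePopulation", element = element, density = density,
      massFraction = massFraction, medianDiameter = medianDiameter,
      gsd = gsd, numberConcentration = numberConcentration)
}

setMethod("show", "ParticlePopulation", function(object) {
  cat("ParticlePopulation:", object@element,
      sprintf("(rho %.3g g/cm3, f %.3g)", object@density, object@massFraction),
      "\n  median d", object@medianDiameter, "nm, gsd", object@gsd,
      ",", format(object@numberConcentration, digits = 4), "particles/mL\n")
})

#' Baseline noise model for simulated traces
#'
#' Poisson baseline counts with an optional slow sinusoidal drift of the mean,
#' emulating dissolved-analyte background plus instrumental drift.
#'
#' @slot baselineMean mean background counts per dwell (Poisson lambda).
#' @slot driftAmplitude amplitude of the sinusoidal drift of the mean,
#'   counts per dwell; must not exceed `baselineMean` so the instantaneous
#'   mean stays non-negative.
#' @slot driftPeriod drift period in seconds (`Inf` disables drift).
#' @seealso [noiseModel()], [simulateTrace()]
#' @export
setClass("NoiseModel",
  representation(baselineMean = "numeric", driftAmplitude = "numeric",
                 driftPeriod = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@baselineMean < 0) msg <- c(msg, "baselineMean must be >= 0")
    if (object@driftAmplitude < 0 ||
        object@driftAmplitude > object@baselineMean)
      msg <- c(msg,
        "driftAmplitude must be in [0, baselineMean] (mean must stay >= 0)")
    if (object@driftPeriod <= 0) msg <- c(msg, "driftPeriod must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a noise model
#'
#' @param baselineMean mean baseline counts per dwell.
#' @param driftAmplitude sinusoidal drift amplitude, counts per dwell.
#' @param driftPeriod drift period, seconds.
#' @return A [NoiseModel-class] object.
#' @export
noiseModel <- function(baselineMean = 1, driftAmplitude = 0,
                       driftPeriod = Inf) {
  new("NoiseModel", baselineMean = baselineMean,
      driftAmplitude = driftAmplitude, driftPeriod = driftPeriod)
}

#' Ionic calibration line
#'
#' Ordinary least-squares line of mean counts per dwell versus dissolved
#' standard concentration, fitted per element and analysis day.
#'
#' @slot slope counts per dwell per (ug/L); must be > 0 for a usable
#'   calibration.
#' @slot intercept counts per dwell.
#' @slot element element symbol.
#' @slot dayId analysis-day identifier.
#' @slot residualSE residual standard error of the fit.
#' @slot slopeSE standard error of the slope.
#' @slot nPoints number of calibration points used.
#' @seealso [fitIonicCalibration()]
#' @export
setClass("IonicCalibration",
  representation(slope = "numeric", intercept = "numeric",
                 element = "character", dayId = "character",
                 residualSE = "numeric", slopeSE = "numeric",
                 nPoints = "integer"),
  validity = function(object) {
    if (object@nPoints < 3L) "a calibration needs at least 3 points" else TRUE
  })

#' @rdname slope
#' @export
setMethod("slope", "IonicCalibration", function(object) object@slope)

#' @rdname intercept
#' @export
setMethod("intercept", "IonicCalibration", function(object) object@intercept)

setMethod("show", "IonicCalibration", function(object) {
  cat("IonicCalibration:", object@element, "|", object@dayId, "\n",
      sprintf(" slope %.4g counts/dwell per ug/L (SE %.3g), intercept %.4g\n",
              object@slope, object@slopeSE, object@intercept),
      sprintf(" %d points, residual SE %.3g\n",
              object@nPoints, object@residualSE))
})

#' Transport efficiency
#'
#' Fraction of nebulized sample reaching the plasma, determined from a
#' reference nanoparticle suspension by the particle-frequency or
#' particle-mass method.
#'
#' @slot eta efficiency as a fraction in (0, 1].
#' @slot method `"frequency"` or `"mass"`.
#' @slot dayId analysis-day identifier.
#' @seealso [transportEfficiencyFrequency()], [transportEfficiencyMass()]
#' @export
setClass("TransportEfficiency",
  representation(eta = "numeric", method = "character", dayId = "character"),
  validity = function(object) {
    msg <- character()
    if (object@eta <= 0 || object@eta > 1)
      msg <- c(msg, "eta must be in (0, 1]")
    if (!object@method %in% c("frequency", "mass"))
      msg <- c(msg, "method must be 'frequency' or 'mass'")
    if (length(msg)) msg else TRUE
  })

#' @rdname eta
#' @export
setMethod("eta", "TransportEfficiency", function(object) object@eta)

setMethod("show", "TransportEfficiency", function(object) {
  cat(sprintf("TransportEfficiency: eta = %.4g (%s method, %s)\n",
              object@eta, object@method, object@dayId))
})

#' Detection and quantification limits for one element
#'
#' Blank-derived concentration limits (mean across analysis days) and the
#' threshold-derived mass-per-particle detection limit (maximum across days,
#' so false-negative rates are comparable between days).
#'
#' @slot element element symbol.
#' @slot massPerParticleLodFg mass-per-particle detection limit, femtograms.
#' @slot numberLod,numberLoq number-concentration limits, particles per g.
#' @slot massLod,massLoq mass-concentration limits, ng per g.
#' @slot dayIds analysis days that contributed.
#' @seealso [detectionLimits()]
#' @export
setClass("DetectionLimits",
  representation(element = "character", massPerParticleLodFg = "numeric",
                 numberLod = "numeric", numberLoq = "numeric",
                 massLod = "numeric", massLoq = "numeric",
                 dayIds = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@numberLod) && !is.na(object@numberLoq) &&
        object@numberLoq < object@numberLod)
      msg <- c(msg, "numberLoq must be >= numberLod")
    if (!is.na(object@massLod) && !is.na(object@massLoq) &&
        object@massLoq < object@massLod)
      msg <- c(msg, "massLoq must be >= massLod")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "DetectionLimits", function(object) {
  cat("DetectionLimits:", object@element,
      sprintf("(%d days)\n", length(object@dayIds)),
      sprintf(" mass/particle LOD %.4g fg\n", object@massPerParticleLodFg),
      sprintf(" number LOD %.4g, LOQ %.4g particles/g\n",
              object@numberLod, object@numberLoq),
      sprintf(" mass LOD %.4g, LOQ %.4g ng/g\n",
              object@massLod, object@massLoq))
})

#' Multi-element, multi-location survey container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with elements as rows and
#' samples (location x parallel) as columns. Assays: `number` (particles per g
#' wet weight), `mass` (ng per g wet weight) and logical censoring masks
#' `censoredNumber` / `censoredMass` flagging values below the detection
#' limit. `colData` carries `location`, `parallel`, `classification`
#' (one of `"anthropogenic"`, `"farm"`, `"natural"`), `season` and optional
#' `shellLength`; `rowData` carries per-element `lodNumber` / `lodMass`.
#'
#' @seealso [surveyExperiment()], [simulateSurvey()], [summarizeSurvey()],
#'   [surveyPca()], [wardCluster()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("SurveyExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    need <- c("number", "mass", "censoredNumber", "censoredMass")
    have <- SummarizedExperiment::assayNames(object)
    if (!all(need %in% have))
      msg <- c(msg, paste("missing assays:",
                          paste(setdiff(need, have), collapse = ", ")))
    cd <- SummarizedExperiment::colData(object)
    for (col in c("location", "parallel", "classification"))
      if (!col %in% colnames(cd))
        msg <- c(msg, sprintf("colData must contain '%s'", col))
    if ("classification" %in% colnames(cd)) {
      cls <- as.character(cd$classification)
      bad <- setdiff(unique(cls), c("anthropogenic", "farm", "natural"))
      if (length(bad))
        msg <- c(msg, paste("invalid classification value(s):",
                            paste(bad, collapse = ", ")))
    }
    if (all(need %in% have)) {
      for (cm in c("censoredNumber", "censoredMass"))
        if (!is.logical(SummarizedExperiment::assay(object, cm)))
          msg <- c(msg, sprintf("assay '%s' must be logical", cm))
    }
    if (length(msg)) msg else TRUE
  })

#' Principal component analysis result with group mean ellipses
#'
#' @slot loadings orthonormal loading matrix (elements x components).
#' @slot scores score matrix (locations x components).
#' @slot explainedVariance fraction of variance per component (sums to 1).
#' @slot ellipses data.frame of 95% confidence ellipses of the group means:
#'   columns `group`, `cx`, `cy` (centre in PC1/PC2), `a`, `b` (semi-axes),
#'   `angle` (radians, orientation of the major axis), `level`, `n`.
#' @slot groups group label per score row.
#' @seealso [surveyPca()]
#' @export
setClass("PcaResult",
  representation(loadings = "matrix", scores = "matrix",
                 explainedVariance = "numeric", ellipses = "data.frame",
                 groups = "character"))

setMethod("show", "PcaResult", function(object) {
  ev <- round(100 * object@explainedVariance[seq_len(
    min(3L, length(object@explainedVariance)))], 1)
  cat("PcaResult:", nrow(object@scores), "observations,",
      nrow(object@loadings), "variables\n",
      " explained variance (%):", paste(ev, collapse = ", "),
      if (length(object@explainedVariance) > 3L) "..." else "", "\n",
      " groups:", paste(unique(object@groups), collapse = ", "), "\n")
})
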
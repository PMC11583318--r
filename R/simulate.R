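## Synthetic raw traces, calibration standards and survey datasets with known
## ground truth. The generator is the reference against which the detector and
## quantification stages are validated, so its physics is deliberately simple
## and fully documented: Poisson baseline counts, homogeneous Poisson particle
## arrivals, triangular multi-dwell transients, lognormal particle sizes.

## Per-dwell drifting baseline mean, counts/dwell.
.baselineMu <- function(noise, settings) {
  nd <- nDwells(settings)
  if (noise@driftAmplitude == 0 || !is.finite(noise@driftPeriod))
    return(rep(noise@baselineMean, nd))
  t <- (seq_len(nd) - 0.5) * settings@dwellTime
  noise@baselineMean +
    noise@driftAmplitude * sin(2 * pi * t / noise@driftPeriod)
}

## counts expected from one gram... no: expected total counts for an event of
## element mass m grams, given ionic response b (counts/dwell per ug/L),
## transport efficiency eta and flow. A dissolved concentration C ug/L
## delivers eta * q[L/s] * t_dwell * C micrograms to the plasma per dwell and
## produces b * C counts, so the detector yields b / (eta q t_dwell) counts
## per microgram of analyte.
.countsPerGram <- function(ionicResponse, eta, settings) {
  1e6 * ionicResponse / (eta * .flowLitrePerSec(settings) *
                           settings@dwellTime)
}

## Triangular weights over a span of s dwells, summing to 1.
.triangleWeights <- function(s) {
  mid <- (s + 1) / 2
  w <- mid - abs(seq_len(s) - mid)
  w / sum(w)
}

#' Simulate a raw single-particle ICP-MS trace
#'
#' Generates one acquisition of integer counts per dwell: Poisson baseline
#' noise (optionally drifting) plus multi-dwell particle transients. Particle
#' arrivals follow a homogeneous Poisson process over dwells with expectation
#' `numberConcentration x flowRate x acquisitionTime x transportEfficiency`;
#' coincident events are allowed and recorded. Each particle's element mass is
#' drawn from the population's lognormal size distribution and converted to
#' expected counts through the ionic response, transport efficiency and flow
#' (the same relation [eventMass()] later inverts); the expected counts are
#' spread triangularly over a transient of `spanRange` dwells and realized as
#' one Poisson draw per dwell together with the baseline.
#'
#' @param settings an [AcquisitionSettings-class].
#' @param population a [ParticlePopulation-class]; its `numberConcentration`
#'   (particles/mL) sets the event rate.
#' @param noise a [NoiseModel-class].
#' @param transportEfficiency true transport efficiency, in (0, 1].
#' @param ionicResponse true ionic sensitivity, counts per dwell per (ug/L).
#' @param seed integer seed; identical seeds give identical traces.
#' @param spanRange integer range of transient durations in dwells
#'   (default 3--7, i.e. 0.3--0.7 ms at 100 us dwell).
#' @param nEvents optional fixed event count overriding the Poisson draw
#'   (useful for constructing exact fixtures).
#' @return A list with elements `trace` (a [TimeTrace-class]) and `truth`,
#'   itself a list with `events` (data.frame: `start`, `span`, `mass` in
#'   grams), `eta`, `ionicResponse` and `numberConcentration`.
#' @examples
#' s <- acquisitionSettings(acquisitionTime = 1, flowRate = 0.5)
#' p <- particlePopulation("Au", 19.32, medianDiameter = 60, gsd = 1.05,
#'                         numberConcentration = 1e5)
#' sim <- simulateTrace(s, p, noiseModel(1), 0.05, 5, seed = 1)
#' nrow(sim$truth$events)
#' @export
simulateTrace <- function(settings, population, noise, transportEfficiency,
                          ionicResponse, seed, spanRange = c(3L, 7L),
                          nEvents = NULL) {
  stopifnot(is(settings, "AcquisitionSettings"),
            is(population, "ParticlePopulation"), is(noise, "NoiseModel"))
  .assertNumber(transportEfficiency, "transportEfficiency", 0, 1,
                strict_lower = TRUE)
  .assertNumber(ionicResponse, "ionicResponse", 0, strict_lower = TRUE)
  nd <- nDwells(settings)
  expected <- population@numberConcentration * settings@flowRate *
    .acqMinutes(settings) * transportEfficiency
  if (expected > nd)
    stop(sprintf(paste("impossible geometry: %.3g expected events exceed the",
                       "%d dwells of the acquisition; reduce the number",
                       "concentration or lengthen the acquisition"),
                 expected, nd))

  withSeed(seed, {
    n <- if (is.null(nEvents)) rpois(1L, expected) else as.integer(nEvents)
    mu <- .baselineMu(noise, settings)
    if (n > 0L) {
      start <- sample.int(nd, n, replace = TRUE)
      span <- sample(seq.int(spanRange[1], spanRange[2]), n, replace = TRUE)
      diam <- rlnorm(n, meanlog = log(population@medianDiameter),
                     sdlog = log(population@gsd))
      mass <- .sphereMassG(diam, population@density, population@massFraction)
      cpg <- .countsPerGram(ionicResponse, transportEfficiency, settings)
      idx <- vector("list", n)
      val <- vector("list", n)
      for (i in seq_len(n)) {
        j <- start[i] + seq_len(span[i]) - 1L
        keep <- j <= nd
        w <- .triangleWeights(span[i])[keep]
        idx[[i]] <- j[keep]
        val[[i]] <- mass[i] * cpg * w
      }
      idx <- unlist(idx); val <- unlist(val)
      add <- rowsum(val, idx)
      mu[as.integer(rownames(add))] <- mu[as.integer(rownames(add))] + add[, 1]
      events <- data.frame(start = start, span = span, mass = mass)
      events <- events[order(events$start), , drop = FALSE]
      rownames(events) <- NULL
    } else {
      events <- data.frame(start = integer(), span = integer(),
                           mass = numeric())
    }
    cts <- rpois(nd, mu)
    trace <- timeTrace(cts, settings, element = population@element)
    list(trace = trace,
         truth = list(events = events, eta = transportEfficiency,
                      ionicResponse = ionicResponse,
                      numberConcentration = population@numberConcentration))
  })
}

#' Simulate an ionic (dissolved) calibration standard trace
#'
#' Counts per dwell are Poisson with mean
#' `baseline + ionicResponse x concentration`.
#'
#' @param settings an [AcquisitionSettings-class].
#' @param concentration dissolved standard concentration, ug/L (>= 0).
#' @param ionicResponse true sensitivity, counts per dwell per (ug/L).
#' @param noise a [NoiseModel-class].
#' @param seed integer seed.
#' @param element element symbol recorded on the trace.
#' @return A [TimeTrace-class].
#' @export
simulateIonicStandard <- function(settings, concentration, ionicResponse,
                                  noise, seed, element = "X") {
  .assertNumber(concentration, "concentration", 0)
  .assertNumber(ionicResponse, "ionicResponse", 0)
  withSeed(seed, {
    mu <- .baselineMu(noise, settings) + ionicResponse * concentration
    timeTrace(rpois(nDwells(settings), mu), settings, element = element,
              sampleId = sprintf("std_%g", concentration))
  })
}

## The eleven survey elements with typical survey magnitudes: median particle
## number concentration per g wet weight and a representative mean element
## mass per particle (g) used to derive the mass assay.
.surveyElementDefaults <- function() {
  data.frame(
    element = c("Ag", "Al", "Ba", "Ce", "Cu", "Fe",
                "Mn", "Pb", "Si", "Ti", "Zr"),
    medianNumber = c(5e6, 6e8, 1e7, 8e7, 1e7, 6e8,
                     2.5e7, 2e7, 6e8, 4e7, 7e6),
    massPerParticle = c(4e-16, 5e-16, 1e-16, 4e-17, 1.2e-16, 1e-15,
                        2.5e-16, 5e-17, 3e-15, 1.2e-15, 2e-17))
}

#' Simulate a multi-location nanoparticle survey
#'
#' Generates a [SurveyExperiment-class] emulating a coastal monitoring survey:
#' lognormal per-location concentrations for each element, multiplicative
#' location-class and season effects, triplicate parallels per location, and
#' censoring of values below a per-element detection limit set at the
#' `censoringRate` quantile of the marginal concentration distribution.
#'
#' @param nLocations number of sampling locations (>= 2; default 69).
#' @param elements character vector of element symbols (default: the eleven
#'   surveyed elements).
#' @param classEffects named list mapping an element to a named numeric vector
#'   of multiplicative effects per classification, e.g.
#'   `list(Pb = c(anthropogenic = 10))`. Unlisted elements/classes get 1.
#' @param seasonEffects same structure keyed by season
#'   (`"DJF"`, `"MAM"`, `"JJA"`, `"SON"`).
#' @param censoringRate per-element fraction of values expected below the
#'   detection limit (recycled; default 0.2).
#' @param seed integer seed.
#' @param nParallels parallels (replicate preparations) per location
#'   (default 3).
#' @param classProportions numeric proportions for farm / anthropogenic /
#'   natural locations (default 47:18:4, the survey design).
#' @param siteSdlog lognormal SD (log scale) of a shared per-location burden
#'   factor applied to every element: samples from the same site share an
#'   overall particle load (filtration activity, resuspension), which is what
#'   makes element concentrations correlate within locations.
#' @param locationSdlog,parallelSdlog lognormal SD (log scale) of the
#'   element-specific between-location variation and of parallels within a
#'   location.
#' @return A [SurveyExperiment-class]; `metadata()$truth` records the
#'   generating parameters (per-element `meanlog`, `sdlog`, effects, LODs).
#' @examples
#' se <- simulateSurvey(nLocations = 10, elements = c("Pb", "Ti"), seed = 1)
#' dim(se)
#' @export
simulateSurvey <- function(nLocations = 69, elements = NULL,
                           classEffects = list(), seasonEffects = list(),
                           censoringRate = 0.2, seed = 1, nParallels = 3,
                           classProportions = c(farm = 47, anthropogenic = 18,
                                                natural = 4),
                           siteSdlog = 0.6, locationSdlog = 0.5,
                           parallelSdlog = 0.2) {
  if (nLocations < 2) stop("'nLocations' must be >= 2")
  defaults <- .surveyElementDefaults()
  if (is.null(elements)) elements <- defaults$element
  if (length(elements) == 0L) stop("'elements' must not be empty")
  if (any(!vapply(classEffects, function(x) all(x > 0), TRUE)) ||
      any(!vapply(seasonEffects, function(x) all(x > 0), TRUE)))
    stop("effects must be positive multipliers")
  censoringRate <- rep_len(censoringRate, length(elements))
  names(censoringRate) <- elements

  base <- defaults[match(elements, defaults$element), ]
  base$element <- elements
  base$medianNumber[is.na(base$medianNumber)] <- 1e7
  base$massPerParticle[is.na(base$massPerParticle)] <- 1e-16

  withSeed(seed, {
    cls <- rep(names(classProportions),
               times = diff(round(cumsum(c(0, classProportions)) /
                                    sum(classProportions) * nLocations)))
    cls <- rep_len(cls, nLocations)[sample.int(nLocations)]
    month <- sample.int(12L, nLocations, replace = TRUE)
    season <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
                "JJA", "JJA", "SON", "SON", "SON", "DJF")[month]
    shell <- round(pmin(7.4, pmax(2.4, rnorm(nLocations, 4, 0.8))), 1)
    loc <- sprintf("loc%02d", seq_len(nLocations))
    site <- rnorm(nLocations, 0, siteSdlog)

    nSamp <- nLocations * nParallels
    sloc <- rep(seq_len(nLocations), each = nParallels)
    effectOf <- function(tab, el, key) {
      v <- tab[[el]]
      if (is.null(v) || is.na(v[key]) || !key %in% names(v)) 1 else v[[key]]
    }
    number <- matrix(NA_real_, length(elements), nSamp,
                     dimnames = list(elements, sprintf("%s_p%d", loc[sloc],
                                                       rep(seq_len(nParallels),
                                                           nLocations))))
    mass <- number
    sigma <- sqrt(siteSdlog^2 + locationSdlog^2 + parallelSdlog^2)
    lodNumber <- lodMass <- numeric(length(elements))
    for (k in seq_along(elements)) {
      el <- elements[k]
      mlog <- log(base$medianNumber[k])
      locEff <- vapply(seq_len(nLocations), function(i)
        log(effectOf(classEffects, el, cls[i])) +
          log(effectOf(seasonEffects, el, season[i])), 0)
      locVal <- mlog + site + locEff + rnorm(nLocations, 0, locationSdlog)
      v <- exp(locVal[sloc] + rnorm(nSamp, 0, parallelSdlog))
      number[k, ] <- v
      mpp <- base$massPerParticle[k]
      mass[k, ] <- v * mpp * 1e9 * exp(rnorm(nSamp, 0, 0.05))
      lodNumber[k] <- qlnorm(censoringRate[k], mlog, sigma)
      lodMass[k] <- lodNumber[k] * mpp * 1e9
    }
    censN <- sweep(number, 1, lodNumber, "<")
    censM <- sweep(mass, 1, lodMass, "<")

    se <- surveyExperiment(
      number = number, mass = mass,
      censoredNumber = censN, censoredMass = censM,
      location = loc[sloc],
      parallel = rep(seq_len(nParallels), nLocations),
      classification = cls[sloc], season = season[sloc],
      shellLength = shell[sloc],
      lodNumber = lodNumber, lodMass = lodMass)
    metadata(se)$truth <- list(
      meanlog = stats::setNames(log(base$medianNumber), elements),
      siteSdlog = siteSdlog, locationSdlog = locationSdlog,
      parallelSdlog = parallelSdlog, siteFactor = site,
      massPerParticle = stats::setNames(base$massPerParticle, elements),
      classEffects = classEffects, seasonEffects = seasonEffects,
      censoringRate = censoringRate, lodNumber = lodNumber,
      lodMass = lodMass, seed = seed)
    se
  })
}
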
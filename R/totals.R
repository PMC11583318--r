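## Total element quantification from full-digest intensities, blank-based
## detection limits, dry-to-wet back-calculation, particle fractions and
## particle/total correlations.

#' Total element concentration of a digested sample
#'
#' Converts a digest intensity to concentration through the ionic calibration
#' (`(I - a) / b`, ug/L of digest), scales by the digest volume over the dry
#' tissue mass, and back-calculates to a wet-weight basis with the sample's
#' dry-weight fraction as a multiplicative factor. The detection limit, when
#' supplied, is on the dry-weight basis and converted alongside.
#'
#' @param intensity mean counts per dwell of the digest run.
#' @param calib an [IonicCalibration-class] (slope > 0).
#' @param digestMass dry tissue mass digested, grams (e.g. 0.2).
#' @param finalMass final gravimetric dilution, grams (= mL of digest;
#'   e.g. 25).
#' @param dryWeightFraction dry/wet mass ratio of the tissue, in (0, 1].
#' @param lodDry optional detection limit on the dry-weight basis, ng/g dry.
#' @param element,sampleId identity strings.
#' @return One-row data.frame: `sampleId`, `element`, `concNgPerGWw` (ng per
#'   g wet weight), `lod` (ng/g wet weight, NA if not supplied), `censored`,
#'   `dryWeightFraction`, `belowIntercept` (TRUE when the intensity fell
#'   below the calibration intercept and the concentration was floored at 0).
#' @examples
#' cal <- fitIonicCalibration(lapply(c(0, 20, 200), function(k)
#'   list(concentration = k, meanCounts = 2 * k)))
#' totalConcentration(80, cal, digestMass = 0.2, finalMass = 25,
#'                    dryWeightFraction = 0.2)
#' @export
totalConcentration <- function(intensity, calib, digestMass, finalMass,
                               dryWeightFraction, lodDry = NA_real_,
                               element = NULL, sampleId = "sample") {
  .assertNumber(digestMass, "digestMass", 0, strict_lower = TRUE)
  .assertNumber(finalMass, "finalMass", 0, strict_lower = TRUE)
  .assertNumber(dryWeightFraction, "dryWeightFraction", 0, 1,
                strict_lower = TRUE)
  if (slope(calib) <= 0) stop("calibration slope must be > 0")
  concUgL <- (intensity - intercept(calib)) / slope(calib)
  below <- concUgL < 0
  concUgL <- max(concUgL, 0)
  finalVolumeL <- finalMass / 1000  # gravimetric: 1 g == 1 mL
  dryNgPerG <- concUgL * 1000 * finalVolumeL / digestMass
  wet <- dryNgPerG * dryWeightFraction
  lodWet <- if (is.na(lodDry)) NA_real_ else lodDry * dryWeightFraction
  data.frame(sampleId = sampleId, element = element %||% calib@element,
             concNgPerGWw = wet, lod = lodWet,
             censored = if (is.na(lodWet)) NA else wet <= lodWet,
             dryWeightFraction = dryWeightFraction,
             belowIntercept = below)
}

#' Blank-based detection limit for total element analysis
#'
#' Three times the sample standard deviation of the procedural blanks. The
#' element rule selects how many blanks enter the computation: 12 by default,
#' 6 for silver.
#'
#' @param blankValues numeric blank results (same units as the measurement).
#' @param element element symbol; `"Ag"` selects the 6-blank rule.
#' @return The detection limit, `3 * sd(blanks used)`.
#' @examples
#' totalLod(1:12)         # 3 * sd(1:12) = 10.817
#' @export
totalLod <- function(blankValues, element = "") {
  nRequired <- if (identical(element, "Ag")) 6L else 12L
  if (length(blankValues) < 2L)
    stop("need at least 2 blank values")
  if (length(blankValues) < nRequired)
    warning(sprintf("element rule asks for %d blanks, %d available; using all",
                    nRequired, length(blankValues)))
  used <- head(blankValues, nRequired)
  3 * sd(used)
}

#' Particle fraction of the total element concentration
#'
#' Particulate mass concentration as a percentage of the total element
#' concentration. Censored operands propagate: a value below the detection
#' limit on either side yields `NA` (the pair is excluded), matching the rule
#' that sub-LOD concentrations enter no derived quantity.
#'
#' @param particleMassConc particle mass concentration, ng/g ww (vectorized).
#' @param totalConc total element concentration, ng/g ww.
#' @param particleCensored,totalCensored logical censoring flags.
#' @return Percent values, `NA` where censored.
#' @examples
#' particleFraction(1, 100)   # 1 percent
#' @export
particleFraction <- function(particleMassConc, totalConc,
                             particleCensored = FALSE,
                             totalCensored = FALSE) {
  n <- max(length(particleMassConc), length(totalConc))
  p <- rep_len(particleMassConc, n)
  tot <- rep_len(totalConc, n)
  pc <- rep_len(particleCensored, n)
  tc <- rep_len(totalCensored, n)
  if (any(tot[!tc & !is.na(tot)] == 0))
    stop("total concentration must be > 0 for uncensored pairs")
  out <- 100 * p / tot
  out[pc | tc | is.na(pc) | is.na(tc)] <- NA_real_
  out
}

#' Particle/total correlation per element
#'
#' Squared Pearson correlation between particle mass concentrations and total
#' element concentrations across locations, censored pairs excluded.
#'
#' @param particleMassConc,totalConc paired concentrations.
#' @param particleCensored,totalCensored logical censoring flags.
#' @return `R^2` of the uncensored pairs.
#' @export
particleTotalCorrelation <- function(particleMassConc, totalConc,
                                     particleCensored = FALSE,
                                     totalCensored = FALSE) {
  n <- length(particleMassConc)
  keep <- !(rep_len(particleCensored, n) | rep_len(totalCensored, n)) &
    !is.na(particleMassConc) & !is.na(totalConc)
  if (sum(keep) < 3L)
    stop("need at least 3 uncensored pairs")
  cor(particleMassConc[keep], totalConc[keep])^2
}
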
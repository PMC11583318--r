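## Baseline estimation, Poisson false-positive thresholding and
## maximum-peak-intensity event discrimination.

#' Rolling-median baseline of a raw trace
#'
#' Estimates the per-dwell background level as the median of counts in a
#' centred window, the standard robust approximation of the dissolved-analyte
#' background in single-particle ICP-MS: particle transients occupy only a few
#' dwells and so never move the median of a long window. Near the trace edges
#' the window shrinks symmetrically.
#'
#' @param trace a [TimeTrace-class] (or bare numeric vector of counts).
#' @param window odd window length in dwells, between 3 and the trace length.
#'   The default 1001 (~0.1 s at 100 us dwell) is long relative to transients
#'   (a few dwells) and short relative to instrumental drift.
#' @return Numeric vector of baseline values, same length as the trace,
#'   all >= 0.
#' @examples
#' rollingMedianBaseline(c(1, 1, 5, 1, 1), window = 3)
#' @export
rollingMedianBaseline <- function(trace, window = 1001L) {
  x <- if (is(trace, "TimeTrace")) counts(trace) else trace
  if (window %% 2 == 0 || window < 3 || window > length(x))
    stop(sprintf(
      "'window' must be odd and in [3, %d] (got %s)", length(x), window))
  as.numeric(stats::runmed(as.numeric(x), k = window, endrule = "median"))
}

#' Poisson intensity threshold from a false-positive-rate criterion
#'
#' Smallest integer count `T` such that a pure-noise dwell with Poisson mean
#' `lambda` exceeds it rarely enough that at most `fpRate` false particle
#' detections are expected per minute of dwells:
#' `P(X >= T) <= fpRate x dwellTime / 60`.
#' The baseline estimate is used as a real number; no integer rounding is
#' applied to `lambda`, avoiding threshold quantization.
#'
#' @param lambda baseline mean counts per dwell (vectorized, >= 0).
#' @param fpRate tolerated false positives per minute (default 1).
#' @param dwellTime dwell time in seconds (default 1e-4).
#' @return Integer threshold(s), >= 1.
#' @examples
#' poissonThreshold(0)          # 1: any nonzero count is significant
#' poissonThreshold(1)          # at 100 us dwell and 1 fp/min
#' @export
poissonThreshold <- function(lambda, fpRate = 1, dwellTime = 1e-4) {
  if (any(is.na(lambda)) || any(lambda < 0))
    stop("'lambda' must be non-negative")
  .assertNumber(fpRate, "fpRate", 0, strict_lower = TRUE)
  .assertNumber(dwellTime, "dwellTime", 0, strict_lower = TRUE)
  alpha <- fpRate * dwellTime / 60
  ## qpois(..., lower.tail = FALSE) returns the smallest x with
  ## P(X > x) <= alpha, so T = x + 1 is the smallest T with P(X >= T) <= alpha
  T <- qpois(alpha, lambda, lower.tail = FALSE) + 1L
  pmax(T, 1L)
}

## Robust global background rate: iteratively exclude dwells at or above the
## current Poisson threshold (particle cores) and re-estimate the mean. Needed
## because the median of low-rate Poisson counts (lambda << 1) is 0 and
## carries no rate information, while the plain mean is inflated by particle
## events.
.robustLambda <- function(x, fpRate, dwell) {
  lam <- mean(x)
  for (i in 1:4) {
    T <- poissonThreshold(lam, fpRate, dwell)
    keep <- x < T
    if (!any(keep)) return(0)
    lam2 <- mean(x[keep])
    if (abs(lam2 - lam) < 1e-9) return(lam2)
    lam <- lam2
  }
  lam
}

#' Detect and integrate particle events in a raw trace
#'
#' Candidate peaks are maximal runs of dwells with counts strictly above the
#' rolling-median baseline; runs separated by at most `gapMerge` sub-baseline
#' dwells are merged (robustness to single-dwell dropouts inside a transient).
#' A candidate is kept as a particle event iff its maximum raw count reaches
#' the Poisson threshold computed from the local baseline at that maximum
#' ([poissonThreshold()]); the event integral is the baseline-corrected sum
#' over the event span, with per-dwell contributions clipped at zero so noise
#' troughs inside an event cannot subtract signal.
#'
#' @param trace a [TimeTrace-class].
#' @param baseline baseline vector from [rollingMedianBaseline()] (computed
#'   with `window` if omitted).
#' @param fpRate tolerated false positives per minute (default 1).
#' @param gapMerge maximum sub-baseline gap (dwells) bridged inside one event
#'   (default 2).
#' @param window rolling-median window used when `baseline` is not supplied.
#'   In that case the rate entering the Poisson threshold is the rolling
#'   median floored by a robust global background estimate (the trace mean
#'   after iteratively excluding above-threshold dwells), and near the trace
#'   edges (within half a window) the first/last full-window baseline value
#'   is used. Both guards exist because a median is a poor *rate* estimate
#'   exactly where the threshold needs one: the median of Poisson counts with
#'   a rate below ~0.7 is 0 regardless of the rate, and the shrunk edge
#'   windows degenerate to a handful of dwells. A supplied `baseline` is used
#'   as given, for both integration and thresholding.
#' @return A data.frame with one row per event: `start`, `end` (dwell indices,
#'   inclusive), `maxIntensity` (raw counts), `integral` (baseline-corrected
#'   counts), `localBaseline` (counts/dwell at the maximum), `threshold`.
#' @examples
#' s <- acquisitionSettings(dwellTime = 1, acquisitionTime = 9)
#' tr <- timeTrace(c(0, 0, 0, 5, 9, 5, 0, 0, 0), s)
#' detectEvents(tr, baseline = rep(0, 9))
#' @export
detectEvents <- function(trace, baseline = NULL, fpRate = 1, gapMerge = 2L,
                         window = 1001L) {
  stopifnot(is(trace, "TimeTrace"))
  x <- as.numeric(counts(trace))
  thrBase <- baseline
  if (is.null(baseline)) {
    baseline <- rollingMedianBaseline(trace, window)
    ## threshold noise level: stabilize the shrunk-window edges and floor by
    ## the robust global rate (the median of low-rate Poisson counts is 0)
    thrBase <- baseline
    h <- (window - 1) / 2
    if (length(x) > window) {
      thrBase[seq_len(h)] <- baseline[h + 1]
      thrBase[(length(x) - h + 1):length(x)] <- baseline[length(x) - h]
    }
    thrBase <- pmax(thrBase,
                    .robustLambda(x, fpRate, trace@settings@dwellTime))
  }
  if (length(baseline) != length(x))
    stop("'baseline' length must match the trace")
  if (any(baseline < 0)) stop("'baseline' must be non-negative")
  dwell <- trace@settings@dwellTime

  pos <- which(x > baseline)
  if (length(pos) == 0L) return(.emptyEvents())
  ## above-baseline runs, with gaps of <= gapMerge dwells bridged: two above
  ## dwells separated by g sub-baseline dwells have index difference g + 1
  runId <- cumsum(c(TRUE, diff(pos) > gapMerge + 1L))
  first <- which(!duplicated(runId))
  runStart <- pos[first]
  runEnd <- pos[c(first[-1L] - 1L, length(pos))]

  ## prefilter: a run can only pass the max-peak criterion if at least one of
  ## its dwells reaches the pointwise threshold (the maximum is such a dwell)
  thrPos <- poissonThreshold(thrBase[pos], fpRate, dwell)
  candidate <- sort(unique(runId[x[pos] >= thrPos]))
  if (length(candidate) == 0L) return(.emptyEvents())

  n <- length(candidate)
  start <- runStart[candidate]
  end <- runEnd[candidate]
  maxI <- numeric(n); imax <- integer(n); integral <- numeric(n)
  for (i in seq_len(n)) {
    span <- start[i]:end[i]
    j <- span[which.max(x[span])]
    imax[i] <- j
    maxI[i] <- x[j]
    integral[i] <- sum(pmax(x[span] - baseline[span], 0))
  }
  lb <- thrBase[imax]
  thr <- poissonThreshold(lb, fpRate, dwell)
  keep <- maxI >= thr
  ev <- data.frame(start = start[keep], end = end[keep],
                   maxIntensity = maxI[keep], integral = integral[keep],
                   localBaseline = lb[keep], threshold = thr[keep])
  rownames(ev) <- NULL
  ev
}

.emptyEvents <- function() {
  data.frame(start = integer(), end = integer(), maxIntensity = numeric(),
             integral = numeric(), localBaseline = numeric(),
             threshold = integer())
}
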
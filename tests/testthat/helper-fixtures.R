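## Shared fixtures: short acquisitions keep unit tests fast; the statistical
## checks use the full 45 s acquisition geometry where rates matter.

fastSettings <- function(acquisitionTime = 2, flowRate = 0.5)
  acquisitionSettings(acquisitionTime = acquisitionTime, flowRate = flowRate)

fullSettings <- function() acquisitionSettings(flowRate = 0.5)

gold60 <- function(numberConcentration = 3e4, gsd = 1.05)
  particlePopulation("Au", density = 19.32, massFraction = 1,
                     medianDiameter = 60, gsd = gsd,
                     numberConcentration = numberConcentration)

## Exact calibration with a known slope, bypassing trace simulation.
exactCalibration <- function(slope = 5, intercept = 1, element = "Au",
                             dayId = "day1") {
  suppressWarnings(fitIonicCalibration(
    lapply(c(0, 20, 200), function(k)
      list(concentration = k, meanCounts = intercept + slope * k)),
    element = element, dayId = dayId))
}

## Brute-force Poisson tail threshold: smallest T with P(X >= T) <= alpha,
## by direct summation of the tail over k = T..kmax.
bruteThreshold <- function(lambda, alpha, kmax = 300) {
  for (T in 0:kmax) {
    if (sum(dpois(T:kmax, lambda)) <= alpha) return(T)
  }
  stop("no threshold below kmax")
}

## Exhaustive Ward oracle: at every step enumerate all cluster pairs, compute
## the increase in total within-cluster sum of squares from scratch (member
## lists and centroids, no Lance-Williams recurrence), merge the minimum.
## Heights reported as sqrt(2 * deltaSSQ), the ward.D2 convention.
wardOracle <- function(x) {
  ssq <- function(idx) {
    ctr <- colMeans(x[idx, , drop = FALSE])
    sum(sweep(x[idx, , drop = FALSE], 2, ctr)^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    bestd <- Inf; best <- NULL
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- ssq(c(clusters[[i]], clusters[[j]])) -
          ssq(clusters[[i]]) - ssq(clusters[[j]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    merges <- c(merges, list(sort(c(clusters[[best[1]]],
                                    clusters[[best[2]]]))))
    heights <- c(heights, sqrt(2 * bestd))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

## Cluster memberships formed at each merge of an hclust tree.
hclustMerges <- function(hc) {
  members <- list()
  out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- sort(c(get(hc$merge[k, 1]), get(hc$merge[k, 2])))
    out[[k]] <- members[[k]]
  }
  out
}
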
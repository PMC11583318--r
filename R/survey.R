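## Survey aggregation: censoring-aware summaries, z-scoring, PCA with group
## mean ellipses, Ward hierarchical clustering.

#' Construct a survey container
#'
#' Assembles number/mass concentration matrices (elements x samples), their
#' censoring masks and sample metadata into a [SurveyExperiment-class].
#'
#' @param number,mass numeric matrices, elements x samples.
#' @param censoredNumber,censoredMass logical matrices of the same shape
#'   (default: nothing censored).
#' @param location,parallel,classification,season,shellLength per-sample
#'   metadata; `classification` must be `"anthropogenic"`, `"farm"` or
#'   `"natural"`.
#' @param lodNumber,lodMass per-element detection limits (particles/g, ng/g).
#' @return A [SurveyExperiment-class].
#' @export
surveyExperiment <- function(number, mass,
                             censoredNumber = NULL, censoredMass = NULL,
                             location, parallel = 1L,
                             classification = "natural", season = NA,
                             shellLength = NA_real_,
                             lodNumber = NA_real_, lodMass = NA_real_) {
  number <- as.matrix(number); mass <- as.matrix(mass)
  if (is.null(censoredNumber))
    censoredNumber <- matrix(FALSE, nrow(number), ncol(number),
                             dimnames = dimnames(number))
  if (is.null(censoredMass))
    censoredMass <- matrix(FALSE, nrow(mass), ncol(mass),
                           dimnames = dimnames(mass))
  ns <- ncol(number)
  cd <- DataFrame(location = rep_len(location, ns),
                  parallel = rep_len(parallel, ns),
                  classification = rep_len(classification, ns),
                  season = rep_len(season, ns),
                  shellLength = rep_len(shellLength, ns),
                  row.names = colnames(number))
  rd <- DataFrame(lodNumber = rep_len(lodNumber, nrow(number)),
                  lodMass = rep_len(lodMass, nrow(number)),
                  row.names = rownames(number))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(number = number, mass = mass,
                  censoredNumber = censoredNumber,
                  censoredMass = censoredMass),
    colData = cd, rowData = rd)
  new("SurveyExperiment", se)
}

.assayFor <- function(what) switch(what, number = "censoredNumber",
                                   mass = "censoredMass")
.lodFor <- function(what) switch(what, number = "lodNumber",
                                 mass = "lodMass")

#' Location means of a survey assay
#'
#' Collapses the triplicate parallels of each location to a location mean,
#' computed over uncensored parallels only; a location with no uncensored
#' parallel, or whose mean does not exceed the element's detection limit, is
#' censored (`NA`).
#'
#' @param se a [SurveyExperiment-class].
#' @param what `"number"` or `"mass"`.
#' @return A list: `values` (locations x elements matrix, `NA` = censored),
#'   `classification`, `season` (per location, from the first parallel),
#'   `lod` (per element).
#' @export
locationMeans <- function(se, what = c("number", "mass")) {
  what <- match.arg(what)
  v <- SummarizedExperiment::assay(se, what)
  cens <- SummarizedExperiment::assay(se, .assayFor(what))
  lod <- SummarizedExperiment::rowData(se)[[.lodFor(what)]]
  cd <- SummarizedExperiment::colData(se)
  locs <- unique(as.character(cd$location))
  m <- matrix(NA_real_, length(locs), nrow(se),
              dimnames = list(locs, rownames(se)))
  for (li in seq_along(locs)) {
    idx <- which(cd$location == locs[li])
    for (k in seq_len(nrow(se))) {
      ok <- idx[!cens[k, idx]]
      if (length(ok)) m[li, k] <- mean(v[k, ok])
    }
  }
  ## censor location means at or below the detection limit
  if (!all(is.na(lod)))
    for (k in seq_len(ncol(m)))
      if (!is.na(lod[k])) m[!is.na(m[, k]) & m[, k] <= lod[k], k] <- NA
  firsts <- match(locs, as.character(cd$location))
  list(values = m,
       classification = as.character(cd$classification)[firsts],
       season = as.character(cd$season)[firsts],
       lod = stats::setNames(lod, rownames(se)))
}

#' Per-element survey summary
#'
#' For each element: the mean and range of the uncensored location means and
#' the percentage of locations whose mean exceeds the detection limit.
#'
#' @param se a [SurveyExperiment-class].
#' @param what `"number"` or `"mass"`.
#' @return data.frame with columns `element`, `mean`, `min`, `max`,
#'   `pctAboveLod`, `nLocations`. `mean`/`min`/`max` are `NA` for an element
#'   with no uncensored location.
#' @export
summarizeSurvey <- function(se, what = c("number", "mass")) {
  what <- match.arg(what)
  lm_ <- locationMeans(se, what)
  m <- lm_$values
  data.frame(
    element = colnames(m),
    mean = apply(m, 2, function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)),
    min = apply(m, 2, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)),
    max = apply(m, 2, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)),
    pctAboveLod = 100 * colSums(!is.na(m)) / nrow(m),
    nLocations = nrow(m),
    row.names = NULL)
}

#' Z-score standardization by column
#'
#' Centres and scales each column to mean 0, sample SD 1. Columns that are
#' entirely `NA` (fully censored elements) or have zero variance are dropped
#' with a warning: they carry no multivariate information.
#'
#' @param x numeric matrix (observations x variables); `NA`s are ignored in
#'   the column statistics and preserved in the output.
#' @return The standardized matrix, possibly with fewer columns.
#' @examples
#' zscoreMatrix(cbind(a = c(1, 2, 3), b = c(2, 2, 2)))
#' @export
zscoreMatrix <- function(x) {
  x <- as.matrix(x)
  mu <- apply(x, 2, mean, na.rm = TRUE)
  sdv <- apply(x, 2, sd, na.rm = TRUE)
  drop <- !is.finite(sdv) | sdv == 0
  if (any(drop)) {
    warning("dropping constant or fully censored column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
    mu <- mu[!drop]; sdv <- sdv[!drop]
  }
  if (ncol(x) == 0L) stop("no informative columns left after dropping")
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

## Location-mean matrix prepared for multivariate analysis: censored cells
## handled by the chosen mode, optionally log10-transformed, then z-scored.
.multivariateInput <- function(se, what, censorMode = c("drop", "impute"),
                               transform = c("log10", "identity")) {
  censorMode <- match.arg(censorMode)
  transform <- match.arg(transform)
  lm_ <- locationMeans(se, what)
  m <- lm_$values
  lod <- lm_$lod
  if (censorMode == "drop") {
    frac <- colMeans(is.na(m))
    keep <- frac <= 0.5
    if (!all(keep))
      message("dropping element(s) censored in > 50% of locations: ",
              paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
    lod <- lod[keep]
  }
  ## remaining censored cells imputed at LOD/sqrt(2), the standard
  ## substitution for left-censored lognormal-like data
  for (k in seq_len(ncol(m))) {
    miss <- is.na(m[, k])
    if (any(miss))
      m[miss, k] <- if (!is.na(lod[k])) lod[k] / sqrt(2) else
        min(m[!miss, k]) / sqrt(2)
  }
  if (transform == "log10") m <- log10(m)
  list(z = zscoreMatrix(m), classification = lm_$classification,
       season = lm_$season)
}

#' Principal component analysis of a survey
#'
#' Eigendecomposition of the covariance of the z-scored location-mean
#' concentration matrix. Scores are the projections of the locations;
#' loadings are orthonormal; explained-variance fractions sum to 1. For each
#' group a 95% confidence ellipse of the group mean is computed from the
#' within-group score covariance scaled by `1/n_group` (bivariate normal
#' approximation, chi-square quantile with 2 df).
#'
#' @param x a [SurveyExperiment-class], or a ready numeric matrix
#'   (observations x variables, no censoring handling applied).
#' @param what assay used when `x` is a survey (default `"number"`).
#' @param groups grouping for the ellipses; defaults to the survey's
#'   classification.
#' @param censorMode `"drop"` (drop elements censored in > 50% of locations,
#'   impute the rest at LOD/sqrt(2)) or `"impute"` (keep all elements).
#' @param transform `"log10"` (default) log-transforms the concentrations
#'   before z-scoring; environmental concentration data are lognormal-like
#'   and a raw-scale z-score would let single extreme locations dominate the
#'   rotation. `"identity"` standardizes the raw scale.
#' @param level confidence level of the mean ellipses (default 0.95).
#' @return A [PcaResult-class].
#' @export
surveyPca <- function(x, what = c("number", "mass"), groups = NULL,
                      censorMode = c("drop", "impute"),
                      transform = c("log10", "identity"), level = 0.95) {
  what <- match.arg(what)
  if (is(x, "SurveyExperiment")) {
    mv <- .multivariateInput(x, what, censorMode, transform)
    z <- mv$z
    if (is.null(groups)) groups <- mv$classification
  } else {
    z <- as.matrix(x)
    if (is.null(groups)) groups <- rep("all", nrow(z))
  }
  if (nrow(z) < 3L) stop("need at least 3 observations")
  if (ncol(z) < 2L) stop("need at least 2 variables")
  if (ncol(z) > nrow(z))
    warning("more variables than observations; the decomposition is ",
            "rank-limited")
  p <- prcomp(z, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  groups <- as.character(groups)
  ell <- do.call(rbind, lapply(unique(groups), function(g) {
    s <- p$x[groups == g, 1:2, drop = FALSE]
    n <- nrow(s)
    if (n < 3L)
      return(data.frame(group = g, cx = mean(s[, 1]), cy = mean(s[, 2]),
                        a = NA_real_, b = NA_real_, angle = NA_real_,
                        level = level, n = n))
    cv <- cov(s) / n      # covariance of the mean
    eg <- eigen(cv, symmetric = TRUE)
    r <- sqrt(pmax(eg$values, 0) * qchisq(level, df = 2))
    data.frame(group = g, cx = mean(s[, 1]), cy = mean(s[, 2]),
               a = r[1], b = r[2],
               angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
               level = level, n = n)
  }))
  new("PcaResult", loadings = p$rotation, scores = p$x,
      explainedVariance = expl, ellipses = ell, groups = groups)
}

#' Component separating one group from the rest
#'
#' Identifies the principal component along which a given group's mean score
#' differs most from the remaining observations, in pooled-SD units, and the
#' variable with the largest-magnitude loading on it.
#'
#' @param pca a [PcaResult-class].
#' @param group the group of interest (e.g. `"anthropogenic"`).
#' @return A list: `component` (index), `separation` (standardized mean
#'   difference per component), `topLoading` (variable name with the largest
#'   absolute loading on the separating component).
#' @export
separatingComponent <- function(pca, group = "anthropogenic") {
  g <- pca@groups == group
  if (!any(g) || all(g)) stop("'group' must split the observations")
  sep <- vapply(seq_len(ncol(pca@scores)), function(k) {
    a <- pca@scores[g, k]; b <- pca@scores[!g, k]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    if (sp == 0) 0 else abs(mean(a) - mean(b)) / sp
  }, 0)
  k <- which.max(sep)
  list(component = k, separation = sep,
       topLoading = rownames(pca@loadings)[which.max(abs(pca@loadings[, k]))])
}

#' Ward hierarchical clustering of a survey
#'
#' Agglomerative clustering by Ward's minimal-increase-of-sum-of-squares
#' criterion on Euclidean distances of the z-scored data
#' (`stats::hclust(method = "ward.D2")`, the convention in which the initial
#' dissimilarities are squared inside the algorithm and the reported merge
#' height for two singletons at Euclidean distance d is d, i.e.
#' `sqrt(2 x deltaSSQ)` in general). Heights are monotone non-decreasing.
#'
#' @param x a [SurveyExperiment-class] (location means of `what` are
#'   clustered, censoring handled per `censorMode` as in [surveyPca()]) or a
#'   ready numeric matrix, z-scored as given.
#' @param what,censorMode,transform see [surveyPca()].
#' @param standardize z-score the matrix input first (default TRUE; survey
#'   input is always standardized).
#' @return An object of class [stats::hclust].
#' @export
wardCluster <- function(x, what = c("number", "mass"),
                        censorMode = c("drop", "impute"),
                        transform = c("log10", "identity"),
                        standardize = TRUE) {
  what <- match.arg(what)
  if (is(x, "SurveyExperiment")) {
    z <- .multivariateInput(x, what, censorMode, transform)$z
  } else {
    z <- as.matrix(x)
    if (standardize) z <- zscoreMatrix(z)
  }
  if (nrow(z) < 2L) stop("need at least 2 rows to cluster")
  if (anyDuplicated(rownames(z)))
    stop("duplicate row labels")
  hclust(dist(z), method = "ward.D2")
}

#' Export a dendrogram as Newick text
#'
#' @param hc an [stats::hclust] object (e.g. from [wardCluster()]).
#' @return A single Newick string with branch lengths derived from merge
#'   heights.
#' @export
dendrogramNewick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
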
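test_that("survey summaries count censoring and recover lognormal means", {
  ## counting: 7 of 10 locations above LOD -> 70%
  vals <- matrix(c(1:7 + 10, 0.1, 0.2, 0.3), 1,
                 dimnames = list("Pb", NULL))
  se <- surveyExperiment(number = vals, mass = vals,
                         censoredNumber = vals < 1, censoredMass = vals < 1,
                         location = sprintf("l%02d", 1:10),
                         lodNumber = 1, lodMass = 1)
  sm <- summarizeSurvey(se, "number")
  expect_equal(sm$pctAboveLod, 70)
  expect_equal(sm$mean, mean(1:7 + 10))
  expect_equal(c(sm$min, sm$max), c(11, 17))
  ## all censored: no mean, 0%
  seC <- surveyExperiment(number = vals, mass = vals,
                          censoredNumber = vals > 0, censoredMass = vals > 0,
                          location = sprintf("l%02d", 1:10))
  smC <- summarizeSurvey(seC, "number")
  expect_equal(smC$pctAboveLod, 0)
  expect_true(is.na(smC$mean))

  ## synthetic survey with known lognormal parameters: the mean of location
  ## means must be within 3 SE of the analytic lognormal mean
  seL <- simulateSurvey(nLocations = 60, elements = "Fe", censoringRate = 0,
                        seed = 3, siteSdlog = 0, locationSdlog = 0.5,
                        parallelSdlog = 0.2)
  truth <- S4Vectors::metadata(seL)$truth
  mlog <- truth$meanlog[["Fe"]]
  ## location mean averages 3 parallels: variance of the log-mean location
  ## value is sdloc^2 + var(mean of 3 lognormal parallels); use the analytic
  ## mean of the generating distribution and a Monte-Carlo SE from the data
  sm <- summarizeSurvey(seL, "number")
  lmv <- locationMeans(seL, "number")$values[, "Fe"]
  analytic <- exp(mlog + 0.5 * 0.5^2) * mean(exp(0.5 * 0.2^2))
  se3 <- 3 * sd(lmv) / sqrt(length(lmv))
  expect_lt(abs(sm$mean - analytic), se3)
})

test_that("summaries are invariant to parallel order and joint rescaling", {
  se <- simulateSurvey(nLocations = 8, elements = c("Pb", "Ti"), seed = 9)
  sm <- summarizeSurvey(se, "number")
  perm <- sample(ncol(se))
  smP <- summarizeSurvey(se[, perm], "number")
  expect_equal(sm, smP)
  ## rescaling values and LODs jointly leaves %>Ld unchanged
  se2 <- se
  SummarizedExperiment::assay(se2, "number") <-
    SummarizedExperiment::assay(se, "number") * 1e3
  SummarizedExperiment::rowData(se2)$lodNumber <-
    SummarizedExperiment::rowData(se)$lodNumber * 1e3
  expect_equal(summarizeSurvey(se2, "number")$pctAboveLod, sm$pctAboveLod)
})

test_that("z-scoring standardizes, is idempotent and drops constants", {
  ## hand-computed: {1,2,3} -> {-1,0,1} with the sample SD
  z <- zscoreMatrix(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  ## already standardized columns are unchanged
  expect_equal(zscoreMatrix(z), z)
  ## constant columns dropped with a warning
  expect_warning(z2 <- zscoreMatrix(cbind(a = c(1, 2, 3), b = c(5, 5, 5))),
                 "constant")
  expect_equal(colnames(z2), "a")
})

test_that("PCA produces orthonormal loadings and conserved variance", {
  se <- simulateSurvey(nLocations = 20, seed = 2)
  p <- surveyPca(se)
  L <- p@loadings
  expect_lt(max(abs(crossprod(L) - diag(ncol(L)))), 1e-10)
  expect_equal(sum(p@explainedVariance), 1, tolerance = 1e-12)
  ## two perfectly correlated variables: PC1 carries 100% of the variance
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  p2 <- surveyPca(zscoreMatrix(x))
  expect_equal(p2@explainedVariance[1], 1, tolerance = 1e-12)
  ## scores invariant (up to sign) to row order
  se2 <- se[, sample(ncol(se))]
  pp <- surveyPca(se2)
  sc1 <- p@scores[order(rownames(p@scores)), ]
  sc2 <- pp@scores[order(rownames(pp@scores)), ]
  for (k in seq_len(ncol(sc1)))
    expect_lt(min(max(abs(sc1[, k] - sc2[, k])),
                  max(abs(sc1[, k] + sc2[, k]))), 1e-8)
})

test_that("a 10x Pb anthropogenic effect dominates the separating component", {
  se <- simulateSurvey(nLocations = 40,
                       elements = c("Pb", "Ti", "Fe", "Al", "Ba"),
                       classEffects = list(Pb = c(anthropogenic = 10)),
                       censoringRate = 0, seed = 13)
  p <- surveyPca(se)
  sepr <- separatingComponent(p, "anthropogenic")
  expect_equal(sepr$topLoading, "Pb")
  ## group mean ellipses exist for each classification present
  expect_true(all(unique(p@groups) %in% p@ellipses$group))
  expect_true(all(p@ellipses$level == 0.95))
})

test_that("ward clustering matches the exhaustive sum-of-squares oracle", {
  ## trivial cases
  x <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 3))
  hc <- wardCluster(x, standardize = FALSE)
  expect_equal(hc$height[1], 0)  # identical points merge at height 0
  x4 <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(10, 10), d = c(10.1, 10))
  hc4 <- wardCluster(x4, standardize = FALSE)
  m <- hclustMerges(hc4)
  expect_setequal(list(m[[1]], m[[2]]), list(c(1L, 2L), c(3L, 4L)))

  ## exhaustive oracle on random 4-5 point instances across 20 seeds:
  ## identical merge order and heights
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:5, 1)
    x <- matrix(rnorm(n * 3), n, dimnames = list(letters[1:n], NULL))
    hc <- wardCluster(x, standardize = FALSE)
    o <- wardOracle(x)
    expect_equal(hc$height, o$heights, tolerance = 1e-10,
                 label = sprintf("heights (seed %d)", seed))
    expect_identical(hclustMerges(hc), o$merges,
                     label = sprintf("merge order (seed %d)", seed))
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone heights
  }
  expect_error(wardCluster(x[c(1, 1), ], standardize = FALSE), "duplicate")
})

test_that("dendrograms export as parseable Newick text", {
  set.seed(1)
  x <- matrix(rnorm(12), 4, dimnames = list(paste0("L", 1:4), NULL))
  nwk <- dendrogramNewick(wardCluster(x, standardize = FALSE))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, paste0("L", 1:4))
})
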
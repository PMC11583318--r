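## End-to-end orchestration: calibrate -> detect -> quantify -> totals ->
## survey, from directories of trace CSVs to result tables. Deterministic
## given identical inputs (no randomness in the reduction itself), so reruns
## are byte-identical.

#' Pipeline run configuration
#'
#' @slot tracesDir,standardsDir,referenceDir,blanksDir directories of trace
#'   CSVs (with sidecars) for samples, ionic standards (sidecar field
#'   `concentration_ug_per_l`), reference nanoparticle runs, and procedural
#'   blanks.
#' @slot outDir output directory.
#' @slot elementTable data.frame with `element`, `density`, `massFraction`:
#'   the compositional assumptions per element.
#' @slot referencePopulation the reference [ParticlePopulation-class].
#' @slot dilution grams of tissue per litre of digest.
#' @slot window,fpRate,gapMerge detection parameters.
#' @slot totalsFile,totalsBlanksFile optional CSVs for the total-element
#'   stage (`NA_character_` to skip).
#' @seealso [runConfig()], [runPipeline()]
#' @export
setClass("RunConfig",
  representation(tracesDir = "character", standardsDir = "character",
                 referenceDir = "character", blanksDir = "character",
                 outDir = "character", elementTable = "data.frame",
                 referencePopulation = "ParticlePopulation",
                 dilution = "numeric", window = "numeric",
                 fpRate = "numeric", gapMerge = "numeric",
                 totalsFile = "character", totalsBlanksFile = "character"),
  validity = function(object) {
    msg <- character()
    for (s in c("tracesDir", "standardsDir", "referenceDir", "blanksDir"))
      if (!dir.exists(slot(object, s)))
        msg <- c(msg, sprintf("%s does not exist: %s", s, slot(object, s)))
    if (!all(c("element", "density", "massFraction") %in%
               names(object@elementTable)))
      msg <- c(msg, "elementTable needs columns element, density, massFraction")
    if (object@dilution <= 0) msg <- c(msg, "dilution must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Build a pipeline configuration
#'
#' @param tracesDir,standardsDir,referenceDir,blanksDir,outDir directories;
#'   see [RunConfig-class].
#' @param elementTable data.frame (`element`, `density`, `massFraction`)
#'   giving the compositional assumption per element.
#' @param referencePopulation reference particle suspension (default
#'   [goldReference()]).
#' @param dilution g tissue per litre of digest (default 1).
#' @param window,fpRate,gapMerge detection parameters (defaults 1001, 1, 2).
#' @param totalsFile optional CSV (`sample_id`, `element`, `intensity`,
#'   `digest_mass_g`, `final_mass_g`, `dry_weight_fraction`).
#' @param totalsBlanksFile optional CSV (`element`, `blank_value`) of
#'   procedural-blank total concentrations (ng/g dry).
#' @return A validated [RunConfig-class].
#' @export
runConfig <- function(tracesDir, standardsDir, referenceDir, blanksDir,
                      outDir, elementTable,
                      referencePopulation = goldReference(),
                      dilution = 1, window = 1001, fpRate = 1, gapMerge = 2,
                      totalsFile = NA_character_,
                      totalsBlanksFile = NA_character_) {
  new("RunConfig", tracesDir = tracesDir, standardsDir = standardsDir,
      referenceDir = referenceDir, blanksDir = blanksDir, outDir = outDir,
      elementTable = elementTable,
      referencePopulation = referencePopulation, dilution = dilution,
      window = window, fpRate = fpRate, gapMerge = gapMerge,
      totalsFile = totalsFile, totalsBlanksFile = totalsBlanksFile)
}

.listTraces <- function(dir) {
  sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
}

.detectFor <- function(trace, config) {
  w <- min(config@window, nDwells(trace) -
             (1 - nDwells(trace) %% 2))  # keep odd and <= length
  if (w %% 2 == 0) w <- w - 1
  detectEvents(trace, fpRate = config@fpRate, gapMerge = config@gapMerge,
               window = max(w, 3))
}

#' Run the full reduction pipeline
#'
#' Fits per-day ionic calibrations from the standards, determines per-day
#' transport efficiency from the reference nanoparticle runs (frequency
#' method, with the mass method logged as a cross-check), detects and
#' quantifies particles in blanks and samples, subtracts mean procedural
#' blanks, derives per-day detection limits, and (when sample sidecars carry
#' locations) assembles the survey products. All tables are written under
#' `config@outDir`; a structured log line per stage records the derived
#' constants (slopes, eta, thresholds, LODs).
#'
#' Elements without a usable calibration for a day are skipped with a
#' warning; a missing reference run stops the pipeline since nothing can be
#' quantified without a transport efficiency.
#'
#' @param config a [RunConfig-class].
#' @return Invisibly, a list with `calibrations`, `efficiencies`, `events`,
#'   `results`, `limits` and (when computed) `surveySummary`, `totals`,
#'   `fractions`.
#' @export
runPipeline <- function(config) {
  validObject(config)
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config@outDir, "run_log.txt")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  logline <- function(...) writeLines(paste(...), logCon)

  ## --- calibrate: ionic standards, grouped by element x day ---------------
  stdFiles <- .listTraces(config@standardsDir)
  standards <- list()
  for (f in stdFiles) {
    tr <- readTrace(f)
    meta <- readTraceMeta(f)
    if (is.null(meta$concentration_ug_per_l))
      stop(f, ": standard sidecar lacks 'concentration_ug_per_l'")
    key <- paste(tr@element, tr@dayId, sep = "|")
    standards[[key]] <- c(standards[[key]],
                          list(list(concentration = meta$concentration_ug_per_l,
                                    trace = tr)))
  }
  calibs <- list()
  for (key in names(standards)) {
    cal <- fitIonicCalibration(standards[[key]])
    calibs[[key]] <- cal
    logline(sprintf("stage=calibrate element=%s day=%s slope=%.6g intercept=%.6g n=%d",
                    cal@element, cal@dayId, slope(cal), intercept(cal),
                    cal@nPoints))
  }
  calTab <- do.call(rbind, lapply(calibs, function(cal)
    data.frame(element = cal@element, day_id = cal@dayId,
               slope = slope(cal), intercept = intercept(cal),
               slope_se = cal@slopeSE, residual_se = cal@residualSE,
               n_points = cal@nPoints)))
  write.csv(calTab, file.path(config@outDir, "calibrations.csv"),
            row.names = FALSE, quote = FALSE)

  ## --- transport efficiency from reference runs, per day ------------------
  refFiles <- .listTraces(config@referenceDir)
  if (length(refFiles) == 0L)
    stop("no reference nanoparticle traces in ", config@referenceDir,
         ": transport efficiency cannot be determined; add at least one ",
         "reference run (e.g. the 60 nm gold suspension) per analysis day")
  etas <- list()
  etaRows <- list()
  for (f in refFiles) {
    tr <- readTrace(f)
    ev <- .detectFor(tr, config)
    te <- transportEfficiencyFrequency(ev, config@referencePopulation,
                                       tr@settings, dayId = tr@dayId)
    etas[[tr@dayId]] <- te
    etaMassVal <- NA_real_
    calKey <- paste(config@referencePopulation@element, tr@dayId, sep = "|")
    if (!is.null(calibs[[calKey]])) {
      tem <- tryCatch(
        transportEfficiencyMass(ev, config@referencePopulation,
                                calibs[[calKey]], tr@settings,
                                dayId = tr@dayId),
        error = function(e) NULL)
      if (!is.null(tem)) etaMassVal <- eta(tem)
    }
    logline(sprintf(
      "stage=transport_efficiency day=%s eta_frequency=%.6g eta_mass=%.6g n_events=%d",
      tr@dayId, eta(te), etaMassVal, nrow(ev)))
    etaRows[[f]] <- data.frame(day_id = tr@dayId, eta_frequency = eta(te),
                               eta_mass = etaMassVal, n_events = nrow(ev))
  }
  write.csv(do.call(rbind, etaRows),
            file.path(config@outDir, "transport_efficiency.csv"),
            row.names = FALSE, quote = FALSE)

  quantifyTrace <- function(tr, ev) {
    key <- paste(tr@element, tr@dayId, sep = "|")
    cal <- calibs[[key]]
    if (is.null(cal) || slope(cal) <= 0) {
      warning(sprintf("no usable calibration for %s on %s; element skipped",
                      tr@element, tr@dayId))
      return(NULL)
    }
    te <- etas[[tr@dayId]]
    if (is.null(te)) {
      warning(sprintf("no reference run for day %s; sample %s skipped",
                      tr@dayId, tr@sampleId))
      return(NULL)
    }
    sampleConcentrations(ev, cal, te, tr@settings, dilution = config@dilution,
                         element = tr@element, sampleId = tr@sampleId,
                         dayId = tr@dayId)
  }

  ## --- procedural blanks ---------------------------------------------------
  blankRows <- list()
  massLod <- list()  # per element: named per-day vectors, fg
  for (f in .listTraces(config@blanksDir)) {
    tr <- readTrace(f)
    ev <- .detectFor(tr, config)
    row <- quantifyTrace(tr, ev)
    if (is.null(row)) next
    blankRows[[f]] <- row
    bl <- rollingMedianBaseline(tr, min(config@window,
                                        nDwells(tr) - 1 + nDwells(tr) %% 2))
    thr <- poissonThreshold(mean(bl), config@fpRate, tr@settings@dwellTime)
    cal <- calibs[[paste(tr@element, tr@dayId, sep = "|")]]
    ml <- .gToFg(eventMass(thr, cal, etas[[tr@dayId]], tr@settings))
    massLod[[tr@element]] <- c(massLod[[tr@element]],
                               stats::setNames(ml, tr@dayId))
  }
  blanks <- do.call(rbind, blankRows)

  ## per-element detection limits
  limits <- list()
  limRows <- list()
  if (!is.null(blanks)) {
    for (el in unique(blanks$element)) {
      b <- blanks[blanks$element == el, , drop = FALSE]
      ml <- massLod[[el]]
      mlByDay <- tapply(ml, names(ml), mean)
      lim <- tryCatch(suppressWarnings(
        detectionLimits(b, stats::setNames(as.numeric(mlByDay),
                                           names(mlByDay)), element = el)),
        error = function(e) NULL)
      if (is.null(lim)) next
      limits[[el]] <- lim
      logline(sprintf(
        "stage=limits element=%s mass_lod_fg=%.6g number_lod=%.6g mass_lod_ng=%.6g",
        el, lim@massPerParticleLodFg, lim@numberLod, lim@massLod))
      limRows[[el]] <- data.frame(
        element = el, mass_per_particle_lod_fg = lim@massPerParticleLodFg,
        number_lod = lim@numberLod, number_loq = lim@numberLoq,
        mass_lod = lim@massLod, mass_loq = lim@massLoq)
    }
    write.csv(do.call(rbind, limRows),
              file.path(config@outDir, "detection_limits.csv"),
              row.names = FALSE, quote = FALSE)
  }

  ## --- samples -------------------------------------------------------------
  eventRows <- list()
  resultRows <- list()
  sampleMeta <- list()
  for (f in .listTraces(config@tracesDir)) {
    tr <- readTrace(f)
    if (!tr@element %in% config@elementTable$element)
      stop(sprintf("element %s (%s) missing from the element table",
                   tr@element, f))
    ev <- .detectFor(tr, config)
    row <- quantifyTrace(tr, ev)
    if (is.null(row)) next
    if (nrow(ev)) {
      ev$sampleId <- tr@sampleId; ev$element <- tr@element
      ev$dayId <- tr@dayId
      eventRows[[f]] <- ev
    }
    if (!is.null(blanks) &&
        any(blanks$element == row$element & blanks$dayId == row$dayId))
      row <- blankSubtract(row, blanks)
    if (!is.null(limits[[row$element]]))
      row <- applyLimits(row, limits[[row$element]])
    logline(sprintf(
      "stage=quantify sample=%s element=%s day=%s n_events=%d number_conc=%.6g mass_conc=%.6g",
      row$sampleId, row$element, row$dayId, row$nEvents,
      row$numberConcPerG, row$massConcNgPerG))
    resultRows[[f]] <- row
    sampleMeta[[f]] <- readTraceMeta(f)
  }
  events <- if (length(eventRows)) do.call(rbind, eventRows) else
    .emptyEvents()
  if (nrow(events))
    writeEvents(events, file.path(config@outDir, "events.csv"))
  results <- if (length(resultRows)) {
    allCols <- unique(unlist(lapply(resultRows, names)))
    do.call(rbind, lapply(resultRows, function(r) {
      r[setdiff(allCols, names(r))] <- NA
      r[allCols]
    }))
  } else NULL
  if (!is.null(results)) {
    rownames(results) <- NULL
    writeSampleResults(results, file.path(config@outDir, "results.csv"))
  }

  ## --- survey products -----------------------------------------------------
  bundle <- list(calibrations = calTab,
                 efficiencies = do.call(rbind, etaRows),
                 events = events, results = results,
                 limits = limits, blanks = blanks)
  locs <- vapply(sampleMeta, function(m)
    if (is.null(m$location)) NA_character_ else m$location, "")
  if (!is.null(results) && sum(!is.na(locs)) == nrow(results) &&
      length(unique(locs)) >= 2L) {
    se <- .surveyFromResults(results, sampleMeta, limits)
    bundle$survey <- se
    bundle$surveySummary <-
      writeSurveySummary(se, file.path(config@outDir, "survey_summary.csv"))
    lmv <- locationMeans(se, "number")$values
    if (nrow(lmv) >= 3L && nrow(se) >= 2L) {
      pca <- tryCatch(surveyPca(se), error = function(e) NULL)
      if (!is.null(pca)) {
        writePcaResult(pca, file.path(config@outDir, "pca_scores.csv"),
                       file.path(config@outDir, "pca_loadings.csv"))
        bundle$pca <- pca
      }
      hc <- tryCatch(wardCluster(se), error = function(e) NULL)
      if (!is.null(hc)) {
        writeLines(dendrogramNewick(hc),
                   file.path(config@outDir, "dendrogram.nwk"))
        bundle$dendrogram <- hc
      }
    }
    logline(sprintf("stage=survey locations=%d elements=%d",
                    length(unique(locs)), nrow(se)))
  }

  ## --- totals --------------------------------------------------------------
  if (!is.na(config@totalsFile)) {
    bundle <- c(bundle, .runTotals(config, calibs, results, logline))
  }
  invisible(bundle)
}

## Assemble a SurveyExperiment from pipeline results + sidecar metadata.
.surveyFromResults <- function(results, sampleMeta, limits) {
  meta <- do.call(rbind, lapply(sampleMeta, function(m)
    data.frame(sampleId = m$sample_id,
               location = m$location %||% NA_character_,
               parallel = m$parallel %||% 1L,
               classification = m$classification %||% "natural",
               season = m$season %||% NA_character_,
               shellLength = m$shell_length %||% NA_real_)))
  meta <- meta[!duplicated(meta$sampleId), , drop = FALSE]
  elements <- sort(unique(results$element))
  ids <- unique(results$sampleId)
  shape <- function(col, default) {
    m <- matrix(default, length(elements), length(ids),
                dimnames = list(elements, ids))
    idx <- cbind(match(results$element, elements),
                 match(results$sampleId, ids))
    m[idx] <- results[[col]]
    m
  }
  number <- shape("numberConcPerG", NA_real_)
  mass <- shape("massConcNgPerG", NA_real_)
  censN <- shape("censoredNumber", TRUE); censN[is.na(censN)] <- TRUE
  censM <- shape("censoredMass", TRUE); censM[is.na(censM)] <- TRUE
  mi <- match(ids, meta$sampleId)
  surveyExperiment(
    number, mass, censoredNumber = censN == 1, censoredMass = censM == 1,
    location = meta$location[mi], parallel = meta$parallel[mi],
    classification = meta$classification[mi], season = meta$season[mi],
    shellLength = meta$shellLength[mi],
    lodNumber = vapply(elements, function(el)
      if (!is.null(limits[[el]])) limits[[el]]@numberLod else NA_real_, 0),
    lodMass = vapply(elements, function(el)
      if (!is.null(limits[[el]])) limits[[el]]@massLod else NA_real_, 0))
}

.runTotals <- function(config, calibs, results, logline) {
  tot <- read.csv(config@totalsFile)
  lods <- NULL
  if (!is.na(config@totalsBlanksFile)) {
    bl <- read.csv(config@totalsBlanksFile)
    lods <- vapply(split(bl$blank_value, bl$element), function(v)
      tryCatch(totalLod(v), error = function(e) NA_real_), 0)
    ## silver's 6-blank rule
    if ("Ag" %in% names(lods)) {
      agv <- bl$blank_value[bl$element == "Ag"]
      lods["Ag"] <- tryCatch(totalLod(agv, "Ag"), error = function(e) NA_real_)
    }
  }
  rows <- list()
  for (i in seq_len(nrow(tot))) {
    key <- grep(paste0("^", tot$element[i], "\\|"), names(calibs), value = TRUE)
    if (length(key) == 0L) {
      warning("no calibration for total element ", tot$element[i])
      next
    }
    lodDry <- if (!is.null(lods) && tot$element[i] %in% names(lods))
      unname(lods[tot$element[i]]) else NA_real_
    rows[[i]] <- totalConcentration(
      tot$intensity[i], calibs[[key[1L]]], tot$digest_mass_g[i],
      tot$final_mass_g[i], tot$dry_weight_fraction[i], lodDry = lodDry,
      element = tot$element[i], sampleId = tot$sample_id[i])
  }
  totals <- do.call(rbind, rows)
  out <- list(totals = totals)
  if (!is.null(totals)) {
    tf <- totals
    names(tf) <- c("sample_id", "element", "conc_ng_per_g_ww", "lod",
                   "censored", "dry_weight_fraction", "below_intercept")
    write.csv(tf, file.path(config@outDir, "totals.csv"),
              row.names = FALSE, quote = FALSE)
    logline(sprintf("stage=totals n=%d", nrow(totals)))
    if (!is.null(results)) {
      merged <- merge(results, totals, by = c("sampleId", "element"))
      if (nrow(merged)) {
        merged$fraction_pct <- particleFraction(
          merged$massConcNgPerG, merged$concNgPerGWw,
          ifelse(is.na(merged$censoredMass), FALSE, merged$censoredMass),
          ifelse(is.na(merged$censored), FALSE, merged$censored))
        frac <- merged[, c("sampleId", "element", "massConcNgPerG",
                           "concNgPerGWw", "fraction_pct")]
        names(frac) <- c("sample_id", "element", "particle_mass_ng_per_g",
                         "total_ng_per_g", "fraction_pct")
        write.csv(frac, file.path(config@outDir, "particle_fractions.csv"),
                  row.names = FALSE, quote = FALSE)
        out$fractions <- frac
      }
    }
  }
  out
}
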
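## CSV readers/writers. Dialect: comma-separated, UTF-8, '.' decimal, header
## row. Each trace CSV has a structured-text (YAML) sidecar with the
## acquisition settings and sample identity.

.traceMetaPath <- function(path) {
  if (grepl("\\.csv$", path)) sub("\\.csv$", ".meta.yaml", path)
  else paste0(path, ".meta.yaml")
}

#' Write a raw trace with its metadata sidecar
#'
#' The trace goes to `path` as a two-column CSV (`dwell_index,counts`); the
#' acquisition settings and identity go to a YAML sidecar next to it
#' (`*.meta.yaml`). Extra metadata fields (e.g. a standard's concentration,
#' a sample's location) are passed through `...` and preserved.
#'
#' @param trace a [TimeTrace-class].
#' @param path output CSV path.
#' @param ... additional scalar metadata written to the sidecar.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path, ...) {
  stopifnot(is(trace, "TimeTrace"))
  df <- data.frame(dwell_index = seq_along(counts(trace)) - 1L,
                   counts = counts(trace))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(element = trace@element, sample_id = trace@sampleId,
                 day_id = trace@dayId,
                 dwell_time_s = trace@settings@dwellTime,
                 acquisition_time_s = trace@settings@acquisitionTime,
                 flow_rate_ml_min = trace@settings@flowRate,
                 n_dwells = nDwells(trace)),
            list(...))
  yaml::write_yaml(meta, .traceMetaPath(path))
  invisible(path)
}

#' Read a trace's metadata sidecar
#'
#' @param path the trace CSV path (the sidecar is located next to it).
#' @return The metadata as a named list.
#' @export
readTraceMeta <- function(path) {
  mp <- .traceMetaPath(path)
  if (!file.exists(mp))
    stop("missing metadata sidecar: ", mp)
  yaml::read_yaml(mp)
}

#' Read a raw trace
#'
#' Validates the CSV (header, integer non-negative counts) against its
#' metadata sidecar (dwell count must match the acquisition settings).
#'
#' @param path trace CSV path written by [writeTrace()].
#' @return A [TimeTrace-class].
#' @export
readTrace <- function(path) {
  df <- read.csv(path)
  if (!all(c("dwell_index", "counts") %in% names(df)))
    stop(path, ": expected columns 'dwell_index,counts'")
  bad <- which(is.na(df$counts) | df$counts < 0 |
                 df$counts != floor(df$counts))
  if (length(bad))
    stop(sprintf("%s: invalid count at row %d (%s)", path, bad[1L],
                 as.character(df$counts[bad[1L]])))
  meta <- readTraceMeta(path)
  settings <- acquisitionSettings(dwellTime = meta$dwell_time_s,
                                  acquisitionTime = meta$acquisition_time_s,
                                  flowRate = meta$flow_rate_ml_min)
  if (nrow(df) != nDwells(settings))
    stop(sprintf(
      "%s: %d dwells on file but metadata implies %d (truncated file?)",
      path, nrow(df), nDwells(settings)))
  timeTrace(df$counts, settings, element = meta$element,
            sampleId = meta$sample_id, dayId = meta$day_id)
}

## Internal <-> on-file column name mapping for event tables.
.eventCols <- c(sampleId = "sample_id", element = "element",
                dayId = "day_id", start = "start_dwell", end = "end_dwell",
                maxIntensity = "max_intensity", integral = "integral",
                localBaseline = "local_baseline", threshold = "threshold")

#' Write a detected-event table
#'
#' @param events event data.frame from [detectEvents()]; identity columns
#'   (`sampleId`, `element`, `dayId`) are added from the arguments when
#'   absent.
#' @param path output CSV path.
#' @param sampleId,element,dayId identity used when `events` lacks them.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path, sampleId = "sample", element = "X",
                        dayId = "day1") {
  for (col in c("sampleId", "element", "dayId"))
    if (is.null(events[[col]]))
      events[[col]] <- switch(col, sampleId = sampleId, element = element,
                              dayId = dayId)
  out <- events[, names(.eventCols)]
  names(out) <- unname(.eventCols)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detected-event table
#'
#' @param path CSV written by [writeEvents()].
#' @return Event data.frame with the package's internal column names.
#' @export
readEvents <- function(path) {
  df <- read.csv(path)
  missing <- setdiff(unname(.eventCols), names(df))
  if (length(missing))
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  df <- df[, unname(.eventCols)]
  names(df) <- names(.eventCols)
  df
}

.resultCols <- c(sampleId = "sample_id", element = "element",
                 dayId = "day_id", nEvents = "n_events",
                 numberConcPerG = "number_conc_per_g",
                 massConcNgPerG = "mass_conc_ng_per_g",
                 censoredNumber = "censored_number",
                 censoredMass = "censored_mass",
                 lodNumber = "lod_number", lodMass = "lod_mass")

#' Write per-sample particle concentration results
#'
#' @param results data.frame of rows from [sampleConcentrations()] (after
#'   [blankSubtract()] / [applyLimits()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSampleResults <- function(results, path) {
  for (col in c("lodNumber", "lodMass"))
    if (is.null(results[[col]])) results[[col]] <- NA_real_
  out <- results[, names(.resultCols)]
  names(out) <- unname(.resultCols)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-sample particle concentration results
#'
#' @param path CSV written by [writeSampleResults()].
#' @return data.frame with internal column names.
#' @export
readSampleResults <- function(path) {
  df <- read.csv(path)
  missing <- setdiff(unname(.resultCols), names(df))
  if (length(missing))
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  df <- df[, unname(.resultCols)]
  names(df) <- names(.resultCols)
  df
}

#' Write a simulation ground-truth manifest
#'
#' @param truth the `truth` component returned by [simulateTrace()].
#' @param path output CSV path (events; scalar truths go in a header-style
#'   comment-free sidecar YAML).
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  ev <- truth$events
  names(ev) <- c("start_dwell", "span_dwells", "mass_g")
  write.csv(ev, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(eta = truth$eta,
                        ionic_response = truth$ionicResponse,
                        number_concentration_per_ml =
                          truth$numberConcentration),
                   .traceMetaPath(path))
  invisible(path)
}

#' Write a survey summary table
#'
#' One row per element with number- and mass-concentration summaries:
#' mean, min, max and the percentage of locations above the detection limit
#' for each basis.
#'
#' @param se a [SurveyExperiment-class].
#' @param path output CSV path.
#' @return The combined summary data.frame, invisibly.
#' @export
writeSurveySummary <- function(se, path) {
  num <- summarizeSurvey(se, "number")
  mas <- summarizeSurvey(se, "mass")
  out <- data.frame(
    element = num$element,
    number_mean = num$mean, number_min = num$min, number_max = num$max,
    number_pct_above_lod = num$pctAboveLod,
    mass_mean = mas$mean, mass_min = mas$min, mass_max = mas$max,
    mass_pct_above_lod = mas$pctAboveLod)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write PCA scores and loadings
#'
#' @param pca a [PcaResult-class].
#' @param scoresPath,loadingsPath output CSV paths.
#' @return `scoresPath`, invisibly.
#' @export
writePcaResult <- function(pca, scoresPath, loadingsPath) {
  sc <- data.frame(observation = rownames(pca@scores), group = pca@groups,
                   pca@scores, check.names = FALSE)
  write.csv(sc, scoresPath, row.names = FALSE, quote = FALSE)
  lo <- data.frame(variable = rownames(pca@loadings), pca@loadings,
                   check.names = FALSE)
  write.csv(lo, loadingsPath, row.names = FALSE, quote = FALSE)
  invisible(scoresPath)
}
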
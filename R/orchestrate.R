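## High-level pipeline commands. Each run writes its outputs plus a
## machine-readable manifest (inputs, config echo, file checksums, seed,
## versions) and never mutates its inputs; identical seed and config give
## byte-identical outputs.

.writeManifest <- function(outDir, command, seed, inputs = character(),
                           config = NULL, outputs = character()) {
  manifest <- list(
    command = command,
    seed = seed,
    package = as.character(utils::packageVersion("qmspanel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    config = config,
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  path <- file.path(outDir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.configAsList <- function(config) {
  list(
    seed = config@seed, nCases = config@nCases,
    nControls = config@nControls,
    markers = lapply(config@markers, function(m) list(
      name = m@name, prevalenceCase = m@prevalenceCase,
      prevalenceControl = m@prevalenceControl,
      ratioMeanlog = m@ratioMeanlog, ratioSdlog = m@ratioSdlog,
      backgroundRatio = m@backgroundRatio)),
    ctNoiseSd = config@ctNoiseSd, curveSlope = config@curveSlope,
    curveIntercept = config@curveIntercept, maxCycles = config@maxCycles,
    dilutionSeries = config@dilutionSeries,
    cytologySensitivity = config@cytologySensitivity,
    cytologySpecificity = config@cytologySpecificity,
    missingRate = config@missingRate
  )
}

#' Simulate a plate and cohort and write them to disk
#'
#' Wraps the synthetic-data generator: writes \code{plate.csv} (well
#' records), \code{cohort.tsv} (per-patient table with latent truth) and a
#' run manifest into \code{outDir}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir output directory (created if needed).
#' @return invisible list with the written paths.
#' @export
runSimulate <- function(config, outDir) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulateCohort(config)
  wells <- simulatePlate(config, cohort)
  platePath <- file.path(outDir, "plate.csv")
  cohortPath <- file.path(outDir, "cohort.tsv")
  writePlateCsv(wells, platePath)
  writeCohortTsv(cohort, cohortPath)
  .writeManifest(outDir, "simulate", config@seed,
                 config = .configAsList(config),
                 outputs = c(platePath, cohortPath))
  invisible(list(plate = platePath, cohort = cohortPath))
}

#' Quantify plate files into a per-sample score table
#'
#' Runs calibration, reference QC and x 1000 scoring on each plate file
#' and concatenates the per-sample tables; per-plate curve diagnostics are
#' attached as the \code{"curves"} attribute. When \code{outDir} is given,
#' writes \code{ratios.tsv} and a manifest.
#'
#' @param plateFiles paths to plate CSV files.
#' @param outDir optional output directory.
#' @param ... passed to \code{\link{quantifyPlate}}.
#' @return per-sample score data.frame (columns \code{plate},
#'   \code{sample_id}, \code{gene}, quantities, \code{ratio},
#'   \code{valid}, \code{reason}).
#' @export
runQuantify <- function(plateFiles, outDir = NULL, ...) {
  res <- lapply(plateFiles, function(p) {
    q <- quantifyPlate(readPlateCsv(p), ...)
    q$samples$plate <- basename(p)
    q
  })
  samples <- do.call(rbind, lapply(res, `[[`, "samples"))
  rownames(samples) <- NULL
  attr(samples, "curves") <- lapply(res, `[[`, "curves")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(outDir, "ratios.tsv")
    utils::write.table(samples, out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    .writeManifest(outDir, "quantify", NA, inputs = plateFiles,
                   outputs = out)
  }
  samples
}

#' Dichotomize, cross-tabulate and evaluate the panel for a cohort
#'
#' The analysis command: takes a cohort that carries either continuous
#' \code{ratio_<gene>} columns (dichotomized at empiric cutoffs derived
#' against \code{groupColumn}) or ready-made "+"/"-" call columns, builds
#' the per-marker association report, and evaluates the any-positive
#' panel on the case rows.
#'
#' @param cohort cohort data.frame.
#' @param markers marker gene symbols.
#' @param groupColumn binary grouping column (default "group" with value
#'   "case" as positive class).
#' @param positiveGroup value of \code{groupColumn} defining cases.
#' @param cutoffs optional named list of \linkS4class{MarkerCutoff} to
#'   apply instead of deriving them (cutoff source "file").
#' @param method association test choice ("auto", "fisher", "chisq").
#' @param outDir optional output directory for the report TSVs and
#'   manifest.
#' @return list with \code{calls} (per-patient data.frame of "+"/"-"
#'   calls), \code{cutoffs}, \code{association} (report data.frame) and
#'   \code{panel} (from \code{\link{panelReport}} on the case rows).
#' @export
runAnalyze <- function(cohort, markers, groupColumn = "group",
                       positiveGroup = "case", cutoffs = NULL,
                       method = "auto", outDir = NULL) {
  if (!groupColumn %in% names(cohort))
    stop("unknown grouping column '", groupColumn, "'; cohort columns: ",
         paste(names(cohort), collapse = ", "))
  labels <- cohort[[groupColumn]] == positiveGroup
  callTable <- data.frame(row.names = seq_len(nrow(cohort)))
  derived <- list()
  for (g in markers) {
    ratioCol <- paste0("ratio_", g)
    if (g %in% names(cohort)) {
      callTable[[g]] <- cohort[[g]]
    } else if (ratioCol %in% names(cohort)) {
      ct <- if (!is.null(cutoffs)) cutoffs[[g]] else
        selectCutoff(cohort[[ratioCol]], labels, gene = g)
      if (is.null(ct)) stop("no cutoff available for ", g)
      derived[[g]] <- ct
      callTable[[g]] <- .logicalToPlus(dichotomize(cohort[[ratioCol]], ct))
    } else {
      stop("cohort has neither a '", g, "' call column nor a '", ratioCol,
           "' score column")
    }
  }
  if (is.null(cutoffs)) cutoffs <- derived
  assocCohort <- cbind(callTable, grp = cohort[[groupColumn]])
  association <- associationReport(assocCohort, markers, "grp", method)
  caseRows <- which(labels)
  panelCohort <- cbind(callTable,
                       cytology = if ("cytology" %in% names(cohort))
                         cohort$cytology else NULL)
  panel <- panelReport(panelCohort[caseRows, , drop = FALSE], markers)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    assocPath <- file.path(outDir, "association.tsv")
    utils::write.table(association, assocPath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <- assocPath
    if (length(cutoffs)) {
      cutPath <- file.path(outDir, "cutoffs.tsv")
      writeCutoffTsv(cutoffs, cutPath)
      outputs <- c(outputs, cutPath)
    }
    .writeManifest(outDir, "analyze", NA, outputs = outputs)
  }
  list(calls = callTable, cutoffs = cutoffs, association = association,
       panel = panel)
}
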
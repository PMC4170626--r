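#' Simulate the standard-dilution wells for one gene
#'
#' Emulates the serial dilution of in vitro methylated DNA run on every
#' plate: triplicate wells at each quantity of the configured dilution
#' series, with Ct drawn from the log-linear calibration model
#' \code{Ct = intercept + slope * log10(ng)} plus Gaussian replicate noise.
#' A Ct beyond the cycling-program length is emitted as undetermined
#' (\code{NA}).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param gene gene symbol to label the wells with.
#' @param nReplicates wells per dilution (default 3, the triplicate
#'   convention).
#' @return A well-record data.frame with columns \code{sample_id},
#'   \code{gene}, \code{replicate}, \code{ct} (\code{NA} = undetermined),
#'   \code{role} ("standard") and \code{quantity_ng}.
#' @examples
#' cfg <- simulationConfig(seed = 7, ctNoiseSd = 0)
#' simulateStandardSeries(cfg, "CCND2")
#' @export
simulateStandardSeries <- function(config, gene, nReplicates = 3L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  q <- config@dilutionSeries
  if (!length(q)) stop("dilution series is empty")
  if (any(q <= 0)) stop("dilution quantities must be positive")
  set.seed(.streamSeed(config@seed, paste0("standards:", gene)))
  n <- length(q) * nReplicates
  quantity <- rep(q, each = nReplicates)
  ct <- config@curveIntercept + config@curveSlope * log10(quantity) +
    stats::rnorm(n, 0, config@ctNoiseSd)
  ct[ct > config@maxCycles] <- NA_real_
  data.frame(
    sample_id = rep(sprintf("STD_%s_D%02d", gene, seq_along(q)),
                    each = nReplicates),
    gene = gene,
    replicate = rep(seq_len(nReplicates), length(q)),
    ct = ct,
    role = "standard",
    quantity_ng = quantity,
    stringsAsFactors = FALSE
  )
}

#' Simulate a patient cohort with known methylation ground truth
#'
#' For each patient and marker, latent methylation is Bernoulli with the
#' group prevalence; methylated samples draw their continuous x 1000 score
#' from the marker's log-normal, unmethylated samples sit at the marker's
#' background score (0 by default). Measurements go missing independently
#' with the configured rate (the latent truth is kept). Cytology is drawn
#' from its sensitivity for cases and specificity for controls.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A data.frame with one row per patient: \code{id}, \code{group}
#'   ("case"/"control"), \code{cytology} ("+"/"-"), and per marker the
#'   observed score \code{ratio_<gene>} (\code{NA} when missing) and latent
#'   truth \code{truth_<gene>} (logical).
#' @examples
#' cohort <- simulateCohort(simulationConfig(seed = 1, nCases = 5,
#'                                           nControls = 5))
#' head(cohort)
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (!length(config@markers)) stop("need at least one marker")
  nCase <- config@nCases
  nCtrl <- config@nControls
  n <- nCase + nCtrl
  group <- rep(c("case", "control"), c(nCase, nCtrl))
  id <- sprintf("%s%03d", ifelse(group == "case", "C", "N"),
                c(seq_len(nCase), seq_len(nCtrl)))
  set.seed(.streamSeed(config@seed, "cohort"))
  out <- data.frame(id = id, group = group, stringsAsFactors = FALSE)
  ## cytology: positive with prob sensitivity for cases, 1 - specificity
  ## for controls
  pPos <- ifelse(group == "case", config@cytologySensitivity,
                 1 - config@cytologySpecificity)
  out$cytology <- .logicalToPlus(stats::runif(n) < pPos)
  for (m in config@markers) {
    prev <- ifelse(group == "case", m@prevalenceCase, m@prevalenceControl)
    truth <- stats::runif(n) < prev
    ratio <- rep(m@backgroundRatio, n)
    nMeth <- sum(truth)
    if (nMeth)
      ratio[truth] <- stats::rlnorm(nMeth, m@ratioMeanlog, m@ratioSdlog)
    ratio[stats::runif(n) < config@missingRate] <- NA_real_
    out[[paste0("ratio_", m@name)]] <- ratio
    out[[paste0("truth_", m@name)]] <- truth
  }
  out
}

#' Simulate a full QMSP plate for a cohort
#'
#' Lays out one synthetic 384-well-style plate: per-gene standard dilution
#' series, triplicate sample wells for the reference gene (beta-actin,
#' "ACTB") and every marker, and no-template-control wells. Each patient
#' gets a log-normal reference-DNA input amount; marker input is
#' \code{score / 1000 * reference input}, so running the plate back through
#' \code{\link{quantifyPlate}} recovers the cohort's generating scores.
#' Zero marker input (truly unmethylated) and any predicted Ct beyond the
#' program length yield undetermined wells; markers missing in the cohort
#' produce no wells for that patient.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param cohort optionally, a cohort from \code{\link{simulateCohort}};
#'   simulated afresh from \code{config} when omitted.
#' @return A well-record data.frame (same columns as
#'   \code{\link{simulateStandardSeries}}) covering standards, samples and
#'   no-template controls for all genes.
#' @examples
#' cfg <- simulationConfig(seed = 2, nCases = 3, nControls = 3,
#'                         ctNoiseSd = 0, missingRate = 0)
#' wells <- simulatePlate(cfg)
#' table(wells$role, wells$gene)
#' @export
simulatePlate <- function(config, cohort = simulateCohort(config)) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  genes <- vapply(config@markers, slot, "", "name")
  standards <- do.call(rbind, lapply(c(genes, "ACTB"), function(g)
    simulateStandardSeries(config, g)))
  set.seed(.streamSeed(config@seed, "plate"))
  n <- nrow(cohort)
  input <- stats::rlnorm(n, config@sampleInputMeanlog,
                         config@sampleInputSdlog)
  ctFor <- function(quantity) {
    ## quantity 0 -> no amplification within the program -> undetermined
    ct <- ifelse(quantity > 0,
                 config@curveIntercept +
                   config@curveSlope * log10(quantity), NA_real_)
    ct <- ct + stats::rnorm(length(ct), 0, config@ctNoiseSd)
    ct[!is.na(ct) & ct > config@maxCycles] <- NA_real_
    ct
  }
  sampleWells <- list()
  for (g in c("ACTB", genes)) {
    quantity <- if (g == "ACTB") input else
      cohort[[paste0("ratio_", g)]] / 1000 * input
    keep <- !is.na(quantity)
    if (!any(keep)) next
    q3 <- rep(quantity[keep], each = 3L)
    sampleWells[[g]] <- data.frame(
      sample_id = rep(cohort$id[keep], each = 3L),
      gene = g,
      replicate = rep(1:3, sum(keep)),
      ct = ctFor(q3),
      role = "sample",
      quantity_ng = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  ntc <- data.frame(
    sample_id = "NTC", gene = rep(c(genes, "ACTB"), each = 3L),
    replicate = rep(1:3, length(genes) + 1L), ct = NA_real_,
    role = "ntc", quantity_ng = NA_real_, stringsAsFactors = FALSE
  )
  out <- rbind(standards, do.call(rbind, sampleWells), ntc)
  rownames(out) <- NULL
  out
}
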
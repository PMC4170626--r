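#' Fit a per-gene calibration curve from standard wells
#'
#' Ordinary least-squares fit of Ct against log10(input quantity) over the
#' standard dilution wells of one gene, as run on every plate. Undetermined
#' standards are excluded from the fit. A fit with fewer than two usable
#' points, or a non-negative slope (which signals inverted or corrupt
#' data), is returned as a failed calibration rather than an error, so a
#' plate report can carry the reason.
#'
#' @param standardWells well-record data.frame; only rows with
#'   \code{role == "standard"} are used, and all must belong to one gene.
#' @return A \linkS4class{StandardCurve}.
#' @examples
#' wells <- data.frame(sample_id = "S", gene = "CCND2", replicate = 1,
#'                     ct = c(24, 20.6781), role = "standard",
#'                     quantity_ng = c(1, 10))
#' fitStandardCurve(wells)
#' @export
fitStandardCurve <- function(standardWells) {
  w <- standardWells[standardWells$role == "standard", , drop = FALSE]
  gene <- unique(w$gene)
  if (length(gene) != 1L)
    stop("standard wells must all belong to a single gene, got: ",
         paste(gene, collapse = ", "))
  if (any(!is.na(w$quantity_ng) & w$quantity_ng <= 0))
    stop("standard quantities must be positive")
  usable <- !is.na(w$ct) & !is.na(w$quantity_ng)
  w <- w[usable, , drop = FALSE]
  fail <- function(reason)
    new("StandardCurve", gene = gene, slope = NA_real_,
        intercept = NA_real_, rSquared = NA_real_,
        nPoints = as.integer(nrow(w)), valid = FALSE, reason = reason)
  if (length(unique(w$quantity_ng)) < 2L)
    return(fail("fewer than 2 usable standard points"))
  fit <- stats::lm(ct ~ log10(quantity_ng), data = w)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    return(fail("non-negative slope (inverted standards?)"))
  ## suppressWarnings: summary.lm warns on noiseless (perfect-fit) standards
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new("StandardCurve", gene = gene, slope = slope,
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = r2, nPoints = as.integer(nrow(w)), valid = TRUE,
      reason = "")
}

#' Convert Ct values to input quantities through a calibration curve
#'
#' Inverts the log-linear calibration model:
#' \code{quantity = 10^((ct - intercept) / slope)}. Undetermined Ct
#' (\code{NA}) maps to quantity 0 - the no-amplification convention for
#' methylation-specific targets, where absence of signal means absence of
#' methylated template.
#'
#' @param ct numeric vector of Ct values; \code{NA} = undetermined.
#' @param curve a valid \linkS4class{StandardCurve}.
#' @return Numeric vector of quantities (ng), monotone decreasing in ct.
#' @examples
#' curve <- fitStandardCurve(data.frame(
#'   sample_id = "S", gene = "g", replicate = 1, ct = c(24, 20.6781),
#'   role = "standard", quantity_ng = c(1, 10)))
#' quantityFromCt(c(24, 24 - 3.3219, NA), curve)
#' @export
quantityFromCt <- function(ct, curve) {
  stopifnot(is(curve, "StandardCurve"))
  if (!isValid(curve))
    stop("cannot invert a failed calibration: ", failureReason(curve))
  q <- 10^((ct - curve@intercept) / curve@slope)
  q[is.na(ct)] <- 0
  q
}

#' Average replicate quantities
#'
#' Arithmetic mean of the replicate quantities of one sample and gene, the
#' "average value of triplicates". Undetermined replicates (\code{NA})
#' contribute quantity 0, consistent with \code{\link{quantityFromCt}}.
#'
#' @param quantities numeric vector of replicate quantities (ng);
#'   \code{NA} = undetermined.
#' @return A list with \code{mean} (ng), \code{nWells} and
#'   \code{nDetected}. Zero replicates yield \code{mean = NA} (sample must
#'   be flagged by the caller).
#' @examples
#' aggregateReplicates(c(4, 5, 6))$mean        # 5
#' aggregateReplicates(c(4, 4, NA))$mean       # 8/3 under the 0 convention
#' @export
aggregateReplicates <- function(quantities) {
  n <- length(quantities)
  if (n == 0L)
    return(list(mean = NA_real_, nWells = 0L, nDetected = 0L))
  q <- ifelse(is.na(quantities), 0, quantities)
  list(mean = mean(q), nWells = n, nDetected = sum(!is.na(quantities)))
}

#' The gene/reference x 1000 relative methylation score
#'
#' \code{geneMean / actinMean * 1000}: the ratio of methylation-specific
#' signal for the gene of interest to the beta-actin reference, scaled by
#' 1000 for tabulation.
#'
#' @param geneMean mean target quantity (ng).
#' @param actinMean mean reference quantity (ng); must be positive - a zero
#'   reference is a QC failure, not a division.
#' @return The x 1000 score (\code{NA} with a warning if the reference mean
#'   is not positive).
#' @examples
#' methylationRatio(4.5, 9)   # 500
#' methylationRatio(5, 5)     # 1000
#' @export
methylationRatio <- function(geneMean, actinMean) {
  out <- ifelse(!is.na(actinMean) & actinMean > 0,
                geneMean / actinMean * 1000, NA_real_)
  if (anyNA(out))
    warning("non-positive reference mean: sample(s) fail QC, score NA")
  out
}

#' Reference-gene quality control for one sample
#'
#' A sample is evaluable only if its beta-actin reaction amplified: at
#' least one replicate determined, and the mean determined Ct at or below
#' the QC threshold (Ct 40 in the assay's range of sensitivity and
#' reproducibility).
#'
#' @param actinCts numeric vector of reference-gene replicate Ct values;
#'   \code{NA} = undetermined.
#' @param ctThreshold QC threshold on the mean determined Ct (default 40).
#' @return list with \code{valid} and \code{reason} ("" when valid).
#' @examples
#' qcSample(c(35, 35, 36))$valid        # TRUE
#' qcSample(c(41, 42, 41))$reason       # reference above CT 40
#' @export
qcSample <- function(actinCts, ctThreshold = 40) {
  det <- actinCts[!is.na(actinCts)]
  if (!length(det))
    return(list(valid = FALSE, reason = "no reference amplification"))
  if (mean(det) > ctThreshold)
    return(list(valid = FALSE,
                reason = sprintf("reference above CT %g", ctThreshold)))
  list(valid = TRUE, reason = "")
}

#' Quantify a whole plate: calibration, QC and x 1000 scores
#'
#' The per-plate pipeline: fit one calibration curve per gene from that
#' plate's standards, convert sample Ct values to quantities, average
#' replicates on the quantity scale, apply reference-gene QC, and compute
#' the gene/reference x 1000 score for every sample and target gene.
#' Undetermined target replicates contribute quantity 0; undetermined
#' reference replicates are dropped from the reference mean (all
#' undetermined fails QC). Replicate Ct ranges above \code{maxSpreadWarn}
#' cycles are reported in the \code{wideSpread} column (no wells are
#' rejected).
#'
#' @param wells well-record data.frame for one plate (standards + samples).
#' @param referenceGene reference amplicon gene symbol (default "ACTB").
#' @param ctThreshold reference QC threshold (default Ct 40).
#' @param maxSpreadWarn replicate Ct range that triggers a spread flag
#'   (default 1 cycle).
#' @return list with \code{curves} (per-gene \linkS4class{StandardCurve})
#'   and \code{samples}, a data.frame with one row per sample x target
#'   gene: mean quantities, \code{ratio}, \code{valid}, \code{reason},
#'   replicate bookkeeping and \code{wideSpread}.
#' @examples
#' cfg <- simulationConfig(seed = 3, nCases = 2, nControls = 2,
#'                         ctNoiseSd = 0, missingRate = 0)
#' res <- quantifyPlate(simulatePlate(cfg))
#' res$curves$CCND2
#' head(res$samples)
#' @export
quantifyPlate <- function(wells, referenceGene = "ACTB", ctThreshold = 40,
                          maxSpreadWarn = 1) {
  need <- c("sample_id", "gene", "replicate", "ct", "role", "quantity_ng")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("well table lacks column(s): ", paste(miss, collapse = ", "))
  std <- wells[wells$role == "standard", , drop = FALSE]
  smp <- wells[wells$role == "sample", , drop = FALSE]
  genes <- unique(smp$gene)
  if (!referenceGene %in% genes)
    genes <- c(genes, referenceGene)
  curves <- lapply(genes, function(g) {
    s <- std[std$gene == g, , drop = FALSE]
    if (!nrow(s))
      new("StandardCurve", gene = g, slope = NA_real_,
          intercept = NA_real_, rSquared = NA_real_, nPoints = 0L,
          valid = FALSE, reason = "no standards on plate")
    else fitStandardCurve(s)
  })
  names(curves) <- genes
  targets <- setdiff(genes, referenceGene)
  ids <- unique(smp$sample_id)

  refCurve <- curves[[referenceGene]]
  refRows <- smp[smp$gene == referenceGene, , drop = FALSE]
  out <- vector("list", length(ids) * length(targets))
  k <- 0L
  for (id in ids) {
    actinCt <- refRows$ct[refRows$sample_id == id]
    qc <- if (!length(actinCt))
      list(valid = FALSE, reason = "no reference wells") else
      qcSample(actinCt, ctThreshold)
    actinMean <- NA_real_
    if (qc$valid) {
      if (!isValid(refCurve)) {
        qc <- list(valid = FALSE, reason = paste0(
          "reference calibration failed: ", failureReason(refCurve)))
      } else {
        ## reference mean over determined replicates only: zero-filling the
        ## denominator would inflate every score
        detCt <- actinCt[!is.na(actinCt)]
        actinMean <- mean(quantityFromCt(detCt, refCurve))
      }
    }
    for (g in targets) {
      k <- k + 1L
      rows <- smp[smp$sample_id == id & smp$gene == g, , drop = FALSE]
      curve <- curves[[g]]
      valid <- qc$valid
      reason <- qc$reason
      geneMean <- NA_real_
      ratio <- NA_real_
      spread <- FALSE
      if (!nrow(rows)) {
        valid <- FALSE
        reason <- "no wells for gene"
      } else if (valid && !isValid(curve)) {
        valid <- FALSE
        reason <- paste0("calibration failed: ", failureReason(curve))
      } else if (valid) {
        agg <- aggregateReplicates(quantityFromCt(rows$ct, curve))
        geneMean <- agg$mean
        ratio <- geneMean / actinMean * 1000
        det <- rows$ct[!is.na(rows$ct)]
        spread <- length(det) > 1L && diff(range(det)) > maxSpreadWarn
      }
      out[[k]] <- data.frame(
        sample_id = id, gene = g,
        mean_gene_quantity = geneMean, mean_actin_quantity = actinMean,
        ratio = ratio, valid = valid, reason = reason,
        n_gene_wells = nrow(rows),
        n_actin_wells = length(actinCt),
        wideSpread = spread,
        stringsAsFactors = FALSE
      )
    }
  }
  samples <- do.call(rbind, out[seq_len(k)])
  rownames(samples) <- NULL
  list(curves = curves, samples = samples)
}
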
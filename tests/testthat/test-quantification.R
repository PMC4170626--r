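test_that("two exact points give the exact line", {
  wells <- data.frame(sample_id = c("a", "b"), gene = "CCND2",
                      replicate = 1L, ct = c(24, 20.6781),
                      role = "standard", quantity_ng = c(1, 10))
  curve <- fitStandardCurve(wells)
  expect_true(isValid(curve))
  expect_equal(curveSlope(curve), -3.3219)
  expect_equal(curveIntercept(curve), 24)
  expect_equal(rSquared(curve), 1)
})

test_that("noiseless dilution series round-trips the generating slope", {
  curve <- fitStandardCurve(makeStandardWells())
  expect_equal(curveSlope(curve), -3.3219, tolerance = 1e-9)
  expect_equal(curveIntercept(curve), 24, tolerance = 1e-9)
})

test_that("slope recovery stays accurate under Ct noise", {
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    curve <- fitStandardCurve(makeStandardWells(noiseSd = 0.3))
    abs(curveSlope(curve) + 3.3219)
  }, 0)
  expect_lt(mean(errs), 0.2)
})

test_that("degenerate standards are flagged as failed calibrations", {
  one <- makeStandardWells(quantities = 1)
  expect_false(isValid(fitStandardCurve(one)))
  expect_match(failureReason(fitStandardCurve(one)), "fewer than 2")
  ## inverted data: Ct rising with quantity
  inv <- makeStandardWells(slope = 3.3219)
  expect_false(isValid(fitStandardCurve(inv)))
  expect_match(failureReason(fitStandardCurve(inv)), "slope")
  ## undetermined standards are excluded from the fit
  part <- makeStandardWells()
  part$ct[part$quantity_ng == 0.009] <- NA
  expect_true(isValid(fitStandardCurve(part)))
  expect_equal(fitStandardCurve(part)@nPoints, 12L)
  expect_error(fitStandardCurve(transform(part, quantity_ng = -quantity_ng)),
               "positive")
})

test_that("quantityFromCt inverts the calibration model", {
  curve <- fitStandardCurve(makeStandardWells())
  expect_equal(quantityFromCt(24, curve), 1, tolerance = 1e-9)
  expect_equal(quantityFromCt(24 - 3.3219, curve), 10, tolerance = 1e-9)
  expect_equal(quantityFromCt(NA, curve), 0)
  set.seed(9)
  q <- 10^runif(100, -3, 2)
  ct <- 24 - 3.3219 * log10(q)
  expect_equal(quantityFromCt(ct, curve), q, tolerance = 1e-9)
  ## monotone decreasing in ct
  expect_true(all(diff(quantityFromCt(seq(20, 40, 0.5), curve)) < 0))
  bad <- fitStandardCurve(makeStandardWells(quantities = 1))
  expect_error(quantityFromCt(30, bad), "failed calibration")
})

test_that("replicate aggregation follows the stated conventions", {
  expect_equal(aggregateReplicates(c(4, 5, 6))$mean, 5)
  agg <- aggregateReplicates(c(4, 4, NA))
  expect_equal(agg$mean, 8 / 3)
  expect_equal(agg$nDetected, 2L)
  expect_equal(aggregateReplicates(7)$mean, 7)
  expect_true(is.na(aggregateReplicates(numeric(0))$mean))
})

test_that("the x 1000 score is the stated arithmetic", {
  expect_equal(methylationRatio(4.5, 9), 500)
  expect_equal(methylationRatio(5, 5), 1000)
  expect_equal(methylationRatio(0, 5), 0)
  expect_warning(out <- methylationRatio(3, 0), "QC")
  expect_true(is.na(out))
})

test_that("reference QC applies the Ct 40 rule", {
  expect_true(qcSample(c(35, 35, 36))$valid)
  bad <- qcSample(c(41, 42, 41))
  expect_false(bad$valid)
  expect_match(bad$reason, "above CT 40")
  none <- qcSample(c(NA, NA, NA))
  expect_false(none$valid)
  expect_match(none$reason, "no reference amplification")
  ## boundary: mean exactly at threshold passes
  expect_true(qcSample(c(40, 40, 40))$valid)
})

test_that("scores are scale invariant and linear in the target", {
  curve <- fitStandardCurve(makeStandardWells(gene = "G"))
  score <- function(geneQ, actinQ) {
    geneCt <- 24 - 3.3219 * log10(geneQ)
    actinCt <- 24 - 3.3219 * log10(actinQ)
    methylationRatio(mean(quantityFromCt(geneCt, curve)),
                     mean(quantityFromCt(actinCt, curve)))
  }
  base <- score(c(1, 2, 3), c(4, 5, 6))
  expect_equal(score(7 * c(1, 2, 3), 7 * c(4, 5, 6)), base,
               tolerance = 1e-9)
  expect_equal(score(2 * c(1, 2, 3), c(4, 5, 6)), 2 * base,
               tolerance = 1e-9)
})

test_that("noiseless plates reproduce the generating scores exactly", {
  cfg <- simulationConfig(seed = 21, nCases = 15, nControls = 15,
                          ctNoiseSd = 0, missingRate = 0)
  cohort <- simulateCohort(cfg)
  res <- quantifyPlate(simulatePlate(cfg, cohort))
  expect_true(all(res$samples$valid))
  expect_true(all(res$samples$ratio >= 0))
  for (i in seq_len(nrow(res$samples))) {
    truth <- cohort[[paste0("ratio_", res$samples$gene[i])]][
      match(res$samples$sample_id[i], cohort$id)]
    expect_equal(res$samples$ratio[i], truth, tolerance = 1e-9)
  }
})

test_that("QC failures carry reasons and never a score", {
  cfg <- simulationConfig(seed = 22, nCases = 4, nControls = 4,
                          ctNoiseSd = 0, missingRate = 0)
  wells <- simulatePlate(cfg)
  ## plate without any reference wells: every sample invalid, no ratio
  noRef <- wells[wells$gene != "ACTB" | wells$role != "sample", ]
  res <- quantifyPlate(noRef)
  expect_true(all(!res$samples$valid))
  expect_true(all(res$samples$reason == "no reference wells"))
  expect_true(all(is.na(res$samples$ratio)))
  ## reference pushed above the QC threshold
  late <- wells
  late$ct[late$gene == "ACTB" & late$role == "sample"] <- 45
  res2 <- quantifyPlate(late)
  expect_true(all(!res2$samples$valid))
  expect_true(all(grepl("above CT 40", res2$samples$reason)))
  expect_true(all(is.na(res2$samples$ratio)))
})

test_that("wide replicate spread is flagged but not rejected", {
  cfg <- simulationConfig(seed = 23, nCases = 2, nControls = 2,
                          ctNoiseSd = 0, missingRate = 0)
  wells <- simulatePlate(cfg)
  pick <- which(wells$gene == "CCND2" & wells$role == "sample" &
                  wells$sample_id == "C001")
  if (all(is.na(wells$ct[pick]))) {
    wells$ct[pick] <- c(30, 32, 30)
  } else {
    wells$ct[pick[1]] <- wells$ct[pick[1]] + 2
  }
  res <- quantifyPlate(wells)
  row <- res$samples[res$samples$sample_id == "C001" &
                       res$samples$gene == "CCND2", ]
  expect_true(row$wideSpread)
  expect_true(row$valid)
})
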
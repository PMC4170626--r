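test_that("build2x2 counts groups x calls with pairwise exclusion", {
  calls <- c(rep(TRUE, 10), rep(FALSE, 9), rep(TRUE, 2), rep(FALSE, 15))
  groups <- factor(rep(c("recurrent", "non-recurrent"), c(19, 17)),
                   levels = c("recurrent", "non-recurrent"))
  tab <- build2x2(calls, groups)
  expect_equal(unname(tableCounts(tab)),
               matrix(c(10, 9, 2, 15), 2, byrow = TRUE))
  expect_equal(rownames(tableCounts(tab)),
               c("recurrent", "non-recurrent"))
  ## missing calls drop pairwise; margins match what remains
  calls[1:3] <- NA
  expect_equal(sum(tableCounts(build2x2(calls, groups))), 33)
  expect_error(build2x2(rep(NA, 5), rep(c("a", "b"), c(2, 3))),
               "no jointly observed")
  expect_error(build2x2(c(TRUE, FALSE), c("a", "a")), "two observed")
})

test_that("synthetic cohort margins match group sizes minus missingness", {
  cfg <- simulationConfig(seed = 41, nCases = 80, nControls = 60,
                          missingRate = 0.2)
  cohort <- simulateCohort(cfg)
  calls <- cohort$ratio_CCNA1 > 0
  tab <- tableCounts(build2x2(calls, cohort$group))
  expect_equal(rowSums(tab)[["case"]],
               sum(cohort$group == "case" & !is.na(calls)))
  expect_equal(rowSums(tab)[["control"]],
               sum(cohort$group == "control" & !is.na(calls)))
})

test_that("hypergeometric pmf is exact on small margins", {
  expect_equal(hypergeomPmf(0:1, r1 = 1, r2 = 1, k = 1), c(0.5, 0.5))
  ## infeasible cells have probability 0
  expect_equal(hypergeomPmf(5, r1 = 3, r2 = 4, k = 4), 0)
  expect_equal(hypergeomPmf(-1, r1 = 3, r2 = 4, k = 4), 0)
  ## normalization over the feasible support
  set.seed(42)
  for (i in 1:20) {
    r1 <- sample(0:15, 1); r2 <- sample(0:15, 1)
    k <- sample(0:(r1 + r2), 1)
    supp <- max(0, k - r2):min(r1, k)
    expect_equal(sum(hypergeomPmf(supp, r1, r2, k)), 1, tolerance = 1e-12)
  }
  ## exact factorial evaluation, margins <= 12
  for (i in 1:50) {
    r1 <- sample(1:12, 1); r2 <- sample(1:12, 1)
    k <- sample(0:(r1 + r2), 1)
    feasible <- max(0, k - r2):min(r1, k)
    a <- feasible[sample.int(length(feasible), 1)]
    direct <- (factorial(r1) / (factorial(a) * factorial(r1 - a))) *
      (factorial(r2) / (factorial(k - a) * factorial(r2 - k + a))) /
      (factorial(r1 + r2) / (factorial(k) * factorial(r1 + r2 - k)))
    expect_equal(hypergeomPmf(a, r1, r2, k), direct, tolerance = 1e-12)
  }
})

test_that("two-sided exact test handles the textbook edge cases", {
  expect_equal(fisherExactTwoSided(contingency2x2(1, 0, 0, 1)), 1)
  ## zero row or column margin: a single feasible table
  expect_equal(fisherExactTwoSided(contingency2x2(0, 0, 3, 4)), 1)
  expect_equal(fisherExactTwoSided(contingency2x2(0, 3, 0, 4)), 1)
  p <- fisherExactTwoSided(contingency2x2(10, 9, 2, 15))
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("exact test agrees with fisher.test across random tables", {
  set.seed(43)
  for (i in 1:300) {
    m <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2)
    if (sum(m) == 0) m[1, 1] <- 1
    expect_equal(fisherExactTwoSided(m), fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("exact test is invariant under row/column swaps and transpose", {
  set.seed(44)
  for (i in 1:40) {
    m <- matrix(rpois(4, 7), 2)
    if (sum(m) == 0) m[2, 2] <- 3
    p <- fisherExactTwoSided(m)
    expect_equal(fisherExactTwoSided(m[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisherExactTwoSided(m[, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisherExactTwoSided(t(m)), p, tolerance = 1e-12)
  }
})

test_that("exact test matches the exact-integer enumeration oracle", {
  set.seed(45)
  tables <- data.frame(a = rpois(60, 6), b = rpois(60, 6),
                       c = rpois(60, 6), d = rpois(60, 6))
  tables <- tables[rowSums(tables) > 0, ]
  ours <- apply(tables, 1, function(r)
    fisherExactTwoSided(matrix(r, 2, byrow = TRUE)))
  oracle <- pythonFisherOracle(tables)
  expect_equal(ours, oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("chi-square test behaves and tracks the exact test", {
  prop <- chiSquareTest(contingency2x2(10, 10, 5, 5))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p.value, 1)
  expect_error(chiSquareTest(contingency2x2(0, 0, 3, 4)), "zero margin")
  tab <- contingency2x2(10, 9, 2, 15)
  expect_lt(abs(chiSquareTest(tab)$p.value - fisherExactTwoSided(tab)),
            0.02)
})

test_that("type-I error of both tests is controlled under the null", {
  set.seed(46)
  nRep <- 2000
  rejF <- rejC <- logical(nRep)
  for (i in seq_len(nRep)) {
    calls <- runif(60) < 0.4
    groups <- rep(c("a", "b"), 30)
    tab <- build2x2(calls, groups)
    rejF[i] <- fisherExactTwoSided(tab) < 0.05
    m <- tableCounts(tab)
    rejC[i] <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) FALSE
      else chiSquareTest(m)$p.value < 0.05
  }
  se <- sqrt(0.05 * 0.95 / nRep)
  ## the exact test is conservative by construction
  expect_lte(mean(rejF), 0.05 + 3 * se)
  expect_lt(abs(mean(rejC) - 0.05), 3 * se + 0.01)
})

test_that("auto test choice follows the expected-count rule", {
  small <- associationTest(contingency2x2(2, 3, 1, 4))
  expect_equal(small$method, "fisher")
  big <- associationTest(contingency2x2(30, 40, 25, 45))
  expect_equal(big$method, "chisq")
  forced <- associationTest(contingency2x2(30, 40, 25, 45), "fisher")
  expect_equal(forced$method, "fisher")
  zero <- associationTest(contingency2x2(0, 0, 3, 4))
  expect_equal(zero$method, "fisher")
  expect_equal(zero$p.value, 1)
})

test_that("association report reproduces per-marker tables from a cohort", {
  cohort <- data.frame(
    grp = rep(c("case", "control"), each = 6),
    CCND2 = c("+", "+", "+", "-", "-", NA, "-", "-", "-", "-", "-", "-"),
    CALCA = c("+", "+", "+", "+", "-", "-", "+", "-", "-", "-", "-", "-"))
  rep <- associationReport(cohort, c("CCND2", "CALCA"), "grp")
  expect_equal(nrow(rep), 2)
  expect_equal(rep$a[rep$gene == "CCND2"], 3)
  expect_equal(rep$b[rep$gene == "CCND2"], 2)
  expect_equal(rep$test, c("fisher", "fisher"))
  expect_equal(rep$p.value[1],
               fisherExactTwoSided(contingency2x2(3, 2, 0, 6)))
})
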
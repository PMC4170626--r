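test_that("perfectly separated classes reach sensitivity = specificity = 1", {
  ratios <- c(10, 20, 30, 0, 1, 2)
  labels <- rep(c(TRUE, FALSE), each = 3)
  roc <- buildRoc(ratios, labels)
  p <- rocPoints(roc)
  expect_true(any(p$sensitivity == 1 & p$specificity == 1))
  cut <- empiricCutoff(roc)
  ## the largest control value: strict ">" positivity
  expect_equal(cutoffValue(cut), 2)
  expect_equal(youdenJ(cut), 1)
})

test_that("identical score distributions carry no information", {
  cut <- selectCutoff(c(5, 5, 5, 5), c(TRUE, TRUE, FALSE, FALSE),
                      direction = "greater")
  expect_equal(youdenJ(cut), 0)
})

test_that("ROC preconditions are enforced", {
  expect_error(buildRoc(c(1, 2), c(TRUE, TRUE)), "single class")
  expect_error(buildRoc(c(1, NA), c(TRUE, FALSE)), "missing")
  expect_error(buildRoc(c(1, 2, 3), c(TRUE, FALSE)), "lengths differ")
})

test_that("ROC monotonicity: sensitivity falls and specificity rises", {
  set.seed(31)
  ratios <- c(rlnorm(40, 4, 1.5), rexp(40, 1))
  labels <- rep(c(TRUE, FALSE), each = 40)
  p <- rocPoints(buildRoc(ratios, labels))
  expect_true(all(diff(p$sensitivity) <= 1e-12))
  expect_true(all(diff(p$specificity) >= -1e-12))
  expect_true(all(p$sensitivity >= 0 & p$sensitivity <= 1))
})

test_that("permuted labels give a null AUC near 0.5", {
  set.seed(32)
  ratios <- rnorm(50)
  aucs <- vapply(1:200, function(i) {
    rocAuc(buildRoc(ratios, sample(rep(c(TRUE, FALSE), 25))))
  }, 0)
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  ratios <- c(rlnorm(30, 4, 1), rlnorm(30, 2, 1))
  labels <- rep(c(1, 0), each = 30)
  ours <- rocAuc(buildRoc(ratios, labels == 1))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, ratios, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("empiric cutoff J matches an exhaustive brute-force scan", {
  set.seed(34)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    ratios <- round(rlnorm(n, 3, 2), 2) * rbinom(n, 1, 0.8)
    cut <- selectCutoff(ratios, labels, direction = "greater")
    expect_equal(youdenJ(cut), bruteForceBestJ(ratios, labels),
                 tolerance = 1e-12)
  }
})

test_that("auto direction picks the side with the larger J", {
  set.seed(35)
  up <- c(rlnorm(30, 5, 1), rlnorm(30, 1, 1))
  labels <- rep(c(TRUE, FALSE), each = 30)
  expect_equal(positiveDirection(selectCutoff(up, labels)), "greater")
  ## scores lower in the positive class: direction flips
  expect_equal(positiveDirection(selectCutoff(-up, labels)), "less")
})

test_that("dichotomization is strict, monotone and records its cutoff", {
  cut <- selectCutoff(c(10, 20, 30, 0, 1, 2),
                      rep(c(TRUE, FALSE), each = 3), gene = "CCND2")
  calls <- dichotomize(c(0, 1000, NA, 2), cut)
  expect_identical(as.logical(calls), c(FALSE, TRUE, NA, FALSE))
  expect_equal(attr(calls, "gene"), "CCND2")
  ## score 0 at cutoff 0 is unmethylated (strict inequality)
  zeroCut <- new("MarkerCutoff", gene = "g", value = 0,
                 direction = "greater", youden = 0.5, sensitivity = 0.7,
                 specificity = 0.8)
  expect_false(as.logical(dichotomize(0, zeroCut)))
  ## monotone: raising a score never turns a positive negative
  set.seed(36)
  r <- rlnorm(50, 3, 1)
  before <- as.logical(dichotomize(r, cut))
  after <- as.logical(dichotomize(r + rexp(50), cut))
  expect_true(all(after >= before))
})

test_that("training-set calls reproduce the recorded operating point", {
  set.seed(37)
  ratios <- rlnorm(60, 3, 2) * rbinom(60, 1, 0.7)
  labels <- rep(c(TRUE, FALSE), 30)
  cut <- selectCutoff(ratios, labels, direction = "greater")
  calls <- as.logical(dichotomize(ratios, cut))
  expect_equal(mean(calls[labels]), cut@sensitivity)
  expect_equal(mean(!calls[!labels]), cut@specificity)
})

test_that("cutoff selection is invariant under increasing transforms", {
  set.seed(38)
  ratios <- rlnorm(40, 3, 1.5) * rbinom(40, 1, 0.8)
  labels <- rep(c(TRUE, FALSE), 20)
  cut1 <- selectCutoff(ratios, labels, direction = "greater")
  f <- function(x) log1p(x)^3 + 2 * x   # strictly increasing
  cut2 <- selectCutoff(f(ratios), labels, direction = "greater")
  expect_equal(youdenJ(cut1), youdenJ(cut2), tolerance = 1e-12)
  expect_identical(as.logical(dichotomize(ratios, cut1)),
                   as.logical(dichotomize(f(ratios), cut2)))
})

test_that("cutoff tables survive a serialization round trip", {
  cut <- selectCutoff(c(10, 20, 30, 0, 1, 2),
                      rep(c(TRUE, FALSE), each = 3), gene = "CCND2")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCutoffTsv(list(cut), path)
  back <- readCutoffTsv(path)[["CCND2"]]
  expect_equal(cutoffValue(back), cutoffValue(cut))
  expect_equal(youdenJ(back), youdenJ(cut))
  expect_equal(positiveDirection(back), positiveDirection(cut))
})
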
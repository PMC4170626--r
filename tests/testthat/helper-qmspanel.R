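## Shared fixture builders (everything is generated in code).

## Standard wells on an exact line Ct = intercept + slope * log10(ng).
makeStandardWells <- function(quantities = c(90, 9, 0.9, 0.09, 0.009),
                              slope = -3.3219, intercept = 24,
                              gene = "CCND2", replicates = 3L,
                              noiseSd = 0) {
  q <- rep(quantities, each = replicates)
  ct <- intercept + slope * log10(q)
  if (noiseSd > 0) ct <- ct + stats::rnorm(length(ct), 0, noiseSd)
  data.frame(sample_id = paste0("STD", seq_along(q)), gene = gene,
             replicate = rep(seq_len(replicates), length(quantities)),
             ct = ct, role = "standard", quantity_ng = q,
             stringsAsFactors = FALSE)
}

markerColumns <- c("CCNA1", "CCND2", "CALCA")

## Brute-force two-sided Fisher p through explicit factorials; exact for
## small margins, independent of the log-gamma implementation.
bruteForceFisherP <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); k <- sum(m[, 1]); N <- r1 + r2
  supp <- max(0, k - r2):min(r1, k)
  pmf <- vapply(supp, function(x)
    choose(r1, x) * choose(r2, k - x) / choose(N, k), 0)
  obs <- pmf[supp == m[1, 1]]
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

## Exhaustive-scan Youden oracle: every observed value (and one below) as
## cutoff, strict ">" positivity.
bruteForceBestJ <- function(ratios, labels) {
  cand <- c(min(ratios) - 1, sort(unique(ratios)))
  j <- vapply(cand, function(ct)
    mean(ratios[labels] > ct) + mean(ratios[!labels] <= ct) - 1, 0)
  max(j)
}

## Exact-integer enumeration oracle for the two-sided Fisher test, run
## through the system python (arbitrary-precision integers). Takes a
## data.frame with columns a, b, c, d; returns the p-values.
pythonFisherOracle <- function(tables) {
  script <- test_path("fisher_oracle.py")
  input <- tempfile(fileext = ".csv")
  on.exit(unlink(input))
  utils::write.table(tables[, c("a", "b", "c", "d")], input, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  out <- system2("python", c(script, input), stdout = TRUE)
  as.numeric(out)
}
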
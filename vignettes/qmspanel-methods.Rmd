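---
title: "Methods: QMSP calibration, empiric cutoffs and panel evaluation"
author: "qmspanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QMSP calibration, empiric cutoffs and panel evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmspanel)
```

## The assay model

Quantitative methylation-specific PCR amplifies bisulfite-converted DNA
with primers and a probe specific to the *methylated* sequence of a
promoter, alongside a methylation-independent reference amplicon
(β-actin) that measures total input DNA. Real-time fluorescence yields a
threshold cycle Ct per well; within an assay's dynamic range Ct is linear
in log10 of input amount:

$$\mathrm{Ct} = b_0 + b_1 \log_{10}(q), \qquad b_1 < 0,$$

with $b_1 = -3.3219$ cycles per decade at 100 % amplification efficiency
($-1/\log_{10} 2$). Each plate carries a serial dilution (90 to 0.009 ng)
of fully methylated DNA from which `fitStandardCurve()` estimates
$(b_0, b_1)$ by ordinary least squares per gene; `quantityFromCt()`
inverts the line. The per-sample methylation score is

$$\mathrm{score} = \frac{\overline{q}_{\text{gene}}}
  {\overline{q}_{\beta\text{-actin}}} \times 1000,$$

with triplicates averaged **on the quantity scale**: the score is defined
as a ratio of averaged amounts, and quantity-scale averaging keeps it
exactly linear in target amount and invariant to rescaling both amplicons
(both properties are tested). Averaging on the Ct scale (a geometric
quantity mean) is a defensible alternative the package does not default
to.

### Conventions for undetermined wells

A well that never crosses threshold within the 50-cycle program carries
no Ct. For a *target* gene this is biologically meaningful — no
methylated template — so undetermined target replicates enter the average
as quantity 0. For the *reference* gene absence of signal invalidates the
sample instead: `qcSample()` fails a sample whose β-actin replicates are
all undetermined, or whose mean determined β-actin Ct exceeds 40 (the
assay's stated reproducibility bound). Partially undetermined reference
triplicates keep only their determined replicates in the denominator
mean; zero-filling there would silently inflate every score, the opposite
of what a conservative QC should do. These conventions are recorded in
the output (`valid`, `reason`) rather than applied silently.

Replicate outliers are never rejected — a replicate Ct range above 1
cycle only raises the `wideSpread` flag — because the assay protocol
defines no rejection rule, and silent rejection would be invisible
downstream.

## Empiric cutoffs

Markers are dichotomized at a per-gene "empiric cutoff": the point of the
empirical ROC maximizing Youden's $J = \text{sensitivity} +
\text{specificity} - 1$. Numerical choices, each made for exact
reproducibility without interpolation:

* candidate cutoffs are the *observed* score values plus one sentinel
  below the minimum (the all-positive operating point), not midpoints;
* positivity is strict (`score > cutoff`), so a score of 0 — no
  amplification — is negative even at cutoff 0, matching the observation
  that fully unmethylated control cohorts can show 0 positives;
* ties in $J$ are broken by higher specificity, then by lower cutoff
  value;
* with `direction = "auto"` both orientations are scanned and the larger
  $J$ kept ("greater" on ties).

The scan is invariant under strictly increasing transforms of the scores,
and its $J$ matches an exhaustive brute-force oracle in the tests. As in
the source study design, cutoffs are selected and applied on the same
cohort; this is an acknowledged optimism bias (the recovered $J$ is
slightly upward-biased at small $n$), which is why the recovery tests
compare against the generating optimum with a tolerance rather than
expecting unbiasedness.

## Association tests

`fisherExactTwoSided()` implements the exact conditional test with the
probability-mass two-sided rule: sum the hypergeometric probabilities of
all tables with the observed margins whose probability does not exceed
the observed table's. Probabilities are computed in log-gamma space
(`lchoose`) for overflow safety, with a $1 + 10^{-7}$ relative slack on
the comparison to absorb floating-point ties between symmetric tables —
the convention used by standard statistical software, and the one that
reproduces the published p-values the package ships as fixtures. The
test suite verifies the kernel three independent ways: against
`stats::fisher.test`, against explicit factorial arithmetic at small
margins, and against an exact-integer full-enumeration oracle (Python
arbitrary-precision integers) over *every* 2×2 table with $N \le 40$.

The χ² test (1 df, optional Yates correction) delegates to
`stats::chisq.test`; "as appropriate" is operationalized as: exact test
whenever any expected cell count is below 5 or a margin is zero, χ²
otherwise. Both are always available explicitly. No multiple-testing
correction is applied anywhere, matching the study design the package
reproduces.

## Panel evaluation

The any-positive panel call is positive when at least one *observed*
marker is methylated, negative when every observed marker is
unmethylated, and missing only when no marker was observed. Ignoring
missing markers (rather than propagating missingness) is the rule that
reproduces the published per-patient "Any positive" column exactly,
including its NA-containing rows, and it is the clinically conservative
choice for a rule whose purpose is sensitivity. Rates are reported with
explicit numerators and denominators; undefined rates (empty
denominator) are `NA`, never 0. Printed-style integer percentages round
half away from zero.

## The synthetic-data generator

`simulateCohort()`/`simulatePlate()` emulate the study conditions: a
cohort of cases and controls (defaults 148/56, the urine study size);
three markers (CCND2, CCNA1, CALCA) with case/control methylation
prevalences 0.256/0, 0.684/0.166, 0.635/0.285 (the published
frequencies); per-marker missingness 0.1 (the published cohort loses
roughly this fraction of measurements per marker); cytology sensitivity
0.5 (the published 44/88) and specificity 0.95 (typical of cytology,
which is highly specific; no study value exists).

Truly methylated samples draw their ×1000 score from a log-normal,
`meanlog = log(100)`, `sdlog = 1.5`. The study's scatter plots span
roughly four orders of magnitude on log axes with zeros plotted off-scale
— i.e. a zero-inflated, heavy-tailed positive continuum — and a
log-normal is the simplest distribution with that shape. The exact
distribution among methylated samples is a modelling decision, not an
observed quantity; nothing downstream depends on its precise form, since
the cutoff machinery is rank-based. Unmethylated samples sit exactly at
`backgroundRatio = 0` (no amplification), with small positive leakage
available as an option.

Plate emulation: Ct noise is Gaussian per well (`ctNoiseSd = 0.25`
cycles, a typical replicate SD for TaqMan assays); per-sample reference
input is log-normal around 5 ng; marker input is
`score / 1000 × reference input`, so the generator and the quantifier
are exact inverses when noise is 0 — the pipeline-identity test. A
single integer seed drives everything; each stream (standards per gene,
cohort, plate) derives its own substream seed deterministically, so
components are reproducible in isolation.

What the generator does **not** emulate: bisulfite-conversion
efficiency, primer thermodynamics, PCR inhibition, plate-position
effects, or correlated markers (markers are independent given group).
Passing tests on synthetic cohorts therefore demonstrate correctness of
the *analysis* under the stated sampling model, not robustness to every
artefact of real plates.

## Problem sizes and tolerances in the test suite

Monte-Carlo checks use: 100–200 seeds for slope recovery (noise SD
0.2–0.3 cycles), 5 000 patients per arm for prevalence convergence (3
standard errors), 2 000 replicates for test calibration, 100 simulated
cohorts of 200 per arm for cutoff/prevalence recovery (Youden within 0.1
of the generating optimum and exact 95 % binomial-interval coverage, each
required at rate ≥ 0.90 — coverage statements, not per-replicate
guarantees). Exact identities (noiseless pipeline, ΔΔCT) are asserted at
relative 10⁻⁹ or tighter; the Fisher kernel is asserted at 10⁻⁹ against
the integer oracle.

## Known limitations

* Cutoffs are trained and evaluated on the same cohort by default
  (matching the reproduced study); a k-fold mode is a natural extension
  the package does not currently implement.
* The exact test's two-sided rule is the probability-mass convention;
  other two-sided conventions (doubling, central) give different
  p-values and are not provided.
* No odds-ratio confidence intervals, logistic regression, survival or
  follow-up-time stratification: the reproduced study explicitly did not
  perform them, and the package stays within that scope.
* `foldChangeTable()` pairs expression replicates by index for its
  t-test on ΔCt values, which assumes replicate $i$ of target and
  reference share a plate context.
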
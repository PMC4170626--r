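## Internal helpers shared across modules.

## Deterministic substream seed: one global integer seed, per-stream seeds
## derived from it by hashing the stream name. Keeps independent stages
## (standards vs cohort vs plate noise) reproducible in isolation.
.streamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## Round half away from zero, the convention used for the printed integer
## percentages (e.g. 25/30 -> 83%).
roundHalfAwayFromZero <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## "+" / "-" / NA coding used in cohort tables <-> logical calls.
.plusToLogical <- function(x) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  out <- rep(NA, length(x))
  out[!is.na(x) & x == "+"] <- TRUE
  out[!is.na(x) & x == "-"] <- FALSE
  bad <- !is.na(x) & !x %in% c("+", "-", "NA", "")
  if (any(bad))
    stop("invalid call code(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected \"+\", \"-\" or NA)")
  out
}

.logicalToPlus <- function(x) {
  out <- rep(NA_character_, length(x))
  out[which(x)] <- "+"
  out[which(!x)] <- "-"
  out
}

## Exact (Clopper-Pearson style) central 95% interval bounds on a binomial
## count; used by the recovery checks.
binomialInterval <- function(n, p, conf = 0.95) {
  alpha <- 1 - conf
  lower <- stats::qbinom(alpha / 2, n, p)
  upper <- stats::qbinom(1 - alpha / 2, n, p)
  c(lower = lower, upper = upper)
}
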
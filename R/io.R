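## File-format contracts tying the pipeline stages together.
##
## Plate CSV: header sample_id,gene,replicate,ct,role,quantity_ng; the ct
## field is numeric or the literal token "Undetermined" (mirroring
## sequence-detector exports); UTF-8, comma separator, "." decimal.
## Cohort TSV: tab separator, "+"/"-"/"NA" codes for binary clinical and
## marker columns.

.PLATE_COLUMNS <- c("sample_id", "gene", "replicate", "ct", "role",
                    "quantity_ng")

#' Read a plate CSV of well records
#'
#' Parses the plate dialect (columns \code{sample_id, gene, replicate,
#' ct, role, quantity_ng}; \code{ct} numeric or the literal
#' \code{Undetermined}). Malformed content raises an error naming the row
#' and column.
#'
#' @param path file path.
#' @return well-record data.frame with \code{NA} ct for undetermined
#'   wells.
#' @export
readPlateCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot parse plate file '", path, "': ",
                             conditionMessage(e)))
  miss <- setdiff(.PLATE_COLUMNS, names(raw))
  if (length(miss))
    stop("plate file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(raw)) stop("plate file '", path, "' contains no wells")
  parseNum <- function(x, col, allowNA = FALSE) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !(allowNA & (is.na(x) | x == "" |
                                             x == "NA")))
    if (length(bad))
      stop("plate file '", path, "': invalid value '", x[bad[1L]],
           "' in column '", col, "', row ", bad[1L])
    out
  }
  ct <- raw$ct
  und <- !is.na(ct) & ct == "Undetermined"
  ct[und] <- NA
  data.frame(
    sample_id = raw$sample_id,
    gene = raw$gene,
    replicate = as.integer(parseNum(raw$replicate, "replicate")),
    ct = parseNum(ct, "ct", allowNA = TRUE),
    role = raw$role,
    quantity_ng = parseNum(raw$quantity_ng, "quantity_ng", allowNA = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Write a plate CSV of well records
#'
#' @param wells well-record data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePlateCsv <- function(wells, path) {
  out <- wells[, .PLATE_COLUMNS]
  out$ct <- ifelse(is.na(out$ct), "Undetermined",
                   format(out$ct, digits = 15, trim = TRUE,
                          scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a cohort TSV
#'
#' Tab-separated per-patient table with "+"/"-"/"NA" codes, the shape in
#' which published per-patient marker tables can be transcribed verbatim.
#'
#' @param path file path.
#' @return data.frame with character "+"/"-" columns (\code{NA} for
#'   missing) and any numeric columns (e.g. \code{ratio_*}) parsed as
#'   numeric.
#' @export
readCohortTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA")
  if (!nrow(out)) stop("cohort file '", path, "' contains no rows")
  out
}

#' Write a cohort TSV
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCohortTsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Serialize / read marker cutoffs
#'
#' Cutoffs are explicit artifacts (gene, value, direction, youden), so
#' calls published at a fixed cutoff can be ingested without re-deriving
#' it.
#'
#' @param cutoffs list of \linkS4class{MarkerCutoff}.
#' @param path file path.
#' @return \code{writeCutoffTsv}: \code{path} invisibly;
#'   \code{readCutoffTsv}: named list of \linkS4class{MarkerCutoff}.
#' @export
writeCutoffTsv <- function(cutoffs, path) {
  df <- do.call(rbind, lapply(cutoffs, function(ct) data.frame(
    gene = markerName(ct), value = cutoffValue(ct),
    direction = positiveDirection(ct), youden = youdenJ(ct),
    sensitivity = ct@sensitivity, specificity = ct@specificity,
    stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeCutoffTsv
#' @export
readCutoffTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    new("MarkerCutoff", gene = df$gene[i], value = df$value[i],
        direction = df$direction[i], youden = df$youden[i],
        sensitivity = df$sensitivity[i], specificity = df$specificity[i]))
  names(out) <- df$gene
  out
}

#' Bundled per-patient urine cohort table
#'
#' The 70-patient low-grade urothelial carcinoma urine cohort shipped with
#' the package: cytology, cystoscopy, recurrence, grade, three marker
#' calls (CCNA1, CCND2, CALCA) and the published any-positive column, all
#' "+"/"-"/NA coded.
#'
#' @return cohort data.frame (70 rows).
#' @examples
#' cohort <- lguccUrineCohort()
#' nrow(cohort)
#' @export
lguccUrineCohort <- function() {
  readCohortTsv(system.file("extdata", "lgucc_urine_cohort.tsv",
                            package = "qmspanel", mustWork = TRUE))
}

#' Bundled published 2x2 methylation-frequency counts
#'
#' The printed cross-tabulations behind the association analyses: per
#' gene, each grouping (recurrence in tissue; urine cases vs controls;
#' grade; stage), the methylated/total counts in both groups and the
#' published two-sided p-value.
#'
#' @return data.frame with columns \code{panel}, \code{grouping},
#'   \code{gene}, \code{group1}, \code{group2}, \code{meth1}, \code{n1},
#'   \code{meth2}, \code{n2}, \code{printed_p}.
#' @export
publishedMethylationCounts <- function() {
  utils::read.delim(system.file("extdata", "published_2x2_counts.tsv",
                                package = "qmspanel", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
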
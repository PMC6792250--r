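# Expected-coverage arithmetic, depletion ratios, per-position depth,
# patchiness, and error-rate summaries for a query against a read set.

#' Expected aligned bases for a query
#'
#' The bases one expects a read dataset to contribute to a query:
#' `queryLen * copyNumber * datasetDepth`. The dataset fold-coverage is a
#' user input (for example 180X or 60X for a whole-genome long-read run),
#' never estimated internally.
#'
#' @param queryLen Query length in bp (> 0). The length of the supplied
#'   query sequence is always used, whatever inclusive/exclusive
#'   convention its accession coordinates follow.
#' @param copyNumber Genomic copy number of the query (>= 1).
#' @param datasetDepth Fold-coverage of the dataset (> 0).
#' @return Expected bases.
#' @examples
#' expectedCoverageBp(14705, 1, 60)  # 882300
#' @export
expectedCoverageBp <- function(queryLen, copyNumber, datasetDepth) {
  .assertScalarNumber(queryLen, "queryLen", positive = TRUE)
  .assertScalarNumber(copyNumber, "copyNumber", positive = TRUE)
  .assertScalarNumber(datasetDepth, "datasetDepth", positive = TRUE)
  queryLen * copyNumber * datasetDepth
}

#' Observed over expected coverage, as a percent
#'
#' `100 * observedBp / expectedBp` at full precision; rounding is left to
#' the caller.
#'
#' @param observedBp Total aligned query bases (>= 0).
#' @param expectedBp Expected bases (> 0).
#' @return Percent.
#' @examples
#' depletionPercent(98755, 882300)   # ~11.2
#' @export
depletionPercent <- function(observedBp, expectedBp) {
  .assertScalarNumber(observedBp, "observedBp", nonneg = TRUE)
  .assertScalarNumber(expectedBp, "expectedBp", positive = TRUE)
  100 * observedBp / expectedBp
}

#' Per-position alignment depth and patchiness
#'
#' `depth[i]` is the number of retained alignments whose query interval
#' contains position `i`; patchiness is the percent of query positions
#' with zero depth.
#'
#' @param alignments Alignment table from [recruitReads()] (all rows must
#'   reference the same query), or a [CoverageReport] (returns its stored
#'   profile).
#' @param queryLen Query length in bp.
#' @return A list with integer vector `depth` and `patchiness` (percent).
#' @export
depthProfile <- function(alignments, queryLen = NULL) {
  if (is(alignments, "CoverageReport"))
    return(list(depth = alignments@depthProfile,
                patchiness = alignments@patchiness))
  if (is.null(queryLen)) queryLen <- S4Vectors::metadata(alignments)$queryLen
  .assertScalarNumber(queryLen, "queryLen", positive = TRUE)
  df <- as.data.frame(alignments)
  if (nrow(df) > 0 && (any(df$qstart < 1L) || any(df$qend > queryLen)))
    stop("alignment interval outside the query")
  depth <- integer(queryLen)
  if (nrow(df) > 0) {
    cov <- IRanges::coverage(IRanges::IRanges(df$qstart, df$qend),
                             width = queryLen)
    depth <- as.integer(cov)
  }
  list(depth = depth, patchiness = 100 * sum(depth == 0L) / queryLen)
}

#' Assemble a coverage report for one query
#'
#' Combines [expectedCoverageBp()], observed aligned bases,
#' [depletionPercent()], [depthProfile()] and the per-alignment error-rate
#' summary into a [CoverageReport-class]. With no alignments the report has
#' observed 0, depletion 0 and patchiness 100.
#'
#' @param query Query sequence (or a single id string combined with
#'   `queryLen`).
#' @param alignments Alignment table from [recruitReads()].
#' @param copyNumber,datasetDepth See [expectedCoverageBp()].
#' @param queryId Identifier used in the report.
#' @return A [CoverageReport-class].
#' @export
coverageReport <- function(query, alignments, copyNumber = 1,
                           datasetDepth, queryId = "query") {
  query <- .asDNAString(query, "query")
  queryLen <- length(query)
  expected <- expectedCoverageBp(queryLen, copyNumber, datasetDepth)
  df <- as.data.frame(alignments)
  observed <- if (nrow(df)) sum(df$qend - df$qstart + 1) else 0
  prof <- depthProfile(alignments, queryLen)
  err <- if (nrow(df)) {
    e <- alignmentErrorRate(alignments)
    c(mean = mean(e), min = min(e), max = max(e))
  } else c(mean = NA_real_, min = NA_real_, max = NA_real_)
  new("CoverageReport", queryId = queryId, queryLen = queryLen,
      copyNumber = copyNumber, datasetDepth = datasetDepth,
      observedBp = as.numeric(observed), expectedBp = expected,
      depletionPercent = depletionPercent(observed, expected),
      depthProfile = prof$depth, patchiness = prof$patchiness,
      errorRateSummary = err)
}

#' Write a coverage report as JSON and/or TSV
#'
#' @param report A [CoverageReport-class].
#' @param jsonPath,tsvPath Output files (either may be `NULL`).
#' @return Paths written, invisibly.
#' @export
writeCoverageReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  x <- list(query_id = report@queryId, query_len = report@queryLen,
            copy_number = report@copyNumber,
            dataset_depth = report@datasetDepth,
            observed_bp = report@observedBp, expected_bp = report@expectedBp,
            depletion_percent = report@depletionPercent,
            patchiness = report@patchiness,
            error_rate_mean = report@errorRateSummary[["mean"]],
            error_rate_min = report@errorRateSummary[["min"]],
            error_rate_max = report@errorRateSummary[["max"]])
  if (!is.null(jsonPath))
    jsonlite::write_json(x, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(tsvPath)) {
    df <- as.data.frame(x)
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(json = jsonPath, tsv = tsvPath))
}

#' Write a depth profile as bedGraph
#'
#' Runs of equal depth are emitted as 0-based half-open intervals.
#'
#' @param report A [CoverageReport-class] (or the list from
#'   [depthProfile()]).
#' @param path Output file.
#' @param queryId Chrom name; defaults to the report's query id.
#' @return `path`, invisibly.
#' @export
writeDepthBedGraph <- function(report, path, queryId = NULL) {
  if (is(report, "CoverageReport")) {
    depth <- report@depthProfile
    if (is.null(queryId)) queryId <- report@queryId
  } else {
    depth <- report$depth
    if (is.null(queryId)) queryId <- "query"
  }
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  df <- data.frame(chrom = queryId, start = starts, end = ends,
                   value = r$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
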
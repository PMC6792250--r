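# Read recruitment by exact k-mer seeding and banded local alignment
# (Smith-Waterman/Gotoh with affine gaps), replacing external blastn/blasr
# searches. Scoring: match +1, mismatch -2, gap open -2, gap extend -1;
# band half-width max(32, 0.2 * read span) -- tolerant of ~25% error.

.ALN_SCORES <- c(match = 1L, mismatch = -2L, gapOpen = 2L, gapExt = 1L)

.emptyAlignments <- function() {
  S4Vectors::DataFrame(readId = character(0), qstart = integer(0),
                       qend = integer(0), rstart = integer(0),
                       rend = integer(0), strand = character(0),
                       matches = integer(0), mismatches = integer(0),
                       insertions = integer(0), deletions = integer(0),
                       identity = numeric(0), score = integer(0),
                       cigar = character(0), lowConfidence = logical(0))
}

# Cluster seed hits (0-based qpos/rpos) into candidate loci by diagonal
# proximity, then by query-position continuity.
.clusterSeeds <- function(qpos, rpos, band, readLen) {
  diag <- qpos - rpos
  ord <- order(diag)
  qpos <- qpos[ord]; rpos <- rpos[ord]; diag <- diag[ord]
  grp <- cumsum(c(1L, diff(diag) > band))
  out <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    q <- qpos[sel]; r <- rpos[sel]; d <- diag[sel]
    o2 <- order(q)
    q <- q[o2]; r <- r[o2]; d <- d[o2]
    sub <- cumsum(c(1L, diff(q) > readLen))
    for (s in unique(sub)) {
      ss <- sub == s
      out[[length(out) + 1L]] <- list(qpos = q[ss], rpos = r[ss], diag = d[ss])
    }
  }
  out
}

# Align one read (given orientation) against the query around one seed
# cluster. Returns a one-row data.frame in window-shifted query coordinates
# (1-based closed) or NULL.
.alignCluster <- function(qseq, qlen, rseq, cl, band) {
  qlo <- max(0L, min(cl$diag) - band)
  qhi <- min(qlen, max(cl$diag) + nchar(rseq) + band)
  if (qhi - qlo < 1L) return(NULL)
  window <- substring(qseq, qlo + 1L, qhi)
  diag0 <- as.integer(round(median(cl$diag))) - qlo
  res <- .banded_local_align(window, rseq, diag0, as.integer(band),
                             .ALN_SCORES[["match"]], .ALN_SCORES[["mismatch"]],
                             .ALN_SCORES[["gapOpen"]], .ALN_SCORES[["gapExt"]])
  if (res$score <= 0) return(NULL)
  data.frame(qstart = qlo + res$sub_start + 1L, qend = qlo + res$sub_end,
             rstart = res$pat_start + 1L, rend = res$pat_end,
             matches = res$matches, mismatches = res$mismatches,
             insertions = res$insertions, deletions = res$deletions,
             score = res$score, cigar = res$cigar,
             stringsAsFactors = FALSE)
}

#' Recruit reads matching a query sequence
#'
#' For each read at least `minReadLen` long, exact k-mer seeds against the
#' query are collected for the read and its reverse complement, chained by
#' diagonal into candidate loci, and extended by banded local alignment
#' (match +1, mismatch -2, gap open -2, gap extend -1; band half-width
#' `max(minBand, bandScale * read length)`). Alignments shorter than
#' `minAlnLen` columns or below `minIdentity` percent identity are
#' discarded; among alignments of the same read overlapping on the query,
#' only the best is kept (highest score, ties broken by longer alignment,
#' then leftmost query start), so multi-locus hits are reported once per
#' locus. Identity counts all alignment columns, gaps included. Alignments
#' below 75% identity are flagged low-confidence (sequences with error
#' rates above ~25% cannot be aligned reliably).
#'
#' @param query Query sequence (`DNAString`, string, or
#'   `GeneArchitecture`).
#' @param reads Reads (`DNAStringSet`, named character vector, or
#'   [ReadSimulation]).
#' @param k Seed k-mer length (>= 8).
#' @param minReadLen,minAlnLen,minIdentity Recruitment thresholds
#'   (defaults 400, 400, 70).
#' @param bandScale,minBand Band half-width parameters.
#' @return An [S4Vectors::DataFrame], one row per retained alignment, with
#'   columns `readId`, `qstart`, `qend`, `rstart`, `rend` (1-based closed;
#'   read coordinates always on the forward read), `strand`, `matches`,
#'   `mismatches`, `insertions`, `deletions`, `identity`, `score`,
#'   `cigar`, `lowConfidence`. The query length is stored in
#'   `metadata()$queryLen`.
#' @export
recruitReads <- function(query, reads, k = 13L, minReadLen = 400L,
                         minAlnLen = 400L, minIdentity = 70,
                         bandScale = 0.2, minBand = 32L) {
  query <- .asDNAString(query, "query")
  if (k < 8L) stop("k must be >= 8")
  if (length(query) < k) stop("query shorter than k")
  reads <- .asDNAStringSet(reads, "reads")
  qseq <- as.character(query)
  qlen <- length(query)
  rows <- list()
  for (i in seq_along(reads)) {
    rlen <- Biostrings::width(reads)[i]
    if (rlen < minReadLen) next
    rid <- names(reads)[i]
    band <- as.integer(max(minBand, ceiling(bandScale * rlen)))
    cands <- list()
    for (strand in c("+", "-")) {
      rseq <- if (strand == "+") as.character(reads[[i]])
              else as.character(Biostrings::reverseComplement(reads[[i]]))
      hits <- .kmer_seed_hits(qseq, rseq, as.integer(k))
      if (nrow(hits) == 0L) next
      for (cl in .clusterSeeds(hits[, 1], hits[, 2], band, rlen)) {
        a <- .alignCluster(qseq, qlen, rseq, cl, band)
        if (is.null(a)) next
        a$strand <- strand
        if (strand == "-") {
          # map interval on the reverse complement back to forward read
          rs <- rlen - a$rend + 1L
          re <- rlen - a$rstart + 1L
          a$rstart <- rs
          a$rend <- re
        }
        cands[[length(cands) + 1L]] <- a
      }
    }
    if (length(cands) == 0L) next
    df <- do.call(rbind, cands)
    cols <- df$matches + df$mismatches + df$insertions + df$deletions
    df$identity <- 100 * df$matches / cols
    df <- df[cols >= minAlnLen & df$identity >= minIdentity, , drop = FALSE]
    if (nrow(df) == 0L) next
    # best alignment per locus: greedy by score, drop overlapping rivals
    ord <- order(-df$score, -(df$qend - df$qstart), df$qstart)
    df <- df[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (a in seq_len(nrow(df))) {
      if (!keep[a]) next
      if (a < nrow(df)) {
        later <- (a + 1L):nrow(df)
        ovl <- pmin(df$qend[later], df$qend[a]) -
          pmax(df$qstart[later], df$qstart[a]) + 1L
        minw <- pmin(df$qend[later] - df$qstart[later],
                     df$qend[a] - df$qstart[a]) + 1L
        keep[later][ovl > 0.5 * minw] <- FALSE
      }
    }
    df <- df[keep, , drop = FALSE]
    df$readId <- rid
    rows[[length(rows) + 1L]] <- df
  }
  if (length(rows) == 0L) {
    out <- .emptyAlignments()
  } else {
    df <- do.call(rbind, rows)
    df$lowConfidence <- df$identity < 75
    out <- S4Vectors::DataFrame(
      readId = df$readId, qstart = df$qstart, qend = df$qend,
      rstart = df$rstart, rend = df$rend, strand = df$strand,
      matches = df$matches, mismatches = df$mismatches,
      insertions = df$insertions, deletions = df$deletions,
      identity = df$identity, score = df$score, cigar = df$cigar,
      lowConfidence = df$lowConfidence)
    out <- out[order(out$qstart, out$readId), ]
  }
  S4Vectors::metadata(out) <- list(queryLen = qlen)
  out
}

#' Error rate of an alignment
#'
#' `100 - identity`: mismatch, insertion and deletion columns over all
#' alignment columns, as a percent.
#'
#' @param a Alignment table (as returned by [recruitReads()]) or a vector
#'   of identities.
#' @return Numeric vector of per-alignment error rates (percent).
#' @export
alignmentErrorRate <- function(a) {
  if (is(a, "DataFrame") || is.data.frame(a)) return(100 - a$identity)
  100 - a
}

#' Presence/absence decision rule for database hits
#'
#' A query is called present ("positive hit") iff strictly more than 90%
#' of it is aligned and the identity is strictly above 95%.
#'
#' @param alignedQueryBp Aligned query bases.
#' @param identity Percent identity of the alignment.
#' @param queryLen Query length in bp.
#' @return Logical.
#' @examples
#' isPositiveHit(95, 96, 100)   # TRUE
#' isPositiveHit(90, 99, 100)   # FALSE: not more than 90%
#' isPositiveHit(95, 95, 100)   # FALSE: not above 95%
#' @export
isPositiveHit <- function(alignedQueryBp, identity, queryLen) {
  .assertScalarNumber(queryLen, "queryLen", positive = TRUE)
  (alignedQueryBp / queryLen > 0.90) & (identity > 95)
}

#' Contamination decision rule
#'
#' Percent of aligned reads in a file; below 2.5% is considered no
#' significant contamination (the bound itself counts as contaminated).
#'
#' @param nAligned,nTotal Aligned and total read counts.
#' @return A list with `percent` and logical `contaminated`.
#' @examples
#' contaminationFraction(24, 1000)  # 2.4%, clean
#' contaminationFraction(25, 1000)  # 2.5%, contaminated
#' @export
contaminationFraction <- function(nAligned, nTotal) {
  .assertScalarNumber(nTotal, "nTotal", positive = TRUE)
  .assertScalarNumber(nAligned, "nAligned", nonneg = TRUE)
  pct <- 100 * nAligned / nTotal
  list(percent = pct, contaminated = pct >= 2.5)
}

#' Write alignments as TSV
#'
#' Coordinates are written 0-based half-open.
#'
#' @param alignments Result of [recruitReads()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeAlignments <- function(alignments, path) {
  df <- as.data.frame(alignments)
  out <- data.frame(read_id = df$readId,
                    qstart = df$qstart - 1L, qend = df$qend,
                    rstart = df$rstart - 1L, rend = df$rend,
                    strand = df$strand, matches = df$matches,
                    mismatches = df$mismatches, ins = df$insertions,
                    del = df$deletions, identity = df$identity)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Minimal SAM output: one record per alignment with soft-clipped CIGAR
#' (M for both match and mismatch columns), suitable for samtools.
#'
#' @param alignments Result of [recruitReads()].
#' @param reads The recruited reads (`DNAStringSet` or [ReadSimulation]).
#' @param queryId Reference name for the header.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeAlignmentsSam <- function(alignments, reads, queryId, path) {
  reads <- .asDNAStringSet(reads, "reads")
  qlen <- S4Vectors::metadata(alignments)$queryLen
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", queryId, "\tLN:", qlen)), con)
  df <- as.data.frame(alignments)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    seq <- reads[[r$readId]]
    if (r$strand == "-") seq <- Biostrings::reverseComplement(seq)
    rlen <- length(seq)
    # CIGAR in aligned-read orientation; collapse =/X runs into M
    ops <- .parseCigar(r$cigar)
    ops$op[ops$op %in% c("=", "X")] <- "M"
    grp <- cumsum(c(1L, ops$op[-1] != ops$op[-length(ops$op)]))
    len <- tapply(ops$len, grp, sum)
    op <- tapply(ops$op, grp, `[`, 1L)
    cig <- paste0(as.integer(len), op, collapse = "")
    clipL <- if (r$strand == "+") r$rstart - 1L else rlen - r$rend
    clipR <- if (r$strand == "+") rlen - r$rend else r$rstart - 1L
    if (clipL > 0) cig <- paste0(clipL, "S", cig)
    if (clipR > 0) cig <- paste0(cig, clipR, "S")
    flag <- if (r$strand == "-") 16L else 0L
    writeLines(paste(r$readId, flag, queryId, r$qstart, 60L, cig, "*", 0L,
                     0L, as.character(seq), "*", sep = "\t"), con)
  }
  invisible(path)
}
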
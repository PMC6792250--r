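#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show slot
#' @importFrom stats quantile runif rbinom median setNames
#' @importFrom utils write.table read.table packageVersion
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom BiocGenerics start end width strand
#' @useDynLib nonBprofiler, .registration = TRUE
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.assertScalarNumber <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("`", name, "` must be a single number", call. = FALSE)
  if (positive && x <= 0)
    stop("`", name, "` must be > 0", call. = FALSE)
  if (nonneg && x < 0)
    stop("`", name, "` must be >= 0", call. = FALSE)
  invisible(x)
}

.asDNAString <- function(x, name = "sequence") {
  if (is(x, "DNAString")) return(x)
  if (is(x, "GeneArchitecture")) return(geneSequence(x))
  if (is.character(x) && length(x) == 1L) return(Biostrings::DNAString(x))
  stop("`", name, "` must be a DNAString, a single character string, ",
       "or a GeneArchitecture", call. = FALSE)
}

.asDNAStringSet <- function(x, name = "reads") {
  if (is(x, "ReadSimulation")) return(simReads(x))
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  stop("`", name, "` must be a DNAStringSet, character vector, ",
       "or ReadSimulation", call. = FALSE)
}

.revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Random DNA at a fixed GC percent: the exact number of G+C bases is
# round(n * gc / 100); identities and placements are drawn from the current
# RNG stream.
.randomDNA <- function(n, gcPercent) {
  if (n == 0L) return("")
  nGC <- round(n * gcPercent / 100)
  if (nGC > n || nGC < 0) stop("unreachable GC target: ", gcPercent, call. = FALSE)
  gc <- sample(c("G", "C"), nGC, replace = TRUE)
  at <- sample(c("A", "T"), n - nGC, replace = TRUE)
  chars <- character(n)
  pos <- if (nGC > 0L) sample.int(n, nGC) else integer(0)
  chars[pos] <- gc
  chars[setdiff(seq_len(n), pos)] <- at
  paste(chars, collapse = "")
}

# Parse an extended CIGAR (=, X, I, D) into op/len vectors.
.parseCigar <- function(cigar) {
  if (!nzchar(cigar)) return(list(op = character(0), len = integer(0)))
  toks <- regmatches(cigar, gregexpr("[0-9]+[=XID]", cigar))[[1]]
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

#' Global percent identity between two sequences
#'
#' Aligns two sequences end to end (Needleman-Wunsch, affine gaps) and
#' returns the percent of alignment columns that are matches, counting gap
#' columns in the denominator. Used to score a reconstructed consensus
#' against the sequence it was simulated from.
#'
#' @param a,b Sequences (`DNAString` or single character strings).
#' @return A single percent in `[0, 100]`.
#' @examples
#' sequenceIdentity("ACGTACGT", "ACGTACGT")
#' @export
sequenceIdentity <- function(a, b) {
  a <- .asDNAString(a, "a")
  b <- .asDNAString(b, "b")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}
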
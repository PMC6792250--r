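# Non-B DNA determinant scanning: strict G-quadruplex motifs, exact tandem
# repeats, dyad (inverted-repeat) candidates, and GC statistics.
#
# All hits are returned as GRanges on the forward strand of the scanned
# sequence, sorted by start, with a `class` metadata column in
# {g4, tandem, dyad} plus class-specific detail columns.

#' GC percent of a nucleotide sequence
#'
#' Computes `100 * (#G + #C) / (#A + #C + #G + #T)`. `N` and any other
#' ambiguity characters are excluded from numerator and denominator; if a
#' sequence has no unambiguous base the result is `NA`.
#'
#' @param x A `DNAString`, a single character string, or a
#'   `GeneArchitecture` (returns the stored value).
#' @return Percent G+C in `[0, 100]`, or `NA` if undefined.
#' @examples
#' gcPercent("GATC")   # 50
#' gcPercent("GCNN")   # 100: Ns excluded
#' @export
setMethod("gcPercent", "DNAString", function(x) {
  if (length(x) == 0L) stop("empty sequence")
  f <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) return(NA_real_)
  100 * (f[["G"]] + f[["C"]]) / denom
})

#' @rdname gcPercent
#' @export
setMethod("gcPercent", "character", function(x) {
  if (length(x) != 1L) stop("`x` must be a single sequence")
  gcPercent(Biostrings::DNAString(x))
})

#' Batch GC summary: median and quartiles
#'
#' Per-sequence GC percent summarised by quartile 1, median and quartile 3
#' (linear interpolation), as used to compare the GC-content distributions
#' of cDNA catalogues.
#'
#' @param seqs A `DNAStringSet`, character vector of sequences, or list.
#' @return Named numeric vector `c(q1=, median=, q3=)`.
#' @examples
#' gcSummary(c("GGCC", "GATC", "ATAT"))
#' @export
gcSummary <- function(seqs) {
  if (is(seqs, "XStringSet")) {
    vals <- vapply(seq_along(seqs), function(i) gcPercent(seqs[[i]]), numeric(1))
  } else {
    seqs <- as.character(unlist(seqs))
    if (length(seqs) < 1L) stop("need at least one sequence")
    vals <- vapply(seqs, gcPercent, numeric(1), USE.NAMES = FALSE)
  }
  q <- quantile(vals, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Sliding-window GC track
#'
#' @param x Sequence to profile.
#' @param window,step Window and step sizes in bp.
#' @return A list with `window`, `step` and `values` (percent per window);
#'   `values` has length `floor((L - window)/step) + 1` for `L >= window`.
#' @export
gcTrack <- function(x, window = 100L, step = 50L) {
  x <- .asDNAString(x)
  L <- length(x)
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  if (L < window) return(list(window = window, step = step, values = numeric(0)))
  starts <- seq(1L, L - window + 1L, by = step)
  vals <- vapply(starts, function(s) {
    gcPercent(Biostrings::subseq(x, s, s + window - 1L))
  }, numeric(1))
  list(window = as.integer(window), step = as.integer(step), values = vals)
}

# Scan one strand for the strict G4 motif: four maximal runs of >= 3 G
# separated by loops of 1-12 bases. Maximal runs make the G-run matching
# greedy (a long run is never split to start a motif earlier); a literal N
# invalidates a loop. Matches are leftmost and non-overlapping.
.g4OneStrand <- function(s) {
  m <- gregexpr("G{3,}", s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  bs <- as.integer(m)                      # 1-based block starts
  bl <- attr(m, "match.length")
  be <- bs + bl - 1L                       # block ends
  nb <- length(bs)
  if (nb < 4L) return(NULL)
  gaps <- bs[-1] - be[-nb] - 1L
  gapOk <- gaps >= 1L & gaps <= 12L
  if (any(gapOk)) {
    gapSeq <- substring(s, be[-nb] + 1L, bs[-1] - 1L)
    gapOk <- gapOk & !grepl("[^ACGT]", gapSeq)
  }
  hits <- list()
  b <- 1L
  while (b + 3L <= nb) {
    if (all(gapOk[b:(b + 2L)])) {
      hits[[length(hits) + 1L]] <- list(
        start = bs[b], end = be[b + 3L],
        runs = bl[b:(b + 3L)], loops = gaps[b:(b + 2L)])
      b <- b + 4L
    } else b <- b + 1L
  }
  hits
}

#' Scan for strict G-quadruplex motifs
#'
#' Detects the strict G4 motif: four runs of at least three guanines
#' separated by loops of 1-12 bases (any of A, C, G, T; a literal N, being
#' an unknown base, breaks both runs and loops). G runs are maximal
#' (greedy), matches are leftmost and non-overlapping per strand. With
#' `bothStrands` the reverse complement is scanned identically and hits are
#' mapped back to forward coordinates with strand `-`.
#'
#' @param x Sequence to scan.
#' @param bothStrands Also scan the reverse complement (default `TRUE`).
#' @param id Sequence name used in the result (default `"seq"`).
#' @return A `GRanges` sorted by start with columns `class` (`"g4"`),
#'   `detail` (comma-separated G-run lengths `/` loop lengths).
#' @examples
#' scanG4("GGGAGGGAGGGAGGG", bothStrands = FALSE)
#' @export
scanG4 <- function(x, bothStrands = TRUE, id = "seq") {
  x <- .asDNAString(x)
  s <- as.character(x)
  L <- length(x)
  rows <- list()
  add <- function(h, strand, L) {
    if (strand == "+") { st <- h$start; en <- h$end }
    else { st <- L - h$end + 1L; en <- L - h$start + 1L }
    data.frame(start = st, end = en, strand = strand,
               detail = paste0(paste(h$runs, collapse = ","), "/",
                               paste(h$loops, collapse = ",")),
               stringsAsFactors = FALSE)
  }
  for (h in .g4OneStrand(s)) rows[[length(rows) + 1L]] <- add(h, "+", L)
  if (bothStrands) {
    rc <- as.character(Biostrings::reverseComplement(x))
    for (h in .g4OneStrand(rc)) rows[[length(rows) + 1L]] <- add(h, "-", L)
  }
  if (length(rows) == 0L)
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  strand = character(0),
                                  class = character(0), detail = character(0)))
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, class = "g4", detail = df$detail)
  gr[order(GenomicRanges::start(gr), as.character(GenomicRanges::strand(gr)))]
}

#' Scan for exact tandem repeats
#'
#' For each period `p <= maxPeriod`, reports maximal runs where
#' `seq[i] == seq[i - p]` holds contiguously over unambiguous bases,
#' keeping runs with at least `minCopies` copies
#' (`floor(runLength / p)`) and run length `>= minLen`. When the same
#' stretch is describable at several periods, only the report whose period
#' is smallest survives (a hit is suppressed if a smaller-period hit's
#' interval contains it).
#'
#' An approximate mode (`maxMismatchFrac > 0`) additionally bridges
#' isolated single-position interruptions as long as the mismatch fraction
#' of the run stays below the threshold.
#'
#' @param x Sequence to scan.
#' @param maxPeriod Largest repeat unit length considered (default 20).
#' @param minCopies Minimum copy count (default 3).
#' @param minLen Minimum run length in bp (default 12).
#' @param maxMismatchFrac Fraction of within-run mismatches tolerated
#'   (default 0 = exact mode).
#' @param id Sequence name used in the result.
#' @return A `GRanges` sorted by start with columns `class` (`"tandem"`),
#'   `unit`, `period`, `copies`.
#' @examples
#' scanTandem("ACACACACAC")
#' @export
scanTandem <- function(x, maxPeriod = 20L, minCopies = 3L, minLen = 12L,
                       maxMismatchFrac = 0, id = "seq") {
  x <- .asDNAString(x)
  if (maxPeriod < 1L) stop("maxPeriod must be >= 1")
  s <- as.character(x)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  cand <- list()
  for (p in seq_len(min(maxPeriod, max(0L, L - 1L)))) {
    eq <- chars[(p + 1L):L] == chars[1:(L - p)] &
      valid[(p + 1L):L] & valid[1:(L - p)]
    if (maxMismatchFrac > 0) {
      # bridge isolated single mismatches, then re-check the global fraction
      r <- rle(eq)
      bridge <- !r$values & r$lengths == 1L &
        seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
      r$values[bridge] <- TRUE
      eq2 <- inverse.rle(r)
    } else eq2 <- eq
    r <- rle(eq2)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      st <- starts[k]          # index into eq; seq position st .. ends[k]+p
      runStart <- st           # 1-based start of the repeat region
      runEnd <- ends[k] + p
      runLen <- runEnd - runStart + 1L
      copies <- runLen %/% p
      if (copies < minCopies || runLen < minLen) next
      if (maxMismatchFrac > 0) {
        mm <- sum(!eq[st:ends[k]])
        if (mm / runLen > maxMismatchFrac) next
      }
      cand[[length(cand) + 1L]] <- list(start = runStart, end = runEnd,
                                        period = p, copies = copies)
    }
  }
  if (length(cand) == 0L)
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  class = character(0), unit = character(0),
                                  period = integer(0), copies = integer(0)))
  st <- vapply(cand, `[[`, integer(1) + 0L, "start")
  en <- vapply(cand, `[[`, integer(1) + 0L, "end")
  pe <- vapply(cand, `[[`, integer(1) + 0L, "period")
  co <- vapply(cand, `[[`, integer(1) + 0L, "copies")
  # suppress nested duplicates in favour of the smallest period
  keep <- rep(TRUE, length(st))
  for (i in seq_along(st)) {
    keep[i] <- !any(pe < pe[i] & st <= st[i] & en >= en[i])
  }
  st <- st[keep]; en <- en[keep]; pe <- pe[keep]; co <- co[keep]
  gr <- GenomicRanges::GRanges(
    seqnames = id, ranges = IRanges::IRanges(st, en), strand = "+",
    class = "tandem",
    unit = substring(s, st, st + pe - 1L), period = pe, copies = co)
  gr[order(GenomicRanges::start(gr), pe)]
}

#' Scan for dyad (inverted-repeat) candidates
#'
#' Reports positions where a left arm and the reverse complement of a right
#' arm match with at most `maxArmMismatch` Hamming mismatches, separated by
#' a loop of at most `maxLoop` bases. For every loop placement the arm is
#' extended outward to the longest length whose outer base pair matches and
#' whose mismatch count stays within budget; the innermost pair (adjacent
#' to the loop) must also match for an arm to exist. Overlapping candidates
#' are then reduced to local maxima by arm length (ties: smaller loop, then
#' leftmost start).
#'
#' @param x Sequence to scan.
#' @param minArm Minimum arm length (default 6; must be >= 3).
#' @param maxLoop Maximum loop length (default 50).
#' @param maxArmMismatch Hamming mismatch budget per arm pair (default 1).
#' @param id Sequence name used in the result.
#' @return A `GRanges` sorted by start with columns `class` (`"dyad"`),
#'   `arm`, `loop`, `mismatches`.
#' @examples
#' scanDyad("GGGGGGAAAAACCCCCC")
#' @export
scanDyad <- function(x, minArm = 6L, maxLoop = 50L, maxArmMismatch = 1L,
                     id = "seq") {
  if (minArm < 3L) stop("minArm must be >= 3")
  x <- .asDNAString(x)
  cand <- .dyad_candidates(as.character(x), as.integer(minArm),
                           as.integer(maxLoop), as.integer(maxArmMismatch))
  if (nrow(cand) == 0L)
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  class = character(0), arm = integer(0),
                                  loop = integer(0), mismatches = integer(0)))
  # 0-based half-open -> 1-based closed
  cand$start <- cand$start + 1L
  ord <- order(-cand$arm, cand$loop, cand$start)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(0)
  ks <- integer(0); ke <- integer(0)
  keepIdx <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s0 <- cand$start[i]; e0 <- cand$end[i]
    if (!any(s0 <= ke & e0 >= ks)) {
      keepIdx <- c(keepIdx, i)
      ks <- c(ks, s0); ke <- c(ke, e0)
    }
  }
  cand <- cand[keepIdx, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = id, ranges = IRanges::IRanges(cand$start, cand$end),
    strand = "+", class = "dyad", arm = cand$arm, loop = cand$loop,
    mismatches = cand$mismatches)
  BiocGenerics::sort(gr)
}

#' Annotate all non-B DNA determinants of a sequence
#'
#' Runs the G4, tandem and dyad scanners, merges the hit intervals, and
#' reports the fraction of the sequence covered by any hit.
#'
#' @param x Sequence to annotate.
#' @param id Sequence name used in the results.
#' @param g4Args,tandemArgs,dyadArgs Named lists of arguments forwarded to
#'   the individual scanners.
#' @return A list with `hits` (all hits, one `GRanges`), `merged` (reduced
#'   union of intervals) and `fraction` (covered bases / length).
#' @examples
#' ann <- nonbAnnotation(strrep("TTGGGGGGG", 5))
#' ann$fraction
#' @export
nonbAnnotation <- function(x, id = "seq", g4Args = list(),
                           tandemArgs = list(), dyadArgs = list()) {
  x <- .asDNAString(x)
  g4 <- do.call(scanG4, c(list(x = x, id = id), g4Args))
  td <- do.call(scanTandem, c(list(x = x, id = id), tandemArgs))
  dy <- do.call(scanDyad, c(list(x = x, id = id), dyadArgs))
  S4Vectors::mcols(g4) <- S4Vectors::DataFrame(
    class = S4Vectors::mcols(g4)$class,
    detail = S4Vectors::mcols(g4)$detail)
  S4Vectors::mcols(td) <- S4Vectors::DataFrame(
    class = S4Vectors::mcols(td)$class,
    detail = if (length(td)) paste0(S4Vectors::mcols(td)$unit, "x",
                                    S4Vectors::mcols(td)$copies)
             else character(0))
  S4Vectors::mcols(dy) <- S4Vectors::DataFrame(
    class = S4Vectors::mcols(dy)$class,
    detail = if (length(dy)) paste0("arm", S4Vectors::mcols(dy)$arm, "_loop",
                                    S4Vectors::mcols(dy)$loop)
             else character(0))
  hits <- c(g4, td, dy)
  hits <- hits[order(GenomicRanges::start(hits))]
  merged <- GenomicRanges::reduce(hits, ignore.strand = TRUE)
  frac <- sum(GenomicRanges::width(merged)) / length(x)
  list(hits = hits, merged = merged, fraction = frac)
}

#' Per-sequence non-B summary table
#'
#' @param seqs A named `DNAStringSet` (or character vector).
#' @param ... Forwarded to [nonbAnnotation()].
#' @return A `data.frame` with one row per sequence: `id`, `length`,
#'   `gc_percent`, `n_g4_plus`, `n_g4_minus`, `tandem_fraction`,
#'   `dyad_count`, `nonb_fraction`.
#' @export
motifSummary <- function(seqs, ...) {
  seqs <- .asDNAStringSet(seqs, "seqs")
  rows <- lapply(seq_along(seqs), function(i) {
    x <- seqs[[i]]
    ann <- nonbAnnotation(x, id = names(seqs)[i], ...)
    cls <- S4Vectors::mcols(ann$hits)$class
    str <- as.character(GenomicRanges::strand(ann$hits))
    td <- ann$hits[cls == "tandem"]
    tdFrac <- sum(GenomicRanges::width(GenomicRanges::reduce(td))) / length(x)
    data.frame(id = names(seqs)[i], length = length(x),
               gc_percent = gcPercent(x),
               n_g4_plus = sum(cls == "g4" & str == "+"),
               n_g4_minus = sum(cls == "g4" & str == "-"),
               tandem_fraction = tdFrac,
               dyad_count = sum(cls == "dyad"),
               nonb_fraction = ann$fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write motif hits as BED6
#'
#' Chrom is the sequence id, the name column carries `class:detail`, score
#' is the hit length, coordinates are 0-based half-open per BED convention.
#'
#' @param hits A `GRanges` of motif hits (from the scanners or
#'   [nonbAnnotation()]`$hits`).
#' @param path Output file.
#' @param seqLen Optional sequence length for the BED header-free track.
#' @return `path`, invisibly.
#' @export
writeMotifBed <- function(hits, path, seqLen = NULL) {
  gr <- hits
  mc <- S4Vectors::mcols(gr)
  nm <- if ("detail" %in% colnames(mc)) paste0(mc$class, ":", mc$detail)
        else mc$class
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm,
                   score = GenomicRanges::width(gr),
                   strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
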
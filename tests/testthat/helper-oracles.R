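# Independent brute-force oracles used to validate the scanners and the
# banded aligner. These deliberately use naive position-by-position
# enumeration (no regex tokenisation, no rle tricks, no banding) so that
# agreement with the package implementations is meaningful.

randomSeq <- function(n, gc = 50) {
  p <- c((100 - gc) / 200, gc / 200, gc / 200, (100 - gc) / 200)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

.oracleComp <- c(A = "T", C = "G", G = "C", T = "A")

# --- G4: explicit character walk -----------------------------------------
# Maximal G-runs of >= 3, loops of 1-12 ACGT between four consecutive runs,
# leftmost non-overlapping.
bruteG4OneStrand <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  runs <- list()
  i <- 1L
  while (i <= L) {
    if (chars[i] == "G") {
      j <- i
      while (j < L && chars[j + 1L] == "G") j <- j + 1L
      if (j - i + 1L >= 3L) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  hits <- list()
  b <- 1L
  while (b + 3L <= length(runs)) {
    ok <- TRUE
    for (t in 0:2) {
      gapFrom <- runs[[b + t]][2] + 1L
      gapTo <- runs[[b + t + 1L]][1] - 1L
      gapLen <- gapTo - gapFrom + 1L
      if (gapLen < 1L || gapLen > 12L ||
          any(!chars[gapFrom:gapTo] %in% c("A", "C", "G", "T"))) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      hits[[length(hits) + 1L]] <- c(runs[[b]][1], runs[[b + 3L]][2])
      b <- b + 4L
    } else b <- b + 1L
  }
  hits
}

bruteG4 <- function(s) {
  L <- nchar(s)
  fwd <- bruteG4OneStrand(s)
  rc <- paste(rev(.oracleComp[strsplit(s, "", fixed = TRUE)[[1]]]),
              collapse = "")
  rev_ <- bruteG4OneStrand(rc)
  rows <- rbind(
    if (length(fwd)) data.frame(start = vapply(fwd, `[`, 0, 1),
                                end = vapply(fwd, `[`, 0, 2), strand = "+"),
    if (length(rev_)) data.frame(start = L - vapply(rev_, `[`, 0, 2) + 1,
                                 end = L - vapply(rev_, `[`, 0, 1) + 1,
                                 strand = "-"))
  if (is.null(rows)) return(data.frame(start = integer(0), end = integer(0),
                                       strand = character(0)))
  rows <- rows[order(rows$start, rows$strand), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# --- tandem: naive per-period position walk ------------------------------
bruteTandem <- function(s, maxPeriod = 20L, minCopies = 3L, minLen = 12L) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  acgt <- c("A", "C", "G", "T")
  cand <- data.frame(start = integer(0), end = integer(0),
                     period = integer(0), copies = integer(0))
  for (p in seq_len(min(maxPeriod, L - 1L))) {
    i <- p + 1L
    while (i <= L) {
      if (chars[i] == chars[i - p] && chars[i] %in% acgt &&
          chars[i - p] %in% acgt) {
        j <- i
        while (j < L && chars[j + 1L] == chars[j + 1L - p] &&
               chars[j + 1L] %in% acgt && chars[j + 1L - p] %in% acgt)
          j <- j + 1L
        runStart <- i - p
        runEnd <- j
        runLen <- runEnd - runStart + 1L
        copies <- runLen %/% p
        if (copies >= minCopies && runLen >= minLen)
          cand <- rbind(cand, data.frame(start = runStart, end = runEnd,
                                         period = p, copies = copies))
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (nrow(cand) == 0L) return(cand)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    !any(cand$period < cand$period[i] & cand$start <= cand$start[i] &
           cand$end >= cand$end[i])
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start, cand$period), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# --- dyad: full (center, loop) enumeration -------------------------------
bruteDyad <- function(s, minArm = 6L, maxLoop = 50L, maxMm = 1L) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  acgt <- c("A", "C", "G", "T")
  cand <- data.frame(start = integer(0), end = integer(0), arm = integer(0),
                     loop = integer(0), mismatches = integer(0))
  for (c1 in 2:L) {
    for (l in 0:maxLoop) {
      c2 <- c1 + l
      if (c2 > L) break
      cum <- 0L; besta <- 0L; bestmm <- 0L
      j <- 0L
      repeat {
        li <- c1 - 1L - j; ri <- c2 + j
        if (li < 1L || ri > L) break
        ok <- chars[li] %in% acgt && chars[ri] %in% acgt &&
          chars[li] == .oracleComp[[chars[ri]]]
        if (j == 0L && !ok) break
        if (!ok) cum <- cum + 1L
        if (cum > maxMm) break
        if (ok) { besta <- j + 1L; bestmm <- cum }
        j <- j + 1L
      }
      if (besta >= minArm)
        cand <- rbind(cand, data.frame(start = c1 - besta, end = c2 + besta - 1L,
                                       arm = besta, loop = l,
                                       mismatches = bestmm))
    }
  }
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(-cand$arm, cand$loop, cand$start), , drop = FALSE]
  ks <- integer(0); ke <- integer(0); keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= ke & cand$end[i] >= ks)) {
      keep <- c(keep, i)
      ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# Mutate a sequence with the given per-position substitution / insertion /
# deletion probabilities (RNG state of the caller is used).
mutateSeq <- function(s, sub = 0.08, ins = 0.02, del = 0.02) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (ch in chars) {
    if (runif(1) < del) next
    if (runif(1) < sub) ch <- sample(setdiff(c("A", "C", "G", "T"), ch), 1)
    out <- c(out, ch)
    if (runif(1) < ins) out <- c(out, sample(c("A", "C", "G", "T"), 1))
  }
  paste(out, collapse = "")
}

# --- full-matrix local alignment oracle (Biostrings) ---------------------
refLocalScore <- function(query, read) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln <- Biostrings::pairwiseAlignment(read, query, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  list(score = Biostrings::score(aln), nmatch = Biostrings::nmatch(aln))
}

# GRanges of hits -> plain data.frame for comparison with an oracle
hitsToDf <- function(gr, cols) {
  df <- data.frame(start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  for (cc in cols) {
    df[[cc]] <- if (cc == "strand") as.character(GenomicRanges::strand(gr))
                else S4Vectors::mcols(gr)[[cc]]
  }
  rownames(df) <- NULL
  df
}
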
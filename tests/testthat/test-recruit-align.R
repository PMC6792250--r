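test_that("exact substrings are recruited at full identity on both strands", {
  withr::with_seed(1, {
    q <- randomSeq(3000)
    r <- substring(q, 1001, 1500)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    aln <- recruitReads(q, c(fwd = r, rev = rc))
    df <- as.data.frame(aln)
    expect_equal(nrow(df), 2)
    expect_equal(df$identity, c(100, 100))
    expect_equal(df$qstart, c(1001, 1001))
    expect_equal(df$qend, c(1500, 1500))
    expect_equal(df$strand[df$readId == "fwd"], "+")
    expect_equal(df$strand[df$readId == "rev"], "-")
    expect_equal(df$rstart, c(1, 1))
    expect_equal(df$rend, c(500, 500))
  })
})

test_that("the minReadLen and minAlnLen filters use the 400 bp bounds", {
  withr::with_seed(2, {
    q <- randomSeq(2000)
    r399 <- substring(q, 501, 899)
    r400 <- substring(q, 501, 900)
    aln <- recruitReads(q, c(a = r399, b = r400))
    expect_equal(as.data.frame(aln)$readId, "b")
  })
})

test_that("query shorter than k is rejected", {
  expect_error(recruitReads("ACGTACGTACGT", c(r = "ACGTACGTACGTACG")),
               "shorter than k")
  expect_error(recruitReads(randomSeq(100), c(r = randomSeq(50)), k = 5),
               "k must be")
})

test_that("noisy reads recruit near their injected identity and match the full DP", {
  g <- generateGene(1, 1500, exonGC = 55, seed = 23)
  tr <- simulationTruth(depth = 8, seed = 24)
  sim <- simulateLongReads(g, readLenMean = 600, readLenSd = 0, truth = tr,
                           flank = 300)
  aln <- recruitReads(g, sim, minIdentity = 60)
  df <- as.data.frame(aln)
  expect_gt(nrow(df), 5)
  expect_lt(abs(mean(df$identity) - 88), 3)
  # banded result equals the unbanded Biostrings optimum on these instances
  reads <- simReads(sim)
  for (i in head(seq_len(nrow(df)), 8)) {
    rseq <- reads[[df$readId[i]]]
    if (df$strand[i] == "-") rseq <- Biostrings::reverseComplement(rseq)
    ref <- refLocalScore(as.character(geneSequence(g)), as.character(rseq))
    expect_equal(df$score[i], ref$score)
  }
})

test_that("recruiting against the reverse-complement query mirrors the result", {
  withr::with_seed(9, {
    q <- randomSeq(2500)
    L <- nchar(q)
    reads <- c(r1 = substring(q, 201, 700),
               r2 = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substring(q, 1201, 1800)))))
    rcq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    a <- as.data.frame(recruitReads(q, reads))
    b <- as.data.frame(recruitReads(rcq, reads))
    b <- b[match(a$readId, b$readId), ]
    expect_equal(a$qstart, L - b$qend + 1)
    expect_equal(a$qend, L - b$qstart + 1)
    expect_true(all(a$strand != b$strand))
    expect_equal(a$identity, b$identity)
  })
})

test_that("raising minIdentity never enlarges the recruited set", {
  g <- generateGene(1, 1200, exonGC = 60, seed = 33)
  sim <- simulateLongReads(g, depth = 6, readLenMean = 500, readLenSd = 0,
                           truth = simulationTruth(seed = 34), flank = 300)
  lo <- as.data.frame(recruitReads(g, sim, minIdentity = 60))
  hi <- as.data.frame(recruitReads(g, sim, minIdentity = 85))
  expect_lte(nrow(hi), nrow(lo))
  expect_true(all(hi$readId %in% lo$readId))
  expect_true(all(lo$lowConfidence == (lo$identity < 75)))
})

test_that("alignmentErrorRate is the complement of identity", {
  df <- S4Vectors::DataFrame(identity = c(100, 90, 75))
  expect_equal(alignmentErrorRate(df), c(0, 10, 25))
  # 10 mismatches, 90 matches, no indels
  expect_equal(alignmentErrorRate(100 * 90 / 100), 10)
})

test_that("the positive-hit rule uses strict > bounds", {
  expect_true(isPositiveHit(95, 96, 100))
  expect_false(isPositiveHit(90, 99, 100))   # exactly 90% aligned
  expect_false(isPositiveHit(95, 95, 100))   # exactly 95% identity
})

test_that("the contamination rule treats 2.5% as contaminated", {
  r <- contaminationFraction(24, 1000)
  expect_equal(r$percent, 2.4)
  expect_false(r$contaminated)
  r <- contaminationFraction(25, 1000)
  expect_equal(r$percent, 2.5)
  expect_true(r$contaminated)
  expect_false(contaminationFraction(0, 10)$contaminated)
  expect_error(contaminationFraction(5, 0), "> 0")
})

test_that("alignment TSV and SAM outputs parse", {
  withr::with_seed(4, {
    q <- randomSeq(1500)
    reads <- c(p = substring(q, 101, 600),
               m = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substring(q, 801, 1300)))))
    aln <- recruitReads(q, reads)
    tsv <- tempfile(fileext = ".tsv")
    writeAlignments(aln, tsv)
    got <- read.table(tsv, header = TRUE, sep = "\t")
    expect_equal(got$qend - got$qstart, rep(500L, 2))  # 0-based half-open
    sam <- tempfile(fileext = ".sam")
    writeAlignmentsSam(aln, reads, "q1", sam)
    lines <- readLines(sam)
    expect_true(any(grepl("^@SQ\tSN:q1\tLN:1500$", lines)))
    recs <- strsplit(grep("^[^@]", lines, value = TRUE), "\t")
    expect_equal(length(recs), 2)
    expect_true(all(vapply(recs, function(x) grepl("^[0-9]+S?.*M", x[6]) ||
                             grepl("M", x[6]), logical(1))))
  })
})
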
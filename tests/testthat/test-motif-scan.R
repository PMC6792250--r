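test_that("gcPercent follows the ambiguity-exclusion rule", {
  expect_equal(gcPercent("GGCC"), 100)
  expect_equal(gcPercent("GATC"), 50)
  expect_equal(gcPercent("GCNN"), 100)
  expect_true(is.na(gcPercent("NNNN")))
  expect_error(gcPercent(Biostrings::DNAString("")), "empty")
})

test_that("gcPercent is strand-symmetric", {
  withr::with_seed(7, {
    for (i in 1:20) {
      s <- randomSeq(sample(50:500, 1), gc = sample(30:80, 1))
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      expect_equal(gcPercent(s), gcPercent(rc))
    }
  })
})

test_that("gcSummary matches a direct quantile computation", {
  expect_equal(gcSummary(c("GGCC", "GATC", "ATAT"))[["median"]], 50)
  batch <- rep("GATC", 100)
  expect_equal(unname(gcSummary(batch)), c(50, 50, 50))
  withr::with_seed(3, {
    seqs <- replicate(40, randomSeq(200, gc = sample(30:80, 1)))
    vals <- sort(vapply(seqs, gcPercent, numeric(1), USE.NAMES = FALSE))
    # direct type-7 interpolation, written out
    qt <- function(p) {
      h <- (length(vals) - 1) * p + 1
      lo <- floor(h)
      vals[lo] + (h - lo) * (vals[min(lo + 1, length(vals))] - vals[lo])
    }
    got <- gcSummary(seqs)
    expect_equal(unname(got), c(qt(.25), qt(.5), qt(.75)))
  })
})

test_that("gcTrack has the documented window count", {
  tr <- gcTrack(randomSeq(1000), window = 100, step = 50)
  expect_length(tr$values, floor((1000 - 100) / 50) + 1)
  expect_true(all(tr$values >= 0 & tr$values <= 100))
  expect_length(gcTrack(randomSeq(50), window = 100)$values, 0)
})

test_that("scanG4 finds the minimal motif on both strands", {
  h <- scanG4("GGGAGGGAGGGAGGG", bothStrands = FALSE)
  expect_length(h, 1)
  expect_equal(GenomicRanges::start(h), 1)
  expect_equal(GenomicRanges::end(h), 15)
  expect_equal(h$detail, "3,3,3,3/1,1,1")

  hm <- scanG4("CCCTCCCTCCCTCCC", bothStrands = TRUE)
  expect_length(hm, 1)
  expect_equal(as.character(GenomicRanges::strand(hm)), "-")
  expect_equal(GenomicRanges::start(hm), 1)
  expect_equal(GenomicRanges::end(hm), 15)

  expect_length(scanG4("ACGTACGTACGT"), 0)
})

test_that("scanG4 keeps G-runs greedy and treats N as a breaker", {
  # a 6-G run is one run, not two motif starts
  expect_length(scanG4("GGGGGGAGGGAGGGAGGG", bothStrands = FALSE), 1)
  # N in a loop invalidates the motif
  expect_length(scanG4("GGGNGGGAGGGAGGG", bothStrands = FALSE), 0)
  # loops longer than 12 break the motif
  s <- paste0("GGG", strrep("A", 13), "GGGAGGGAGGG")
  expect_length(scanG4(s, bothStrands = FALSE), 0)
})

test_that("scanG4 is the coordinate mirror of itself on the reverse complement", {
  withr::with_seed(11, {
    for (i in 1:10) {
      s <- randomSeq(1500, gc = 65)
      L <- nchar(s)
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      a <- hitsToDf(scanG4(s), "strand")
      b <- hitsToDf(scanG4(rc), "strand")
      mirrored <- data.frame(start = L - b$end + 1, end = L - b$start + 1,
                             strand = as.character(ifelse(b$strand == "+",
                                                          "-", "+")))
      mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
      rownames(mirrored) <- NULL
      expect_equal(a, mirrored)
    }
  })
})

test_that("scanTandem reports period, copies and interval per its contract", {
  h <- scanTandem("ACACACACAC", minLen = 10)
  expect_length(h, 1)
  expect_equal(h$period, 2)
  expect_equal(h$copies, 5)
  expect_equal(GenomicRanges::start(h), 1)
  expect_equal(GenomicRanges::end(h), 10)

  h2 <- scanTandem(strrep("TTGGGGGGG", 4))
  expect_length(h2, 1)
  expect_equal(h2$period, 9)
  expect_equal(h2$copies, 4)
  expect_equal(GenomicRanges::end(h2), 36)
  expect_equal(h2$unit, "TTGGGGGGG")
})

test_that("raising tandem thresholds never adds hits", {
  withr::with_seed(5, {
    for (i in 1:8) {
      s <- paste0(randomSeq(300), strrep("CAG", 10), randomSeq(300))
      base <- length(scanTandem(s, minCopies = 3, minLen = 12))
      expect_lte(length(scanTandem(s, minCopies = 5, minLen = 12)), base)
      expect_lte(length(scanTandem(s, minCopies = 3, minLen = 20)), base)
    }
  })
})

test_that("scanDyad resolves the constructed palindrome and respects minArm", {
  h <- scanDyad("GGGGGGAAAAACCCCCC")
  expect_length(h, 1)
  expect_equal(h$arm, 6)
  expect_equal(h$loop, 5)
  expect_length(scanDyad("ACGTACGT", minArm = 6), 0)
  withr::with_seed(8, {
    for (i in 1:5) {
      s <- randomSeq(400)
      expect_lte(length(scanDyad(s, minArm = 8)), length(scanDyad(s, minArm = 6)))
    }
  })
})

test_that("scanners equal their brute-force oracles on random sequences", {
  withr::with_seed(21, {
    for (i in 1:12) {
      s <- randomSeq(sample(200:1200, 1), gc = sample(c(45, 65, 75), 1))
      expect_equal(hitsToDf(scanG4(s), "strand"), bruteG4(s), info = paste("g4", i))
      expect_equal(hitsToDf(scanTandem(s), c("period", "copies")),
                   bruteTandem(s), info = paste("tandem", i))
    }
    for (i in 1:6) {
      s <- randomSeq(sample(150:400, 1), gc = 55)
      expect_equal(hitsToDf(scanDyad(s), c("arm", "loop", "mismatches")),
                   bruteDyad(s), info = paste("dyad", i))
    }
  })
})

test_that("nonbAnnotation merges hits and reports the covered fraction", {
  # repeat tract whose G4 hits nest inside the tandem hit
  tract <- strrep("TTGGGGGGG", 5)
  filler <- strrep("ACTGA", 11)  # 55 bp, no motif classes at defaults
  ann <- nonbAnnotation(paste0(tract, filler))
  expect_equal(ann$fraction,
               sum(GenomicRanges::width(ann$merged)) / (45 + 55))
  expect_gte(ann$fraction, 45 / 100)
  # a sequence with no determinants at all
  expect_equal(nonbAnnotation("ACGTAGCATGCA")$fraction, 0)
})

test_that("motifSummary and BED export round-trip", {
  seqs <- Biostrings::DNAStringSet(c(g1 = strrep("TTGGGGGGG", 6),
                                     g2 = "ACGTAGCATGCATCAG"))
  sm <- motifSummary(seqs)
  expect_equal(sm$id, c("g1", "g2"))
  expect_gt(sm$n_g4_plus[1], 0)
  expect_equal(sm$nonb_fraction[2], 0)
  ann <- nonbAnnotation(seqs[[1]], id = "g1")
  bed <- tempfile(fileext = ".bed")
  writeMotifBed(ann$hits, bed)
  got <- read.table(bed, sep = "\t")
  expect_equal(nrow(got), length(ann$hits))
  expect_true(all(got$V2 >= 0 & got$V3 <= 54))   # 0-based half-open
  gr <- rtracklayer::import(bed)                  # parses as BED
  expect_equal(GenomicRanges::start(gr), GenomicRanges::start(ann$hits))
})
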
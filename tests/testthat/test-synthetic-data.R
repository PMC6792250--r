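test_that("makeTandemTract concatenates motif blocks deterministically", {
  t1 <- makeTandemTract("TTGGGGGGG", 4)
  expect_equal(t1, strrep("TTGGGGGGG", 4))
  expect_equal(nchar(t1), 36)
  expect_equal(makeTandemTract("AC", 1), "AC")
  expect_equal(nchar(makeTandemTract(c("CCCCCCCA", "TTGGGGGGG"), c(3, 2))),
               8 * 3 + 9 * 2)
  expect_error(makeTandemTract(character(0), integer(0)))
  expect_error(makeTandemTract("A", 3), "2 bp")
  expect_error(makeTandemTract("ACGT", 0), "positive")
  expect_equal(makeTandemTract(c("ACA", "GTG"), c(2, 2), seed = 5, shuffle = TRUE),
               makeTandemTract(c("ACA", "GTG"), c(2, 2), seed = 5, shuffle = TRUE))
})

test_that("generateGene assembles the requested architecture", {
  g <- generateGene(2, 300, "TTGGGGGGG", 150, exonGC = 65, seed = 42)
  expect_equal(length(geneSequence(g)), 2 * 300 + 9 * 150)
  expect_equal(IRanges::start(exons(g)), c(1, 300 + 1350 + 1))
  expect_equal(IRanges::width(exons(g)), c(300, 300))
  # intron is annotated as non-B (tandem hit spanning it)
  td <- nonbTruth(g)[nonbTruth(g)$class == "tandem"]
  expect_true(any(GenomicRanges::start(td) <= 301 &
                  GenomicRanges::end(td) >= 1650))

  g1 <- generateGene(1, 100, exonGC = 50, seed = 1)
  expect_equal(length(geneSequence(g1)), 100)
  expect_equal(as.integer(c(IRanges::start(exons(g1)), IRanges::end(exons(g1)))),
               c(1, 100))

  expect_identical(as.character(geneSequence(generateGene(2, 200, "CAG", 20, 60, seed = 9))),
                   as.character(geneSequence(generateGene(2, 200, "CAG", 20, 60, seed = 9))))
  expect_error(generateGene(2, 200, "CAG", 20, exonGC = 120, seed = 1), "GC")
})

test_that("exon GC hits the requested target within 2 points", {
  for (gc in c(40, 65, 80)) {
    g <- generateGene(1, 500, exonGC = gc, seed = gc)
    expect_lt(abs(gcPercent(g) - gc), 2)
  }
})

test_that("long-read simulation is seeded, conservative and in-bounds", {
  g <- generateGene(1, 2000, exonGC = 50, seed = 2)
  tr <- simulationTruth(depth = 20, seed = 8)
  s1 <- simulateLongReads(g, readLenMean = 400, readLenSd = 100, truth = tr,
                          flank = 500)
  s2 <- simulateLongReads(g, readLenMean = 400, readLenSd = 100, truth = tr,
                          flank = 500)
  expect_identical(as.character(simReads(s1)), as.character(simReads(s2)))
  tt <- as.data.frame(readTruth(s1))
  srcLen <- length(sourceSequence(s1))
  nCand <- round(20 * srcLen / 400)
  expect_lte(nrow(tt), nCand)
  expect_true(all(tt$start >= 1 & tt$end <= srcLen))
  expect_true(all(tt$strand %in% c("+", "-")))
})

test_that("without depletion the realised depth matches the naive target", {
  g <- generateGene(1, 3000, exonGC = 50, seed = 4)  # motif-poor random exon
  tr <- simulationTruth(depletion = 0, depth = 20, seed = 14,
                        backgroundRates = c(sub = 0, ins = 0, del = 0),
                        nonbRates = c(sub = 0, ins = 0, del = 0))
  sim <- simulateLongReads(g, readLenMean = 300, readLenSd = 0, truth = tr,
                           flank = 500)
  tt <- as.data.frame(readTruth(sim))
  cov <- IRanges::coverage(IRanges::IRanges(tt$start, tt$end),
                           width = length(sourceSequence(sim)))
  interior <- as.integer(cov)[501:3500]
  expect_lt(abs(mean(interior) - 20) / 20, 0.15)
})

test_that("depletion suppresses reads inside non-B tracts binomially", {
  g <- mixedTractGene(seed = 31)
  tr <- simulationTruth(depletion = 0.9, depth = 40, seed = 77,
                        backgroundRates = c(sub = 0, ins = 0, del = 0),
                        nonbRates = c(sub = 0, ins = 0, del = 0))
  sim <- simulateLongReads(g, readLenMean = 400, readLenSd = 0, truth = tr,
                           flank = 1000)
  tt <- as.data.frame(readTruth(sim))
  srcLen <- length(sourceSequence(sim))
  nCand <- round(40 * srcLen / 400)
  tract <- IRanges::reduce(IRanges::ranges(nonbTruth(g)))
  tract <- tract[which.max(IRanges::width(tract))]
  lo <- IRanges::start(tract) + 1000  # tract in source coordinates
  hi <- IRanges::end(tract) + 1000
  # candidates fully inside the tract are kept with probability 1 - d = 0.1
  pInside <- (hi - lo + 1 - 400 + 1) / (srcLen - 400 + 1)
  expected <- nCand * pInside * 0.1
  gotInside <- sum(tt$start >= lo & tt$end <= hi)
  sdBin <- sqrt(nCand * pInside * 0.1 * 0.9)
  expect_lt(abs(gotInside - expected), 4 * sdBin)
})

test_that("injected error rates are realised at the configured total", {
  g <- generateGene(1, 4000, exonGC = 50, seed = 6)
  tr <- simulationTruth(depletion = 0, depth = 6, seed = 16,
                        backgroundRates = c(sub = 0.04, ins = 0.06, del = 0.02),
                        nonbRates = c(sub = 0.04, ins = 0.06, del = 0.02))
  sim <- simulateLongReads(g, readLenMean = 500, readLenSd = 0, truth = tr,
                           flank = 500)
  tt <- as.data.frame(readTruth(sim))
  expect_gt(nrow(tt), 50)
  expect_lt(abs(mean(tt$trueErrorRate) - 0.12), 0.01)
  # measured through alignment of the recruited reads
  aln <- recruitReads(g, sim, minIdentity = 60)
  expect_lt(abs(mean(alignmentErrorRate(aln)) - 12), 2)
})

test_that("short-read dropout follows the closed-form expectation", {
  g <- generateGene(2, 300, mixedRepeatMotifs(10, seed = 41), rep(12, 10),
                    exonGC = 55, seed = 12)  # ~1.1 kb mixed tandem intron
  tract <- IRanges::reduce(IRanges::ranges(nonbTruth(g)))
  tract <- tract[which.max(IRanges::width(tract))]

  total <- simulateShortReads(g, readLen = 100, depth = 10, dropout = 1,
                              seed = 3, flank = 500)
  tt <- as.data.frame(readTruth(total))
  lo <- IRanges::start(tract) + 500; hi <- IRanges::end(tract) + 500
  expect_equal(sum(tt$start >= lo & tt$end <= hi), 0)

  none <- simulateShortReads(g, readLen = 100, depth = 10, dropout = 0,
                             seed = 3, flank = 500)
  tn <- as.data.frame(readTruth(none))
  covN <- as.integer(IRanges::coverage(IRanges::IRanges(tn$start, tn$end),
                                       width = length(sourceSequence(none))))
  expect_lt(abs(mean(covN[lo:hi]) - 10) / 10, 0.35)

  part <- simulateShortReads(g, readLen = 100, depth = 10, dropout = 0.95,
                             seed = 3, flank = 500)
  tp <- as.data.frame(readTruth(part))
  covP <- as.integer(IRanges::coverage(IRanges::IRanges(tp$start, tp$end),
                                       width = length(sourceSequence(part))))
  # interior of the tract: acceptance 0.05 of 10X = 0.5X
  expect_lt(mean(covP[(lo + 100):(hi - 100)]), 1.6)
})

test_that("read and truth writers emit parseable files", {
  g <- generateGene(1, 600, exonGC = 60, seed = 17)
  sim <- simulateLongReads(g, depth = 5, readLenMean = 200, readLenSd = 0,
                           truth = simulationTruth(seed = 18), flank = 200)
  fa <- tempfile(fileext = ".fa"); fq <- tempfile(fileext = ".fq")
  tsv <- tempfile(fileext = ".tsv")
  writeReads(sim, fa)
  writeReads(sim, fq, format = "fastq", quality = 25)
  writeReadTruth(sim, tsv)
  rfa <- Biostrings::readDNAStringSet(fa)
  rfq <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(length(rfa), length(simReads(sim)))
  expect_identical(as.character(rfa), as.character(rfq))
  tt <- read.table(tsv, header = TRUE, sep = "\t")
  expect_named(tt, c("read_id", "start", "end", "strand",
                     "class_overlap_fraction", "true_error_rate"))
  expect_equal(tt$end - tt$start,
               as.data.frame(readTruth(sim))$end -
                 as.data.frame(readTruth(sim))$start + 1L)

  gfa <- tempfile(fileext = ".fa"); gbed <- tempfile(fileext = ".bed")
  writeGeneArchitecture(g, gfa, gbed)
  expect_equal(as.character(Biostrings::readDNAStringSet(gfa)[[1]]),
               as.character(geneSequence(g)))
  bed <- read.table(gbed, sep = "\t")
  expect_true("exon" %in% bed$V4)
})
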
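test_that("orientReads flips minus-strand reads and round-trips", {
  withr::with_seed(3, {
    q <- randomSeq(2200)
    plus <- substring(q, 101, 700)
    minus <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substring(q, 1201, 1800))))
    reads <- Biostrings::DNAStringSet(c(p = plus, m = minus))
    aln <- recruitReads(q, reads)
    oriented <- orientReads(aln, reads)
    expect_equal(as.character(oriented[["p"]]), plus)
    expect_equal(as.character(oriented[["m"]]),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(minus))))
    # re-recruiting oriented reads yields all plus strand
    again <- as.data.frame(recruitReads(q, oriented))
    expect_true(all(again$strand == "+"))
    expect_warning(orientReads(aln, c(reads, Biostrings::DNAStringSet(c(x = randomSeq(500))))),
                   "without alignment")
  })
})

test_that("error-free tiling reads reproduce the truth exactly", {
  withr::with_seed(13, {
    truth <- randomSeq(2000, gc = 60)
    # staggered tiles plus extra copies of the terminal tiles, so even the
    # first and last columns see at least minDepth reads
    starts <- c(seq(1, 2000 - 500 + 1, by = 75), rep(1, 4), rep(1501, 4))
    reads <- Biostrings::DNAStringSet(
      setNames(substring(truth, starts, starts + 499),
               paste0("t", seq_along(starts))))
    cm <- buildConsensus(truth, reads, minDepth = 5)
    expect_identical(as.character(consensusSequence(cm)), truth)
    expect_true(all(columnDepth(cm) >= 5))
    expect_true(all(columnSupport(cm) == 1))
  })
})

test_that("fewer reads than minDepth yields an all-N span", {
  withr::with_seed(14, {
    truth <- randomSeq(1200)
    reads <- Biostrings::DNAStringSet(
      setNames(rep(truth, 4), paste0("r", 1:4)))
    cm <- buildConsensus(truth, reads, minDepth = 5)
    expect_equal(as.character(consensusSequence(cm)),
                 strrep("N", 1200))
    expect_true(all(columnDepth(cm) < 5))
  })
})

test_that("N-calls coincide exactly with columns below minDepth", {
  g <- generateGene(1, 1500, exonGC = 55, seed = 61)
  sim <- simulateLongReads(g, depth = 12, readLenMean = 400, readLenSd = 0,
                           truth = simulationTruth(seed = 62), flank = 300)
  aln <- recruitReads(g, sim, minIdentity = 60)
  oriented <- suppressWarnings(orientReads(aln, sim))  # flank reads unaligned
  cm <- buildConsensus(geneSequence(g), oriented, minDepth = 5)
  isN <- strsplit(as.character(consensusSequence(cm)), "")[[1]] == "N"
  expect_identical(isN, columnDepth(cm) < 5L)
})

test_that("15 noisy reads reach 99% consensus accuracy and idempotence holds", {
  g <- generateGene(1, 2000, exonGC = 65, seed = 71)
  tr <- simulationTruth(depth = 15, seed = 72,
                        nonbRates = c(sub = 0.04, ins = 0.06, del = 0.02))
  sim <- simulateLongReads(g, readLenMean = 2000, readLenSd = 0, truth = tr,
                           flank = 0)
  aln <- recruitReads(g, sim, minIdentity = 60)
  oriented <- orientReads(aln, sim)
  cm <- buildConsensus(geneSequence(g), oriented, minDepth = 5)
  expect_gte(sequenceIdentity(consensusSequence(cm), geneSequence(g)), 99)
  # feeding the converged model back in changes nothing
  cm2 <- buildConsensus(consensusSequence(cm), oriented, minDepth = 5)
  expect_true(cm2@converged)
  expect_equal(cm2@iterations, 1L)
  expect_identical(as.character(consensusSequence(cm2)),
                   as.character(consensusSequence(cm)))
})

test_that("consensus accuracy does not degrade with more reads", {
  idAt <- function(n, seed) {
    g <- generateGene(1, 1200, exonGC = 60, seed = 81)
    tr <- simulationTruth(depth = n, seed = seed,
                          nonbRates = c(sub = 0.04, ins = 0.06, del = 0.02))
    sim <- simulateLongReads(g, readLenMean = 1200, readLenSd = 0, truth = tr,
                             flank = 0)
    oriented <- orientReads(recruitReads(g, sim, minIdentity = 60), sim)
    cm <- buildConsensus(geneSequence(g), oriented, minDepth = 3)
    sequenceIdentity(consensusSequence(cm), geneSequence(g))
  }
  id15 <- vapply(1:10, function(s) idAt(15, 1000 + s), numeric(1))
  id5 <- vapply(1:10, function(s) idAt(5, 1000 + s), numeric(1))
  expect_gte(mean(id15), mean(id5))
})

test_that("inferGeneStructure recovers constructed exons and splice classes", {
  fx <- spliceFixture(200, 250, 304, donor = "GT", acceptor = "AG", seed = 5)
  m <- inferGeneStructure(fx$genomic, fx$cdna)
  expect_equal(IRanges::start(exons(m)), c(fx$exon1[1], fx$exon2[1]))
  expect_equal(IRanges::end(exons(m)), c(fx$exon1[2], fx$exon2[2]))
  sd <- as.data.frame(spliceDinucleotides(m))
  expect_equal(sd$donor, "GT")
  expect_equal(sd$acceptor, "AG")
  expect_equal(sd$classification, "canonical")

  fx2 <- spliceFixture(200, 250, 304, donor = "CG", acceptor = "AG", seed = 6)
  m2 <- inferGeneStructure(fx2$genomic, fx2$cdna)
  sd2 <- as.data.frame(spliceDinucleotides(m2))
  expect_equal(sd2$classification, "atypical-known")
  expect_equal(sd2$donor, "CG")

  fx3 <- spliceFixture(300, 300, 200, donor = "TT", acceptor = "CC", seed = 7)
  m3 <- inferGeneStructure(fx3$genomic, fx3$cdna)
  expect_equal(as.data.frame(spliceDinucleotides(m3))$classification,
               "noncanonical")

  # identical cDNA: a single exon, no introns
  m4 <- inferGeneStructure(fx$genomic, fx$genomic)
  expect_length(exons(m4), 1)
  expect_equal(nrow(spliceDinucleotides(m4)), 0)

  expect_error(inferGeneStructure(fx$genomic, randomSeq(300)),
               "undetermined")
})

test_that("structure recovery is exact down to short exons and 50 bp introns", {
  withr::with_seed(91, {
    for (i in 1:6) {
      e1 <- sample(c(20, 60, 150), 1)
      e2 <- sample(c(80, 200), 1)
      il <- sample(c(50, 120, 700), 1)
      fx <- spliceFixture(e1, e2, il, seed = 900 + i)
      m <- inferGeneStructure(fx$genomic, fx$cdna)
      expect_equal(IRanges::start(exons(m)), c(fx$exon1[1], fx$exon2[1]),
                   info = paste("case", i))
      expect_equal(IRanges::end(exons(m)), c(fx$exon1[2], fx$exon2[2]),
                   info = paste("case", i))
    }
  })
})

test_that("modelStats aggregates length, GC, introns and non-B fraction", {
  allN <- buildConsensus(randomSeq(300), Biostrings::DNAStringSet())
  st <- modelStats(allN)
  expect_equal(st$length, 300)
  expect_equal(st$nCount, 300)
  expect_true(is.na(st$gcPercent))

  fx <- spliceFixture(300, 300, 1497, seed = 12)
  m <- inferGeneStructure(fx$genomic, fx$cdna)
  st2 <- modelStats(m)
  expect_equal(st2$intronLengths, 1497L)
  expect_equal(st2$length, nchar(fx$genomic))
})

test_that("consensus writers emit FASTA, depth TSV and GFF3 that parse", {
  fx <- spliceFixture(250, 250, 300, seed = 15)
  m <- inferGeneStructure(fx$genomic, fx$cdna)
  fa <- tempfile(fileext = ".fa"); dp <- tempfile(fileext = ".tsv")
  gff <- tempfile(fileext = ".gff3")
  writeConsensusModel(m, fa, dp, gff, id = "model1")
  expect_equal(as.character(Biostrings::readDNAStringSet(fa)[[1]]),
               fx$genomic)
  d <- read.table(dp, header = TRUE, sep = "\t")
  expect_equal(nrow(d), nchar(fx$genomic))
  gr <- rtracklayer::import(gff)
  expect_equal(sum(gr$type == "exon"), 2)
  ex <- gr[gr$type == "exon"]
  expect_equal(GenomicRanges::start(ex), IRanges::start(exons(m)))
})
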
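# Shared fixture builders. All randomness is seeded by the caller.

# Distinct GC-rich 9-mers, so a tandem tract built from them is locally
# repetitive (each block is annotated by the tandem scanner) but globally
# unique, giving reads an unambiguous placement.
mixedRepeatMotifs <- function(n, seed = 99) {
  withr::with_seed(seed, {
    pool <- replicate(3 * n, paste(
      sample(c("G", "C", "T", "A"), 9, TRUE, prob = c(.45, .3, .15, .1)),
      collapse = ""))
    unique(pool)[seq_len(n)]
  })
}

# Two 500 bp exons around a ~5.9 kb mixed-motif tandem tract.
mixedTractGene <- function(seed = 11, nMotifs = 55, copies = 12) {
  motifs <- mixedRepeatMotifs(nMotifs)
  generateGene(2, 500, motifs, rep(copies, nMotifs), exonGC = 55, seed = seed)
}

# Two-exon construction with a chosen intron, plus its spliced cDNA.
spliceFixture <- function(exon1Len, exon2Len, intronLen, donor = "GT",
                          acceptor = "AG", seed = 1) {
  withr::with_seed(seed, {
    e1 <- randomSeq(exon1Len)
    e2 <- randomSeq(exon2Len)
    mid <- randomSeq(intronLen - 4L)
    list(genomic = paste0(e1, donor, mid, acceptor, e2),
         cdna = paste0(e1, e2),
         exon1 = c(1L, exon1Len),
         exon2 = c(exon1Len + intronLen + 1L,
                   exon1Len + intronLen + exon2Len))
  })
}
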
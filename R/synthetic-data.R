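# Synthetic GC-rich gene architectures and context-dependent read
# simulation. The generator builds multi-exon genes whose introns are
# concatenated short tandem repeats (the architecture seen in GC-rich avian
# genes), then simulates long reads whose sampling probability and error
# rate depend on overlap with non-B DNA truth intervals, and error-free
# short reads with dropout over the same intervals.

#' Build a tandem-repeat tract
#'
#' Concatenates each motif repeated its copy number of times:
#' `motif1 x copies1 + motif2 x copies2 + ...`. With `shuffle = TRUE` the
#' per-motif blocks are permuted under `seed`; otherwise the result is
#' fully deterministic and `seed` is unused.
#'
#' @param motifs Character vector of repeat units (each at least 2 bp).
#' @param copies Positive integer copy number per motif (same length).
#' @param seed Integer seed, used only when `shuffle = TRUE`.
#' @param shuffle Permute the order of the motif blocks.
#' @return A single character string.
#' @examples
#' nchar(makeTandemTract("TTGGGGGGG", 4))  # 36
#' @export
makeTandemTract <- function(motifs, copies, seed = 0L, shuffle = FALSE) {
  motifs <- as.character(motifs)
  copies <- as.integer(copies)
  if (length(motifs) == 0L || length(motifs) != length(copies))
    stop("`motifs` and `copies` must be non-empty and of equal length")
  if (any(!nzchar(motifs)) || any(nchar(motifs) < 2L))
    stop("each motif must be at least 2 bp")
  if (any(is.na(copies)) || any(copies < 1L))
    stop("each copy number must be a positive integer")
  blocks <- strrep(motifs, copies)
  if (shuffle) blocks <- withSeed(seed, sample(blocks))
  paste(blocks, collapse = "")
}

#' Generate a GC-rich gene architecture
#'
#' Exons are random sequences at the requested GC percent (achieved
#' exactly up to rounding, so always within 2 points); introns are tandem
#' tracts built by [makeTandemTract()] from `intronMotifs`/`intronCopies`
#' (the same tract specification is used for every intron). The non-B
#' truth annotation is obtained by running the motif scanners on the
#' finished sequence. Fully reproducible per `seed`.
#'
#' @param nExons Number of exons (>= 1).
#' @param exonLen Exon length in bp.
#' @param intronMotifs,intronCopies Tandem tract specification for each
#'   intron (both may be empty when `nExons == 1`).
#' @param exonGC Target exon GC percent.
#' @param seed Integer seed.
#' @param id Identifier for the gene.
#' @param scanArgs Named list of argument lists (`g4Args`, `tandemArgs`,
#'   `dyadArgs`) forwarded to [nonbAnnotation()] when computing the truth.
#' @return A [GeneArchitecture].
#' @examples
#' g <- generateGene(2, 300, "TTGGGGGGG", 150, exonGC = 65, seed = 42)
#' length(geneSequence(g))  # 2*300 + 9*150
#' @export
generateGene <- function(nExons, exonLen, intronMotifs = character(0),
                         intronCopies = integer(0), exonGC = 65, seed = 1L,
                         id = "synthetic_gene", scanArgs = list()) {
  if (nExons < 1L) stop("nExons must be >= 1")
  if (exonLen < 1L) stop("exonLen must be >= 1")
  if (exonGC < 0 || exonGC > 100) stop("unreachable GC target: ", exonGC)
  intron <- if (nExons > 1L) {
    if (length(intronMotifs) == 0L) "" else makeTandemTract(intronMotifs, intronCopies)
  } else ""
  pieces <- withSeed(seed, {
    lapply(seq_len(nExons), function(i) .randomDNA(exonLen, exonGC))
  })
  seqParts <- character(0)
  exStart <- integer(nExons)
  pos <- 0L
  for (i in seq_len(nExons)) {
    exStart[i] <- pos + 1L
    seqParts <- c(seqParts, pieces[[i]])
    pos <- pos + exonLen
    if (i < nExons && nzchar(intron)) {
      seqParts <- c(seqParts, intron)
      pos <- pos + nchar(intron)
    }
  }
  seqChar <- paste(seqParts, collapse = "")
  dna <- Biostrings::DNAString(seqChar)
  ann <- do.call(nonbAnnotation, c(list(x = dna, id = id), scanArgs))
  truth <- ann$hits
  S4Vectors::mcols(truth) <- S4Vectors::DataFrame(
    class = S4Vectors::mcols(truth)$class)
  new("GeneArchitecture", id = id, sequence = dna,
      exons = IRanges::IRanges(exStart, width = exonLen),
      nonbTruth = truth, gcPercent = gcPercent(dna))
}

#' Simulation parameter set
#'
#' Constructor for [SimulationTruth-class]. Defaults mirror routine
#' long-read behaviour: a total error of 12% split sub:ins:del = 2:3:1
#' over background positions, a heavier 20% total over non-B positions
#' (the 15-25% band seen over GC-rich sequences), and no depletion.
#'
#' @param depletion Non-B depletion `d` in `[0, 1]`; reads are kept with
#'   probability `(1 - d)^f`, `f` being their overlap fraction with non-B
#'   truth intervals.
#' @param backgroundRates,nonbRates Named `c(sub=, ins=, del=)` fractions.
#' @param depth Naive fold-coverage target.
#' @param seed Integer seed.
#' @return A `SimulationTruth`.
#' @examples
#' simulationTruth(depletion = 0.9, depth = 60)
#' @export
simulationTruth <- function(depletion = 0,
                            backgroundRates = c(sub = 0.04, ins = 0.06, del = 0.02),
                            nonbRates = c(sub = 2/30, ins = 0.1, del = 1/30),
                            depth = 60, seed = 1L) {
  new("SimulationTruth", depletion = depletion,
      backgroundRates = backgroundRates, nonbRates = nonbRates,
      depth = depth, seed = as.integer(seed))
}

# Apply per-position substitution/insertion/deletion errors to the source
# substring [start, end] (1-based), with rates chosen per position from the
# background or non-B class. Returns list(seq=, nEdits=).
.injectErrors <- function(chars, isNonb, start, end, bg, nb) {
  n <- end - start + 1L
  base <- chars[start:end]
  cls <- isNonb[start:end]
  subRate <- ifelse(cls, nb[["sub"]], bg[["sub"]])
  insRate <- ifelse(cls, nb[["ins"]], bg[["ins"]])
  delRate <- ifelse(cls, nb[["del"]], bg[["del"]])
  del <- runif(n) < delRate
  sub <- runif(n) < subRate & !del
  ins <- runif(n) < insRate
  if (any(sub)) {
    alt <- c("A", "C", "G", "T")
    base[sub] <- vapply(base[sub], function(b) sample(setdiff(alt, b), 1L),
                        character(1), USE.NAMES = FALSE)
  }
  main <- ifelse(del, NA_character_, base)
  insChar <- ifelse(ins, sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    NA_character_)
  inter <- as.vector(rbind(main, insChar))
  inter <- inter[!is.na(inter)]
  list(seq = paste(inter, collapse = ""),
       nEdits = sum(del) + sum(sub) + sum(ins))
}

# Shared driver for long- and short-read simulation.
.simulateReads <- function(gene, depth, lenFun, accProb, bg, nb, seed,
                           flank, flankGC, params) {
  if (!is(gene, "GeneArchitecture")) stop("`gene` must be a GeneArchitecture")
  .assertScalarNumber(depth, "depth", positive = TRUE)
  withSeed(seed, {
    geneSeq <- as.character(geneSequence(gene))
    left <- .randomDNA(flank, flankGC)
    right <- .randomDNA(flank, flankGC)
    src <- paste0(left, geneSeq, right)
    L <- nchar(src)
    chars <- strsplit(src, "", fixed = TRUE)[[1]]
    nonb <- IRanges::reduce(IRanges::shift(IRanges::ranges(nonbTruth(gene)),
                                           flank))
    isNonb <- logical(L)
    if (length(nonb) > 0) {
      for (i in seq_along(nonb))
        isNonb[IRanges::start(nonb)[i]:IRanges::end(nonb)[i]] <- TRUE
    }
    lens <- lenFun(L)
    nCand <- length(lens)
    starts <- floor(runif(nCand) * (L - lens + 1L)) + 1L
    ends <- starts + lens - 1L
    cand <- IRanges::IRanges(starts, ends)
    ovBp <- numeric(nCand)
    if (length(nonb) > 0) {
      hits <- IRanges::findOverlaps(cand, nonb)
      if (length(hits) > 0) {
        w <- IRanges::width(IRanges::pintersect(
          cand[S4Vectors::queryHits(hits)], nonb[S4Vectors::subjectHits(hits)]))
        agg <- tapply(w, S4Vectors::queryHits(hits), sum)
        ovBp[as.integer(names(agg))] <- as.numeric(agg)
      }
    }
    f <- ovBp / lens
    keep <- runif(nCand) < accProb(f)
    idx <- which(keep)
    readSeqs <- character(length(idx))
    errRates <- numeric(length(idx))
    strands <- character(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      inj <- .injectErrors(chars, isNonb, starts[i], ends[i], bg, nb)
      s <- inj$seq
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") s <- .revcompChar(s)
      readSeqs[k] <- s
      errRates[k] <- inj$nEdits / lens[i]
      strands[k] <- strand
    }
    ids <- sprintf("read_%05d", seq_along(idx))
    reads <- Biostrings::DNAStringSet(readSeqs)
    names(reads) <- ids
    truth <- S4Vectors::DataFrame(
      readId = ids, start = starts[idx], end = ends[idx],
      strand = strands, classOverlap = f[idx], trueErrorRate = errRates)
    new("ReadSimulation", reads = reads, truth = truth,
        source = Biostrings::DNAString(src), geneStart = flank + 1L,
        gene = gene, params = params)
  })
}

#' Simulate long reads with non-B-dependent sampling and errors
#'
#' The gene is embedded in random flanking sequence; candidate reads with
#' log-normal lengths are drawn uniformly until the naive depth is
#' reached, then each candidate is kept with acceptance probability
#' `(1 - d)^f` where `d` is the configured depletion and `f` the fraction
#' of the read overlapping non-B truth intervals. Kept reads receive
#' substitutions, insertions and deletions at the per-class rates of
#' `truth`, and are reverse-complemented with probability 0.5. The truth
#' table records source interval, strand, overlap fraction and realised
#' error rate per read.
#'
#' @param gene A [GeneArchitecture].
#' @param depth Naive fold-coverage (defaults to `truth@depth`).
#' @param readLenMean Mean read length in bp.
#' @param truth A [SimulationTruth-class] (see [simulationTruth()]).
#' @param readLenSd Standard deviation of read length in bp; 0 gives
#'   fixed-length reads.
#' @param flank Flanking sequence added on each side (bp).
#' @param flankGC GC percent of the flanks.
#' @param seed Integer seed (defaults to `truth@seed`).
#' @return A [ReadSimulation].
#' @export
simulateLongReads <- function(gene, depth = NULL, readLenMean = 1000,
                              truth = simulationTruth(), readLenSd = 250,
                              flank = 2000L, flankGC = 45, seed = NULL) {
  validObject(truth)
  if (is.null(depth)) depth <- truth@depth
  if (is.null(seed)) seed <- truth@seed
  d <- truth@depletion
  lenFun <- function(L) {
    # starts are confined to [1, L - len + 1]; calibrating the candidate
    # pool to the number of start positions makes `depth` the per-position
    # coverage away from the source edges (for full-length reads it is
    # simply the read count), with no interior inflation
    nStarts <- max(1, L - readLenMean + 1)
    n <- max(1L, round(depth * nStarts / min(readLenMean, nStarts)))
    lens <- if (readLenSd <= 0) rep(round(readLenMean), n) else {
      s2 <- log(1 + (readLenSd / readLenMean)^2)
      round(stats::rlnorm(n, meanlog = log(readLenMean) - s2 / 2,
                          sdlog = sqrt(s2)))
    }
    pmin(pmax(lens, 50L), L)
  }
  .simulateReads(gene, depth, lenFun,
                 accProb = function(f) (1 - d)^f,
                 bg = truth@backgroundRates, nb = truth@nonbRates,
                 seed = seed, flank = as.integer(flank), flankGC = flankGC,
                 params = list(type = "long", depth = depth,
                               readLenMean = readLenMean,
                               readLenSd = readLenSd, depletion = d,
                               backgroundRates = truth@backgroundRates,
                               nonbRates = truth@nonbRates, seed = seed))
}

#' Simulate error-free short reads with non-B dropout
#'
#' As [simulateLongReads()] but reads are error-free, of fixed length, and
#' the dropout is applied as acceptance probability `(1 - dropout)^f` over
#' non-B intervals — emulating short-read libraries in which reads over
#' non-B tracts are simply absent.
#'
#' @param gene A [GeneArchitecture].
#' @param readLen Fixed read length in bp.
#' @param depth Naive fold-coverage.
#' @param dropout Dropout fraction over non-B intervals in `[0, 1]`.
#' @param seed Integer seed.
#' @param flank,flankGC Flanking sequence parameters.
#' @return A [ReadSimulation].
#' @export
simulateShortReads <- function(gene, readLen = 150L, depth = 30,
                               dropout = 0, seed = 1L, flank = 2000L,
                               flankGC = 45) {
  .assertScalarNumber(dropout, "dropout", nonneg = TRUE)
  if (dropout > 1) stop("`dropout` must be in [0, 1]")
  zero <- c(sub = 0, ins = 0, del = 0)
  lenFun <- function(L) {
    nStarts <- max(1, L - readLen + 1)
    n <- max(1L, round(depth * nStarts / min(readLen, nStarts)))
    rep(min(as.integer(readLen), L), n)
  }
  .simulateReads(gene, depth, lenFun,
                 accProb = function(f) (1 - dropout)^f,
                 bg = zero, nb = zero, seed = seed,
                 flank = as.integer(flank), flankGC = flankGC,
                 params = list(type = "short", depth = depth,
                               readLen = readLen, dropout = dropout,
                               seed = seed))
}

#' Write simulated reads as FASTA or FASTQ
#'
#' @param sim A [ReadSimulation] (or a `DNAStringSet`).
#' @param path Output file.
#' @param format `"fasta"` or `"fastq"`.
#' @param quality Constant Phred quality for FASTQ output.
#' @return `path`, invisibly.
#' @export
writeReads <- function(sim, path, format = c("fasta", "fastq"), quality = 30L) {
  format <- match.arg(format)
  reads <- .asDNAStringSet(sim, "sim")
  if (format == "fasta") {
    Biostrings::writeXStringSet(reads, path)
  } else {
    q <- Biostrings::PhredQuality(
      vapply(Biostrings::width(reads),
             function(w) paste(rep(rawToChar(as.raw(quality + 33L)), w),
                               collapse = ""), character(1)))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Write the per-read truth table as TSV
#'
#' Columns: `read_id`, `start`, `end` (0-based half-open on the source),
#' `strand`, `class_overlap_fraction`, `true_error_rate`.
#'
#' @param sim A [ReadSimulation].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeReadTruth <- function(sim, path) {
  tr <- readTruth(sim)
  df <- data.frame(read_id = tr$readId, start = tr$start - 1L, end = tr$end,
                   strand = tr$strand,
                   class_overlap_fraction = tr$classOverlap,
                   true_error_rate = tr$trueErrorRate)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene architecture as FASTA plus BED
#'
#' The BED (0-based half-open) contains the exons (name `exon`) and the
#' non-B truth intervals (name = determinant class).
#'
#' @param gene A [GeneArchitecture].
#' @param fastaPath,bedPath Output files.
#' @return A list of the two paths, invisibly.
#' @export
writeGeneArchitecture <- function(gene, fastaPath, bedPath) {
  dss <- Biostrings::DNAStringSet(list(geneSequence(gene)))
  names(dss) <- gene@id
  Biostrings::writeXStringSet(dss, fastaPath)
  ex <- exons(gene)
  tr <- nonbTruth(gene)
  df <- rbind(
    data.frame(chrom = gene@id, start = IRanges::start(ex) - 1L,
               end = IRanges::end(ex), name = "exon", score = 0L,
               strand = "+"),
    data.frame(chrom = gene@id, start = GenomicRanges::start(tr) - 1L,
               end = GenomicRanges::end(tr),
               name = as.character(tr$class), score = 0L,
               strand = sub("\\*", "+", as.character(GenomicRanges::strand(tr)))))
  write.table(df, bedPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fastaPath, bed = bedPath))
}
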
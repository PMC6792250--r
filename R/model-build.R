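# Consensus gene-model reconstruction from recruited noisy reads:
# orientation, iterative align-and-call with majority vote and N tracts,
# and exon/intron inference by mapping a cDNA onto the genomic model.

#' Orient recruited reads
#'
#' Reads whose retained alignment is on the minus strand are
#' reverse-complemented so that all subsequent coordinates are forward with
#' respect to the query. Reads without an alignment are skipped with a
#' warning.
#'
#' @param alignments Alignment table from [recruitReads()] (one retained
#'   alignment per read; for multi-locus reads the first is used).
#' @param reads The read set (`DNAStringSet` or [ReadSimulation]).
#' @return A `DNAStringSet` of oriented reads, in alignment order.
#' @export
orientReads <- function(alignments, reads) {
  reads <- .asDNAStringSet(reads, "reads")
  df <- as.data.frame(alignments)
  df <- df[!duplicated(df$readId), , drop = FALSE]
  missing <- setdiff(names(reads), df$readId)
  if (length(missing) > 0)
    warning(length(missing), " read(s) without alignment skipped")
  out <- reads[df$readId]
  flip <- df$strand == "-"
  if (any(flip)) out[flip] <- Biostrings::reverseComplement(out[flip])
  out
}

# Align one oriented read against the current model; returns NULL or a
# list(qstart, ops) with 1-based model start of the alignment and parsed
# CIGAR ops. Band per the recruit_align convention.
.alignToModel <- function(modelSeq, modelLen, rseq, k, bandScale, minBand) {
  rlen <- nchar(rseq)
  band <- as.integer(max(minBand, ceiling(bandScale * rlen)))
  hits <- .kmer_seed_hits(modelSeq, rseq, as.integer(k))
  if (nrow(hits) == 0L) return(NULL)
  cls <- .clusterSeeds(hits[, 1], hits[, 2], band, rlen)
  best <- NULL
  for (cl in cls) {
    a <- .alignCluster(modelSeq, modelLen, rseq, cl, band)
    if (is.null(a)) next
    if (is.null(best) || a$score > best$score) best <- a
  }
  if (is.null(best)) return(NULL)
  list(qstart = best$qstart, ops = .parseCigar(best$cigar), rseq = rseq,
       rstart = best$rstart)
}

# One round of per-column voting. Returns list(sequence, columnDepth,
# support, changed).
.callConsensus <- function(modelSeq, alnList, minDepth) {
  L <- nchar(modelSeq)
  bases <- c("A", "C", "G", "T")
  votes <- matrix(0L, nrow = 5L, ncol = L,
                  dimnames = list(c(bases, "-"), NULL))
  spanStart <- integer(0); spanEnd <- integer(0)
  insKey <- character(0); insCount <- integer(0)
  insTab <- new.env(parent = emptyenv())
  for (aln in alnList) {
    p <- aln$qstart          # current model column
    r <- aln$rstart          # current read position
    chars <- strsplit(aln$rseq, "", fixed = TRUE)[[1]]
    ops <- aln$ops
    spanStart <- c(spanStart, p)
    for (t in seq_along(ops$op)) {
      op <- ops$op[t]; len <- ops$len[t]
      if (op == "=" || op == "X") {
        cols <- p:(p + len - 1L)
        b <- chars[r:(r + len - 1L)]
        bi <- match(b, bases)
        ok <- !is.na(bi)
        if (any(ok)) {
          idx <- cbind(bi[ok], cols[ok])
          for (u in seq_len(nrow(idx)))
            votes[idx[u, 1], idx[u, 2]] <- votes[idx[u, 1], idx[u, 2]] + 1L
        }
        p <- p + len; r <- r + len
      } else if (op == "D") {
        cols <- p:(p + len - 1L)
        votes[5L, cols] <- votes[5L, cols] + 1L
        p <- p + len
      } else if (op == "I") {
        # insertion between model columns p-1 and p: record first base
        b <- chars[r]
        if (p > 1L && b %in% bases) {
          key <- paste0(p - 1L, "_", b)
          cur <- insTab[[key]]
          insTab[[key]] <- if (is.null(cur)) 1L else cur + 1L
        }
        r <- r + len
      }
    }
    spanEnd <- c(spanEnd, p - 1L)
  }
  # reads spanning each inter-column junction (covers col j and j+1)
  spanCov <- integer(L)
  if (length(spanStart) > 0) {
    cov <- IRanges::coverage(IRanges::IRanges(spanStart, spanEnd), width = L)
    spanCov <- as.integer(cov)
  }
  baseVotes <- votes[1:4, , drop = FALSE]
  nongap <- colSums(baseVotes)
  gapv <- votes[5L, ]
  total <- nongap + gapv
  top <- apply(baseVotes, 2L, which.max)   # ties resolved A<C<G<T by which.max
  topVotes <- baseVotes[cbind(top, seq_len(L))]
  outChar <- character(0)
  outDepth <- integer(0)
  outSupp <- numeric(0)
  insAt <- vector("list", L)
  for (key in ls(insTab)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    j <- as.integer(parts[1]); b <- parts[2]; n <- insTab[[key]]
    cur <- insAt[[j]]
    if (is.null(cur) || n > cur$n || (n == cur$n && b < cur$b))
      insAt[[j]] <- list(b = b, n = n)
  }
  for (j in seq_len(L)) {
    drop <- total[j] > 0L && gapv[j] > total[j] / 2  # gap majority deletes
    if (!drop) {
      if (nongap[j] < minDepth) {
        outChar <- c(outChar, "N"); outDepth <- c(outDepth, nongap[j])
        outSupp <- c(outSupp, NA_real_)
      } else {
        outChar <- c(outChar, c("A", "C", "G", "T")[top[j]])
        outDepth <- c(outDepth, nongap[j])
        outSupp <- c(outSupp, topVotes[j] / nongap[j])
      }
    }
    insj <- insAt[[j]]
    if (!is.null(insj)) {
      # strict plurality: more than half the spanning reads insert this base
      spanN <- min(spanCov[j], if (j < L) spanCov[j + 1L] else spanCov[j])
      if (spanN > 0L && insj$n > spanN / 2) {
        outChar <- c(outChar, if (insj$n >= minDepth) insj$b else "N")
        outDepth <- c(outDepth, insj$n)
        outSupp <- c(outSupp, insj$n / spanN)
      }
    }
  }
  newSeq <- paste(outChar, collapse = "")
  list(sequence = newSeq, columnDepth = as.integer(outDepth),
       support = outSupp, changed = !identical(newSeq, modelSeq))
}

#' Build a consensus model from oriented reads
#'
#' Each read is aligned to the current model (banded local alignment with
#' the recruit_align scoring); per column the majority character among
#' contributing reads is called, with ties broken by base order
#' A < C < G < T and a gap losing ties to bases. A column whose votes are
#' mostly gaps is deleted; a new column is opened where a strict plurality
#' (more than half of the reads spanning the junction) insert the same
#' base. Columns with fewer than `minDepth` non-gap reads are called `N`.
#' Alignment and calling iterate until the model is unchanged or `maxIter`
#' rounds.
#'
#' @param seedModel Starting model sequence (e.g. a cDNA or a perfect
#'   reference fragment).
#' @param reads Oriented reads (`DNAStringSet`, from [orientReads()]).
#' @param minDepth Minimum per-column read depth for a base call
#'   (default 5).
#' @param maxIter Maximum align-and-call iterations (default 5).
#' @param k,bandScale,minBand Alignment parameters as in [recruitReads()].
#' @return A [ConsensusModel-class].
#' @export
buildConsensus <- function(seedModel, reads, minDepth = 5L, maxIter = 5L,
                           k = 13L, bandScale = 0.2, minBand = 32L) {
  seed <- .asDNAString(seedModel, "seedModel")
  if (length(seed) == 0L) stop("seedModel must be non-empty")
  reads <- .asDNAStringSet(reads, "reads")
  modelSeq <- as.character(seed)
  res <- NULL
  iter <- 0L
  converged <- FALSE
  if (length(reads) == 0L) {
    L <- nchar(modelSeq)
    return(new("ConsensusModel",
               sequence = Biostrings::DNAString(strrep("N", L)),
               columnDepth = integer(L), support = rep(NA_real_, L),
               exons = IRanges::IRanges(),
               spliceDinucleotides = S4Vectors::DataFrame(),
               iterations = 0L, converged = TRUE))
  }
  rseqs <- as.character(reads)
  while (iter < maxIter) {
    iter <- iter + 1L
    L <- nchar(modelSeq)
    alnList <- list()
    for (i in seq_along(rseqs)) {
      a <- .alignToModel(modelSeq, L, rseqs[i], k, bandScale, minBand)
      if (!is.null(a)) alnList[[length(alnList) + 1L]] <- a
    }
    res <- .callConsensus(modelSeq, alnList, minDepth)
    if (!res$changed) { converged <- TRUE; break }
    modelSeq <- res$sequence
  }
  new("ConsensusModel", sequence = Biostrings::DNAString(res$sequence),
      columnDepth = res$columnDepth, support = res$support,
      exons = IRanges::IRanges(),
      spliceDinucleotides = S4Vectors::DataFrame(),
      iterations = iter, converged = converged)
}

# Split an alignment row's cigar into exon-like blocks at deletion runs of
# at least `minIntron` (query-consuming gaps = introns skipped by the cDNA).
.splitBlocks <- function(row, minIntron = 40L) {
  ops <- .parseCigar(row$cigar)
  blocks <- list()
  q <- row$qstart; r <- row$rstart
  bq <- q; br <- r
  open <- FALSE
  for (t in seq_along(ops$op)) {
    op <- ops$op[t]; len <- ops$len[t]
    if (op == "D" && len >= minIntron) {
      if (open) blocks[[length(blocks) + 1L]] <-
          list(qstart = bq, qend = q - 1L, rstart = br, rend = r - 1L)
      q <- q + len
      bq <- q; br <- r
      open <- FALSE
      next
    }
    open <- TRUE
    if (op == "=" || op == "X") { q <- q + len; r <- r + len }
    else if (op == "D") q <- q + len
    else r <- r + len
  }
  if (open) blocks[[length(blocks) + 1L]] <-
      list(qstart = bq, qend = q - 1L, rstart = br, rend = r - 1L)
  blocks
}

#' Infer exon/intron structure by mapping a cDNA onto a genomic model
#'
#' The cDNA is recruited against the genomic model with exon-scale
#' thresholds; aligned blocks become exons and the gaps between
#' consecutive blocks become introns. Each intron's boundary is allowed to
#' shift by up to 5 bp (when the flanking genomic sequence makes the
#' placement ambiguous) to expose a GT/AG donor/acceptor first, then
#' CG/AG, before a noncanonical pair is accepted; the applied shift is
#' recorded. Introns are classified `canonical` (GT/AG), `atypical-known`
#' (CG/AG) or `noncanonical`.
#'
#' @param genomicModel The genomic sequence (string, `DNAString`, or
#'   [ConsensusModel-class], whose sequence is used and which is returned
#'   annotated).
#' @param cdna The cDNA sequence.
#' @param minExon Minimum exon length (default 20); also used as
#'   `minAlnLen`/`minReadLen` for the recruitment.
#' @param minIdentity Minimum block identity (default 90).
#' @param maxShift Largest boundary shift tried (default 5).
#' @param k Seed length for the recruitment (default 11).
#' @return The input [ConsensusModel-class] (or a new one wrapping the
#'   plain sequence) with `exons` and `spliceDinucleotides` filled in.
#' @export
inferGeneStructure <- function(genomicModel, cdna, minExon = 20L,
                               minIdentity = 90, maxShift = 5L, k = 11L) {
  model <- if (is(genomicModel, "ConsensusModel")) genomicModel else {
    s <- .asDNAString(genomicModel, "genomicModel")
    new("ConsensusModel", sequence = s,
        columnDepth = rep(NA_integer_, length(s)),
        support = rep(NA_real_, length(s)),
        exons = IRanges::IRanges(),
        spliceDinucleotides = S4Vectors::DataFrame(),
        iterations = 0L, converged = TRUE)
  }
  g <- consensusSequence(model)
  cdna <- .asDNAString(cdna, "cdna")
  cset <- Biostrings::DNAStringSet(list(cdna)); names(cset) <- "cdna"
  aln <- recruitReads(g, cset, k = k, minReadLen = minExon,
                      minAlnLen = minExon, minIdentity = minIdentity,
                      minBand = 32L)
  if (nrow(aln) == 0L)
    stop("structure undetermined: cDNA could not be recruited to the model")
  df <- as.data.frame(aln)
  if (length(unique(df$strand)) > 1L)
    df <- df[df$strand == names(sort(table(df$strand), decreasing = TRUE))[1], ]
  blocks <- do.call(c, lapply(seq_len(nrow(df)), function(i)
    .splitBlocks(df[i, ])))
  blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "qstart"))]
  # exon boundaries can double-use cDNA bases when the intron edge matches
  # the next exon's edge; trim the later block so blocks tile the cDNA
  if (length(blocks) > 1L) {
    for (i in 2:length(blocks)) {
      ov <- blocks[[i - 1L]]$rend - blocks[[i]]$rstart + 1L
      if (ov > 0L) {
        blocks[[i]]$rstart <- blocks[[i]]$rstart + ov
        blocks[[i]]$qstart <- blocks[[i]]$qstart + ov
      }
    }
    blocks <- blocks[vapply(blocks, function(b) b$rend >= b$rstart, logical(1))]
  }
  blocks <- blocks[vapply(blocks, function(b) b$qend - b$qstart + 1L,
                          numeric(1)) >= minExon]
  if (length(blocks) == 0L)
    stop("structure undetermined: no block of at least minExon bp")
  gs <- as.character(g)
  exStart <- vapply(blocks, `[[`, numeric(1), "qstart")
  exEnd <- vapply(blocks, `[[`, numeric(1), "qend")
  nIntron <- length(blocks) - 1L
  donors <- character(nIntron); acceptors <- character(nIntron)
  classes <- character(nIntron); shifts <- integer(nIntron)
  if (nIntron > 0) {
    for (i in seq_len(nIntron)) {
      d <- exEnd[i] + 1L        # first intron base
      a <- exStart[i + 1L] - 1L # last intron base
      pick <- .pickSpliceShift(gs, d, a, maxShift)
      shifts[i] <- pick$shift
      exEnd[i] <- exEnd[i] + pick$shift
      exStart[i + 1L] <- exStart[i + 1L] + pick$shift
      donors[i] <- pick$donor
      acceptors[i] <- pick$acceptor
      classes[i] <- pick$class
    }
  }
  model@exons <- IRanges::IRanges(as.integer(exStart), as.integer(exEnd))
  model@spliceDinucleotides <- S4Vectors::DataFrame(
    donor = donors, acceptor = acceptors, classification = classes,
    shift = shifts)
  model
}

# Choose the intron boundary shift that exposes GT/AG, then CG/AG, then
# accept the unshifted noncanonical pair. A shift delta is valid when the
# exonic bases it exchanges are identical, so the spliced product is
# unchanged: for delta > 0, g[d .. d+delta-1] == g[a+1 .. a+delta];
# for delta < 0 the mirrored condition holds.
.pickSpliceShift <- function(gs, d, a, maxShift) {
  L <- nchar(gs)
  dinucs <- function(d2, a2) c(substring(gs, d2, d2 + 1L),
                               substring(gs, a2 - 1L, a2))
  valid <- function(delta) {
    if (delta == 0L) return(TRUE)
    if (delta > 0L) {
      if (a + delta > L) return(FALSE)
      substring(gs, d, d + delta - 1L) == substring(gs, a + 1L, a + delta)
    } else {
      k <- -delta
      if (d - k < 1L) return(FALSE)
      substring(gs, d - k, d - 1L) == substring(gs, a - k + 1L, a)
    }
  }
  deltas <- c(0L, as.vector(rbind(seq_len(maxShift), -seq_len(maxShift))))
  for (target in list(c("GT", "AG", "canonical"),
                      c("CG", "AG", "atypical-known"))) {
    for (delta in deltas) {
      d2 <- d + delta; a2 <- a + delta
      if (d2 < 1L || a2 > L || a2 - d2 < 3L) next
      if (!valid(delta)) next
      dn <- dinucs(d2, a2)
      if (dn[1] == target[1] && dn[2] == target[2])
        return(list(shift = delta, donor = dn[1], acceptor = dn[2],
                    class = target[3]))
    }
  }
  dn <- dinucs(d, a)
  list(shift = 0L, donor = dn[1], acceptor = dn[2], class = "noncanonical")
}

#' Summary statistics of a consensus model
#'
#' @param model A [ConsensusModel-class] (or any sequence).
#' @param ... Forwarded to [nonbAnnotation()].
#' @return A list with `length`, `nCount`, `gcPercent` (N excluded, `NA`
#'   for an all-N model), `intronLengths` (empty unless exons are
#'   annotated) and `nonbFraction`.
#' @export
modelStats <- function(model, ...) {
  seq <- if (is(model, "ConsensusModel")) consensusSequence(model)
         else .asDNAString(model, "model")
  ex <- if (is(model, "ConsensusModel")) exons(model) else IRanges::IRanges()
  intronLengths <- if (length(ex) >= 2L) {
    IRanges::start(ex)[-1] - IRanges::end(ex)[-length(ex)] - 1L
  } else integer(0)
  ann <- nonbAnnotation(seq, ...)
  list(length = length(seq),
       nCount = sum(Biostrings::letterFrequency(seq, "N")),
       gcPercent = gcPercent(seq),
       intronLengths = intronLengths,
       nonbFraction = ann$fraction)
}

#' Write a consensus model as FASTA, per-column TSV, and GFF3
#'
#' The FASTA carries the consensus with literal N tracts; the TSV holds
#' per-column depth and support; the GFF3 (1-based inclusive, per GFF
#' convention) holds gene/exon features when exons are annotated.
#'
#' @param model A [ConsensusModel-class].
#' @param fastaPath,depthPath,gffPath Output files (any may be `NULL`).
#' @param id Sequence identifier.
#' @return Paths written, invisibly.
#' @export
writeConsensusModel <- function(model, fastaPath = NULL, depthPath = NULL,
                                gffPath = NULL, id = "consensus") {
  if (!is.null(fastaPath)) {
    dss <- Biostrings::DNAStringSet(list(consensusSequence(model)))
    names(dss) <- id
    Biostrings::writeXStringSet(dss, fastaPath)
  }
  if (!is.null(depthPath)) {
    df <- data.frame(position = seq_along(columnDepth(model)),
                     depth = columnDepth(model),
                     support = columnSupport(model))
    write.table(df, depthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(gffPath)) {
    ex <- exons(model)
    gr <- GenomicRanges::GRanges(
      seqnames = id,
      ranges = c(IRanges::IRanges(1L, length(consensusSequence(model))), ex),
      strand = "+")
    gr$type <- c("gene", rep("exon", length(ex)))
    gr$ID <- c(paste0(id, ".gene"),
               if (length(ex)) paste0(id, ".exon", seq_along(ex)) else character(0))
    rtracklayer::export.gff3(gr, gffPath)
  }
  invisible(c(fasta = fastaPath, depth = depthPath, gff = gffPath))
}
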
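#' GeneArchitecture: a gene as exon/intron intervals with non-B truth
#'
#' Container for a (typically synthetic) gene: its nucleotide sequence, the
#' exon intervals, and a truth annotation of non-B DNA determinants
#' (G-quadruplex motifs, tandem repeats, dyads) as a [GenomicRanges::GRanges]
#' whose `class` metadata column carries the determinant class. Coordinates
#' inside the object are 1-based closed per Bioconductor convention; BED
#' output is 0-based half-open.
#'
#' @slot id Single identifier string.
#' @slot sequence A [Biostrings::DNAString] over A, C, G, T, N.
#' @slot exons An [IRanges::IRanges] of exon intervals, disjoint and sorted.
#' @slot nonbTruth A [GenomicRanges::GRanges] with metadata column `class`
#'   in `g4`, `tandem`, `dyad`.
#' @slot gcPercent Percent G+C among unambiguous bases of `sequence`.
#' @export
setClass("GeneArchitecture",
         representation(id = "character",
                        sequence = "DNAString",
                        exons = "IRanges",
                        nonbTruth = "GRanges",
                        gcPercent = "numeric"))

setValidity("GeneArchitecture", function(object) {
  msg <- character(0)
  len <- length(object@sequence)
  ex <- object@exons
  if (length(object@id) != 1L || is.na(object@id))
    msg <- c(msg, "id must be a single string")
  if (length(ex) > 0) {
    if (any(IRanges::start(ex) < 1L) || any(IRanges::end(ex) > len))
      msg <- c(msg, "exons must lie within the sequence")
    if (is.unsorted(IRanges::start(ex)))
      msg <- c(msg, "exons must be sorted")
    if (length(ex) > 1 &&
        any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be disjoint")
  }
  tr <- object@nonbTruth
  if (length(tr) > 0) {
    if (any(GenomicRanges::start(tr) < 1L) || any(GenomicRanges::end(tr) > len))
      msg <- c(msg, "nonbTruth intervals must lie within the sequence")
    if (is.null(tr$class) || !all(tr$class %in% c("g4", "tandem", "dyad")))
      msg <- c(msg, "nonbTruth$class must be g4, tandem or dyad")
  }
  gc <- gcPercent(object@sequence)
  if (!isTRUE(is.na(gc) == is.na(object@gcPercent)) ||
      (!is.na(gc) && abs(gc - object@gcPercent) > 1e-6))
    msg <- c(msg, "gcPercent does not match the sequence")
  if (length(msg)) msg else TRUE
})

#' SimulationTruth: read-simulation parameters with non-B context dependence
#'
#' Holds the parameters that make simulated reads emulate long-read
#' behaviour over GC-rich non-B DNA: a depletion `d` applied per read as an
#' acceptance probability `(1 - d)^f` (with `f` the fraction of the read
#' overlapping non-B truth intervals), and per-class substitution /
#' insertion / deletion rates (background vs non-B positions).
#'
#' @slot depletion Depletion `d` in `[0, 1]` over non-B intervals.
#' @slot backgroundRates Named numeric `c(sub=, ins=, del=)`, each in `[0, 1]`.
#' @slot nonbRates Same shape, applied to positions inside non-B intervals.
#' @slot depth Target naive fold-coverage (> 0).
#' @slot seed Integer seed driving all randomness of a simulation call.
#' @export
setClass("SimulationTruth",
         representation(depletion = "numeric",
                        backgroundRates = "numeric",
                        nonbRates = "numeric",
                        depth = "numeric",
                        seed = "integer"))

setValidity("SimulationTruth", function(object) {
  msg <- character(0)
  ok01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (length(object@depletion) != 1L || !ok01(object@depletion))
    msg <- c(msg, "depletion must be a single value in [0, 1]")
  for (nm in c("backgroundRates", "nonbRates")) {
    r <- slot(object, nm)
    if (length(r) != 3L || !identical(names(r), c("sub", "ins", "del")) || !ok01(r))
      msg <- c(msg, paste0(nm, " must be c(sub=, ins=, del=) with rates in [0, 1]"))
  }
  if (length(object@depth) != 1L || !is.finite(object@depth) || object@depth <= 0)
    msg <- c(msg, "depth must be > 0")
  if (length(msg)) msg else TRUE
})

#' ReadSimulation: simulated reads plus machine-readable truth
#'
#' The result of [simulateLongReads()] or [simulateShortReads()]: the reads
#' as a [Biostrings::DNAStringSet], a truth table (one row per read: source
#' interval on the embedded source sequence, strand, overlap fraction with
#' non-B truth, realised error rate), the full source sequence (gene plus
#' flanks), and the 1-based offset of the gene within the source.
#'
#' @slot reads Simulated reads ([Biostrings::DNAStringSet]).
#' @slot truth [S4Vectors::DataFrame] with columns `readId`, `start`, `end`
#'   (1-based closed on the source), `strand`, `classOverlap`,
#'   `trueErrorRate`.
#' @slot source The embedded source sequence the reads were drawn from.
#' @slot geneStart 1-based position of the gene's first base in `source`.
#' @slot gene The originating [GeneArchitecture].
#' @slot params A list recording the simulation parameters.
#' @export
setClass("ReadSimulation",
         representation(reads = "DNAStringSet",
                        truth = "DataFrame",
                        source = "DNAString",
                        geneStart = "integer",
                        gene = "GeneArchitecture",
                        params = "list"))

setValidity("ReadSimulation", function(object) {
  msg <- character(0)
  tr <- object@truth
  need <- c("readId", "start", "end", "strand", "classOverlap", "trueErrorRate")
  if (!all(need %in% colnames(tr)))
    msg <- c(msg, paste("truth must have columns", paste(need, collapse = ", ")))
  else {
    if (nrow(tr) != length(object@reads))
      msg <- c(msg, "truth must have one row per read")
    if (nrow(tr) > 0) {
      if (any(tr$start < 1L) || any(tr$end > length(object@source)))
        msg <- c(msg, "every true_source interval must lie within the source")
      if (!all(tr$strand %in% c("+", "-")))
        msg <- c(msg, "strand must be + or -")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CoverageReport: observed vs expected coverage for one query
#'
#' Aggregates the coverage diagnostics for a query sequence against a read
#' set: observed aligned bases, the expected total
#' (query length x copy number x dataset fold-coverage), their ratio as a
#' percent, the per-position alignment depth, patchiness (percent of
#' positions with zero depth), and a summary of per-alignment error rates.
#'
#' @slot queryId,queryLen Query identifier and length (bp).
#' @slot copyNumber Genomic copy number of the query (>= 1).
#' @slot datasetDepth Fold-coverage of the read dataset (user input).
#' @slot observedBp Total aligned query bases over all retained alignments.
#' @slot expectedBp `queryLen * copyNumber * datasetDepth`.
#' @slot depletionPercent `100 * observedBp / expectedBp`.
#' @slot depthProfile Integer vector of per-position alignment depth.
#' @slot patchiness Percent of query positions with zero depth.
#' @slot errorRateSummary Named numeric `c(mean=, min=, max=)` of
#'   per-alignment error rates (percent); `NA` when there are no alignments.
#' @export
setClass("CoverageReport",
         representation(queryId = "character",
                        queryLen = "integer",
                        copyNumber = "numeric",
                        datasetDepth = "numeric",
                        observedBp = "numeric",
                        expectedBp = "numeric",
                        depletionPercent = "numeric",
                        depthProfile = "integer",
                        patchiness = "numeric",
                        errorRateSummary = "numeric"))

setValidity("CoverageReport", function(object) {
  msg <- character(0)
  if (length(object@depthProfile) != object@queryLen)
    msg <- c(msg, "depthProfile must have one entry per query position")
  if (object@patchiness < 0 || object@patchiness > 100)
    msg <- c(msg, "patchiness must be in [0, 100]")
  if (object@depletionPercent < 0)
    msg <- c(msg, "depletionPercent must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ConsensusModel: a consensus gene model reconstructed from reads
#'
#' The product of [buildConsensus()] (optionally annotated by
#' [inferGeneStructure()]): the consensus sequence with N tracts where
#' fewer than `minDepth` reads contribute a base, per-column depth and
#' agreement, and, when a cDNA has been mapped, the inferred exons and the
#' splice-site dinucleotides of each intron.
#'
#' @slot sequence Consensus [Biostrings::DNAString]; under-supported
#'   columns are `N`.
#' @slot columnDepth Per-column count of reads contributing a non-gap
#'   character.
#' @slot support Per-column fraction of contributing reads that agree with
#'   the called character (`NA` at N columns).
#' @slot exons Inferred exon intervals ([IRanges::IRanges]); empty until a
#'   cDNA is mapped.
#' @slot spliceDinucleotides [S4Vectors::DataFrame] with one row per intron:
#'   `donor`, `acceptor` 2-mers, `classification` (canonical GT/AG,
#'   atypical-known CG/AG, else noncanonical) and the boundary `shift`
#'   applied.
#' @slot iterations Number of align-and-call iterations performed.
#' @slot converged Whether the model stopped changing before `maxIter`.
#' @export
setClass("ConsensusModel",
         representation(sequence = "DNAString",
                        columnDepth = "integer",
                        support = "numeric",
                        exons = "IRanges",
                        spliceDinucleotides = "DataFrame",
                        iterations = "integer",
                        converged = "logical"))

setValidity("ConsensusModel", function(object) {
  msg <- character(0)
  if (length(object@columnDepth) != length(object@sequence))
    msg <- c(msg, "columnDepth must have one entry per consensus column")
  if (length(object@support) != length(object@sequence))
    msg <- c(msg, "support must have one entry per consensus column")
  if (length(msg)) msg else TRUE
})
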
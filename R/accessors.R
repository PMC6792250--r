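# Accessors and show methods for the package's S4 classes.

#' @describeIn GeneArchitecture the gene's nucleotide sequence
#' @param x A `GeneArchitecture`.
#' @export
setMethod("geneSequence", "GeneArchitecture", function(x) x@sequence)

#' @describeIn GeneArchitecture the exon intervals (1-based closed)
#' @export
setMethod("exons", "GeneArchitecture", function(x) x@exons)

#' @describeIn GeneArchitecture the non-B truth annotation
#' @export
setMethod("nonbTruth", "GeneArchitecture", function(x) x@nonbTruth)

#' @describeIn GeneArchitecture the stored GC percent (recomputable from
#'   the sequence)
#' @export
setMethod("gcPercent", "GeneArchitecture", function(x) x@gcPercent)

setMethod("show", "GeneArchitecture", function(object) {
  cat("GeneArchitecture ", sQuote(object@id), "\n",
      "  length: ", length(object@sequence), " bp, GC ",
      sprintf("%.1f", object@gcPercent), "%\n",
      "  exons: ", length(object@exons),
      ", non-B truth intervals: ", length(object@nonbTruth), "\n", sep = "")
})

#' @describeIn ReadSimulation the simulated reads
#' @param x A `ReadSimulation`.
#' @export
setMethod("simReads", "ReadSimulation", function(x) x@reads)

#' @describeIn ReadSimulation the per-read truth table
#' @export
setMethod("readTruth", "ReadSimulation", function(x) x@truth)

#' @describeIn ReadSimulation the embedded source sequence (gene + flanks)
#' @export
setMethod("sourceSequence", "ReadSimulation", function(x) x@source)

setMethod("show", "ReadSimulation", function(object) {
  cat("ReadSimulation: ", length(object@reads), " reads over a ",
      length(object@source), " bp source (gene at position ",
      object@geneStart, ")\n", sep = "")
  if (length(object@reads) > 0) {
    cat("  mean read length: ",
        round(mean(Biostrings::width(object@reads))), " bp; mean realised ",
        "error rate: ",
        sprintf("%.3f", mean(object@truth$trueErrorRate)), "\n", sep = "")
  }
})

#' @describeIn CoverageReport total aligned query bases
#' @param x A `CoverageReport`.
#' @export
setMethod("observedBp", "CoverageReport", function(x) x@observedBp)

#' @describeIn CoverageReport expected bases (length x copies x depth)
#' @export
setMethod("expectedBp", "CoverageReport", function(x) x@expectedBp)

#' @describeIn CoverageReport percent of query positions with zero depth
#' @export
setMethod("patchiness", "CoverageReport", function(x) x@patchiness)

setMethod("show", "CoverageReport", function(object) {
  cat("CoverageReport for ", sQuote(object@queryId), " (", object@queryLen,
      " bp x ", object@copyNumber, " copies at ", object@datasetDepth,
      "X)\n", sep = "")
  cat(sprintf("  observed %.0f bp of %.0f bp expected (%.1f%%)\n",
              object@observedBp, object@expectedBp, object@depletionPercent))
  cat(sprintf("  patchiness %.1f%%; error rate mean %.1f%% [%.1f, %.1f]\n",
              object@patchiness, object@errorRateSummary[["mean"]],
              object@errorRateSummary[["min"]], object@errorRateSummary[["max"]]))
})

#' @describeIn ConsensusModel the consensus sequence (with N tracts)
#' @param x A `ConsensusModel`.
#' @export
setMethod("consensusSequence", "ConsensusModel", function(x) x@sequence)

#' @describeIn ConsensusModel per-column non-gap read depth
#' @export
setMethod("columnDepth", "ConsensusModel", function(x) x@columnDepth)

#' @describeIn ConsensusModel per-column agreement fraction
#' @export
setMethod("columnSupport", "ConsensusModel", function(x) x@support)

#' @describeIn ConsensusModel inferred exon intervals
#' @export
setMethod("exons", "ConsensusModel", function(x) x@exons)

#' @describeIn ConsensusModel donor/acceptor 2-mers per intron
#' @export
setMethod("spliceDinucleotides", "ConsensusModel", function(x) x@spliceDinucleotides)

setMethod("show", "ConsensusModel", function(object) {
  nN <- sum(Biostrings::letterFrequency(object@sequence, "N"))
  cat("ConsensusModel: ", length(object@sequence), " bp (", nN, " N), ",
      object@iterations, " iteration(s), ",
      if (object@converged) "converged" else "not converged", "\n", sep = "")
  if (length(object@exons) > 0)
    cat("  exons: ", length(object@exons), "; introns: ",
        nrow(object@spliceDinucleotides), "\n", sep = "")
})
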
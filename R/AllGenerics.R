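#' @export
setGeneric("gcPercent", function(x) standardGeneric("gcPercent"))

#' @export
setGeneric("geneSequence", function(x) standardGeneric("geneSequence"))

#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @export
setGeneric("nonbTruth", function(x) standardGeneric("nonbTruth"))

#' @export
setGeneric("simReads", function(x) standardGeneric("simReads"))

#' @export
setGeneric("readTruth", function(x) standardGeneric("readTruth"))

#' @export
setGeneric("sourceSequence", function(x) standardGeneric("sourceSequence"))

#' @export
setGeneric("observedBp", function(x) standardGeneric("observedBp"))

#' @export
setGeneric("expectedBp", function(x) standardGeneric("expectedBp"))

#' @export
setGeneric("patchiness", function(x) standardGeneric("patchiness"))

#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))

#' @export
setGeneric("columnDepth", function(x) standardGeneric("columnDepth"))

#' @export
setGeneric("columnSupport", function(x) standardGeneric("columnSupport"))

#' @export
setGeneric("spliceDinucleotides", function(x) standardGeneric("spliceDinucleotides"))
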
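Package: nonBprofiler
Title: Non-B DNA Annotation, Long-Read Coverage Depletion and Consensus
    Gene Models for GC-Rich Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to investigate why GC-rich genes are missing from genome
    assemblies built from long and short reads. The package annotates non-B
    DNA determinants (strict G-quadruplex motifs on both strands, exact
    tandem repeats, dyad/inverted-repeat candidates), recruits long reads
    against a query gene by k-mer seeding and banded local alignment,
    quantifies coverage depletion against an expected-coverage formula
    (query length x copy number x dataset fold-coverage) together with
    patchiness and per-alignment error rates, and reconstructs consensus
    gene models from noisy reads by iterative alignment and majority vote,
    rendering unalignable or under-covered sections as N tracts and
    inferring exon/intron structure with splice-site dinucleotides from a
    cDNA. A seeded simulator generates GC-rich gene architectures with
    tandem-repeat introns and reads whose sampling probability and error
    rate depend on non-B context, with machine-readable truth, so the whole
    pipeline is testable without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
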
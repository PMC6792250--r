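# Pipeline orchestration: a validated configuration, three entry points
# (simulate / profile / reconstruct), standard-format outputs and a run
# manifest. All randomness flows from the single seed in the config.

.defaultConfig <- function() {
  list(
    queryFasta = NULL, readsFile = NULL, cdnaFasta = NULL,
    outDir = ".",
    seed = 1L,
    datasetDepth = 60, copyNumber = 1,
    k = 13L, minReadLen = 400L, minAlnLen = 400L, minIdentity = 70,
    minDepth = 5L, maxIter = 5L,
    g4MaxLoop = 12L, tandemMaxPeriod = 20L, tandemMinCopies = 3L,
    tandemMinLen = 12L, dyadMinArm = 6L, dyadMaxLoop = 50L,
    dyadMaxArmMismatch = 1L,
    simulate = list(nExons = 2L, exonLen = 500L,
                    intronMotifs = "TTGGGGGGG", intronCopies = 170L,
                    exonGC = 65, depth = 60, readLenMean = 1000,
                    readLenSd = 250, depletion = 0.9,
                    backgroundRates = c(sub = 0.04, ins = 0.06, del = 0.02),
                    nonbRates = c(sub = 2/30, ins = 0.1, del = 1/30),
                    flank = 2000L, flankGC = 45))
}

#' Build a pipeline configuration
#'
#' Returns the default configuration with any supplied overrides applied
#' and validated. The defaults describe the GC-rich gene setting the
#' package emulates: a two-exon 65%-GC gene with a ~1.5 kb tandem-repeat
#' intron, 60X long reads of ~1 kb with 12% background error (sub:ins:del
#' = 2:3:1), 20% error over non-B tracts, and depletion 0.9 over non-B
#' intervals.
#'
#' @param ... Named overrides of top-level fields; `simulate` may be a
#'   (partial) named list of simulation fields.
#' @return A validated config (named list, class `nonb_config`).
#' @export
pipelineConfig <- function(...) {
  cfg <- .defaultConfig()
  over <- list(...)
  for (nm in names(over)) {
    if (nm == "simulate") {
      for (nm2 in names(over$simulate)) cfg$simulate[[nm2]] <- over$simulate[[nm2]]
    } else cfg[[nm]] <- over[[nm]]
  }
  validateConfig(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg A config list.
#' @return The config, invisibly classed, or an error describing the
#'   offending field.
#' @export
validateConfig <- function(cfg) {
  .assertScalarNumber(cfg$seed, "seed")
  .assertScalarNumber(cfg$datasetDepth, "datasetDepth", positive = TRUE)
  .assertScalarNumber(cfg$copyNumber, "copyNumber", positive = TRUE)
  if (cfg$k < 8L) stop("k must be >= 8")
  for (f in c("minReadLen", "minAlnLen"))
    .assertScalarNumber(cfg[[f]], f, nonneg = TRUE)
  if (cfg$minIdentity < 0 || cfg$minIdentity > 100)
    stop("minIdentity must be a percent")
  .assertScalarNumber(cfg$minDepth, "minDepth", positive = TRUE)
  s <- cfg$simulate
  if (s$depletion < 0 || s$depletion > 1) stop("depletion must be in [0, 1]")
  if (s$exonGC < 0 || s$exonGC > 100) stop("exonGC must be a percent")
  class(cfg) <- "nonb_config"
  invisible(cfg)
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip through YAML unchanged.
#'
#' @param path YAML file.
#' @return For `readPipelineConfig`, the validated config.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("backgroundRates", "nonbRates")) {
    if (!is.null(raw$simulate[[nm]]))
      raw$simulate[[nm]] <- unlist(raw$simulate[[nm]])
  }
  do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @param cfg A config from [pipelineConfig()].
#' @export
writePipelineConfig <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  x$simulate$backgroundRates <- as.list(x$simulate$backgroundRates)
  x$simulate$nonbRates <- as.list(x$simulate$nonbRates)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

.manifest <- function(cfg, stage, outDir, extra = list()) {
  m <- c(list(stage = stage,
              package = "nonBprofiler",
              version = as.character(packageVersion("nonBprofiler")),
              seed = cfg$seed,
              thresholds = list(k = cfg$k, minReadLen = cfg$minReadLen,
                                minAlnLen = cfg$minAlnLen,
                                minIdentity = cfg$minIdentity,
                                minDepth = cfg$minDepth)),
         extra)
  jsonlite::write_json(m, file.path(outDir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(m)
}

.readQuery <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop("missing input: ", if (is.null(path)) "(unset)" else path)
  Biostrings::readDNAStringSet(path)
}

.readReads <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop("missing input: ", if (is.null(path)) "(unset)" else path)
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Run the simulation stage
#'
#' Generates the configured gene architecture and long reads, and writes
#' the bundle: gene FASTA + BED (exons and non-B truth), reads FASTA,
#' truth TSV, and a run manifest.
#'
#' @param cfg Config from [pipelineConfig()].
#' @return Invisibly, a list with `gene`, `sim` and the output paths.
#' @export
runSimulate <- function(cfg) {
  cfg <- validateConfig(cfg)
  s <- cfg$simulate
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  message("simulate: gene (", s$nExons, " exons, GC ", s$exonGC, ") seed ",
          cfg$seed)
  gene <- generateGene(s$nExons, s$exonLen, s$intronMotifs, s$intronCopies,
                       exonGC = s$exonGC, seed = cfg$seed)
  truth <- simulationTruth(depletion = s$depletion,
                           backgroundRates = s$backgroundRates,
                           nonbRates = s$nonbRates, depth = s$depth,
                           seed = cfg$seed)
  sim <- simulateLongReads(gene, depth = s$depth,
                           readLenMean = s$readLenMean, truth = truth,
                           readLenSd = s$readLenSd, flank = s$flank,
                           flankGC = s$flankGC, seed = cfg$seed)
  paths <- list(
    geneFasta = file.path(cfg$outDir, "gene.fa"),
    geneBed = file.path(cfg$outDir, "gene.bed"),
    readsFasta = file.path(cfg$outDir, "reads.fa"),
    truthTsv = file.path(cfg$outDir, "reads_truth.tsv"))
  writeGeneArchitecture(gene, paths$geneFasta, paths$geneBed)
  writeReads(sim, paths$readsFasta)
  writeReadTruth(sim, paths$truthTsv)
  .manifest(cfg, "simulate", cfg$outDir,
            list(nReads = length(simReads(sim)),
                 geneLength = length(geneSequence(gene))))
  message("simulate: ", length(simReads(sim)), " reads written")
  invisible(c(list(gene = gene, sim = sim), paths))
}

#' Run the coverage-profiling stage
#'
#' Recruits the reads against the query, assembles the
#' [CoverageReport-class], annotates the query's non-B determinants, and
#' writes alignments TSV, report JSON/TSV, depth bedGraph, motif BED and
#' summary TSV. With zero recruited reads a report with depletion 0 and
#' patchiness 100 is still emitted, with a warning.
#'
#' @param cfg Config from [pipelineConfig()]; `queryFasta` and `readsFile`
#'   must be set.
#' @param strict Error (exit-code semantics for the CLI) on empty result.
#' @return Invisibly, a list with `report`, `alignments`, `annotation` and
#'   paths.
#' @export
runProfile <- function(cfg, strict = FALSE) {
  cfg <- validateConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  qset <- .readQuery(cfg$queryFasta)
  reads <- .readReads(cfg$readsFile)
  query <- qset[[1L]]
  qid <- names(qset)[1L]
  message("profile: query ", qid, " (", length(query), " bp), ",
          length(reads), " reads")
  aln <- recruitReads(query, reads, k = cfg$k, minReadLen = cfg$minReadLen,
                      minAlnLen = cfg$minAlnLen,
                      minIdentity = cfg$minIdentity)
  if (nrow(aln) == 0L) {
    msg <- "profile: zero reads recruited"
    if (strict) stop(msg)
    warning(msg)
  }
  report <- coverageReport(query, aln, copyNumber = cfg$copyNumber,
                           datasetDepth = cfg$datasetDepth, queryId = qid)
  ann <- nonbAnnotation(query, id = qid,
                        tandemArgs = list(maxPeriod = cfg$tandemMaxPeriod,
                                          minCopies = cfg$tandemMinCopies,
                                          minLen = cfg$tandemMinLen),
                        dyadArgs = list(minArm = cfg$dyadMinArm,
                                        maxLoop = cfg$dyadMaxLoop,
                                        maxArmMismatch = cfg$dyadMaxArmMismatch))
  paths <- list(alignments = file.path(cfg$outDir, "alignments.tsv"),
                reportJson = file.path(cfg$outDir, "coverage_report.json"),
                reportTsv = file.path(cfg$outDir, "coverage_report.tsv"),
                bedgraph = file.path(cfg$outDir, "depth.bedgraph"),
                motifBed = file.path(cfg$outDir, "motifs.bed"),
                summaryTsv = file.path(cfg$outDir, "nonb_summary.tsv"))
  writeAlignments(aln, paths$alignments)
  writeCoverageReport(report, paths$reportJson, paths$reportTsv)
  writeDepthBedGraph(report, paths$bedgraph)
  writeMotifBed(ann$hits, paths$motifBed)
  sm <- motifSummary(stats::setNames(Biostrings::DNAStringSet(list(query)), qid))
  write.table(sm, paths$summaryTsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  .manifest(cfg, "profile", cfg$outDir,
            list(nAlignments = nrow(aln),
                 depletionPercent = report@depletionPercent,
                 patchiness = report@patchiness))
  message(sprintf("profile: depletion %.1f%%, patchiness %.1f%%",
                  report@depletionPercent, report@patchiness))
  invisible(c(list(report = report, alignments = aln, annotation = ann),
              paths))
}

#' Run the model-reconstruction stage
#'
#' Recruits and orients the reads, builds the consensus model from the
#' query as seed, optionally infers exon/intron structure from a cDNA, and
#' writes consensus FASTA, per-column depth TSV, GFF3 and a stats JSON.
#'
#' @param cfg Config from [pipelineConfig()]; `queryFasta` (seed model)
#'   and `readsFile` must be set, `cdnaFasta` optionally.
#' @param strict Error on empty recruitment instead of warning.
#' @return Invisibly, a list with `model`, `stats`, `alignments` and paths.
#' @export
runReconstruct <- function(cfg, strict = FALSE) {
  cfg <- validateConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  qset <- .readQuery(cfg$queryFasta)
  reads <- .readReads(cfg$readsFile)
  seedModel <- qset[[1L]]
  message("reconstruct: seed ", names(qset)[1L], " (", length(seedModel),
          " bp), ", length(reads), " reads")
  aln <- recruitReads(seedModel, reads, k = cfg$k,
                      minReadLen = cfg$minReadLen,
                      minAlnLen = cfg$minAlnLen,
                      minIdentity = cfg$minIdentity)
  if (nrow(aln) == 0L) {
    msg <- "reconstruct: zero reads recruited"
    if (strict) stop(msg)
    warning(msg)
  }
  oriented <- if (nrow(aln) > 0L) orientReads(aln, reads)
              else Biostrings::DNAStringSet()
  model <- buildConsensus(seedModel, oriented, minDepth = cfg$minDepth,
                          maxIter = cfg$maxIter, k = cfg$k)
  if (!is.null(cfg$cdnaFasta)) {
    cdna <- .readQuery(cfg$cdnaFasta)[[1L]]
    model <- inferGeneStructure(model, cdna)
  }
  st <- modelStats(model)
  paths <- list(fasta = file.path(cfg$outDir, "consensus.fa"),
                depth = file.path(cfg$outDir, "consensus_depth.tsv"),
                gff = file.path(cfg$outDir, "consensus.gff3"),
                stats = file.path(cfg$outDir, "consensus_stats.json"))
  writeConsensusModel(model, paths$fasta, paths$depth,
                      if (length(exons(model)) > 0) paths$gff else NULL)
  jsonlite::write_json(st, paths$stats, auto_unbox = TRUE, digits = NA,
                       na = "null")
  .manifest(cfg, "reconstruct", cfg$outDir,
            list(modelLength = st$length, nCount = st$nCount,
                 iterations = model@iterations))
  message("reconstruct: model ", st$length, " bp with ", st$nCount, " N")
  invisible(c(list(model = model, stats = st, alignments = aln), paths))
}
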
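#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the simulate -> genotype -> associate
#' -> concordance pipeline. A single global seed is expanded into per-stage
#' child seeds by a fixed arithmetic scheme (seed * 7919 + stage-hash mod
#' 2^31 - 1), so any stage can be re-run in isolation and two runs with the
#' same configuration are byte-identical.
#'
#' @param seed global integer seed.
#' @param locus list of [buildLocus()] arguments.
#' @param cohort list of [cohortConfig()] arguments (seed is derived).
#' @param reads list of [readSimConfig()] arguments (seed is derived).
#' @param genotyper list: `clipWindow`, `minOverlap`, `minRatio`, `maxRatio`,
#'   `absCount`.
#' @param association list: `mafMin`, `maxMissing`, `useKinship`.
#' @param svstruct list: `anchorK`, `minChainAnchors`, `minStem`,
#'   `bandWidth`, `run` (logical; haplotype comparison is optional in the
#'   pipeline).
#' @return list of class `PipelineConfig`; serializable to JSON and back
#'   without loss via [writePipelineConfig()] / [readPipelineConfig()].
#' @export
pipelineConfig <- function(seed = 1L,
                           locus = list(refLength = 10000L, armLength = 4100L,
                                        loopLength = 50L, armEditCount = 2L,
                                        breakpoint = 5000L),
                           cohort = list(nIndividuals = 300L,
                                         gAlleleFreq = 0.1,
                                         pUntransformedHet = 0.08,
                                         pUntransformedHom = 0.01,
                                         phenocopyRate = 0.01,
                                         nBackgroundMarkers = 500L,
                                         backgroundMafRange = c(0.05, 0.5),
                                         missingRate = 0.02,
                                         population = "simulated"),
                           reads = list(coverage = 30, readLength = 100L,
                                        substitutionRate = 0,
                                        duplicateRate = 0),
                           genotyper = list(clipWindow = 5L, minOverlap = 5L,
                                            minRatio = 0.1, maxRatio = 0.9,
                                            absCount = 2L),
                           association = list(mafMin = 0.05,
                                              maxMissing = 0.20,
                                              useKinship = TRUE),
                           svstruct = list(anchorK = 21L,
                                           minChainAnchors = 10L,
                                           minStem = 100L, bandWidth = 16L,
                                           run = FALSE)) {
  cfg <- list(seed = as.integer(seed), locus = locus, cohort = cohort,
              reads = reads, genotyper = genotyper,
              association = association, svstruct = svstruct)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Serialize / deserialize a pipeline configuration as JSON
#'
#' @param config a [pipelineConfig()].
#' @param path JSON path.
#' @return `writePipelineConfig` returns `path` invisibly;
#'   `readPipelineConfig` the configuration.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

.stageLog <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full simulation-to-association pipeline
#'
#' Executes, in order: locus construction, cohort simulation, per-individual
#' read simulation, split-read genotyping at the known breakpoint, appending
#' the SV genotype to the background marker set, the mixed-model scan, and
#' concordance accounting (optionally also haplotype-comparison insertion
#' discovery and inverted-repeat characterization). Stage-tagged progress
#' lines go to the message stream; machine-readable outputs go to `outdir`.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory (created if needed).
#' @return A run manifest (list): configuration, per-stage child seeds,
#'   output file md5 hashes, and key per-stage summaries. Also written to
#'   `outdir/manifest.json`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile("run")) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(
    locus = childSeed(config$seed, "locus"),
    cohort = childSeed(config$seed, "cohort"),
    reads = childSeed(config$seed, "reads")
  )

  .stageLog("simulate", "building locus model")
  locus <- do.call(buildLocus, c(config$locus, list(seed = seeds$locus)))
  cohortCfg <- do.call(cohortConfig,
                       c(config$cohort, list(seed = seeds$cohort)))
  sim <- simulateCohort(cohortCfg, locus)
  writeCohortTable(sim$cohort, file.path(outdir, "cohort.tsv"))

  .stageLog("genotype", "simulating reads and genotyping ",
            nrow(sim$cohort), " individuals")
  aln <- lapply(seq_len(nrow(sim$cohort)), function(i) {
    rc <- do.call(readSimConfig,
                  c(config$reads, list(seed = childSeed(seeds$reads, i))))
    simulateReads(sim$cohort$true_genotype[i], locus, rc)
  })
  names(aln) <- sim$cohort$id
  calls <- do.call(genotypeCohort,
                   c(list(alignments = aln, breakpoint = breakpoint(locus)),
                     config$genotyper))
  write.table(calls, file.path(outdir, "sv_evidence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeSvVCF(calls, file.path(outdir, "sv_genotypes.vcf"), chrom = "11",
             pos = breakpoint(locus),
             svlen = insertionLength(locus))

  .stageLog("assoc", "mixed-model scan")
  svGm <- svCallsToMatrix(calls, chrom = "11", pos = breakpoint(locus))
  gm <- bindVariants(sim$markers, svGm)
  svMaf <- {
    dd <- svGm@dosage[, 1]
    af <- mean(dd, na.rm = TRUE) / 2
    if (is.nan(af)) 0 else min(af, 1 - af)
  }
  if (svMaf < config$association$mafMin) {
    .stageLog("assoc", "SV is (near-)monomorphic (MAF ",
              sprintf("%.3f", svMaf),
              " < ", config$association$mafMin,
              "); it is removed by the frequency filter")
  }
  phenotype <- as.numeric(sim$cohort$phenotype == "gold")
  kin <- if (isTRUE(config$association$useKinship)) {
    computeKinship(filterVariants(sim$markers, config$association$mafMin,
                                  config$association$maxMissing))
  } else NULL
  scan <- gwasScan(gm, phenotype, kinship = kin,
                   mafMin = config$association$mafMin,
                   maxMissing = config$association$maxMissing)
  writeScanTSV(scan, file.path(outdir, "assoc.tsv"))

  .stageLog("concord", "genotype-phenotype concordance")
  cohortCalled <- sim$cohort
  cohortCalled$called_genotype <- calls$call[match(cohortCalled$id,
                                                   calls$sample_id)]
  tab <- concordanceTable(cohortCalled)
  writeConcordance(tab, file.path(outdir, "concordance.json"))

  svres <- NULL
  if (isTRUE(config$svstruct$run)) {
    .stageLog("svcall", "haplotype comparison and inverted-repeat scan")
    ic <- callInsertion(refHaplotype(locus), altHaplotype(locus),
                        anchorK = config$svstruct$anchorK,
                        minChainAnchors = config$svstruct$minChainAnchors)
    ir <- findInvertedRepeat(insertedSeq(ic),
                             minStem = config$svstruct$minStem,
                             bandWidth = config$svstruct$bandWidth)
    writeIrReport(ir, file.path(outdir, "inverted_repeat.json"))
    svres <- list(breakpoint = breakpoint(ic),
                  length = length(insertedSeq(ic)),
                  stem = ir@stemLength, loop = ir@loopLength,
                  arm_differences = nrow(armDifferences(ir)))
  }

  files <- list.files(outdir, full.names = TRUE)
  files <- setdiff(files, file.path(outdir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("goldscan")),
    seed = config$seed,
    stage_seeds = seeds,
    config = unclass(config),
    outputs = as.list(tools::md5sum(sort(files))),
    summary = list(
      n_individuals = nrow(sim$cohort),
      genotype_concordance = mean(calls$call == sim$cohort$true_genotype),
      top_variant = if (nrow(scan)) {
        scan$id[which.max(scan$minus_log10_p)]
      } else NA_character_,
      conflicts = conflictRates(tab),
      svstruct = svres
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
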
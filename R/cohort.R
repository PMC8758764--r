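#' Cohort simulation settings
#'
#' Parameters of the diploid cohort generator. Genotypes at the gold locus are
#' drawn under Hardy-Weinberg equilibrium at the G-allele frequency; the
#' phenotype follows a dominant model with incomplete penetrance: carriers are
#' gold unless sampled before their ontogenetic colour transition
#' ("untransformed"), with the untransformed probability dosage-dependent
#' (heterozygotes transform later, so `pUntransformedHom <=
#' pUntransformedHet` is required), and non-carriers are gold only as rare
#' phenocopies. Background markers are independent biallelic variants with
#' minor-allele frequencies drawn uniformly from `backgroundMafRange` and
#' per-marker missingness.
#'
#' @param nIndividuals cohort size.
#' @param gAlleleFreq frequency of the insertion (G) allele.
#' @param pUntransformedHet probability a Gd carrier is still phenotypically
#'   dark at sampling.
#' @param pUntransformedHom the same for GG carriers; must not exceed
#'   `pUntransformedHet`.
#' @param phenocopyRate probability a dd individual is phenotypically gold.
#' @param nBackgroundMarkers number of neutral background markers.
#' @param backgroundMafRange length-2 numeric, MAF interval for background
#'   markers.
#' @param missingRate probability any one marker genotype is missing.
#' @param population population label written to the cohort table.
#' @param seed integer seed.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nIndividuals = 300L,
                         gAlleleFreq = 0.1,
                         pUntransformedHet = 0.08,
                         pUntransformedHom = 0.01,
                         phenocopyRate = 0.01,
                         nBackgroundMarkers = 500L,
                         backgroundMafRange = c(0.05, 0.5),
                         missingRate = 0.02,
                         population = "simulated",
                         seed = 1L) {
  cfg <- list(
    nIndividuals = as.integer(nIndividuals),
    gAlleleFreq = gAlleleFreq,
    pUntransformedHet = pUntransformedHet,
    pUntransformedHom = pUntransformedHom,
    phenocopyRate = phenocopyRate,
    nBackgroundMarkers = as.integer(nBackgroundMarkers),
    backgroundMafRange = as.numeric(backgroundMafRange),
    missingRate = missingRate,
    population = as.character(population),
    seed = as.integer(seed)
  )
  probs <- c(cfg$gAlleleFreq, cfg$pUntransformedHet, cfg$pUntransformedHom,
             cfg$phenocopyRate, cfg$missingRate, cfg$backgroundMafRange)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$pUntransformedHom > cfg$pUntransformedHet) {
    stop("pUntransformedHom must be <= pUntransformedHet ",
         "(colour transition is dosage-dependent)")
  }
  if (cfg$nIndividuals < 1L || cfg$nBackgroundMarkers < 0L) {
    stop("nIndividuals must be >= 1 and nBackgroundMarkers >= 0")
  }
  if (diff(cfg$backgroundMafRange) < 0) {
    stop("backgroundMafRange must be an interval")
  }
  class(cfg) <- "CohortConfig"
  cfg
}

#' Simulate a diploid cohort with a dominant, incompletely penetrant phenotype
#'
#' Draws per-individual genotypes at the gold locus under Hardy-Weinberg
#' equilibrium, assigns the dark/gold phenotype under the dominance model
#' described in [cohortConfig()], and simulates an independent background
#' marker matrix used downstream for kinship estimation and scan calibration.
#'
#' @param config a [cohortConfig()] object.
#' @param locus optional [LocusModel-class]; when supplied, the SV coordinates
#'   recorded with the marker matrix use its breakpoint.
#' @return A list with elements `cohort` (data.frame: `id`, `population`,
#'   `true_genotype` in dd/Gd/GG, `phenotype` in dark/gold) and `markers`
#'   (a [GenotypeMatrix-class] of the background markers).
#' @examples
#' sim <- simulateCohort(cohortConfig(nIndividuals = 50, seed = 2))
#' table(sim$cohort$true_genotype, sim$cohort$phenotype)
#' @export
simulateCohort <- function(config, locus = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  withSeed(config$seed, {
    n <- config$nIndividuals
    g <- config$gAlleleFreq
    dosage <- rbinom(n, 2L, g)  # number of G alleles; HWE by construction
    geno <- c("dd", "Gd", "GG")[dosage + 1L]
    pGold <- ifelse(dosage == 2L, 1 - config$pUntransformedHom,
             ifelse(dosage == 1L, 1 - config$pUntransformedHet,
                    config$phenocopyRate))
    pheno <- ifelse(runif(n) < pGold, "gold", "dark")
    cohort <- data.frame(
      id = sprintf("ind%03d", seq_len(n)),
      population = config$population,
      true_genotype = geno,
      phenotype = pheno,
      stringsAsFactors = FALSE
    )
    p <- config$nBackgroundMarkers
    mat <- matrix(NA_real_, nrow = n, ncol = p,
                  dimnames = list(cohort$id, NULL))
    if (p > 0L) {
      maf <- runif(p, config$backgroundMafRange[1], config$backgroundMafRange[2])
      for (j in seq_len(p)) {
        mat[, j] <- rbinom(n, 2L, maf[j])
      }
      if (config$missingRate > 0) {
        miss <- matrix(runif(n * p) < config$missingRate, n, p)
        mat[miss] <- NA_real_
      }
      colnames(mat) <- sprintf("bg%04d", seq_len(p))
    }
    variants <- data.frame(
      id = if (p > 0L) colnames(mat) else character(0),
      chrom = rep("1", p),
      pos = if (p > 0L) seq_len(p) * 1000L else integer(0),
      stringsAsFactors = FALSE
    )
    markers <- new("GenotypeMatrix", dosage = mat, variants = variants)
    list(cohort = cohort, markers = markers)
  })
}

#' Read and write the cohort truth table
#'
#' Tab-separated with columns `id`, `population`, `true_genotype`,
#' `phenotype`; round-trips losslessly.
#' @param cohort cohort data.frame as produced by [simulateCohort()].
#' @param path TSV path.
#' @return `writeCohortTable` returns `path` invisibly; `readCohortTable`
#'   returns the data.frame.
#' @export
writeCohortTable <- function(cohort, path) {
  stopifnot(all(c("id", "population", "true_genotype", "phenotype")
                %in% names(cohort)))
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
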
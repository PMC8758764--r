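#' Classify reads at a known insertion breakpoint
#'
#' Implements split-read evidence classification at a 1-based breakpoint
#' coordinate. Reads flagged unmapped or duplicate are excluded. A read is
#' *split* (supports the insertion allele) when a clip boundary — the
#' reference base immediately left of a soft- or hard-clip junction — falls
#' within `clipWindow` bases of the breakpoint. A read is *reference* when its
#' aligned (reference-consuming) span covers at least `minOverlap` bases on
#' each side of the breakpoint and carries no qualifying clip. All other reads
#' (too little overlap, or malformed alignment strings) are excluded;
#' malformed records additionally raise a warning.
#'
#' @param records alignment data.frame (`name`, `flag`, `pos`, `cigar`).
#' @param breakpoint 1-based reference coordinate of the last base before the
#'   insertion.
#' @param clipWindow window (bases) around the breakpoint in which a clip
#'   boundary counts as insertion evidence; accounts for random matches at
#'   the junction.
#' @param minOverlap minimum aligned bases required on each side of the
#'   breakpoint for a reference-supporting read.
#' @return factor of length `nrow(records)` with levels split, reference,
#'   excluded.
#' @examples
#' reads <- data.frame(name = c("a", "b"), flag = c(0L, 0L),
#'                     pos = c(950L, 951L),
#'                     cigar = c("100M", "50M50S"))
#' classifyReads(reads, breakpoint = 1000)
#' @export
classifyReads <- function(records, breakpoint, clipWindow = 5L,
                          minOverlap = 5L) {
  breakpoint <- as.integer(breakpoint)
  n <- nrow(records)
  out <- factor(rep("excluded", n), levels = c("split", "reference", "excluded"))
  if (n == 0L) return(out)
  excludedFlag <- bitwAnd(records$flag, FLAG_UNMAPPED) != 0L |
    bitwAnd(records$flag, FLAG_DUPLICATE) != 0L
  cg <- parseCigar(records$cigar)
  malformed <- !cg$valid & !excludedFlag
  if (any(malformed)) {
    warning(sum(malformed), " read(s) with unparseable CIGAR excluded: ",
            paste(utils::head(records$name[malformed], 3L), collapse = ", "))
  }
  usable <- !excludedFlag & cg$valid
  pos <- records$pos
  alnStart <- pos
  alnEnd <- pos + cg$ref_span - 1L
  ## clip boundaries: base left of the junction
  leadBoundary <- ifelse(cg$lead_clip > 0L, pos - 1L, NA_integer_)
  trailBoundary <- ifelse(cg$trail_clip > 0L, alnEnd, NA_integer_)
  nearBp <- function(b) !is.na(b) & abs(b - breakpoint) <= clipWindow
  isSplit <- usable & (nearBp(leadBoundary) | nearBp(trailBoundary))
  ## reference support: >= minOverlap aligned bases each side
  covers <- usable & !isSplit &
    alnStart <= breakpoint - minOverlap + 1L &
    alnEnd >= breakpoint + minOverlap
  out[isSplit] <- "split"
  out[covers] <- "reference"
  out
}

#' Call the structural-variant genotype from split-read evidence
#'
#' Decision rule: an individual is homozygous reference (dd) when the
#' split-read ratio is below `minRatio` or the absolute split-read count is at
#' most `absCount`; homozygous insertion (GG) when the ratio is above
#' `maxRatio` or the number of reference-supporting reads
#' (total minus split) is at most `absCount`; otherwise heterozygous (Gd).
#' When both homozygote conditions fire simultaneously (possible only at very
#' low coverage) or no classifiable read exists, the genotype is a no-call
#' rather than a guess.
#'
#' @param nSplit,nTotal per-sample counts of insertion-supporting and total
#'   classifiable reads (vectors recycle).
#' @param minRatio,maxRatio ratio thresholds for the dd and GG calls.
#' @param absCount absolute-count override for either homozygote.
#' @return character vector of calls in \{"dd", "Gd", "GG", "no-call"\}.
#' @examples
#' callGenotype(nSplit = c(0, 20, 2, 28), nTotal = c(100, 40, 30, 30))
#' @export
callGenotype <- function(nSplit, nTotal, minRatio = 0.1, maxRatio = 0.9,
                         absCount = 2L) {
  if (any(nSplit < 0) || any(nTotal < 0)) stop("counts must be non-negative")
  if (any(nSplit > nTotal)) stop("nSplit cannot exceed nTotal")
  k <- max(length(nSplit), length(nTotal))
  nSplit <- rep_len(nSplit, k)
  nTotal <- rep_len(nTotal, k)
  ratio <- ifelse(nTotal > 0, nSplit / nTotal, NA_real_)
  ddCond <- nTotal > 0 & (ratio < minRatio | nSplit <= absCount)
  ggCond <- nTotal > 0 & (ratio > maxRatio | (nTotal - nSplit) <= absCount)
  out <- rep("Gd", k)
  out[ddCond & !ggCond] <- "dd"
  out[ggCond & !ddCond] <- "GG"
  out[(ddCond & ggCond) | nTotal == 0] <- "no-call"
  out
}

#' Genotype a cohort at a known breakpoint from per-sample alignments
#'
#' Runs [classifyReads()] and [callGenotype()] for every sample. Alignments
#' may be given as in-memory record data.frames or as SAM/BAM file paths.
#' Reads positioned far from the breakpoint cannot be classifiable and are
#' pre-filtered on position for speed; classification is therefore independent
#' of read order and of distant reads.
#'
#' @param alignments named list: per-sample alignment data.frames (see
#'   [simulateReads()]) or file paths.
#' @param breakpoint 1-based reference coordinate.
#' @param clipWindow,minOverlap,minRatio,maxRatio,absCount see
#'   [classifyReads()] and [callGenotype()].
#' @return data.frame with one row per sample: `sample_id`, `n_total`,
#'   `n_split`, `ratio`, `call`.
#' @export
genotypeCohort <- function(alignments, breakpoint, clipWindow = 5L,
                           minOverlap = 5L, minRatio = 0.1, maxRatio = 0.9,
                           absCount = 2L) {
  stopifnot(length(alignments) > 0)
  ids <- names(alignments)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_along(alignments))
  ev <- lapply(seq_along(alignments), function(i) {
    rec <- alignments[[i]]
    if (is.character(rec)) rec <- readAlignments(rec)
    if (nrow(rec) == 0L) {
      message("sample ", ids[i], ": no reads at locus, emitting no-call")
      return(c(total = 0L, split = 0L))
    }
    ## coarse positional pre-filter: anything with an alignment start further
    ## than 2 read lengths from the breakpoint can touch it with neither a
    ## qualifying clip nor minOverlap coverage
    rl <- suppressWarnings(max(nchar(rec$seq), 2L * clipWindow, na.rm = TRUE))
    keep <- bitwAnd(rec$flag, FLAG_UNMAPPED) != 0L |
      (rec$pos >= breakpoint - 2L * rl - clipWindow &
       rec$pos <= breakpoint + clipWindow + 1L)
    rec <- rec[keep, , drop = FALSE]
    cls <- classifyReads(rec, breakpoint, clipWindow, minOverlap)
    c(total = sum(cls != "excluded"), split = sum(cls == "split"))
  })
  nTotal <- vapply(ev, `[[`, integer(1), "total")
  nSplit <- vapply(ev, `[[`, integer(1), "split")
  data.frame(
    sample_id = ids,
    n_total = nTotal,
    n_split = nSplit,
    ratio = ifelse(nTotal > 0, nSplit / nTotal, NA_real_),
    call = callGenotype(nSplit, nTotal, minRatio, maxRatio, absCount),
    stringsAsFactors = FALSE
  )
}

#' Write cohort SV genotypes as a single-record VCF
#'
#' Emits a VCF 4.2 record with a symbolic `<INS>` alternate allele, per-sample
#' `GT` (no-calls as `./.`) and split/total evidence counts as FORMAT fields.
#' @param calls data.frame from [genotypeCohort()].
#' @param path output path.
#' @param chrom,pos variant coordinate (1-based).
#' @param refBase reference base at `pos`.
#' @param svlen insertion length for the INFO field (optional).
#' @return `path`, invisibly.
#' @export
writeSvVCF <- function(calls, path, chrom = "11", pos = 7069471L,
                       refBase = "N", svlen = NA_integer_) {
  gtMap <- c(dd = "0/0", Gd = "0/1", GG = "1/1", `no-call` = "./.")
  info <- sprintf("SVTYPE=INS;END=%d", as.integer(pos))
  if (!is.na(svlen)) info <- paste0(info, sprintf(";SVLEN=%d", as.integer(svlen)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=goldscan",
    sprintf("##contig=<ID=%s>", chrom),
    "##ALT=<ID=INS,Description=\"Insertion relative to the reference\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Insertion length\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=SP,Number=1,Type=Integer,Description=\"Split (insertion-supporting) reads\">",
    "##FORMAT=<ID=TO,Number=1,Type=Integer,Description=\"Total classifiable reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$sample_id), collapse = "\t")
  )
  samples <- sprintf("%s:%d:%d", gtMap[calls$call], calls$n_split,
                     calls$n_total)
  rec <- paste(c(chrom, pos, "gold_SV", refBase, "<INS>", ".", "PASS", info,
                 "GT:SP:TO", samples), collapse = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Convert SV genotype calls to a one-variant GenotypeMatrix
#'
#' Appends naturally to a marker matrix with [bindVariants()], mirroring the
#' strategy of genotyping the structural variant and adding it to an existing
#' call set before association mapping.
#' @param calls data.frame from [genotypeCohort()].
#' @param chrom,pos coordinate of the SV record.
#' @param id variant id.
#' @return a [GenotypeMatrix-class] with a single column; no-calls become NA.
#' @export
svCallsToMatrix <- function(calls, chrom = "11", pos = 7069471L,
                            id = "gold_SV") {
  dosage <- c(dd = 0, Gd = 1, GG = 2, `no-call` = NA_real_)[calls$call]
  m <- matrix(dosage, ncol = 1L,
              dimnames = list(calls$sample_id, id))
  new("GenotypeMatrix", dosage = m,
      variants = data.frame(id = id, chrom = chrom, pos = as.integer(pos),
                            stringsAsFactors = FALSE))
}
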
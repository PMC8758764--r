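#' LocusModel: a two-haplotype locus carrying an inverted-repeat insertion
#'
#' Describes a reference ("d") haplotype and an alternate ("G") haplotype in
#' which a transposon-derived inverted repeat (arm + loop + reverse-complement
#' arm, the second arm carrying a small number of single-base deletions) is
#' inserted at a known breakpoint. The alternate haplotype is never stored; it
#' is reconstructed deterministically from the slots via [altHaplotype()].
#'
#' @slot refSeq [Biostrings::DNAString] the reference (d) haplotype.
#' @slot armSeq [Biostrings::DNAString] one arm of the inverted repeat.
#' @slot loopSeq [Biostrings::DNAString] the spacer between the two arms.
#' @slot editPositions integer positions (1-based, arm coordinates) deleted
#'   from the second arm before reverse-complementing, so the two arms differ
#'   by exactly `length(editPositions)` single-base indels.
#' @slot breakpoint 1-based position on `refSeq`: the last reference base
#'   before the insertion (left-aligned convention).
#' @export
setClass("LocusModel",
  representation(
    refSeq = "DNAString",
    armSeq = "DNAString",
    loopSeq = "DNAString",
    editPositions = "integer",
    breakpoint = "integer"
  )
)

setValidity("LocusModel", function(object) {
  msgs <- character(0)
  n <- length(object@refSeq)
  bp <- object@breakpoint
  if (length(bp) != 1L || is.na(bp) || bp <= 1L || bp >= n) {
    msgs <- c(msgs, sprintf(
      "breakpoint must lie strictly inside the reference sequence (got %s for length %d)",
      paste(bp, collapse = ","), n))
  }
  if (anyDuplicated(object@editPositions)) {
    msgs <- c(msgs, "editPositions must be distinct")
  }
  if (length(object@editPositions) &&
      (any(object@editPositions < 1L) ||
       any(object@editPositions > length(object@armSeq)))) {
    msgs <- c(msgs, "editPositions must fall inside the arm")
  }
  if (length(msgs)) msgs else TRUE
})

#' GenotypeMatrix: sample-by-variant dosage matrix with variant coordinates
#'
#' @slot dosage numeric matrix, samples in rows, variants in columns; entries
#'   in \{0, 1, 2\} (alternate-allele dosage) or NA for missing calls.
#' @slot variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   one row per column of `dosage`.
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", variants = "data.frame")
)

setValidity("GenotypeMatrix", function(object) {
  msgs <- character(0)
  if (ncol(object@dosage) != nrow(object@variants)) {
    msgs <- c(msgs, "one variants row is required per dosage column")
  }
  if (!all(c("id", "chrom", "pos") %in% names(object@variants))) {
    msgs <- c(msgs, "variants needs columns id, chrom, pos")
  }
  d <- object@dosage
  if (length(d) && any(!is.na(d) & !(d %in% c(0, 1, 2)))) {
    msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' InsertionCall: an insertion discovered by haplotype comparison
#'
#' @slot breakpoint 1-based position on the reference haplotype of the base
#'   immediately left of the insertion (left-aligned).
#' @slot insertedSeq [Biostrings::DNAString] the inserted sequence.
#' @slot events data.frame of all gap events found between chained anchors
#'   (columns `breakpoint`, `ref_gap`, `alt_gap`, `length`), flagged when more
#'   than one distinct gap is present.
#' @slot flags character vector of quality flags (e.g. "multiple-gaps").
#' @export
setClass("InsertionCall",
  representation(
    breakpoint = "integer",
    insertedSeq = "DNAString",
    events = "data.frame",
    flags = "character"
  )
)

#' InvertedRepeatReport: stem/loop geometry of an inverted repeat
#'
#' @slot arm1 [IRanges::IRanges] interval of the first arm (1-based, on the
#'   analysed sequence).
#' @slot arm2 [IRanges::IRanges] interval of the second arm.
#' @slot stemLength integer, aligned arm (stem) length in bases.
#' @slot loopLength integer, separation between the arms in bases.
#' @slot armDifferences data.frame of differences between arm1 and the
#'   reverse complement of arm2 (columns `position` on arm1 coordinates,
#'   `type` in \{"substitution", "single-base indel", "indel"\}, `length`).
#' @slot flags character vector (e.g. "degenerate-overlap-trimmed").
#' @export
setClass("InvertedRepeatReport",
  representation(
    arm1 = "IRanges",
    arm2 = "IRanges",
    stemLength = "integer",
    loopLength = "integer",
    armDifferences = "data.frame",
    flags = "character"
  )
)

setValidity("InvertedRepeatReport", function(object) {
  msgs <- character(0)
  if (length(object@arm1) != 1L || length(object@arm2) != 1L) {
    msgs <- c(msgs, "arm1 and arm2 must each be a single interval")
  } else {
    if (IRanges::start(object@arm2) <= IRanges::end(object@arm1)) {
      msgs <- c(msgs, "arm1 must precede arm2 without overlap")
    }
  }
  if (object@loopLength < 0L) msgs <- c(msgs, "loopLength must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' ConcordanceTable: genotype-by-phenotype counts
#'
#' @slot counts integer matrix with rows dd, Gd, GG and columns dark, gold.
#' @slot noCall integer, individuals excluded for missing genotype.
#' @export
setClass("ConcordanceTable",
  representation(counts = "matrix", noCall = "integer")
)

setValidity("ConcordanceTable", function(object) {
  msgs <- character(0)
  if (!identical(rownames(object@counts), c("dd", "Gd", "GG")) ||
      !identical(colnames(object@counts), c("dark", "gold"))) {
    msgs <- c(msgs, "counts must be a dd/Gd/GG x dark/gold matrix")
  }
  if (any(object@counts < 0) || object@noCall < 0L) {
    msgs <- c(msgs, "counts must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})
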
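#' Build a two-haplotype locus model carrying an inverted-repeat insertion
#'
#' Constructs a random reference ("d") haplotype and the parameters of an
#' alternate ("G") haplotype that carries, at a chosen breakpoint, an
#' insertion of the form `arm + loop + reverse-complement(arm')`, where `arm'`
#' is the arm with `armEditCount` single-base deletions. This mirrors the
#' structure of a transposon-derived inverted repeat whose two copies differ
#' only by a small number of single-base indels. With the default acceptance
#' geometry (arm 4100 bp, loop 50 bp, 2 edits) the insertion is
#' 2*4100 + 50 - 2 = 8248 bp, i.e. an 8.2 kb element with a 4.1 kb stem.
#'
#' @param refLength length of the reference haplotype in bases.
#' @param armLength length of one inverted-repeat arm in bases (>= 0).
#' @param loopLength length of the spacer between the arms in bases (>= 0).
#' @param armEditCount number of single-base deletions distinguishing the
#'   second arm from the first.
#' @param breakpoint 1-based position on the reference haplotype of the last
#'   base before the insertion; must be strictly inside the sequence.
#' @param seed integer seed; the model is fully reproducible.
#' @return A [LocusModel-class] object.
#' @examples
#' locus <- buildLocus(1000, 100, 10, 0, 500, seed = 7)
#' length(altHaplotype(locus)) - length(refHaplotype(locus))  # 210
#' @export
buildLocus <- function(refLength, armLength, loopLength, armEditCount,
                       breakpoint, seed) {
  stopifnot(refLength >= 2, armLength >= 0, loopLength >= 0,
            armEditCount >= 0)
  breakpoint <- as.integer(breakpoint)
  if (breakpoint <= 1L || breakpoint >= refLength) {
    stop("breakpoint must lie strictly inside the reference sequence (1 < ",
         breakpoint, " < ", refLength, " fails)")
  }
  if (armEditCount > armLength) {
    stop("cannot place ", armEditCount, " edits in an arm of length ",
         armLength)
  }
  withSeed(seed, {
    ref <- randomSequence(refLength)
    arm <- randomSequence(armLength)
    loop <- randomSequence(loopLength)
    ## keep the stem maximal at exactly armLength: if the loop's terminal
    ## bases could base-pair, the self-complementary run would genuinely
    ## extend into the loop and the nominal arm/loop geometry would be off
    if (armLength > 0 && loopLength >= 2) {
      first <- substr(loop, 1L, 1L)
      lastComp <- revcompChar(substr(loop, loopLength, loopLength))
      if (first == lastComp) {
        substr(loop, 1L, 1L) <- sample(setdiff(c("A", "C", "G", "T"),
                                               lastComp), 1L)
      }
    }
    ## edits are sampled away from the arm termini: an indel at the very end
    ## of the stem is indistinguishable from a shorter stem with an unpaired
    ## flap, which would make the nominal arm/loop geometry ill-defined
    ## and kept well separated from each other: adjacent single-base
    ## deletions would coalesce into one multi-base indel
    margin <- min(15L, (armLength - armEditCount) %/% 2L)
    minSep <- min(16L, max(2L, (armLength - 2L * margin) %/%
                                 max(1L, armEditCount)))
    edits <- integer(0)
    if (armEditCount > 0) {
      pool <- seq.int(margin + 1L, armLength - margin)
      repeat {
        edits <- sort(sample(pool, armEditCount))
        if (armEditCount == 1L || min(diff(edits)) >= minSep) break
      }
    }
    new("LocusModel",
        refSeq = Biostrings::DNAString(ref),
        armSeq = Biostrings::DNAString(arm),
        loopSeq = Biostrings::DNAString(loop),
        editPositions = as.integer(edits),
        breakpoint = breakpoint)
  })
}

#' @rdname LocusModel-class
#' @export
setMethod("refHaplotype", "LocusModel", function(x) x@refSeq)

#' @rdname LocusModel-class
#' @export
setMethod("insertionSeq", "LocusModel", function(x) {
  arm1 <- x@armSeq
  if (length(arm1) == 0L) {
    return(Biostrings::DNAString(as.character(x@loopSeq)))
  }
  keep <- setdiff(seq_len(length(arm1)), x@editPositions)
  arm2src <- arm1[keep]
  Biostrings::xscat(arm1, x@loopSeq, Biostrings::reverseComplement(arm2src))
})

#' @rdname LocusModel-class
#' @export
setMethod("altHaplotype", "LocusModel", function(x) {
  ref <- x@refSeq
  bp <- x@breakpoint
  ins <- insertionSeq(x)
  if (length(ins) == 0L) return(ref)
  Biostrings::xscat(
    Biostrings::subseq(ref, 1L, bp),
    ins,
    Biostrings::subseq(ref, bp + 1L, length(ref))
  )
})

#' @rdname breakpoint
#' @export
setMethod("breakpoint", "LocusModel", function(x) x@breakpoint)

#' Insertion length of a locus model
#' @param x a `LocusModel`
#' @return integer length in bases of the inserted segment of the G haplotype.
#' @export
insertionLength <- function(x) {
  stopifnot(is(x, "LocusModel"))
  2L * length(x@armSeq) + length(x@loopSeq) - length(x@editPositions)
}

#' Left-aligned breakpoint of a locus model
#'
#' An insertion whose last base equals the reference base at the breakpoint
#' admits more than one placement; the conventional single-coordinate report
#' is the left-most (left-aligned) one. This helper normalizes the
#' construction breakpoint of a [LocusModel-class] to that convention, so it
#' can be compared directly with the breakpoint reported by
#' [callInsertion()], which is left-aligned by design.
#'
#' @param locus a [LocusModel-class]
#' @return integer: the left-aligned 1-based breakpoint.
#' @export
leftAlignedBreakpoint <- function(locus) {
  stopifnot(is(locus, "LocusModel"))
  ref <- as.character(refHaplotype(locus))
  ins <- as.character(insertionSeq(locus))
  bp <- breakpoint(locus)
  len <- nchar(ins)
  if (len == 0L) return(bp)
  while (bp > 1L && substr(ins, len, len) == substr(ref, bp, bp)) {
    ins <- paste0(substr(ref, bp, bp), substr(ins, 1L, len - 1L))
    bp <- bp - 1L
  }
  bp
}

setMethod("show", "LocusModel", function(object) {
  cat("LocusModel\n")
  cat("  reference haplotype: ", length(object@refSeq), " bp\n", sep = "")
  cat("  breakpoint:          ", object@breakpoint, "\n", sep = "")
  cat("  insertion:           ", insertionLength(object),
      " bp (arm ", length(object@armSeq), " bp, loop ",
      length(object@loopSeq), " bp, ", length(object@editPositions),
      " arm edit(s))\n", sep = "")
})

#' Write the two haplotypes of a locus to FASTA
#'
#' @param locus a [LocusModel-class]
#' @param path output FASTA path.
#' @param names sequence names for the d and G haplotypes.
#' @return `path`, invisibly.
#' @export
writeHaplotypeFasta <- function(locus, path, names = c("hap_d", "hap_G")) {
  seqs <- Biostrings::DNAStringSet(list(refHaplotype(locus),
                                        altHaplotype(locus)))
  names(seqs) <- names
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read FASTA with normalization
#'
#' Reads sequences with [Biostrings::readDNAStringSet()] and uppercases them;
#' N bases are preserved.
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet]
#' @export
readFastaNormalized <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  Biostrings::DNAStringSet(toupper(x))
}
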
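## Haplotype comparison and inverted-repeat characterization.
##
## Insertion discovery uses unique-anchor (MUM-like) chaining rather than full
## dynamic-programming alignment: k-mers unique in both haplotypes are
## chained colinearly by longest-increasing-subsequence, and a gap present in
## the alternate but not the reference haplotype is reported as an insertion.

.asCharSeq <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  toupper(x)
}

#' Discover an insertion by comparing two haplotype sequences
#'
#' Anchors are k-mers that occur exactly once in each haplotype; they are
#' chained colinearly (longest increasing subsequence over alternate-sequence
#' positions, scanned in reference order). A between-anchor gap larger in the
#' alternate than in the reference is an insertion; its breakpoint is reported
#' as the reference base immediately left of the gap (left-aligned, matching
#' the single-coordinate convention for insertion positions). Multiple
#' distinct gaps are all recorded and flagged.
#'
#' @param refHap,altHap reference (d) and alternate (G) haplotype sequences
#'   (character or [Biostrings::DNAString]).
#' @param anchorK anchor k-mer size.
#' @param minChainAnchors minimum number of chained anchors required to trust
#'   the colinear chain.
#' @return an [InsertionCall-class], or NULL when the haplotypes carry no
#'   insertion; unrelated sequences (no chain) produce an explicit no-call
#'   error.
#' @examples
#' locus <- buildLocus(4000, 300, 30, 1, 2000, seed = 5)
#' callInsertion(refHaplotype(locus), altHaplotype(locus))
#' @export
callInsertion <- function(refHap, altHap, anchorK = 21L,
                          minChainAnchors = 10L) {
  ref <- .asCharSeq(refHap)
  alt <- .asCharSeq(altHap)
  stopifnot(nchar(ref) > 0, nchar(alt) > 0)
  ktRef <- kmerTable(ref, anchorK)
  ktAlt <- kmerTable(alt, anchorK)
  uRef <- ktRef[!(duplicated(ktRef$kmer) |
                  duplicated(ktRef$kmer, fromLast = TRUE)), ]
  uAlt <- ktAlt[!(duplicated(ktAlt$kmer) |
                  duplicated(ktAlt$kmer, fromLast = TRUE)), ]
  m <- match(uRef$kmer, uAlt$kmer)
  hit <- !is.na(m)
  anchors <- data.frame(ref = uRef$pos[hit], alt = uAlt$pos[m[hit]])
  anchors <- anchors[order(anchors$ref), , drop = FALSE]
  if (nrow(anchors) < minChainAnchors) {
    stop("no usable anchor chain between the haplotypes (",
         nrow(anchors), " shared unique ", anchorK, "-mers); no-call")
  }
  chainIdx <- longestIncreasingSubsequence(anchors$alt)
  chain <- anchors[chainIdx, , drop = FALSE]
  if (nrow(chain) < minChainAnchors) {
    stop("colinear chain too short (", nrow(chain), " anchors); no-call")
  }
  refGap <- chain$ref[-1] - (chain$ref[-nrow(chain)] + anchorK)
  altGap <- chain$alt[-1] - (chain$alt[-nrow(chain)] + anchorK)
  ins <- which(altGap - refGap > 0L)
  if (length(ins) == 0L) return(NULL)
  events <- data.frame(
    breakpoint = chain$ref[ins] + anchorK - 1L + refGap[ins],
    ref_gap = refGap[ins],
    alt_gap = altGap[ins],
    length = altGap[ins] - refGap[ins]
  )
  flags <- character(0)
  if (nrow(events) > 1L) flags <- "multiple-gaps"
  if (any(events$ref_gap > 0L)) flags <- c(flags, "gap-with-divergence")
  ## primary event: the longest gap; for a clean insertion (ref_gap 0) the
  ## inserted bases are exactly the alternate gap
  primary <- which.max(events$length)
  k <- ins[primary]
  insSeq <- substr(alt, chain$alt[k] + anchorK + refGap[k],
                   chain$alt[k + 1L] - 1L)
  new("InsertionCall",
      breakpoint = as.integer(events$breakpoint[primary]),
      insertedSeq = Biostrings::DNAString(insSeq),
      events = events,
      flags = flags)
}

#' @rdname breakpoint
#' @export
setMethod("breakpoint", "InsertionCall", function(x) x@breakpoint)

#' @rdname insertedSeq
#' @export
setMethod("insertedSeq", "InsertionCall", function(x) x@insertedSeq)

setMethod("show", "InsertionCall", function(object) {
  cat("InsertionCall: ", length(object@insertedSeq),
      " bp inserted after reference position ", object@breakpoint, "\n",
      sep = "")
  if (nrow(object@events) > 1L) {
    cat("  (", nrow(object@events), " gap events; flags: ",
        paste(object@flags, collapse = ", "), ")\n", sep = "")
  }
})

#' Find the longest inverted repeat in a sequence
#'
#' Seeds k-mer matches between the sequence and its reverse complement; a
#' matched pair corresponds to two loci whose sequences are reverse
#' complements of each other, and all seed pairs of one inverted repeat share
#' (up to indels) a common anti-diagonal. The densest anti-diagonal cluster
#' (within a `bandWidth` tolerance, which absorbs indel shifts between the
#' arms) spanning at least `minStem` bases defines the two arms. The first
#' arm is then globally aligned against the reverse complement of the second
#' with unit edit costs and the differences (substitutions / indels)
#' enumerated.
#'
#' @param sequence character or [Biostrings::DNAString]; N bases never seed
#'   matches.
#' @param minStem minimum arm length in bases to report.
#' @param bandWidth tolerance (bases) for anti-diagonal clustering and arm
#'   alignment offsets.
#' @param seedK seed k-mer size.
#' @return an [InvertedRepeatReport-class], or NULL when no inverted repeat of
#'   the requested size exists.
#' @examples
#' arm <- paste(sample(c("A","C","G","T"), 200, TRUE), collapse = "")
#' seqc <- paste0(arm, "ACGTACGTAC",
#'                as.character(Biostrings::reverseComplement(
#'                  Biostrings::DNAString(arm))))
#' findInvertedRepeat(seqc, minStem = 100)
#' @export
findInvertedRepeat <- function(sequence, minStem = 100L, bandWidth = 16L,
                               seedK = 15L) {
  s <- .asCharSeq(sequence)
  L <- nchar(s)
  if (L < 2L * minStem) return(NULL)
  rc <- revcompChar(s)
  ktS <- kmerTable(s, seedK)
  ktR <- kmerTable(rc, seedK)
  ## positions in rc map back to s: word at rc[j..j+k-1] is the reverse
  ## complement of s[y..y+k-1] with y = L - j - seedK + 2
  byKmer <- split(ktR$pos, ktR$kmer)
  present <- ktS$kmer %in% names(byKmer)
  if (!any(present)) return(NULL)
  reps <- lengths(byKmer[ktS$kmer[present]])
  i <- rep(ktS$pos[present], reps)
  j <- unlist(byKmer[ktS$kmer[present]], use.names = FALSE)
  y <- L - j - seedK + 2L
  keep <- i < y   # one triangle; the pairing is symmetric
  i <- i[keep]
  y <- y[keep]
  if (length(i) == 0L) return(NULL)
  diag <- i + y
  ## cluster anti-diagonals within bandWidth
  ord <- order(diag, i)
  i <- i[ord]; y <- y[ord]; diag <- diag[ord]
  grp <- cumsum(c(TRUE, diff(diag) > bandWidth))
  span <- tapply(i, grp, function(v) max(v) - min(v)) + seedK
  cand <- order(span, decreasing = TRUE)
  best <- NULL
  for (g in as.integer(names(span))[cand]) {
    if (span[as.character(g)] < minStem) break
    sel <- grp == g
    iSel <- i[sel]
    ySel <- y[sel]
    ## frontiers are taken from actual seed pairs (not cluster-wide extremes)
    ## so each boundary starts from an exactly base-paired state before
    ## extension; within a seed, s[i + k - 1] pairs with s[y]
    outSeed <- which.min(iSel)
    innSeed <- which.max(iSel)
    a1 <- c(iSel[outSeed], iSel[innSeed] + seedK - 1L)
    a2 <- c(ySel[innSeed], ySel[outSeed] + seedK - 1L)
    best <- list(arm1 = a1, arm2 = a2)
    break
  }
  if (is.null(best)) return(NULL)
  ext <- .extendArms(s, best$arm1, best$arm2, maxEvents = bandWidth)
  best$arm1 <- ext$arm1
  best$arm2 <- ext$arm2
  flags <- character(0)
  if (best$arm2[1] <= best$arm1[2]) {
    ## degenerate: arms overlap (palindrome without loop or noisy seeds);
    ## trim to the midpoint and flag
    mid <- (best$arm1[2] + best$arm2[1]) %/% 2L
    best$arm1[2] <- mid
    best$arm2[1] <- mid + 1L
    flags <- "degenerate-overlap-trimmed"
  }
  arm1Seq <- substr(s, best$arm1[1], best$arm1[2])
  arm2Seq <- substr(s, best$arm2[1], best$arm2[2])
  cmp <- .compareArms(arm1Seq, arm2Seq)
  new("InvertedRepeatReport",
      arm1 = IRanges::IRanges(best$arm1[1], best$arm1[2]),
      arm2 = IRanges::IRanges(best$arm2[1], best$arm2[2]),
      stemLength = nchar(arm1Seq),
      loopLength = best$arm2[1] - best$arm1[2] - 1L,
      armDifferences = cmp,
      flags = flags)
}

## Refine seed-derived arm intervals by contiguous base-pair extension.
## Seed matching alone under-reaches when an arm difference lies within one
## seed length of an arm end: the flanking seeds are destroyed and the
## boundary (and the difference itself) fall outside the seed extent. Both
## arm ends are therefore extended while bases continue to complement-pair;
## at a stall, a single-base skip on either arm (indel) or a joint advance
## (substitution) is accepted only when the next `lookahead` bases pair
## contiguously, so chance extension beyond the true stem needs ~4^-lookahead
## luck. Events are capped at `maxEvents` per end.
.extendArms <- function(s, a1, a2, lookahead = 12L, maxEvents = 16L) {
  L <- nchar(s)
  base <- function(i) substr(s, i, i)
  pairs <- function(i, j) {
    i >= 1L && j <= L && j >= 1L && i <= L &&
      base(i) == revcompChar(base(j)) && base(i) != "N"
  }
  runPairs <- function(i, j, step) {
    ## longest contiguous pairing run walking i by -step and j by +step
    n <- 0L
    while (n < lookahead && pairs(i, j)) {
      i <- i - step
      j <- j + step
      n <- n + 1L
    }
    n
  }
  accept <- function(i, j, avail, step = 1L) {
    need <- min(lookahead, max(avail, 0L))
    need >= 1L && runPairs(i, j, step) >= need
  }
  ## outer ends: arm1 start vs arm2 end
  events <- 0L
  repeat {
    if (pairs(a1[1] - 1L, a2[2] + 1L)) {
      a1[1] <- a1[1] - 1L
      a2[2] <- a2[2] + 1L
      next
    }
    if (events >= maxEvents || a1[1] <= 1L || a2[2] >= L) break
    avail <- min(a1[1] - 2L, L - a2[2] - 1L, lookahead)
    if (accept(a1[1] - 2L, a2[2] + 1L, min(a1[1] - 2L, L - a2[2]))) {
      a1[1] <- a1[1] - 1L            # unpaired extra base on arm1 (arm2 indel)
    } else if (accept(a1[1] - 1L, a2[2] + 2L, min(a1[1] - 1L, L - a2[2] - 1L))) {
      a2[2] <- a2[2] + 1L            # unpaired extra base on arm2
    } else if (accept(a1[1] - 2L, a2[2] + 2L, avail)) {
      a1[1] <- a1[1] - 1L            # substitution: advance both
      a2[2] <- a2[2] + 1L
    } else break
    events <- events + 1L
  }
  ## inner ends: arm1 end vs arm2 start, stopping before the arms touch
  events <- 0L
  repeat {
    if (a2[1] - a1[2] <= 2L) break
    if (pairs(a1[2] + 1L, a2[1] - 1L)) {
      a1[2] <- a1[2] + 1L
      a2[1] <- a2[1] - 1L
      next
    }
    if (events >= maxEvents) break
    gap <- a2[1] - a1[2] - 2L
    if (accept(a1[2] + 2L, a2[1] - 1L, gap %/% 2L, step = -1L)) {
      a1[2] <- a1[2] + 1L
    } else if (accept(a1[2] + 1L, a2[1] - 2L, gap %/% 2L, step = -1L)) {
      a2[1] <- a2[1] - 1L
    } else if (accept(a1[2] + 2L, a2[1] - 2L, gap %/% 2L, step = -1L)) {
      a1[2] <- a1[2] + 1L
      a2[1] <- a2[1] - 1L
    } else break
    events <- events + 1L
  }
  list(arm1 = a1, arm2 = a2)
}

## align arm1 against revcomp(arm2) with unit edit costs and enumerate
## differences in arm1 coordinates
.compareArms <- function(arm1Seq, arm2Seq) {
  p <- Biostrings::DNAString(arm1Seq)
  sq <- Biostrings::reverseComplement(Biostrings::DNAString(arm2Seq))
  nuc <- c("A", "C", "G", "T", "N")
  mat <- matrix(-1, 5, 5, dimnames = list(nuc, nuc))
  diag(mat) <- 0
  mat["N", "N"] <- -1  # N counts as a mismatch, never a match
  aln <- Biostrings::pairwiseAlignment(p, sq, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  diffs <- list()
  mm <- Biostrings::mismatchTable(aln)
  if (nrow(mm)) {
    diffs[[length(diffs) + 1L]] <- data.frame(
      position = mm$PatternStart, type = "substitution", length = 1L)
  }
  ## deletions from the pattern's view = gaps in pattern (bases present in
  ## subject only); insertions = gaps in subject
  insP <- Biostrings::indel(aln)@insertion[[1]]  # gaps in subject
  delP <- Biostrings::indel(aln)@deletion[[1]]   # gaps in pattern
  if (length(insP)) {
    diffs[[length(diffs) + 1L]] <- data.frame(
      position = IRanges::start(insP),
      type = ifelse(IRanges::width(insP) == 1L, "single-base indel", "indel"),
      length = IRanges::width(insP))
  }
  if (length(delP)) {
    diffs[[length(diffs) + 1L]] <- data.frame(
      position = IRanges::start(delP),
      type = ifelse(IRanges::width(delP) == 1L, "single-base indel", "indel"),
      length = IRanges::width(delP))
  }
  if (length(diffs) == 0L) {
    return(data.frame(position = integer(0), type = character(0),
                      length = integer(0)))
  }
  out <- do.call(rbind, diffs)
  out[order(out$position), , drop = FALSE]
}

#' @rdname armDifferences
#' @export
setMethod("armDifferences", "InvertedRepeatReport",
          function(x) x@armDifferences)

setMethod("show", "InvertedRepeatReport", function(object) {
  cat("InvertedRepeatReport\n")
  cat("  arm1: [", IRanges::start(object@arm1), ", ",
      IRanges::end(object@arm1), "]\n", sep = "")
  cat("  arm2: [", IRanges::start(object@arm2), ", ",
      IRanges::end(object@arm2), "]\n", sep = "")
  cat("  stem: ", object@stemLength, " bp, loop: ", object@loopLength,
      " bp, ", nrow(object@armDifferences), " arm difference(s)\n", sep = "")
  if (length(object@flags)) {
    cat("  flags: ", paste(object@flags, collapse = ", "), "\n", sep = "")
  }
})

#' Self-comparison dotplot match set
#'
#' Records all exact word matches of a sequence against itself (forward
#' orientation) and against its reverse complement, merged into maximal runs
#' suitable for dotplot rendering. The forward main diagonal is always
#' present; symmetric counterparts of off-diagonal runs are both reported.
#'
#' @param sequence character or [Biostrings::DNAString].
#' @param wordSize exact-match word size (>= 4).
#' @param step sampling step for word starts (1 = every position).
#' @return data.frame with `x_start`, `y_start`, `length`, `orientation`
#'   (forward / reverse-complement). Both coordinates are 1-based interval
#'   starts on the sequence itself; for reverse-complement runs the segment
#'   starting at `x_start` matches the reverse complement of the equally long
#'   segment starting at `y_start`, so runs come in symmetric (x, y)/(y, x)
#'   pairs.
#' @export
selfDotplot <- function(sequence, wordSize = 15L, step = 1L) {
  stopifnot(wordSize >= 4L)
  s <- .asCharSeq(sequence)
  L <- nchar(s)
  kt <- kmerTable(s, wordSize)
  if (step > 1L) kt <- kt[(kt$pos - 1L) %% step == 0L, , drop = FALSE]
  runs <- list()
  ## forward: pairs of identical words
  byK <- split(kt$pos, kt$kmer)
  byK <- byK[lengths(byK) > 1L]
  fwdPairs <- do.call(rbind, lapply(byK, function(p) {
    cmb <- t(utils::combn(p, 2L))
    rbind(cmb, cmb[, 2:1, drop = FALSE])  # symmetric halves
  }))
  main <- data.frame(x_start = 1L, y_start = 1L, length = L,
                     orientation = "forward", stringsAsFactors = FALSE)
  runs[["main"]] <- main
  if (!is.null(fwdPairs) && nrow(fwdPairs)) {
    off <- fwdPairs[, 2L] - fwdPairs[, 1L]
    for (o in unique(off)) {
      if (o == 0L) next
      xs <- sort(fwdPairs[off == o, 1L])
      mr <- mergeRuns(xs)
      runs[[paste0("f", o)]] <- data.frame(
        x_start = mr$start, y_start = mr$start + o,
        length = mr$len + wordSize - 1L,
        orientation = "forward", stringsAsFactors = FALSE)
    }
  }
  ## reverse-complement matches
  rc <- revcompChar(s)
  ktR <- kmerTable(rc, wordSize)
  byR <- split(ktR$pos, ktR$kmer)
  present <- kt$kmer %in% names(byR)
  if (any(present)) {
    reps <- lengths(byR[kt$kmer[present]])
    x <- rep(kt$pos[present], reps)
    j <- unlist(byR[kt$kmer[present]], use.names = FALSE)
    y <- L - j - wordSize + 2L
    dg <- x + y
    for (o in unique(dg)) {
      sel <- dg == o
      mr <- mergeRuns(x[sel])
      ## partner interval runs anti-diagonally: its start pairs with the
      ## run's last seed, so both coordinates are interval starts
      runs[[paste0("r", o)]] <- data.frame(
        x_start = mr$start, y_start = o - (mr$start + mr$len - 1L),
        length = mr$len + wordSize - 1L,
        orientation = "reverse-complement", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out[order(out$orientation, out$x_start), , drop = FALSE]
}

#' Export helpers for structure reports
#'
#' `writeInsertionVCF` emits the insertion as a VCF record (full inserted
#' sequence in ALT); `writeIrReport` writes the inverted-repeat report as
#' JSON plus a BED file of the arm intervals; `writeDotplotTSV` writes the
#' match set as TSV.
#' @param call an [InsertionCall-class].
#' @param path output path (for the BED companion, `path` with a `.bed`
#'   extension is used).
#' @param chrom,refBase VCF record fields.
#' @return `path`, invisibly.
#' @export
writeInsertionVCF <- function(call, path, chrom = "11", refBase = "N") {
  hdr <- c("##fileformat=VCFv4.2", "##source=goldscan",
           sprintf("##contig=<ID=%s>", chrom),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  alt <- paste0(refBase, as.character(call@insertedSeq))
  rec <- paste(c(chrom, call@breakpoint, "ins_call", refBase, alt, ".",
                 "PASS",
                 sprintf("SVTYPE=INS;SVLEN=%d", length(call@insertedSeq))),
               collapse = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname writeInsertionVCF
#' @param report an [InvertedRepeatReport-class].
#' @param seqname sequence name for the BED intervals.
#' @export
writeIrReport <- function(report, path, seqname = "insertion") {
  obj <- list(
    arm1 = c(IRanges::start(report@arm1), IRanges::end(report@arm1)),
    arm2 = c(IRanges::start(report@arm2), IRanges::end(report@arm2)),
    stem_length = report@stemLength,
    loop_length = report@loopLength,
    arm_differences = report@armDifferences,
    flags = report@flags
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  bed <- sub("\\.[^.]+$", ".bed", path)
  bedLines <- sprintf("%s\t%d\t%d\t%s", seqname,
                      c(IRanges::start(report@arm1) - 1L,
                        IRanges::start(report@arm2) - 1L),
                      c(IRanges::end(report@arm1), IRanges::end(report@arm2)),
                      c("arm1", "arm2"))
  writeLines(bedLines, bed)
  invisible(path)
}

#' @rdname writeInsertionVCF
#' @param dotplot data.frame from [selfDotplot()].
#' @export
writeDotplotTSV <- function(dotplot, path) {
  write.table(dotplot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
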
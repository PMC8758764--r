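#' Read-simulation settings
#'
#' @param coverage mean sequencing depth over the locus (both haplotypes
#'   combined); each haplotype contributes coverage/2.
#' @param readLength read length in bases.
#' @param substitutionRate per-base substitution error probability.
#'   Substitutions are injected after alignment geometry is decided, so they
#'   never move a clip boundary.
#' @param duplicateRate probability a read is duplicate-flagged.
#' @param seed integer seed.
#' @return a list of class `ReadSimConfig`.
#' @export
readSimConfig <- function(coverage = 30, readLength = 100,
                          substitutionRate = 0, duplicateRate = 0,
                          seed = 1L) {
  stopifnot(coverage > 0, readLength >= 1,
            substitutionRate >= 0, substitutionRate <= 1,
            duplicateRate >= 0, duplicateRate <= 1)
  cfg <- list(coverage = coverage, readLength = as.integer(readLength),
              substitutionRate = substitutionRate,
              duplicateRate = duplicateRate, seed = as.integer(seed))
  class(cfg) <- "ReadSimConfig"
  cfg
}

## flags (SAM bitwise)
FLAG_UNMAPPED <- 4L
FLAG_DUPLICATE <- 1024L

## Reads from one haplotype of one individual, projected onto the reference.
## Alignment emulation is analytic: a read overlapping the insertion junction
## is written as reference-aligned with a soft clip whose boundary sits at the
## breakpoint; reads wholly inside the insertion are unmapped.
.simulateHaplotypeReads <- function(hapSeq, isAlt, locus, nReads, readLength,
                                    prefix) {
  hapLen <- nchar(hapSeq)
  bp <- breakpoint(locus)
  ilen <- insertionLength(locus)
  start <- sample.int(hapLen - readLength + 1L, nReads, replace = TRUE)
  end <- start + readLength - 1L
  seq <- substring(hapSeq, start, end)
  pos <- start
  cigar <- rep(sprintf("%dM", readLength), nReads)
  flag <- rep(0L, nReads)
  if (isAlt && ilen > 0L) {
    insEnd <- bp + ilen             # alt coordinate of last inserted base
    leftSpan <- start <= bp & end > bp
    inside <- start > bp & end <= insEnd
    rightSpan <- start > bp & start <= insEnd & end > insEnd
    rightFlank <- start > insEnd
    ## spans junction from the left: matched prefix, soft-clipped tail
    m1 <- bp - start[leftSpan] + 1L
    cigar[leftSpan] <- sprintf("%dM%dS", m1, readLength - m1)
    ## starts in the insertion, runs into right flank: clipped head
    c1 <- insEnd - start[rightSpan] + 1L
    cigar[rightSpan] <- sprintf("%dS%dM", c1, readLength - c1)
    pos[rightSpan] <- bp + 1L
    ## wholly inside the insertion: the element multi-maps, mark unmapped
    flag[inside] <- FLAG_UNMAPPED
    pos[inside] <- 0L
    cigar[inside] <- "*"
    pos[rightFlank] <- start[rightFlank] - ilen
  }
  data.frame(
    name = sprintf("%s_%05d", prefix, seq_along(start)),
    flag = flag, pos = pos, cigar = cigar, seq = seq,
    stringsAsFactors = FALSE
  )
}

.injectSubstitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  nuc <- c("A", "C", "G", "T")
  vapply(seq, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(nuc, b), 1L),
                      character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate breakpoint-realistic short-read alignments for one individual
#'
#' Samples reads uniformly and independently from each of the individual's
#' two haplotypes at half the configured coverage each (read counts are
#' Poisson). Reads from the insertion-bearing haplotype that span the
#' insertion junction are emitted as reference alignments soft-clipped exactly
#' at the breakpoint; reads wholly internal to the insertion are flagged
#' unmapped. Duplicate flags are set independently at `duplicateRate`.
#'
#' @param genotype one of `"dd"`, `"Gd"`, `"GG"`.
#' @param locus a [LocusModel-class].
#' @param config a [readSimConfig()].
#' @return A data.frame of alignment records (`name`, `flag`, `pos`, `cigar`,
#'   `seq`) in the reference coordinate system of the locus.
#' @examples
#' locus <- buildLocus(2000, 150, 20, 0, 1000, seed = 1)
#' reads <- simulateReads("Gd", locus, readSimConfig(coverage = 10, seed = 3))
#' head(reads)
#' @export
simulateReads <- function(genotype, locus, config = readSimConfig()) {
  genotype <- match.arg(genotype, c("dd", "Gd", "GG"))
  stopifnot(is(locus, "LocusModel"), inherits(config, "ReadSimConfig"))
  refSeq <- as.character(refHaplotype(locus))
  if (config$readLength > nchar(refSeq)) {
    stop("readLength (", config$readLength,
         ") exceeds the reference haplotype length (", nchar(refSeq), ")")
  }
  altSeq <- if (genotype != "dd") as.character(altHaplotype(locus)) else NULL
  haps <- switch(genotype,
    dd = list(list(seq = refSeq, alt = FALSE), list(seq = refSeq, alt = FALSE)),
    Gd = list(list(seq = refSeq, alt = FALSE), list(seq = altSeq, alt = TRUE)),
    GG = list(list(seq = altSeq, alt = TRUE), list(seq = altSeq, alt = TRUE))
  )
  withSeed(config$seed, {
    recs <- lapply(seq_along(haps), function(h) {
      hp <- haps[[h]]
      lambda <- (config$coverage / 2) * nchar(hp$seq) / config$readLength
      nReads <- rpois(1L, lambda)
      if (nReads == 0L) return(NULL)
      .simulateHaplotypeReads(hp$seq, hp$alt, locus, nReads,
                              config$readLength, sprintf("h%d", h))
    })
    recs <- do.call(rbind, recs)
    if (is.null(recs)) {
      recs <- data.frame(name = character(0), flag = integer(0),
                         pos = integer(0), cigar = character(0),
                         seq = character(0), stringsAsFactors = FALSE)
    }
    if (nrow(recs) && config$duplicateRate > 0) {
      dup <- runif(nrow(recs)) < config$duplicateRate
      recs$flag[dup] <- recs$flag[dup] + FLAG_DUPLICATE
    }
    recs$seq <- .injectSubstitutions(recs$seq, config$substitutionRate)
    recs
  })
}

#' Write alignment records as SAM
#'
#' Emits a valid SAM file (with `@HD` and `@SQ` header) in the reference
#' coordinate system; convertible to BAM with [Rsamtools::asBam()].
#' @param records alignment data.frame from [simulateReads()].
#' @param path output SAM path.
#' @param refName reference sequence name.
#' @param refLength reference sequence length for the `@SQ` line.
#' @return `path`, invisibly.
#' @export
writeSAM <- function(records, path, refName = "ref", refLength) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", refName, as.integer(refLength)))
  if (nrow(records)) {
    unmapped <- bitwAnd(records$flag, FLAG_UNMAPPED) != 0L
    rname <- ifelse(unmapped, "*", refName)
    mapq <- ifelse(unmapped, 0L, 60L)
    body <- paste(records$name, records$flag, rname, records$pos, mapq,
                  records$cigar, "*", 0L, 0L, records$seq, "*", sep = "\t")
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignment records from SAM or BAM
#'
#' SAM text is parsed directly (malformed lines produce an error naming the
#' line); BAM is read through [Rsamtools::scanBam()]. Only the fields the
#' breakpoint genotyper uses are retained.
#' @param path `.sam` or `.bam` file.
#' @return alignment data.frame (`name`, `flag`, `pos`, `cigar`, `seq`).
#' @export
readAlignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    res <- Rsamtools::scanBam(path,
      param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "pos", "cigar", "seq")))[[1]]
    return(data.frame(
      name = res$qname, flag = as.integer(res$flag),
      pos = ifelse(is.na(res$pos), 0L, res$pos),
      cigar = ifelse(is.na(res$cigar), "*", res$cigar),
      seq = as.character(res$seq), stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad)) {
    stop("malformed SAM record at line ", body[bad[1]], " of ", path)
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:11)), ncol = 11L, byrow = TRUE)
  data.frame(name = m[, 1], flag = as.integer(m[, 2]),
             pos = as.integer(m[, 4]), cigar = m[, 6], seq = m[, 10],
             stringsAsFactors = FALSE)
}
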
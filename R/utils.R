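#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom IRanges IRanges
#' @importFrom stats optimize pchisq rbinom rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

## Deterministic child seeds: one global seed fans out to per-stage seeds so
## any stage can be re-run in isolation with identical results.
childSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  idx <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.integer(stage)
  }
  as.integer((as.double(seed) * 7919 + idx * 104729) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## random nucleotide string
randomSequence <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## ---- CIGAR handling -------------------------------------------------------

#' Parse CIGAR strings into operation tables
#'
#' Splits each CIGAR string of an alignment into its ordered
#' (operation, length) pairs and derives the quantities breakpoint
#' classification needs: the reference span consumed by the alignment and the
#' lengths of any leading/trailing soft or hard clips.
#'
#' @param cigar character vector of CIGAR strings (`"*"` allowed for unmapped
#'   records).
#' @return A data.frame with one row per input: `ref_span` (bases of reference
#'   consumed by M/D/N/=/X operations), `lead_clip`, `trail_clip` (lengths of
#'   clipping at the read start/end, soft and hard clips treated alike), and
#'   `valid` (FALSE for malformed strings).
#' @examples
#' parseCigar(c("50M50S", "10S90M", "100M", "*"))
#' @export
parseCigar <- function(cigar) {
  n <- length(cigar)
  out <- data.frame(
    ref_span = integer(n), lead_clip = integer(n), trail_clip = integer(n),
    valid = rep(TRUE, n)
  )
  if (n == 0L) return(out)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  for (i in seq_len(n)) {
    cg <- cigar[i]
    if (is.na(cg) || cg == "*") {
      out$valid[i] <- FALSE
      next
    }
    tk <- toks[[i]]
    if (length(tk) == 0L || sum(nchar(tk)) != nchar(cg)) {
      out$valid[i] <- FALSE
      next
    }
    len <- as.integer(sub("[MIDNSHP=X]$", "", tk))
    op <- substr(tk, nchar(tk), nchar(tk))
    ## clips only legal at the ends (hard outside soft)
    inner <- op[!(op %in% c("S", "H"))]
    clipIdx <- which(op %in% c("S", "H"))
    nEnd <- length(op)
    okClips <- all(clipIdx %in% c(1L, 2L, nEnd - 1L, nEnd)) || length(clipIdx) == 0L
    if (!okClips || length(inner) == 0L) {
      out$valid[i] <- FALSE
      next
    }
    out$ref_span[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    lead <- 0L
    j <- 1L
    while (j <= nEnd && op[j] %in% c("S", "H")) {
      lead <- lead + len[j]
      j <- j + 1L
    }
    trail <- 0L
    j <- nEnd
    while (j >= 1L && op[j] %in% c("S", "H")) {
      trail <- trail + len[j]
      j <- j - 1L
    }
    out$lead_clip[i] <- lead
    out$trail_clip[i] <- trail
  }
  out
}

## ---- k-mer helpers --------------------------------------------------------

## start positions and k-mer strings; k-mers containing N never seed matches
kmerTable <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) {
    return(data.frame(pos = integer(0), kmer = character(0)))
  }
  pos <- seq_len(n - k + 1L)
  km <- substring(seq, pos, pos + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  data.frame(pos = pos[keep], kmer = km[keep], stringsAsFactors = FALSE)
}

## longest strictly-increasing subsequence; returns indices into x
longestIncreasingSubsequence <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- numeric(0)     # smallest tail value for LIS of each length
  tailIdx <- integer(0)   # index in x achieving that tail
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 0.5, tails) + 1L  # first tail >= x[i]
    prev[i] <- if (j > 1L) tailIdx[j - 1L] else 0L
    tails[j] <- x[i]
    tailIdx[j] <- i
  }
  res <- integer(length(tails))
  k <- tailIdx[length(tails)]
  for (j in rev(seq_along(tails))) {
    res[j] <- k
    k <- prev[k]
  }
  res
}

## merge sorted integer positions into runs of consecutive values
mergeRuns <- function(pos) {
  if (length(pos) == 0L) return(data.frame(start = integer(0), len = integer(0)))
  pos <- sort(unique(pos))
  brk <- c(TRUE, diff(pos) != 1L)
  grp <- cumsum(brk)
  start <- tapply(pos, grp, min)
  end <- tapply(pos, grp, max)
  data.frame(start = as.integer(start), len = as.integer(end - start + 1L))
}
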
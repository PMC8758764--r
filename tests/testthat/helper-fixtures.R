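# shared fixture builders: everything is generated in code at test time

randomDna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# one alignment record for classifier unit tests
makeRead <- function(pos, cigar, flag = 0L, name = "r") {
  data.frame(name = name, flag = flag, pos = as.integer(pos), cigar = cigar,
             seq = "*", stringsAsFactors = FALSE)
}

# small locus shared by the read/genotyper tests
smallLocus <- function(seed = 2) {
  buildLocus(refLength = 2000, armLength = 300, loopLength = 30,
             armEditCount = 1, breakpoint = 1000, seed = seed)
}
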
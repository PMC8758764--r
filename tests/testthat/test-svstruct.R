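test_that("a constructed flank-insertion-flank pair is called exactly", {
  left <- randomDna(5000, seed = 1)
  right <- randomDna(5000, seed = 2)
  ins <- randomDna(8192, seed = 3)
  # avoid placement ambiguity so the construction coordinate is canonical
  if (substr(ins, 8192, 8192) == substr(left, 5000, 5000)) {
    substr(ins, 8192, 8192) <- setdiff(c("A", "C", "G", "T"),
                                       substr(left, 5000, 5000))[1]
  }
  call <- callInsertion(paste0(left, right), paste0(left, ins, right))
  expect_equal(breakpoint(call), 5000L)
  expect_equal(length(insertedSeq(call)), 8192L)
  expect_equal(as.character(insertedSeq(call)), ins)
})

test_that("identical haplotypes yield no insertion call", {
  s <- randomDna(4000, seed = 5)
  expect_null(callInsertion(s, s))
})

test_that("unrelated sequences produce an explicit no-call", {
  expect_error(callInsertion(randomDna(3000, seed = 1),
                             randomDna(3000, seed = 99)),
               "no-call")
})

test_that("locus-model haplotypes are recovered within the edit tolerance", {
  for (sd in c(3, 8, 15)) {
    locus <- buildLocus(3000, 300, 30, 2, 1500, seed = sd)
    call <- callInsertion(refHaplotype(locus), altHaplotype(locus))
    expect_equal(breakpoint(call), leftAlignedBreakpoint(locus))
    expect_lte(abs(length(insertedSeq(call)) - 628L), 2L)
  }
})

test_that("a clean inverted repeat reports exact stem and loop geometry", {
  arm <- randomDna(200, seed = 7)
  # non-palindromic loop whose termini cannot base-pair with each other
  loop <- "ACCACCACCACCACCACCAA"
  s <- paste0(arm, loop, revcomp(arm))
  rep <- findInvertedRepeat(s, minStem = 100)
  expect_equal(rep@stemLength, 200L)
  expect_equal(rep@loopLength, 20L)
  expect_equal(nrow(armDifferences(rep)), 0L)
  expect_equal(IRanges::start(rep@arm1), 1L)
  expect_equal(IRanges::end(rep@arm2), nchar(s))
})

test_that("injected single-base deletions are enumerated as arm differences", {
  arm <- randomDna(400, seed = 9)
  loop <- randomDna(40, seed = 10)
  arm2src <- paste0(substr(arm, 1, 99), substr(arm, 101, 299),
                    substr(arm, 301, 400))  # delete arm positions 100 and 300
  s <- paste0(arm, loop, revcomp(arm2src))
  rep <- findInvertedRepeat(s, minStem = 200)
  diffs <- armDifferences(rep)
  expect_equal(nrow(diffs), 2L)
  expect_true(all(diffs$type == "single-base indel"))
  # positions are reported on arm1 coordinates near the injected sites
  expect_true(all(abs(sort(diffs$position) - c(100, 300)) <= 2))
})

test_that("random sequence contains no reportable inverted repeat", {
  s <- randomDna(2000, seed = 13)
  expect_null(findInvertedRepeat(s, minStem = 100))
  # brute-force oracle: no 100-mer of the sequence occurs in its reverse
  # complement, so no exact stem of length >= 100 exists
  rc <- revcomp(s)
  pos <- 1:(2000 - 99)
  words <- substring(s, pos, pos + 99)
  rwords <- substring(rc, pos, pos + 99)
  expect_equal(length(intersect(words, rwords)), 0L)
})

test_that("the inverted-repeat report maps through reverse complementation", {
  arm <- randomDna(300, seed = 17)
  s <- paste0(randomDna(50, seed = 18), arm, randomDna(25, seed = 19),
              revcomp(arm), randomDna(60, seed = 20))
  a <- findInvertedRepeat(s, minStem = 150)
  b <- findInvertedRepeat(revcomp(s), minStem = 150)
  expect_equal(a@stemLength, b@stemLength)
  expect_equal(a@loopLength, b@loopLength)
  L <- nchar(s)
  # arm1 of the flipped sequence is the mirror image of arm2
  expect_equal(IRanges::start(b@arm1), L - IRanges::end(a@arm2) + 1L)
  expect_equal(IRanges::end(b@arm2), L - IRanges::start(a@arm1) + 1L)
})

test_that("dotplots of random sequence show only the main diagonal", {
  dp <- selfDotplot(randomDna(300, seed = 23), wordSize = 15)
  expect_equal(nrow(dp), 1L)
  expect_equal(dp$x_start, 1L)
  expect_equal(dp$length, 300L)
  expect_equal(dp$orientation, "forward")
})

test_that("inverted and tandem repeats appear in the expected dotplot orientations", {
  arm <- randomDna(120, seed = 29)
  ir <- paste0(arm, randomDna(15, seed = 30), revcomp(arm))
  dpIr <- selfDotplot(ir, wordSize = 15)
  rev <- dpIr[dpIr$orientation == "reverse-complement", ]
  expect_gte(max(rev$length), 120L)

  tand <- paste0(arm, randomDna(15, seed = 31), arm)
  dpT <- selfDotplot(tand, wordSize = 15)
  fwd <- dpT[dpT$orientation == "forward" & dpT$x_start != dpT$y_start, ]
  expect_gte(max(fwd$length), 120L)
  expect_equal(nrow(dpT[dpT$orientation == "reverse-complement", ]), 0L)
})

test_that("dotplot runs are involution-symmetric", {
  arm <- randomDna(80, seed = 37)
  s <- paste0(arm, randomDna(10, seed = 38), revcomp(arm),
              randomDna(30, seed = 39), arm)
  dp <- selfDotplot(s, wordSize = 12)
  off <- dp[dp$x_start != 1L | dp$orientation != "forward" |
              dp$y_start != 1L, ]
  for (i in seq_len(nrow(off))) {
    mate <- off[off$x_start == off$y_start[i] &
                  off$y_start == off$x_start[i] &
                  off$orientation == off$orientation[i] &
                  off$length == off$length[i], ]
    expect_equal(nrow(mate), 1L,
                 info = paste("run", off$x_start[i], off$y_start[i],
                              off$orientation[i]))
  }
})

test_that("structure reports serialize to VCF, JSON and BED", {
  locus <- buildLocus(2000, 150, 20, 1, 1000, seed = 41)
  call <- callInsertion(refHaplotype(locus), altHaplotype(locus))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeInsertionVCF(call, vcf)
  parsed <- vcfR::read.vcfR(vcf, verbose = FALSE)
  expect_equal(as.integer(parsed@fix[1, "POS"]), breakpoint(call))

  rep <- findInvertedRepeat(as.character(insertionSeq(locus)), minStem = 50)
  json <- withr::local_tempfile(fileext = ".json")
  writeIrReport(rep, json)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$stem_length, rep@stemLength)
  bed <- read.delim(sub("\\.json$", ".bed", json), header = FALSE)
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$V2[1] + 1L, IRanges::start(rep@arm1))
})
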
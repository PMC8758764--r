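bp <- 1000L

test_that("read classification follows the overlap and clip-window rules", {
  # fully matching read spanning [bp-50, bp+49] supports the reference
  expect_equal(as.character(classifyReads(makeRead(bp - 50L, "100M"), bp)),
               "reference")
  # 50 matched bases then a 50-base soft clip: boundary exactly at bp
  expect_equal(as.character(classifyReads(makeRead(bp - 49L, "50M50S"), bp)),
               "split")
  # leading clip ending just before bp+1 is the mirrored split signal
  expect_equal(as.character(classifyReads(makeRead(bp + 1L, "50S50M"), bp)),
               "split")
  # hard clips mark the same breakpoint signal as soft clips
  expect_equal(as.character(classifyReads(makeRead(bp - 49L, "50M50H"), bp)),
               "split")
  # clip boundary within +/- clip_window still counts
  expect_equal(as.character(classifyReads(makeRead(bp - 44L, "50M50S"), bp)),
               "split")
  expect_equal(as.character(classifyReads(makeRead(bp - 56L, "50M50S"), bp)),
               "excluded")
  # duplicate- or unmapped-flagged reads are excluded outright
  expect_equal(as.character(classifyReads(makeRead(bp - 50L, "100M",
                                                   flag = 1024L), bp)),
               "excluded")
  expect_equal(as.character(classifyReads(makeRead(0L, "*", flag = 4L), bp)),
               "excluded")
  # matching read ending only 3 bases past the breakpoint overlaps too little
  expect_equal(as.character(classifyReads(makeRead(bp - 96L, "100M"), bp)),
               "excluded")
  # exactly 5 aligned bases on each side is the minimum for reference support
  expect_equal(as.character(classifyReads(makeRead(bp - 95L, "100M"), bp)),
               "excluded")  # 4 bases past the breakpoint
  expect_equal(as.character(classifyReads(makeRead(bp - 94L, "100M"), bp)),
               "reference")
  expect_equal(as.character(classifyReads(makeRead(bp - 4L, "100M"), bp)),
               "reference")
  expect_equal(as.character(classifyReads(makeRead(bp - 3L, "100M"), bp)),
               "excluded")
})

test_that("malformed CIGAR strings are excluded with a warning", {
  rec <- rbind(makeRead(bp - 50L, "100M"), makeRead(bp - 50L, "12Q"))
  expect_warning(cls <- classifyReads(rec, bp), "CIGAR")
  expect_equal(as.character(cls), c("reference", "excluded"))
})

test_that("genotype calling reproduces the ratio and absolute-count rules", {
  expect_equal(callGenotype(0, 100), "dd")        # ratio 0
  expect_equal(callGenotype(20, 40), "Gd")        # ratio 0.5
  expect_equal(callGenotype(2, 30), "dd")         # absolute split <= 2
  expect_equal(callGenotype(28, 30), "GG")        # total - split <= 2
  expect_equal(callGenotype(2, 3), "no-call")     # both overrides fire
  expect_equal(callGenotype(0, 0), "no-call")     # no classifiable reads
  # boundaries are strict: ratio exactly 0.1 / 0.9 is heterozygous
  expect_equal(callGenotype(10, 100), "Gd")
  expect_equal(callGenotype(90, 100), "Gd")
  expect_error(callGenotype(-1, 10), "non-negative")
  expect_error(callGenotype(11, 10), "exceed")
})

test_that("calls move monotonically from dd to GG as split support grows", {
  ord <- c(dd = 1L, Gd = 2L, GG = 3L)
  for (n in c(5L, 10L, 30L, 60L)) {
    calls <- callGenotype(0:n, n)
    lvl <- ord[calls]
    informative <- !is.na(lvl)
    expect_true(all(diff(lvl[informative]) >= 0),
                info = paste("n_total =", n))
  }
})

test_that("cohort genotyping recovers simulation truth exactly at moderate coverage", {
  locus <- smallLocus()
  genos <- rep(c("dd", "Gd", "GG"), each = 10)
  aln <- lapply(seq_along(genos), function(i) {
    simulateReads(genos[i], locus, readSimConfig(coverage = 30, seed = 100 + i))
  })
  calls <- genotypeCohort(aln, breakpoint(locus))
  expect_equal(calls$call, genos)
  expect_true(all(calls$n_split <= calls$n_total))
})

test_that("duplicate-flagged reads do not change the genotype calls", {
  locus <- smallLocus()
  genos <- c("dd", "Gd", "GG", "Gd")
  clean <- lapply(seq_along(genos), function(i) {
    simulateReads(genos[i], locus, readSimConfig(coverage = 30, seed = 40 + i))
  })
  dup <- lapply(seq_along(genos), function(i) {
    simulateReads(genos[i], locus,
                  readSimConfig(coverage = 30, duplicateRate = 0.1,
                                seed = 40 + i))
  })
  expect_equal(genotypeCohort(dup, breakpoint(locus))$call,
               genotypeCohort(clean, breakpoint(locus))$call)
})

test_that("classification is independent of read order", {
  locus <- smallLocus()
  reads <- simulateReads("Gd", locus, readSimConfig(coverage = 30, seed = 5))
  set.seed(1)
  shuffled <- reads[sample.int(nrow(reads)), , drop = FALSE]
  a <- genotypeCohort(list(s = reads), breakpoint(locus))
  b <- genotypeCohort(list(s = shuffled), breakpoint(locus))
  expect_equal(a[c("n_total", "n_split", "call")],
               b[c("n_total", "n_split", "call")])
})

test_that("samples without reads are reported as no-call", {
  empty <- data.frame(name = character(0), flag = integer(0),
                      pos = integer(0), cigar = character(0),
                      seq = character(0))
  expect_message(calls <- genotypeCohort(list(s1 = empty, s2 = empty), bp),
                 "no-call")
  expect_equal(calls$call, c("no-call", "no-call"))
})

test_that("heterozygote split-read fractions match the junction geometry", {
  # a het samples both haplotypes equally, but the insertion-bearing haplotype
  # presents two clip-producing junction edges while the reference haplotype
  # presents one matched window, so the expected split fraction is
  # 2(L-1) / (2(L-1) + (L - 2*minOverlap + 1)), not 1/2
  locus <- smallLocus()
  ev <- genotypeCohort(lapply(1:12, function(i) {
    simulateReads("Gd", locus, readSimConfig(coverage = 30, seed = 200 + i))
  }), breakpoint(locus))
  L <- 100
  pExp <- 2 * (L - 1) / (2 * (L - 1) + (L - 2 * 5 + 1))
  pooledN <- sum(ev$n_total)
  pooled <- sum(ev$n_split) / pooledN
  expect_lt(abs(pooled - pExp), 4 * sqrt(pExp * (1 - pExp) / pooledN))
  # every heterozygote lands strictly inside the het calling band
  expect_true(all(ev$call == "Gd"))
})

test_that("SV genotypes export to a parseable single-record VCF", {
  calls <- data.frame(sample_id = c("a", "b", "c", "d"),
                      n_total = c(30L, 40L, 28L, 0L),
                      n_split = c(1L, 21L, 27L, 0L),
                      ratio = c(1 / 30, 21 / 40, 27 / 28, NA),
                      call = c("dd", "Gd", "GG", "no-call"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeSvVCF(calls, path, chrom = "11", pos = 7069471L, svlen = 8248L)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(vcf@gt), 1L)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  expect_equal(unname(gt[1, ]), c("0/0", "0/1", "1/1", NA))
  gm <- svCallsToMatrix(calls)
  expect_equal(unname(dosages(gm)[, 1]), c(0, 1, 2, NA))
})
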
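makeGm <- function(dosage) {
  genotypeMatrix(dosage)
}

test_that("variant filters drop low-MAF, high-missingness and monomorphic sites", {
  n <- 100
  d <- cbind(
    maf04 = c(rep(1, 8), rep(0, 92)),          # MAF 0.04 -> removed
    maf05 = c(rep(1, 10), rep(0, 90)),         # MAF 0.05 -> kept (boundary)
    mono = rep(0, n),                          # monomorphic -> removed
    common = rep(c(0, 1, 2, 1), 25)            # kept
  )
  d2 <- d
  d2[1:25, "common"] <- NA                     # 25% missing -> removed
  kept <- variantInfo(filterVariants(makeGm(d)))$id
  expect_equal(kept, c("maf05", "common"))
  kept2 <- variantInfo(filterVariants(makeGm(d2)))$id
  expect_equal(kept2, "maf05")
  # exactly 20% missing survives the "more than 20%" rule
  d3 <- cbind(x = rep(c(0, 1), 50))
  d3[1:20, 1] <- NA
  expect_equal(nrow(variantInfo(filterVariants(makeGm(d3)))), 1L)
  expect_warning(empty <- filterVariants(makeGm(d[, "mono", drop = FALSE])),
                 "no variants")
  expect_equal(ncol(dosages(empty)), 0L)
})

test_that("centered kinship matches the brute-force double loop", {
  set.seed(10)
  d <- matrix(sample(c(0, 1, 2, NA), 20 * 50, replace = TRUE,
                     prob = c(0.4, 0.3, 0.25, 0.05)), 20, 50)
  K <- computeKinship(d)
  # naive oracle: mean-impute, center, average outer products
  imp <- apply(d, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v - mean(v)
  })
  Ko <- matrix(0, 20, 20)
  for (j in 1:50) Ko <- Ko + outer(imp[, j], imp[, j])
  Ko <- Ko / 50
  expect_lt(max(abs(K - Ko)), 1e-10)
  expect_equal(K, t(K))
})

test_that("kinship degenerate cases behave as the algebra dictates", {
  # a single all-heterozygous variant centers to the zero matrix
  expect_equal(max(abs(computeKinship(matrix(1, 5, 1)))), 0)
  # duplicated genomes share diagonal and off-diagonal entries
  set.seed(2)
  d <- matrix(rbinom(8 * 30, 2, 0.3), 8, 30)
  d[2, ] <- d[1, ]
  K <- computeKinship(d)
  expect_equal(K[1, 1], K[2, 2])
  expect_equal(K[1, 2], K[1, 1])
  expect_error(computeKinship(matrix(1, 1, 3)), "two samples")
})

test_that("with identity kinship the mixed-model LRT equals the OLS likelihood ratio", {
  set.seed(31)
  n <- 150
  y <- rnorm(n)
  for (r in 1:10) {
    x <- rbinom(n, 2, runif(1, 0.1, 0.5))
    res <- lmmLRT(y, x, kinship = diag(n))
    lrtOls <- as.numeric(2 * (logLik(stats::lm(y ~ x)) -
                              logLik(stats::lm(y ~ 1))))
    pOls <- pchisq(lrtOls, df = 1, lower.tail = FALSE)
    expect_lt(abs(res$minus_log10_p - (-log10(pOls))), 1e-6)
  }
})

test_that("null LRT statistics average to one as chi-square(1) predicts", {
  set.seed(77)
  n <- 250
  y <- rnorm(n)
  stats <- replicate(200, {
    x <- rbinom(n, 2, 0.3)
    lmmLRT(y, x, kinship = NULL)$lrt
  })
  # mean of 200 chi-square(1) draws: sd = sqrt(2/200) = 0.1
  expect_lt(abs(mean(stats) - 1), 0.4)
})

test_that("degenerate phenotypes and dosages are flagged, not mis-tested", {
  set.seed(4)
  x <- rbinom(80, 2, 0.4)
  const <- lmmLRT(rnorm(80), rep(1, 80), kinship = NULL)
  expect_equal(const$flag, "untestable")
  sep <- lmmLRT(as.numeric(x), x, kinship = NULL)
  expect_equal(sep$flag, "underflow")
  expect_equal(sep$p_value, 5e-324)
  expect_error(lmmLRT(c(1, NA, 3), c(0, 1, 2)), "non-finite")
})

test_that("the LRT is invariant under affine rescaling of the phenotype", {
  set.seed(12)
  n <- 120
  d <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
  y <- rnorm(n) + 0.5 * d[, 7]
  K <- computeKinship(d)
  a <- lmmLRT(y, d[, 7], kinship = K)
  b <- lmmLRT(3 + 2 * y, d[, 7], kinship = K)
  expect_lt(abs(a$lrt - b$lrt), 1e-5)
})

test_that("a large-effect causal variant tops the scan", {
  sim <- simulateCohort(cohortConfig(nIndividuals = 200,
                                     nBackgroundMarkers = 200, seed = 21))
  sv <- genotypeMatrix(
    matrix(c(dd = 0, Gd = 1, GG = 2)[sim$cohort$true_genotype],
           ncol = 1, dimnames = list(sim$cohort$id, "causal_SV")),
    data.frame(id = "causal_SV", chrom = "11", pos = 7069471L))
  gm <- bindVariants(sim$markers, sv)
  scan <- gwasScan(gm, as.numeric(sim$cohort$phenotype == "gold"))
  expect_equal(scan$id[which.max(scan$minus_log10_p)], "causal_SV")
  # the scan is ordered by position within chromosome
  expect_true(all(diff(scan$pos[scan$chrom == "1"]) > 0))
})

test_that("a single retained variant yields a scan of length one", {
  d <- matrix(rep(c(0, 1, 2), length.out = 60), ncol = 1,
              dimnames = list(NULL, "only"))
  y <- 0.3 * d[, 1] + rnorm(60, sd = 0.5)
  scan <- gwasScan(genotypeMatrix(d), y, kinship = NULL)
  expect_equal(nrow(scan), 1L)
  expect_lt(scan$p_value, 0.05)
})

test_that("with identity kinship a whole scan matches an OLS scan", {
  set.seed(99)
  n <- 100
  d <- matrix(rbinom(n * 25, 2, 0.4), n, 25)
  y <- rnorm(n)
  scan <- gwasScan(genotypeMatrix(d), y, kinship = diag(n),
                   mafMin = 0, maxMissing = 1)
  ols <- vapply(seq_len(ncol(d)), function(j) {
    lrt <- as.numeric(2 * (logLik(stats::lm(y ~ d[, j])) -
                           logLik(stats::lm(y ~ 1))))
    -log10(pchisq(lrt, 1, lower.tail = FALSE))
  }, numeric(1))
  expect_lt(max(abs(sort(scan$minus_log10_p) - sort(ols))), 1e-6)
})
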
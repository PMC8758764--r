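#' Filter variants on minor allele frequency and missingness
#'
#' Retains variants with minor allele frequency (computed on non-missing
#' calls) at least `mafMin` and missingness at most `maxMissing`. No
#' Hardy-Weinberg filter is applied, so out-of-equilibrium causal candidates
#' are never discarded.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param mafMin minimum minor allele frequency (default 0.05; variants with
#'   MAF strictly below are removed).
#' @param maxMissing maximum fraction of missing calls (default 0.20;
#'   variants with strictly more are removed).
#' @return a filtered [GenotypeMatrix-class]; empty (with a warning) when
#'   nothing survives.
#' @export
filterVariants <- function(gm, mafMin = 0.05, maxMissing = 0.20) {
  stopifnot(is(gm, "GenotypeMatrix"))
  d <- gm@dosage
  missFrac <- colMeans(is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  maf <- pmin(af, 1 - af)
  keep <- which(maf >= mafMin & missFrac <= maxMissing)
  if (length(keep) == 0L) {
    warning("no variants pass the MAF/missingness filters")
  }
  new("GenotypeMatrix",
      dosage = d[, keep, drop = FALSE],
      variants = gm@variants[keep, , drop = FALSE])
}

## per-variant mean imputation of missing dosages
imputeDosages <- function(d) {
  if (!anyNA(d)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  d
}

#' Centered kinship matrix
#'
#' Computes the centered relatedness matrix K = (1/p) * Xc %*% t(Xc), where
#' Xc is the sample-by-variant dosage matrix with missing entries mean-imputed
#' per variant and each variant centered on its mean. This is the standard
#' centered kinship used as the random-effect covariance in mixed-model
#' association.
#'
#' @param gm a [GenotypeMatrix-class] or plain dosage matrix (samples x
#'   variants).
#' @return symmetric n x n matrix.
#' @export
computeKinship <- function(gm) {
  d <- if (is(gm, "GenotypeMatrix")) gm@dosage else as.matrix(gm)
  if (nrow(d) < 2L) stop("kinship requires at least two samples")
  if (ncol(d) < 1L) stop("kinship requires at least one variant")
  d <- imputeDosages(d)
  xc <- scale(d, center = TRUE, scale = FALSE)
  K <- tcrossprod(xc) / ncol(xc)
  (K + t(K)) / 2
}

## ML log-likelihood of y ~ N(X b, s2 * (lambda * K + I)) in the
## eigen-rotated basis: v_i = lambda * d_i + 1 are the rotated variances.
.rotatedML <- function(log10lambda, yt, Xt, d) {
  v <- 10^log10lambda * d + 1
  w <- 1 / v
  Xw <- Xt * sqrt(w)
  yw <- yt * sqrt(w)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  n <- length(yt)
  if (rss <= 0) rss <- .Machine$double.xmin
  -0.5 * (n * log(2 * pi * rss / n) + n + sum(log(v)))
}

## maximize over lambda: coarse log-spaced grid then bounded refinement
.fitVarianceRatio <- function(yt, Xt, d, gridN = 21L, tol = 1e-8) {
  grid <- seq(-5, 5, length.out = gridN)
  ll <- vapply(grid, .rotatedML, numeric(1), yt = yt, Xt = Xt, d = d)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(gridN, i + 1L)]
  opt <- optimize(.rotatedML, c(lo, hi), yt = yt, Xt = Xt, d = d,
                  maximum = TRUE, tol = tol)
  if (opt$objective < ll[i]) {
    list(log10lambda = grid[i], logLik = ll[i])
  } else {
    list(log10lambda = opt$maximum, logLik = opt$objective)
  }
}

.betaAt <- function(log10lambda, yt, Xt, d) {
  v <- 10^log10lambda * d + 1
  w <- sqrt(1 / v)
  fit <- stats::lm.fit(Xt * w, yt * w)
  fit$coefficients
}

#' Single-variant mixed-model likelihood-ratio test
#'
#' Fits, by maximum likelihood, the linear mixed model
#' `y = W a + x b + u + e` with `u ~ N(0, sg^2 K)` and `e ~ N(0, se^2 I)`,
#' via eigendecomposition of the kinship matrix and one-dimensional
#' optimization of the variance ratio `lambda = sg^2 / se^2`. The
#' likelihood-ratio statistic compares against the null model without the
#' variant (lambda re-estimated under each model); the p-value is from a
#' chi-square distribution with 1 df. A binary phenotype is analysed as
#' quantitative 0/1.
#'
#' @param y numeric phenotype vector.
#' @param x variant dosage vector (mean-imputed beforehand if missing).
#' @param kinship n x n kinship matrix, or a precomputed `eigen()` result, or
#'   NULL for independent samples (identity covariance, equivalent to OLS).
#' @param covariates optional covariate matrix (an intercept is always
#'   included).
#' @return list with `beta`, `lambda` (variance ratio at the alternative
#'   fit), `lrt`, `p_value`, `minus_log10_p`, and `flag`
#'   ("" | "untestable" — constant dosage | "underflow" — p below
#'   double-precision resolution, reported as 5e-324).
#' @export
lmmLRT <- function(y, x, kinship = NULL, covariates = NULL) {
  n <- length(y)
  stopifnot(length(x) == n)
  if (!all(is.finite(y)) || !all(is.finite(x))) {
    stop("non-finite phenotype or dosage values")
  }
  W <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates))
  if (stats::sd(x) == 0) {
    return(list(beta = NA_real_, lambda = NA_real_, lrt = NA_real_,
                p_value = NA_real_, minus_log10_p = NA_real_,
                flag = "untestable"))
  }
  if (is.null(kinship)) {
    ed <- list(values = rep(1, n), vectors = diag(n))
  } else if (is.list(kinship) && !is.null(kinship$vectors)) {
    ed <- kinship
  } else {
    ed <- eigen(kinship, symmetric = TRUE)
  }
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)
  xt <- drop(crossprod(U, x))
  fit0 <- .fitVarianceRatio(yt, Wt, d)
  fit1 <- .fitVarianceRatio(yt, cbind(Wt, xt), d)
  if (!is.finite(fit0$logLik) || !is.finite(fit1$logLik)) {
    stop("non-finite likelihood; check kinship conditioning and phenotype scale")
  }
  lrt <- max(0, 2 * (fit1$logLik - fit0$logLik))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  flag <- ""
  if (p == 0) {
    p <- 5e-324
    flag <- "underflow"
  }
  beta <- .betaAt(fit1$log10lambda, yt, cbind(Wt, xt), d)
  list(beta = unname(beta[length(beta)]),
       lambda = 10^fit1$log10lambda,
       lrt = lrt, p_value = p, minus_log10_p = -log10(p), flag = flag)
}

#' Genome scan: per-variant mixed-model association
#'
#' Applies the MAF/missingness filters, mean-imputes remaining missing calls,
#' and runs [lmmLRT()] for every retained variant against the phenotype, with
#' the kinship eigendecomposition computed once and shared. The null-model
#' likelihood is also shared across variants since the null does not involve
#' the tested variant.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param phenotype numeric vector (0/1 for dark/gold) aligned with the
#'   samples of `gm`.
#' @param kinship n x n matrix or NULL (no random effect). By default the
#'   centered kinship of the filtered matrix itself is used.
#' @param covariates optional covariate matrix.
#' @param mafMin,maxMissing filter settings, see [filterVariants()].
#' @return data.frame ordered by chrom/pos: `id`, `chrom`, `pos`, `beta`,
#'   `lambda`, `lrt`, `p_value`, `minus_log10_p`, `flag`.
#' @export
gwasScan <- function(gm, phenotype, kinship = computeKinship(gm),
                     covariates = NULL, mafMin = 0.05, maxMissing = 0.20) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (length(phenotype) != nrow(gm@dosage)) {
    stop("phenotype length must match the number of samples")
  }
  fl <- filterVariants(gm, mafMin, maxMissing)
  d <- imputeDosages(fl@dosage)
  if (ncol(d) == 0L) {
    return(data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), beta = numeric(0),
                      lambda = numeric(0), lrt = numeric(0),
                      p_value = numeric(0), minus_log10_p = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE))
  }
  n <- nrow(d)
  W <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates))
  if (is.null(kinship)) {
    eigval <- rep(1, n)
    yt <- phenotype
    Wt <- W
    Xt <- d
  } else {
    ed <- eigen(kinship, symmetric = TRUE)
    eigval <- pmax(ed$values, 0)
    yt <- drop(crossprod(ed$vectors, phenotype))
    Wt <- crossprod(ed$vectors, W)
    Xt <- crossprod(ed$vectors, d)
  }
  fit0 <- .fitVarianceRatio(yt, Wt, eigval)
  p <- ncol(d)
  beta <- lambda <- lrt <- pval <- rep(NA_real_, p)
  flag <- character(p)
  for (j in seq_len(p)) {
    if (stats::sd(d[, j]) == 0) {
      flag[j] <- "untestable"
      next
    }
    X1 <- cbind(Wt, Xt[, j])
    fit1 <- .fitVarianceRatio(yt, X1, eigval)
    lrt[j] <- max(0, 2 * (fit1$logLik - fit0$logLik))
    pv <- pchisq(lrt[j], df = 1, lower.tail = FALSE)
    if (pv == 0) {
      pv <- 5e-324
      flag[j] <- "underflow"
    }
    pval[j] <- pv
    lambda[j] <- 10^fit1$log10lambda
    b <- .betaAt(fit1$log10lambda, yt, X1, eigval)
    beta[j] <- unname(b[length(b)])
  }
  out <- data.frame(id = fl@variants$id, chrom = fl@variants$chrom,
                    pos = fl@variants$pos, beta = beta, lambda = lambda,
                    lrt = lrt, p_value = pval,
                    minus_log10_p = -log10(pval), flag = flag,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write scan results as a Manhattan-style TSV
#'
#' Floating point columns are written at 6 significant digits.
#' @param scan data.frame from [gwasScan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScanTSV <- function(scan, path) {
  out <- scan
  for (cl in c("beta", "lambda", "lrt", "p_value", "minus_log10_p")) {
    out[[cl]] <- signif(out[[cl]], 6)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
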
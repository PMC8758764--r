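#' Construct a GenotypeMatrix
#'
#' @param dosage samples x variants numeric matrix of alternate-allele
#'   dosages (0/1/2, NA = missing); row names are sample ids.
#' @param variants data.frame with `id`, `chrom`, `pos` for each column; when
#'   omitted, placeholder coordinates are generated.
#' @return a [GenotypeMatrix-class]
#' @export
genotypeMatrix <- function(dosage, variants = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(variants)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- sprintf("var%04d", seq_len(ncol(dosage)))
    variants <- data.frame(id = ids, chrom = "1",
                           pos = seq_len(ncol(dosage)),
                           stringsAsFactors = FALSE)
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$id
  new("GenotypeMatrix", dosage = dosage, variants = variants)
}

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @rdname variantInfo
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) x@variants)

#' @describeIn genotypeMatrix number of samples and variants
#' @param x a `GenotypeMatrix`
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosage))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dim(object@dosage)
  miss <- mean(is.na(object@dosage))
  cat("GenotypeMatrix: ", d[1], " samples x ", d[2], " variants (",
      sprintf("%.1f", 100 * miss), "% missing)\n", sep = "")
})

#' Combine genotype matrices column-wise
#'
#' Adds variants (columns) for the same samples, e.g. appending the
#' split-read-genotyped structural variant to a background marker set the way
#' the SV genotype is added to an existing call set before association
#' mapping.
#' @param x,y `GenotypeMatrix` objects over identical samples.
#' @return a [GenotypeMatrix-class]
#' @export
bindVariants <- function(x, y) {
  stopifnot(is(x, "GenotypeMatrix"), is(y, "GenotypeMatrix"))
  if (!identical(rownames(x@dosage), rownames(y@dosage))) {
    stop("sample sets differ")
  }
  new("GenotypeMatrix",
      dosage = cbind(x@dosage, y@dosage),
      variants = rbind(x@variants, y@variants))
}

## genotype string (VCF GT) <-> dosage
gtToDosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_real_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  out[gt %in% c("1/1", "1|1")] <- 2
  out
}

dosageToGT <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0] <- "0/0"
  out[!is.na(d) & d == 1] <- "0/1"
  out[!is.na(d) & d == 2] <- "1/1"
  out
}

#' Write a GenotypeMatrix as a VCF 4.2 file with GT fields
#'
#' Biallelic sites only; ref/alt alleles are written as placeholder A/G for
#' simulated markers unless supplied in the variants table (`ref`, `alt`
#' columns).
#' @param gm a [GenotypeMatrix-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVCF <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  v <- gm@variants
  ref <- if ("ref" %in% names(v)) v$ref else rep("A", nrow(v))
  alt <- if ("alt" %in% names(v)) v$alt else rep("G", nrow(v))
  samples <- rownames(gm@dosage)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=goldscan",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(j) {
    gts <- dosageToGT(gm@dosage[, j])
    paste(c(v$chrom[j], v$pos[j], v$id[j], ref[j], alt[j], ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read GT-based dosages from a VCF file
#'
#' Uses \pkg{vcfR}; multi-allelic records are rejected.
#' @param path VCF path.
#' @return a [GenotypeMatrix-class]
#' @export
readGenotypeVCF <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix[, , drop = FALSE], stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic records are not supported")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- t(matrix(gtToDosage(gt), nrow = nrow(gt),
                     dimnames = dimnames(gt)))
  variants <- data.frame(
    id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  new("GenotypeMatrix", dosage = dosage, variants = variants)
}
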
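#' Cross-tabulate genotypes against phenotypes
#'
#' Builds the 3x2 genotype-by-morph count table (dd/Gd/GG x dark/gold)
#' underlying penetrance bookkeeping. No-call genotypes are excluded from the
#' table but tallied separately. Unknown genotype or phenotype labels are
#' rejected.
#'
#' @param cohort data.frame with one row per individual.
#' @param genotypeCol,phenotypeCol column names holding the genotype
#'   (dd/Gd/GG/no-call) and phenotype (dark/gold).
#' @return a [ConcordanceTable-class].
#' @examples
#' cohort <- data.frame(
#'   g = c(rep("dd", 10), rep("Gd", 5)),
#'   p = c(rep("dark", 10), rep("gold", 5)))
#' concordanceTable(cohort, "g", "p")
#' @export
concordanceTable <- function(cohort, genotypeCol = "called_genotype",
                             phenotypeCol = "phenotype") {
  g <- cohort[[genotypeCol]]
  p <- cohort[[phenotypeCol]]
  if (is.null(g) || is.null(p)) {
    stop("cohort must contain columns '", genotypeCol, "' and '",
         phenotypeCol, "'")
  }
  okG <- c("dd", "Gd", "GG", "no-call")
  okP <- c("dark", "gold")
  if (any(!g %in% okG)) {
    stop("unknown genotype label(s): ",
         paste(unique(setdiff(g, okG)), collapse = ", "))
  }
  if (any(!p %in% okP)) {
    stop("unknown phenotype label(s): ",
         paste(unique(setdiff(p, okP)), collapse = ", "))
  }
  noCall <- sum(g == "no-call")
  keep <- g != "no-call"
  counts <- table(factor(g[keep], levels = c("dd", "Gd", "GG")),
                  factor(p[keep], levels = c("dark", "gold")))
  m <- matrix(as.integer(counts), nrow = 3,
              dimnames = list(c("dd", "Gd", "GG"), c("dark", "gold")))
  new("ConcordanceTable", counts = m, noCall = as.integer(noCall))
}

#' @rdname counts
#' @export
setMethod("counts", "ConcordanceTable", function(x) x@counts)

setMethod("show", "ConcordanceTable", function(object) {
  cat("ConcordanceTable (", sum(object@counts), " individuals, ",
      object@noCall, " no-call)\n", sep = "")
  print(object@counts)
})

## round half-even to one decimal, as a percentage of count/total;
## undefined (NA) when total is zero rather than 0
.pct1 <- function(count, total) {
  if (total == 0L) return(NA_real_)
  round(100 * count / total, 1)
}

#' Genotype-phenotype conflict rates
#'
#' From a concordance table, counts the individuals whose phenotype conflicts
#' with strict dominance: dark individuals carrying at least one insertion (G)
#' allele (interpreted as not-yet-transformed carriers) and gold individuals
#' without one (phenocopies). Percentages are of the respective phenotype
#' total, rounded half-even to one decimal; a zero phenotype total yields an
#' undefined (NA) percentage, never 0.
#'
#' @param tab a [ConcordanceTable-class].
#' @return list with `n_dark_with_G`, `dark_total`, `pct_dark_with_G`,
#'   `n_gold_dd`, `gold_total`, `pct_gold_dd`.
#' @examples
#' m <- matrix(c(177L, 8L, 0L, 1L, 29L, 58L), nrow = 3, byrow = FALSE,
#'             dimnames = list(c("dd", "Gd", "GG"), c("dark", "gold")))
#' conflictRates(new("ConcordanceTable", counts = m, noCall = 0L))
#' @export
conflictRates <- function(tab) {
  stopifnot(is(tab, "ConcordanceTable"))
  m <- tab@counts
  darkTotal <- sum(m[, "dark"])
  goldTotal <- sum(m[, "gold"])
  nDarkG <- m["Gd", "dark"] + m["GG", "dark"]
  nGoldDD <- m["dd", "gold"]
  list(
    n_dark_with_G = as.integer(nDarkG),
    dark_total = as.integer(darkTotal),
    pct_dark_with_G = .pct1(nDarkG, darkTotal),
    n_gold_dd = as.integer(nGoldDD),
    gold_total = as.integer(goldTotal),
    pct_gold_dd = .pct1(nGoldDD, goldTotal)
  )
}

#' Signed distance between two genomic coordinates in kilobases
#'
#' Accepts `"chrom:pos"` strings (commas in positions allowed) or bare
#' positions; both coordinates must be on the same chromosome. The distance is
#' (b - a)/1000, rounded half-even to one decimal, with sign preserved
#' (negative = b lies before a).
#'
#' @param a,b coordinates, e.g. `"11:7,069,471"` or `7069471`.
#' @return numeric distance in kb.
#' @examples
#' peakDistance("11:7,069,471", "11:7,063,765")  # -5.7
#' @export
peakDistance <- function(a, b) {
  parse1 <- function(x) {
    if (is.character(x) && grepl(":", x, fixed = TRUE)) {
      parts <- strsplit(x, ":", fixed = TRUE)[[1]]
      list(chrom = parts[1], pos = as.numeric(gsub(",", "", parts[2])))
    } else {
      list(chrom = NA_character_, pos = as.numeric(gsub(",", "", x)))
    }
  }
  pa <- parse1(a)
  pb <- parse1(b)
  if (!is.na(pa$chrom) && !is.na(pb$chrom) && pa$chrom != pb$chrom) {
    stop("coordinates lie on different chromosomes (", pa$chrom, " vs ",
         pb$chrom, ")")
  }
  round((pb$pos - pa$pos) / 1000, 1)
}

#' Write concordance results
#'
#' @param tab a [ConcordanceTable-class].
#' @param rates output of [conflictRates()] (computed if NULL).
#' @param path output path; JSON for a `.json` extension, TSV otherwise.
#' @return `path`, invisibly.
#' @export
writeConcordance <- function(tab, path, rates = NULL) {
  if (is.null(rates)) rates <- conflictRates(tab)
  if (grepl("\\.json$", path)) {
    obj <- list(counts = as.data.frame(as.table(tab@counts),
                                       stringsAsFactors = FALSE),
                no_call = tab@noCall, conflicts = rates)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(as.table(tab@counts), stringsAsFactors = FALSE)
    names(df) <- c("genotype", "phenotype", "count")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
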
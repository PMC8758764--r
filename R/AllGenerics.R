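#' @rdname LocusModel-class
#' @param object,x a `LocusModel`
#' @export
setGeneric("refHaplotype", function(x) standardGeneric("refHaplotype"))

#' @rdname LocusModel-class
#' @export
setGeneric("altHaplotype", function(x) standardGeneric("altHaplotype"))

#' @rdname LocusModel-class
#' @export
setGeneric("insertionSeq", function(x) standardGeneric("insertionSeq"))

#' Breakpoint accessor
#'
#' 1-based reference coordinate of the base immediately left of the insertion.
#' @param x a `LocusModel` or `InsertionCall`
#' @export
setGeneric("breakpoint", function(x) standardGeneric("breakpoint"))

#' Dosage matrix accessor
#' @param x a `GenotypeMatrix`
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Variant coordinate table accessor
#' @param x a `GenotypeMatrix`
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' Inserted sequence accessor
#' @param x an `InsertionCall`
#' @export
setGeneric("insertedSeq", function(x) standardGeneric("insertedSeq"))

#' Arm difference table accessor
#' @param x an `InvertedRepeatReport`
#' @export
setGeneric("armDifferences", function(x) standardGeneric("armDifferences"))

#' Count matrix accessor
#' @param x a `ConcordanceTable`
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
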
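#' Is an allele pair strand-ambiguous?
#'
#' A biallelic SNP is ambiguous (palindromic, cryptic) when its allele pair is
#' its own reverse complement -- A/T or C/G -- so the strand cannot be
#' determined from the allele letters alone. Called on a
#' [GenotypeData-class] object it returns one logical per variant (variants
#' with an unknown second allele count as non-ambiguous: they are excluded
#' from alignment as monomorphic long before strand matters).
#'
#' @param a Character vector of first alleles, or a `GenotypeData` object.
#' @param b Character vector of second alleles (recycled against `a`);
#'   missing when `a` is a `GenotypeData`.
#' @param ... Unused.
#' @return Logical vector: `TRUE` for A/T and C/G pairs, `FALSE` otherwise.
#' @examples
#' isAmbiguous("A", "T")  # TRUE
#' isAmbiguous("T", "G")  # FALSE
#' @export
setGeneric("isAmbiguous", function(a, b, ...) standardGeneric("isAmbiguous"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("variantIds<-", function(x, value) standardGeneric("variantIds<-"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("alleleA", function(x) standardGeneric("alleleA"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("alleleB", function(x) standardGeneric("alleleB"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("isPhased", function(x) standardGeneric("isPhased"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("hasProbabilities", function(x) standardGeneric("hasProbabilities"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("haplotypeCalls", function(x) standardGeneric("haplotypeCalls"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("genotypeProbabilities",
           function(x) standardGeneric("genotypeProbabilities"))

#' @rdname swapStrand
#' @export
setGeneric("swapStrand", function(x, i, ...) standardGeneric("swapStrand"))

#' @rdname HarmonizationResult-class
#' @export
setGeneric("alignedData", function(x) standardGeneric("alignedData"))

#' @rdname HarmonizationResult-class
#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))

#' @rdname HarmonizationResult-class
#' @export
setGeneric("actionCounts", function(x) standardGeneric("actionCounts"))
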
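#' GenotypeData: a variant-by-sample genotype container
#'
#' `GenotypeData` extends
#' [SummarizedExperiment::RangedSummarizedExperiment]. Variants live in
#' `rowRanges(x)` (width-1 ranges; metadata columns `alleleA`, `alleleB`),
#' samples in the columns. The mandatory `"calls"` assay holds genotypes as
#' counts of `alleleB` copies: 0, 1, 2 or `NA` for missing. Optional assays:
#'
#' * `"hapA"`, `"hapB"` -- phased haplotype alleles per sample, coded as the
#'   B-allele count (0 or 1) of each of the two haplotypes;
#' * `"probAA"`, `"probAB"`, `"probBB"` -- per-genotype posterior probability
#'   triplets as carried by Oxford GEN files.
#'
#' Invariants enforced by the validity method: alleles are canonical A/C/G/T
#' (`alleleB` may be `NA` for a variant whose second allele is unobservable,
#' e.g. one monomorphic in a PLINK text file) and differ within a variant;
#' positions are >= 1; variants are sorted by position within contiguous
#' chromosome blocks; where phase is present the unphased call equals the sum
#' of the two haplotype B-counts; probability triplets are non-negative and
#' sum to at most 1 + 1e-6.
#'
#' @seealso [readGenotypes()], [writeGenotypes()], [harmonize()]
#' @aliases GenotypeData-class
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

.normChrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

.validGenotypeData <- function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!("calls" %in% an)) {
    return("assay 'calls' is required")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  if (!all(c("alleleA", "alleleB") %in% colnames(mc))) {
    return("rowRanges must carry 'alleleA' and 'alleleB' metadata columns")
  }
  aA <- as.character(mc$alleleA)
  aB <- as.character(mc$alleleB)
  if (any(!(aA %in% CANONICAL_ALLELES))) {
    msg <- c(msg, "alleleA contains non-canonical alleles")
  }
  if (any(!(aB %in% CANONICAL_ALLELES) & !is.na(aB))) {
    msg <- c(msg, "alleleB contains non-canonical alleles")
  }
  same <- !is.na(aB) & aA == aB
  if (any(same, na.rm = TRUE)) {
    msg <- c(msg, "alleleA and alleleB must differ (biallelic SNPs only)")
  }
  if (length(rr) && any(BiocGenerics::start(rr) < 1L)) {
    msg <- c(msg, "positions must be >= 1")
  }
  chrom <- .normChrom(GenomicRanges::seqnames(rr))
  if (length(chrom) > 1L) {
    blocks <- rle(chrom)$values
    if (anyDuplicated(blocks)) {
      msg <- c(msg, "variants of one chromosome must form a contiguous block")
    }
    pos <- BiocGenerics::start(rr)
    updown <- diff(pos) < 0 & chrom[-1L] == chrom[-length(chrom)]
    if (any(updown)) {
      msg <- c(msg, "positions must be non-decreasing within each chromosome")
    }
  }
  calls <- SummarizedExperiment::assay(object, "calls")
  if (any(!(calls %in% c(0L, 1L, 2L)) & !is.na(calls))) {
    msg <- c(msg, "genotype calls must be 0, 1, 2 or NA")
  }
  if (all(c("hapA", "hapB") %in% an)) {
    hA <- SummarizedExperiment::assay(object, "hapA")
    hB <- SummarizedExperiment::assay(object, "hapB")
    if (any(!(hA %in% c(0L, 1L)) & !is.na(hA)) ||
        any(!(hB %in% c(0L, 1L)) & !is.na(hB))) {
      msg <- c(msg, "haplotype assays must be 0, 1 or NA")
    }
    ok <- !is.na(hA) & !is.na(hB)
    if (any(calls[ok] != (hA + hB)[ok], na.rm = TRUE) ||
        any(is.na(calls[ok]))) {
      msg <- c(msg, "calls must equal hapA + hapB wherever phase is present")
    }
  } else if (any(c("hapA", "hapB") %in% an)) {
    msg <- c(msg, "phased data needs both 'hapA' and 'hapB' assays")
  }
  pn <- c("probAA", "probAB", "probBB")
  if (all(pn %in% an)) {
    s <- SummarizedExperiment::assay(object, "probAA") +
      SummarizedExperiment::assay(object, "probAB") +
      SummarizedExperiment::assay(object, "probBB")
    if (any(s > 1 + 1e-6, na.rm = TRUE)) {
      msg <- c(msg, "probability triplets must sum to at most 1 + 1e-6")
    }
    neg <- vapply(pn, function(p)
      any(SummarizedExperiment::assay(object, p) < 0, na.rm = TRUE),
      logical(1))
    if (any(neg)) msg <- c(msg, "probabilities must be non-negative")
  } else if (any(pn %in% an)) {
    msg <- c(msg, "probability data needs all of probAA/probAB/probBB")
  }
  if (length(msg)) msg else TRUE
}

setValidity("GenotypeData", .validGenotypeData)

#' Construct a GenotypeData object
#'
#' @param variants `data.frame` with columns `id`, `chrom`, `pos`, `alleleA`,
#'   `alleleB` (one row per variant). Rows are sorted by position within
#'   chromosome; chromosome blocks keep their order of first appearance.
#' @param samples Character vector of sample identifiers.
#' @param calls Variant-by-sample matrix of alleleB copy counts
#'   (0/1/2/`NA`).
#' @param hapA,hapB Optional variant-by-sample matrices of per-haplotype
#'   B-allele indicators (0/1/`NA`); both or neither. When given and `calls`
#'   is `NULL`, calls are derived as `hapA + hapB`.
#' @param probAA,probAB,probBB Optional probability matrices; all or none.
#' @return A validated [GenotypeData-class] object.
#' @examples
#' v <- data.frame(id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'                 alleleA = c("A", "C"), alleleB = c("C", "G"))
#' g <- GenotypeData(v, c("s1", "s2"),
#'                   calls = matrix(c(0L, 1L, 2L, 1L), nrow = 2))
#' genotypeCalls(g)
#' @export
GenotypeData <- function(variants, samples, calls = NULL,
                         hapA = NULL, hapB = NULL,
                         probAA = NULL, probAB = NULL, probBB = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "alleleA", "alleleB") %in%
                  colnames(variants)))
  samples <- as.character(samples)
  ord <- order(factor(.normChrom(variants$chrom),
                      levels = unique(.normChrom(variants$chrom))),
               variants$pos)
  variants <- variants[ord, , drop = FALSE]
  reorder_m <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    dimnames(m) <- NULL
    m[ord, , drop = FALSE]
  }
  calls <- reorder_m(calls)
  hapA <- reorder_m(hapA)
  hapB <- reorder_m(hapB)
  if (!is.null(hapA)) {
    storage.mode(hapA) <- "integer"
    storage.mode(hapB) <- "integer"
    if (is.null(calls)) calls <- hapA + hapB
  }
  if (is.null(calls)) stop("either 'calls' or phased haplotypes are required")
  storage.mode(calls) <- "integer"
  assays <- list(calls = calls)
  if (!is.null(hapA)) assays <- c(assays, list(hapA = hapA, hapB = hapB))
  if (!is.null(probAA)) {
    assays <- c(assays, list(probAA = reorder_m(probAA),
                             probAB = reorder_m(probAB),
                             probBB = reorder_m(probBB)))
  }
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = as.integer(variants$pos), width = 1L))
  names(rr) <- as.character(variants$id)
  S4Vectors::mcols(rr)$alleleA <- as.character(variants$alleleA)
  S4Vectors::mcols(rr)$alleleB <- as.character(variants$alleleB)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = rr,
    colData = S4Vectors::DataFrame(row.names = samples))
  methods::new("GenotypeData", se)
}

#' Accessors for GenotypeData
#'
#' @param x A [GenotypeData-class] object.
#' @param value Replacement character vector of variant identifiers.
#' @return `variantIds`, `sampleIds`, `chromosomes`, `alleleA`, `alleleB`
#'   return character vectors; `positions` an integer vector; `genotypeCalls`
#'   the integer calls matrix; `isPhased`/`hasProbabilities` a logical;
#'   `haplotypeCalls` a list of the two haplotype matrices (or `NULL`);
#'   `genotypeProbabilities` a list of the three probability matrices (or
#'   `NULL`).
#' @name GenotypeData-accessors
NULL

#' @rdname GenotypeData-accessors
#' @export
setMethod("variantIds", "GenotypeData", function(x) {
  names(SummarizedExperiment::rowRanges(x))
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("variantIds<-", "GenotypeData", function(x, value) {
  rr <- SummarizedExperiment::rowRanges(x)
  names(rr) <- as.character(value)
  SummarizedExperiment::rowRanges(x) <- rr
  x
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("sampleIds", "GenotypeData", function(x) colnames(x))

#' @rdname GenotypeData-accessors
#' @export
setMethod("chromosomes", "GenotypeData", function(x) {
  as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x)))
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("positions", "GenotypeData", function(x) {
  BiocGenerics::start(SummarizedExperiment::rowRanges(x))
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("alleleA", "GenotypeData", function(x) {
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$alleleA
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("alleleB", "GenotypeData", function(x) {
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$alleleB
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("genotypeCalls", "GenotypeData", function(x) {
  SummarizedExperiment::assay(x, "calls")
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("isPhased", "GenotypeData", function(x) {
  all(c("hapA", "hapB") %in% SummarizedExperiment::assayNames(x))
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("hasProbabilities", "GenotypeData", function(x) {
  all(c("probAA", "probAB", "probBB") %in%
        SummarizedExperiment::assayNames(x))
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("haplotypeCalls", "GenotypeData", function(x) {
  if (!isPhased(x)) return(NULL)
  list(hapA = SummarizedExperiment::assay(x, "hapA"),
       hapB = SummarizedExperiment::assay(x, "hapB"))
})

#' @rdname GenotypeData-accessors
#' @export
setMethod("genotypeProbabilities", "GenotypeData", function(x) {
  if (!hasProbabilities(x)) return(NULL)
  list(probAA = SummarizedExperiment::assay(x, "probAA"),
       probAB = SummarizedExperiment::assay(x, "probAB"),
       probBB = SummarizedExperiment::assay(x, "probBB"))
})

#' @rdname isAmbiguous
#' @export
setMethod("isAmbiguous", signature("character", "character"),
          function(a, b, ...) .isAmbiguousPair(a, b))

#' @rdname isAmbiguous
#' @export
setMethod("isAmbiguous", signature("GenotypeData", "missing"),
          function(a, b, ...) {
            out <- .isAmbiguousPair(alleleA(a), alleleB(a))
            out[is.na(out)] <- FALSE  # unknown second allele: not alignable anyway
            out
          })

#' Swap the genomic strand of variants
#'
#' Relabels the alleles of the selected variants by their Watson-Crick
#' complements. Genotype calls are untouched: a strand swap changes allele
#' letters, never B-allele counts, so ambiguity status is preserved and the
#' operation is an involution.
#'
#' @param x A [GenotypeData-class] object.
#' @param i Variant selector (integer or logical index); defaults to all
#'   variants.
#' @param ... Unused.
#' @return `x` with the selected variants' alleles complemented.
#' @examples
#' v <- data.frame(id = "rs1", chrom = "1", pos = 100L,
#'                 alleleA = "A", alleleB = "C")
#' g <- GenotypeData(v, "s1", calls = matrix(1L))
#' alleleA(swapStrand(g))  # "T"
#' @export
setMethod("swapStrand", "GenotypeData", function(x, i, ...) {
  if (missing(i)) i <- seq_len(nrow(x))
  rr <- SummarizedExperiment::rowRanges(x)
  mc <- S4Vectors::mcols(rr)
  mc$alleleA[i] <- complementAllele(mc$alleleA[i])
  mc$alleleB[i] <- complementAllele(mc$alleleB[i])
  S4Vectors::mcols(rr) <- mc
  SummarizedExperiment::rowRanges(x) <- rr
  methods::validObject(x)
  x
})

.isAmbiguousPair <- function(a, b) {
  .checkAlleles(a, allow_na = TRUE)
  .checkAlleles(b, allow_na = TRUE)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  ifelse(is.na(a) | is.na(b), NA, unname(.COMPLEMENT[a]) == b)
}

#' @describeIn GenotypeData-accessors Compact display.
#' @param object A `GenotypeData` object.
#' @export
setMethod("show", "GenotypeData", function(object) {
  amb <- isAmbiguous(object)
  cat("GenotypeData:", nrow(object), "variants x", ncol(object), "samples\n")
  cat("  chromosomes:",
      paste(unique(chromosomes(object)), collapse = ", "), "\n")
  cat("  ambiguous (A/T, C/G) variants:", sum(amb), "\n")
  cat("  phased:", isPhased(object),
      "| probabilities:", hasProbabilities(object), "\n")
})
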
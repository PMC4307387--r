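#' Canonical nucleotide alleles
#'
#' The four canonical single-nucleotide alleles handled by the package.
#' Indels, multi-base alleles and IUPAC ambiguity codes are not representable;
#' readers skip such records.
#'
#' @format A character vector `c("A", "C", "G", "T")`.
#' @export
CANONICAL_ALLELES <- c("A", "C", "G", "T")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.checkAlleles <- function(x, allow_na = FALSE) {
  bad <- !(x %in% CANONICAL_ALLELES)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop("non-canonical allele(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (only A/C/G/T are allowed)", call. = FALSE)
  }
  invisible(x)
}

#' Watson-Crick complement of alleles
#'
#' Maps each allele to its complement on the opposite genomic strand
#' (A<->T, C<->G). A SNP coded T/G on the forward strand is coded A/C on the
#' reverse strand; complementation is an involution.
#'
#' @param x Character vector of alleles in `A`, `C`, `G`, `T`. `NA` values
#'   (unknown allele of a monomorphic variant) pass through as `NA`.
#' @return Character vector of complemented alleles, same length as `x`.
#' @examples
#' complementAllele(c("T", "G"))  # "A" "C"
#' @export
complementAllele <- function(x) {
  .checkAlleles(x, allow_na = TRUE)
  out <- unname(.COMPLEMENT[x])
  out[is.na(x)] <- NA_character_
  out
}

#' Allele-B frequency and minor allele frequency from genotype calls
#'
#' Genotype calls count copies of alleleB, so the alleleB frequency of a call
#' vector is `(n_het + 2 n_homB) / (2 n_nonmissing)`; the minor allele
#' frequency (MAF) is `min(f, 1 - f)`.
#'
#' @param calls Integer/numeric vector of genotypes in `{0, 1, 2}`, `NA` for
#'   missing; or a variants-by-samples matrix (one frequency per row).
#' @return For `alleleBFreq`, frequency in `[0, 1]`; for `mafFromCalls`,
#'   frequency in `[0, 0.5]`. One value per variant.
#' @examples
#' alleleBFreq(c(0L, 1L, 2L, NA))  # 0.5
#' mafFromCalls(rep(c(0L, 1L), c(6, 4)))  # 0.2
#' @export
alleleBFreq <- function(calls) {
  if (is.matrix(calls)) {
    return(apply(calls, 1L, alleleBFreq))
  }
  ok <- !is.na(calls)
  if (!any(ok)) {
    stop("allele frequency undefined: all genotype calls are missing",
         call. = FALSE)
  }
  if (any(!(calls[ok] %in% 0:2))) {
    stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  sum(calls[ok]) / (2 * sum(ok))
}

#' @rdname alleleBFreq
#' @export
mafFromCalls <- function(calls) {
  f <- alleleBFreq(calls)
  pmin(f, 1 - f)
}

#' Hard-call genotypes from probability triplets
#'
#' Converts per-genotype posterior probability triplets (pAA, pAB, pBB), as
#' carried by Oxford GEN files, into discrete 0/1/2 calls. The argmax genotype
#' is returned when the maximum probability reaches `threshold`; otherwise the
#' call is missing. Exact ties for the maximum are uninformative and also give
#' missing. Raising the threshold can only turn calls into missing -- never
#' change one call into another.
#'
#' @param pAA,pAB,pBB Numeric vectors of probabilities in `[0, 1]` (recycled
#'   to a common length). Triplets may sum below 1 (GEN encodes missingness
#'   that way) but not above `1 + 1e-6`.
#' @param threshold Minimum posterior probability required to emit a call.
#'   Default 0.4.
#' @return Integer vector of genotypes in `{0, 1, 2}` with `NA` for missing.
#' @examples
#' hardCall(0.95, 0.04, 0.01)            # 0
#' hardCall(0.35, 0.33, 0.32)            # NA (below threshold)
#' hardCall(0.2, 0.5, 0.3, threshold = 0.4)  # 1
#' @export
hardCall <- function(pAA, pAB, pBB, threshold = 0.4) {
  n <- max(length(pAA), length(pAB), length(pBB))
  p <- cbind(rep_len(as.numeric(pAA), n),
             rep_len(as.numeric(pAB), n),
             rep_len(as.numeric(pBB), n))
  if (any(p < 0, na.rm = TRUE)) {
    stop("genotype probabilities must be non-negative", call. = FALSE)
  }
  if (any(rowSums(p) > 1 + 1e-6, na.rm = TRUE)) {
    stop("genotype probability triplet sums exceed 1", call. = FALSE)
  }
  pmax <- do.call(pmax, c(as.data.frame(p), na.rm = FALSE))
  tie <- rowSums(p == pmax) > 1L
  out <- max.col(p, ties.method = "first") - 1L
  out[is.na(pmax) | pmax < threshold | tie] <- NA_integer_
  out
}
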
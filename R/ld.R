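## Two-locus haplotype-frequency machinery. Frequency vectors are length-4,
## named f00/f01/f10/f11: first digit = B-allele count at the first locus,
## second digit = B-allele count at the second locus.

.stopDegenerate <- function(msg) {
  stop(errorCondition(msg, class = c("degenerateLD", "error", "condition")))
}
.stopInsufficient <- function(msg) {
  stop(errorCondition(msg, class = c("insufficientData", "error", "condition")))
}

.hapFreqNames <- c("f00", "f01", "f10", "f11")

#' Two-locus haplotype frequencies from phased haplotypes
#'
#' When phase is known, two-locus haplotype frequencies are direct relative
#' counts of the four haplotype classes; no estimation is involved.
#'
#' @param hapsX,hapsY Equal-length vectors of per-haplotype B-allele
#'   indicators (0/1, `NA` for missing) at the two loci. Haplotypes missing at
#'   either locus are dropped pairwise.
#' @return Named numeric 4-vector `(f00, f01, f10, f11)` summing to 1, where
#'   the digits are the B-allele counts at the first and second locus.
#' @examples
#' hapFreqsPhased(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 0.5 0 0 0.5
#' @export
hapFreqsPhased <- function(hapsX, hapsY) {
  if (length(hapsX) != length(hapsY)) {
    stop("haplotype vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(hapsX) & !is.na(hapsY)
  hx <- hapsX[ok]
  hy <- hapsY[ok]
  if (length(hx) < 2L) {
    .stopInsufficient("fewer than 2 complete haplotype pairs")
  }
  if (any(!(hx %in% c(0, 1))) || any(!(hy %in% c(0, 1)))) {
    stop("haplotype alleles must be coded 0/1", call. = FALSE)
  }
  counts <- tabulate(2L * hx + hy + 1L, nbins = 4L)
  setNames(counts / sum(counts), .hapFreqNames)
}

#' Two-locus haplotype frequencies from unphased genotypes (EM)
#'
#' Maximum-likelihood estimation of the four two-locus haplotype frequencies
#' from unphased genotype calls. Phase is observable for every genotype
#' combination except the double heterozygote, which the EM algorithm splits
#' between the coupling (00/11) and repulsion (01/10) gamete pairs in
#' proportion to their current likelihood. Initialisation is at linkage
#' equilibrium (the product of the observed allele frequencies), which is
#' deterministic; the log-likelihood is non-decreasing across iterations.
#'
#' @param callsX,callsY Equal-length genotype vectors (0/1/2/`NA`, counting
#'   B alleles). Samples missing at either locus are dropped pairwise.
#' @param tol Convergence tolerance on the maximum absolute frequency change
#'   per iteration. Default 1e-6.
#' @param maxIter Iteration cap. Default 100.
#' @param minSamples Minimum pairwise-complete sample count. Default 10.
#' @param checkLikelihood If `TRUE`, assert the monotone-likelihood invariant
#'   at every iteration (debugging aid).
#' @return Named numeric 4-vector as in [hapFreqsPhased()].
#' @section Errors: a locus monomorphic among the complete samples raises a
#'   `degenerateLD` condition; too few complete samples raises
#'   `insufficientData`.
#' @examples
#' gx <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1, 0, 2)
#' gy <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1, 0, 2)
#' hapFreqsEM(gx, gy)  # strong coupling: f00 and f11 dominate
#' @export
hapFreqsEM <- function(callsX, callsY, tol = 1e-6, maxIter = 100L,
                       minSamples = 10L, checkLikelihood = FALSE) {
  if (length(callsX) != length(callsY)) {
    stop("genotype vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(callsX) & !is.na(callsY)
  gx <- as.integer(callsX[ok])
  gy <- as.integer(callsY[ok])
  nc <- length(gx)
  if (nc < minSamples) {
    .stopInsufficient(sprintf(
      "only %d pairwise-complete samples (minimum %d)", nc, minSamples))
  }
  n <- tabulate(3L * gx + gy + 1L, nbins = 9L)  # n[3*gx+gy+1]
  .emFromCounts(matrix(n, nrow = 3L, byrow = TRUE), tol, maxIter,
                checkLikelihood)
}

## EM on a 3x3 genotype count table n[gx+1, gy+1].
.emFromCounts <- function(n, tol = 1e-6, maxIter = 100L,
                          checkLikelihood = FALSE) {
  N <- sum(n)
  px <- sum(n * matrix(0:2, 3, 3)) / (2 * N)        # B freq at locus X
  py <- sum(n * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
  if (px <= 0 || px >= 1 || py <= 0 || py >= 1) {
    .stopDegenerate("monomorphic locus: haplotype frequencies are degenerate")
  }
  .emCore(n, N, px, py, tol, maxIter, checkLikelihood)
}

.emCore <- function(n, N, px, py, tol = 1e-6, maxIter = 100L,
                    checkLikelihood = FALSE) {
  ## gamete counts fixed by single-phase genotypes (all cells but the
  ## double heterozygote n[2,2])
  base <- c(
    `00` = 2 * n[1, 1] + n[1, 2] + n[2, 1],
    `01` = 2 * n[1, 3] + n[1, 2] + n[2, 3],
    `10` = 2 * n[3, 1] + n[3, 2] + n[2, 1],
    `11` = 2 * n[3, 3] + n[3, 2] + n[2, 3])
  nDH <- n[2, 2]
  f <- c((1 - px) * (1 - py), (1 - px) * py, px * (1 - py), px * py)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    denom <- f[1] * f[4] + f[2] * f[3]
    p <- if (denom > 0) f[1] * f[4] / denom else 0.5
    counts <- base + nDH * c(p, 1 - p, 1 - p, p)
    fNew <- counts / (2 * N)
    if (checkLikelihood) {
      llNew <- .pairLogLik(n, fNew)
      stopifnot(llNew >= ll - 1e-9)
      ll <- llNew
    }
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol) break
  }
  setNames(f, .hapFreqNames)
}

## Multinomial log-likelihood of a 3x3 genotype table under random union of
## gametes with haplotype frequencies f = (f00, f01, f10, f11).
.pairLogLik <- function(n, f) {
  P <- .genoProbsFromHapFreqs(f)
  sum(n[n > 0] * log(P[n > 0]))
}

.genoProbsFromHapFreqs <- function(f) {
  f00 <- f[1]; f01 <- f[2]; f10 <- f[3]; f11 <- f[4]
  P <- matrix(0, 3, 3)
  P[1, 1] <- f00^2
  P[1, 2] <- 2 * f00 * f01
  P[1, 3] <- f01^2
  P[2, 1] <- 2 * f00 * f10
  P[2, 2] <- 2 * (f00 * f11 + f01 * f10)
  P[2, 3] <- 2 * f01 * f11
  P[3, 1] <- f10^2
  P[3, 2] <- 2 * f10 * f11
  P[3, 3] <- f11^2
  P
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' Computes the signed disequilibrium coefficient `D = f11 - px * py` (equal
#' to `f00 - (1-px)(1-py)`) and the squared correlation
#' `r2 = D^2 / (px (1-px) py (1-py))`, where `px`, `py` are the B-allele
#' frequencies at the two loci.
#'
#' @param f Haplotype frequency 4-vector as returned by [hapFreqsPhased()] or
#'   [hapFreqsEM()].
#' @return A list with elements `D` and `r2`.
#' @examples
#' ldStats(c(0.25, 0.25, 0.25, 0.25))  # D = 0, r2 = 0
#' ldStats(c(0.5, 0, 0, 0.5))          # D = 0.25, r2 = 1
#' @export
ldStats <- function(f) {
  f <- as.numeric(f)
  stopifnot(length(f) == 4L)
  if (abs(sum(f) - 1) > 1e-6 || any(f < -1e-12)) {
    stop("haplotype frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }
  px <- f[3] + f[4]
  py <- f[2] + f[4]
  if (px <= 0 || px >= 1 || py <= 0 || py >= 1) {
    .stopDegenerate("marginal allele frequency of 0 or 1: LD undefined")
  }
  D <- f[4] - px * py
  list(D = D, r2 = D^2 / (px * (1 - px) * py * (1 - py)))
}

#' Correlation of haplotype frequencies between two datasets
#'
#' The strand-decision signal for ambiguous SNPs: the Pearson correlation of
#' the four two-locus haplotype-class frequencies estimated in the study and
#' in the reference, with the haplotype classes matched by allele letter
#' between datasets beforehand. When the ambiguous SNP is on the same strand
#' in both datasets the correlation is positive; a strand flip permutes the
#' classes `(f00, f01, f10, f11) -> (f01, f00, f11, f10)` and drives it
#' negative.
#'
#' @param fStudy,fRef Aligned haplotype frequency 4-vectors.
#' @return Pearson correlation in `[-1, 1]`, or `NA` when either vector has
#'   zero variance (an uninformative pair the caller must skip).
#' @examples
#' f <- c(0.5, 0, 0, 0.5)
#' hapFreqCorrelation(f, f)               # +1
#' hapFreqCorrelation(f, f[c(2, 1, 4, 3)])  # -1 (strand flip image)
#' @export
hapFreqCorrelation <- function(fStudy, fRef) {
  fStudy <- as.numeric(fStudy)
  fRef <- as.numeric(fRef)
  stopifnot(length(fStudy) == 4L, length(fRef) == 4L)
  if (stats::sd(fStudy) == 0 || stats::sd(fRef) == 0) {
    return(NA_real_)
  }
  stats::cor(fStudy, fRef)
}

## Fast two-locus frequency estimate from raw vectors: direct counting when
## haplotype vectors are supplied, EM on genotype calls otherwise. Returns an
## unnamed 4-vector (f00, f01, f10, f11), or NULL when the pair is degenerate
## (a monomorphic locus) or has too few complete observations. This is the
## hot path of the harmonizer; no conditions are raised.
.pairFreqsFast <- function(cx = NULL, cy = NULL, hx = NULL, hy = NULL,
                           minSamples = 10L) {
  if (!is.null(hx)) {
    ok <- which(!is.na(hx) & !is.na(hy))
    if (length(ok) < 2L * minSamples) return(NULL)
    counts <- tabulate(2L * hx[ok] + hy[ok] + 1L, nbins = 4L)
    f <- counts / length(ok)
    px <- f[3] + f[4]
    py <- f[2] + f[4]
    if (px <= 0 || px >= 1 || py <= 0 || py >= 1) return(NULL)
    return(f)
  }
  ok <- which(!is.na(cx) & !is.na(cy))
  if (length(ok) < minSamples) return(NULL)
  n <- tabulate(3L * cx[ok] + cy[ok] + 1L, nbins = 9L)
  N <- length(ok)
  px <- (n[4] + n[5] + n[6] + 2 * (n[7] + n[8] + n[9])) / (2 * N)
  py <- (n[2] + n[5] + n[8] + 2 * (n[3] + n[6] + n[9])) / (2 * N)
  if (px <= 0 || px >= 1 || py <= 0 || py >= 1) return(NULL)
  unname(.emCore(matrix(n, nrow = 3L, byrow = TRUE), N, px, py))
}

## Best-available haplotype-frequency estimate for loci i and j of a
## GenotypeData: direct counting when phase is present, EM otherwise.
## Returns the 4-vector, or a condition object (degenerateLD /
## insufficientData) instead of signalling.
.pairHapFreqs <- function(g, i, j, minSamples = 10L) {
  res <- tryCatch({
    if (isPhased(g)) {
      h <- haplotypeCalls(g)
      hx <- c(h$hapA[i, ], h$hapB[i, ])
      hy <- c(h$hapA[j, ], h$hapB[j, ])
      if (sum(!is.na(hx) & !is.na(hy)) < 2L * minSamples) {
        .stopInsufficient("too few complete haplotypes")
      }
      f <- hapFreqsPhased(hx, hy)
      px <- f[3] + f[4]
      py <- f[2] + f[4]
      if (px <= 0 || px >= 1 || py <= 0 || py >= 1) {
        .stopDegenerate("monomorphic locus")
      }
      f
    } else {
      calls <- genotypeCalls(g)
      hapFreqsEM(calls[i, ], calls[j, ], minSamples = minSamples)
    }
  }, degenerateLD = function(c) c, insufficientData = function(c) c)
  res
}
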
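# Independent oracle for the two-locus haplotype-frequency MLE.
#
# The multinomial likelihood of a 3x3 genotype table under random union of
# gametes has the property that every stationary point keeps the marginal
# allele frequencies at their observed values (each genotype reveals its
# allele counts regardless of phase, so re-estimated gamete counts always
# reproduce the observed margins). The MLE therefore lies on a 1-parameter
# family indexed by f11, and a dense grid search over f11 at the observed
# margins is an exhaustive independent maximizer.
oracleHapFreqs <- function(n, step = 1e-4) {
  stopifnot(is.matrix(n), dim(n) == c(3, 3))
  N <- sum(n)
  px <- (sum(n[2, ]) + 2 * sum(n[3, ])) / (2 * N)
  py <- (sum(n[, 2]) + 2 * sum(n[, 3])) / (2 * N)
  lo <- max(0, px + py - 1)
  hi <- min(px, py)
  f11 <- seq(lo, hi, by = step)
  if (f11[length(f11)] < hi) f11 <- c(f11, hi)
  f10 <- px - f11
  f01 <- py - f11
  f00 <- 1 - px - py + f11
  P <- rbind(f00^2, 2 * f00 * f01, f01^2,
             2 * f00 * f10, 2 * (f00 * f11 + f01 * f10), 2 * f01 * f11,
             f10^2, 2 * f10 * f11, f11^2)
  counts <- c(n[1, 1], n[1, 2], n[1, 3],
              n[2, 1], n[2, 2], n[2, 3],
              n[3, 1], n[3, 2], n[3, 3])
  ll <- colSums(counts * log(pmax(P, 1e-300)))
  k <- which.max(ll)
  c(f00[k], f01[k], f10[k], f11[k])
}

# Draw a diploid genotype table from known haplotype frequencies.
sampleGenoTable <- function(f, nInd) {
  h1 <- sample.int(4L, nInd, replace = TRUE, prob = f) - 1L
  h2 <- sample.int(4L, nInd, replace = TRUE, prob = f) - 1L
  gx <- (h1 >= 2L) + (h2 >= 2L)
  gy <- (h1 %% 2L) + (h2 %% 2L)
  matrix(tabulate(3L * gx + gy + 1L, nbins = 9L), nrow = 3L, byrow = TRUE)
}

# Genotype vectors (not just the table) from known haplotype frequencies,
# returning the generating haplotypes too.
sampleGenoVectors <- function(f, nInd) {
  h1 <- sample.int(4L, nInd, replace = TRUE, prob = f) - 1L
  h2 <- sample.int(4L, nInd, replace = TRUE, prob = f) - 1L
  list(gx = (h1 >= 2L) + (h2 >= 2L),
       gy = (h1 %% 2L) + (h2 %% 2L),
       hapX = c(h1 >= 2L, h2 >= 2L) + 0L,
       hapY = c(h1 %% 2L, h2 %% 2L) + 0L)
}
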
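## Seeded generator of LD-structured study/reference cohort pairs with a
## known strand-flip truth table, plus the scorer comparing harmonization
## decisions against that truth.

## Derive independent sub-seeds (one PRNG stream per purpose) from a master
## seed, so e.g. adding variants never perturbs the flip pattern.
.subSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulate a haplotype panel with tunable linkage disequilibrium
#'
#' Generates a pool of haplotypes over `nVariants` biallelic SNPs on one
#' chromosome using a first-order copying chain: the allele of haplotype `h`
#' at locus `i` copies the same haplotype's allele at locus `i - 1` with
#' probability `ldStrength`, and is otherwise drawn from the locus's own
#' marginal frequency (uniform on 0.05--0.95). `ldStrength = 0` gives
#' independent loci; `ldStrength = 1` copies the first locus down the whole
#' chromosome. A fraction `ambiguousFraction` of variants receives an
#' ambiguous allele pair (A/T or C/G); the rest receive a random
#' non-complementary pair. Everything is deterministic given `seed`.
#'
#' @param nVariants,nHaplotypes Panel dimensions (both >= 2).
#' @param ambiguousFraction Fraction of variants given A/T or C/G alleles.
#' @param ldStrength Copying probability of the chain, in `[0, 1]`.
#' @param seed Master seed.
#' @return A list of class `"HaplotypePool"`: `haps` (haplotype-by-variant
#'   0/1 matrix of B-allele indicators), `variants` (data.frame `id`,
#'   `chrom`, `pos`, `alleleA`, `alleleB`), `adjacentHapFreqs` (per
#'   adjacent-pair 4-column matrix of generating haplotype frequencies
#'   `f00, f01, f10, f11`), and `seed`.
#' @export
simulatePanel <- function(nVariants, nHaplotypes, ambiguousFraction = 0.1,
                          ldStrength = 0.9, seed = 1L) {
  stopifnot(nVariants >= 2L, nHaplotypes >= 2L,
            ldStrength >= 0, ldStrength <= 1,
            ambiguousFraction >= 0, ambiguousFraction <= 1)
  seeds <- .subSeeds(seed, 2L)
  haps <- .withSeed(seeds[1L], {
    p <- stats::runif(nVariants, 0.05, 0.95)
    h <- matrix(0L, nrow = nHaplotypes, ncol = nVariants)
    h[, 1L] <- stats::rbinom(nHaplotypes, 1L, p[1L])
    for (i in seq_len(nVariants)[-1L]) {
      copy <- stats::runif(nHaplotypes) < ldStrength
      fresh <- stats::rbinom(nHaplotypes, 1L, p[i])
      h[, i] <- ifelse(copy, h[, i - 1L], fresh)
    }
    h
  })
  variants <- .withSeed(seeds[2L], {
    nAmb <- round(ambiguousFraction * nVariants)
    ambIdx <- sample.int(nVariants, nAmb)
    aA <- character(nVariants)
    aB <- character(nVariants)
    ambPairs <- rbind(c("A", "T"), c("C", "G"))
    nonAmb <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    pickAmb <- ambPairs[sample.int(2L, nAmb, replace = TRUE), , drop = FALSE]
    rest <- setdiff(seq_len(nVariants), ambIdx)
    pickNon <- nonAmb[sample.int(4L, length(rest), replace = TRUE), ,
                      drop = FALSE]
    swapAB <- stats::runif(nVariants) < 0.5  # random A/B orientation
    aA[ambIdx] <- ifelse(swapAB[ambIdx], pickAmb[, 2L], pickAmb[, 1L])
    aB[ambIdx] <- ifelse(swapAB[ambIdx], pickAmb[, 1L], pickAmb[, 2L])
    aA[rest] <- ifelse(swapAB[rest], pickNon[, 2L], pickNon[, 1L])
    aB[rest] <- ifelse(swapAB[rest], pickNon[, 1L], pickNon[, 2L])
    data.frame(id = sprintf("snp%04d", seq_len(nVariants)), chrom = "1",
               pos = 1000L * seq_len(nVariants), alleleA = aA, alleleB = aB)
  })
  x <- haps[, -nVariants, drop = FALSE]
  y <- haps[, -1L, drop = FALSE]
  f11 <- colMeans(x * y)
  f10 <- colMeans(x) - f11
  f01 <- colMeans(y) - f11
  adj <- cbind(f00 = 1 - f11 - f10 - f01, f01 = f01, f10 = f10, f11 = f11)
  structure(list(haps = haps, variants = variants, adjacentHapFreqs = adj,
                 seed = as.integer(seed)),
            class = "HaplotypePool")
}

#' Draw a study/reference cohort pair with known strand flips
#'
#' Samples disjoint sets of pool haplotypes, pairs them into diploid
#' individuals, and strand-swaps a random `flipFraction` of the ambiguous
#' variants in the study copy (allele labels complemented, genotype calls
#' untouched). The returned truth table records exactly which variants were
#' flipped, emulating a split-cohort experiment in which roughly half the
#' ambiguous SNPs of one half are put on the other strand.
#'
#' @param pool A `"HaplotypePool"` from [simulatePanel()].
#' @param nStudy,nRef Diploid cohort sizes.
#' @param flipFraction Per-ambiguous-variant flip probability.
#' @param seed Master seed (independent streams for sampling and flipping).
#' @param phased Keep the generating haplotypes in the returned
#'   [GenotypeData-class] objects (default `FALSE`: unphased calls only).
#' @param replace Sample pool haplotypes with replacement; required when
#'   `2 * (nStudy + nRef)` exceeds the pool size.
#' @return A list: `study`, `ref` (GenotypeData) and `truth` (list with
#'   `flippedIds`, `ambiguousIds`, `variantIds`, `poolHapFreqs`, `seed`).
#' @export
makeStudyRefPair <- function(pool, nStudy, nRef, flipFraction = 0.5,
                             seed = 1L, phased = FALSE, replace = FALSE) {
  stopifnot(inherits(pool, "HaplotypePool"))
  nHapNeeded <- 2L * (nStudy + nRef)
  if (!replace && nHapNeeded > nrow(pool$haps)) {
    stop("pool has ", nrow(pool$haps), " haplotypes; ", nHapNeeded,
         " needed (use replace = TRUE to sample with replacement)",
         call. = FALSE)
  }
  seeds <- .subSeeds(seed, 2L)
  idx <- .withSeed(seeds[1L],
                   sample.int(nrow(pool$haps), nHapNeeded, replace = replace))
  mk <- function(rows, prefix, n) {
    hapA <- t(pool$haps[rows[seq_len(n)], , drop = FALSE])
    hapB <- t(pool$haps[rows[n + seq_len(n)], , drop = FALSE])
    samples <- sprintf("%s%04d", prefix, seq_len(n))
    if (phased) {
      GenotypeData(pool$variants, samples, hapA = hapA, hapB = hapB)
    } else {
      GenotypeData(pool$variants, samples, calls = hapA + hapB)
    }
  }
  study <- mk(idx[seq_len(2L * nStudy)], "study", nStudy)
  ref <- mk(idx[2L * nStudy + seq_len(2L * nRef)], "ref", nRef)
  ambIdx <- which(isAmbiguous(study))
  flipIdx <- .withSeed(seeds[2L],
                       ambIdx[stats::runif(length(ambIdx)) < flipFraction])
  if (length(flipIdx)) study <- swapStrand(study, flipIdx)
  truth <- list(flippedIds = variantIds(study)[flipIdx],
                ambiguousIds = variantIds(study)[ambIdx],
                variantIds = variantIds(study),
                poolHapFreqs = pool$adjacentHapFreqs,
                seed = as.integer(seed))
  list(study = study, ref = ref, truth = truth)
}

#' Score harmonization decisions against simulation truth
#'
#' Confusion counts over the ambiguous variants of a simulated panel:
#' `correctly_flipped` (truly flipped and strand_flipped),
#' `incorrectly_flipped` (unflipped but strand_flipped, plus flipped but left
#' unchanged), `correctly_unchanged`, and `excluded`. The four counts sum to
#' the number of ambiguous variants scored.
#'
#' @param decisions The [decisions()] table of a
#'   [HarmonizationResult-class] (or any data.frame with `variant_id` and
#'   `action` columns).
#' @param truth Truth table from [makeStudyRefPair()].
#' @return Named integer vector of the four counts.
#' @export
scoreAlignment <- function(decisions, truth) {
  decisions <- as.data.frame(decisions)
  unknown <- setdiff(decisions$variant_id, truth$variantIds)
  if (length(unknown)) {
    stop("decision(s) for unknown variant id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  hit <- match(truth$ambiguousIds, decisions$variant_id)
  if (anyNA(hit)) {
    stop("no decision for ambiguous variant(s): ",
         paste(utils::head(truth$ambiguousIds[is.na(hit)], 5L),
               collapse = ", "), call. = FALSE)
  }
  act <- decisions$action[hit]
  flipped <- truth$ambiguousIds %in% truth$flippedIds
  c(correctly_flipped = sum(flipped & act == "strand_flipped"),
    incorrectly_flipped = sum((!flipped & act == "strand_flipped") |
                                (flipped & act == "unchanged")),
    correctly_unchanged = sum(!flipped & act == "unchanged"),
    excluded = sum(!(act %in% c("strand_flipped", "unchanged"))))
}
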
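#' Harmonizer configuration
#'
#' Bundles the tunable thresholds of [harmonize()].
#'
#' @param flankVariants Number of aligned non-ambiguous neighbours considered
#'   on each side of an ambiguous SNP (by variant order on the same
#'   chromosome). Default 100.
#' @param minR2 LD screen: a supporting neighbour must reach this r-squared
#'   with the ambiguous SNP in both the study and the reference. Default 0.3.
#' @param minSupport Minimum number of informative supporting neighbours
#'   required before the haplotype-frequency correlation vote decides a
#'   strand; below it the variant falls through to the MAF rule (if enabled)
#'   or is excluded. Default 3.
#' @param mafAlignThreshold Minor-allele-frequency ceiling below which the
#'   minor-allele fallback may align a variant that the LD rule could not
#'   decide; 0 disables the fallback. Default 0.
#' @param updateId Replace matched study variant identifiers by the reference
#'   identifiers. Default `FALSE`.
#' @param keepUnmatched Keep study variants absent from the reference in the
#'   output (action `kept_unaligned`) instead of dropping them. Default
#'   `FALSE`.
#' @param callThreshold Hard-call threshold for probabilistic input; see
#'   [hardCall()]. Default 0.4.
#' @param minPairSamples Minimum pairwise-complete samples for a two-locus
#'   haplotype-frequency estimate. Default 10.
#' @return A validated list of class `"HarmonizerConfig"`.
#' @export
harmonizerConfig <- function(flankVariants = 100L, minR2 = 0.3,
                             minSupport = 3L, mafAlignThreshold = 0,
                             updateId = FALSE, keepUnmatched = FALSE,
                             callThreshold = 0.4, minPairSamples = 10L) {
  stopifnot(flankVariants >= 1L, minR2 >= 0, minR2 <= 1, minSupport >= 1L,
            mafAlignThreshold >= 0, mafAlignThreshold <= 0.5,
            callThreshold >= 0, callThreshold <= 1, minPairSamples >= 2L)
  structure(list(flankVariants = as.integer(flankVariants), minR2 = minR2,
                 minSupport = as.integer(minSupport),
                 mafAlignThreshold = mafAlignThreshold,
                 updateId = isTRUE(updateId),
                 keepUnmatched = isTRUE(keepUnmatched),
                 callThreshold = callThreshold,
                 minPairSamples = as.integer(minPairSamples)),
            class = "HarmonizerConfig")
}

#' HarmonizationResult: aligned data plus per-variant decisions
#'
#' Returned by [harmonize()]. `alignedData(x)` is the harmonized
#' [GenotypeData-class]; `decisions(x)` is a [S4Vectors::DataFrame] with one
#' row per input study variant (columns `variant_id`, `chromosome`,
#' `position`, `action`, `n_positive`, `n_negative`, `reason`);
#' `actionCounts(x)` tabulates actions. When identifiers were updated, the
#' rename log is in `renames(x)`... stored in `metadata(alignedData(x))$renames`.
#'
#' @param x A `HarmonizationResult`.
#' @aliases HarmonizationResult
#' @export
setClass("HarmonizationResult",
         representation(data = "GenotypeData", decisions = "DataFrame",
                        config = "list"))

#' @rdname HarmonizationResult-class
#' @export
setMethod("alignedData", "HarmonizationResult", function(x) x@data)

#' @rdname HarmonizationResult-class
#' @export
setMethod("decisions", "HarmonizationResult", function(x) x@decisions)

#' @rdname HarmonizationResult-class
#' @export
setMethod("actionCounts", "HarmonizationResult", function(x) {
  table(factor(x@decisions$action,
               levels = c("unchanged", "strand_flipped", "excluded",
                          "kept_unaligned")))
})

#' @describeIn HarmonizationResult-class Summary display.
#' @param object A `HarmonizationResult`.
#' @export
setMethod("show", "HarmonizationResult", function(object) {
  cat("HarmonizationResult\n")
  cnt <- actionCounts(object)
  for (a in names(cnt)) cat(sprintf("  %-15s %d\n", a, cnt[[a]]))
  cat("  output:", nrow(object@data), "variants x", ncol(object@data),
      "samples\n")
})

#' Match study variants to reference variants
#'
#' Variants are matched on normalised chromosome (`"chr1"` equals `"1"`) and
#' 1-based position, not on identifier: identifiers drift across dbSNP builds
#' while positions (within one genome build) do not. A matched pair is
#' allele-compatible when the study allele set equals the reference allele
#' set, or equals its Watson-Crick complement.
#'
#' @param study,ref [GenotypeData-class] objects.
#' @return A list with `pairs` (data.frame: `studyIdx`, `refIdx`,
#'   `compatible`, `flip` -- for non-ambiguous pairs, whether complementation
#'   is needed; `NA` for ambiguous or incompatible pairs) and `unmatched`
#'   (study indices with no positional match).
#' @export
matchVariants <- function(study, ref) {
  keyS <- paste(.normChrom(chromosomes(study)), positions(study))
  keyR <- paste(.normChrom(chromosomes(ref)), positions(ref))
  hit <- match(keyS, keyR)
  dupS <- duplicated(keyS) & !is.na(hit)
  if (any(dupS)) {
    off <- which(keyS %in% keyS[dupS])
    stop("ambiguous match: multiple study variants at one position match a ",
         "single reference variant: ",
         paste(variantIds(study)[off], collapse = ", "), call. = FALSE)
  }
  dupR <- unique(keyR[duplicated(keyR)])
  bad <- !is.na(hit) & keyS %in% dupR
  if (any(bad)) {
    stop("ambiguous match: multiple reference variants at one position: ",
         paste(variantIds(study)[bad], collapse = ", "), call. = FALSE)
  }
  sIdx <- which(!is.na(hit))
  rIdx <- hit[sIdx]
  sA <- alleleA(study)[sIdx]; sB <- alleleB(study)[sIdx]
  rA <- alleleA(ref)[rIdx];   rB <- alleleB(ref)[rIdx]
  sameSet <- !is.na(sB) & !is.na(rB) &
    ((sA == rA & sB == rB) | (sA == rB & sB == rA))
  csA <- complementAllele(sA)
  csB <- complementAllele(sB)
  compSet <- !is.na(csB) & !is.na(rB) &
    ((csA == rA & csB == rB) | (csA == rB & csB == rA))
  compatible <- sameSet | compSet
  ambig <- isAmbiguous(study)[sIdx]
  flip <- ifelse(!compatible | ambig, NA, compSet & !sameSet)
  list(pairs = data.frame(studyIdx = sIdx, refIdx = rIdx,
                          compatible = compatible, flip = flip),
       unmatched = setdiff(seq_len(nrow(study)), sIdx))
}

## Orient a reference haplotype-frequency 4-vector (neighbour = first locus,
## target = second locus) into the study's allele-letter space. Returns NULL
## when letters cannot be reconciled.
.orientRefFreqs <- function(f, sNbB, rNbAB, sTgB, rTgAB) {
  if (identical(rNbAB[2L], sNbB)) {
  } else if (identical(rNbAB[1L], sNbB)) {
    f <- f[c(3L, 4L, 1L, 2L)]  # swap neighbour axis
  } else {
    return(NULL)
  }
  if (identical(rTgAB[2L], sTgB)) {
  } else if (identical(rTgAB[1L], sTgB)) {
    f <- f[c(2L, 1L, 4L, 3L)]  # swap target axis
  } else {
    return(NULL)
  }
  f
}

## r2 from a frequency 4-vector with marginals known to lie inside (0,1).
.r2FromFreqs <- function(f) {
  px <- f[3] + f[4]
  py <- f[2] + f[4]
  (f[4] - px * py)^2 / (px * (1 - px) * py * (1 - py))
}

## LD vote for one ambiguous matched variant. `env` carries raw study and
## reference matrices plus allele vectors, precomputed once per harmonize()
## call (S4 accessor dispatch is too slow for this loop). Returns
## list(decided, action, reason, nPos, nNeg).
.ldVote <- function(sIdx, rIdx, env, cfg, nbStudy, nbRef) {
  nPos <- 0L
  nNeg <- 0L
  sTgB <- env$aB_S[sIdx]
  rTgAB <- c(env$aA_R[rIdx], env$aB_R[rIdx])
  for (k in seq_along(nbStudy)) {
    i <- nbStudy[k]
    j <- nbRef[k]
    fS <- if (is.null(env$hS)) {
      .pairFreqsFast(env$callsS[i, ], env$callsS[sIdx, ],
                     minSamples = cfg$minPairSamples)
    } else {
      .pairFreqsFast(hx = c(env$hS$hapA[i, ], env$hS$hapB[i, ]),
                     hy = c(env$hS$hapA[sIdx, ], env$hS$hapB[sIdx, ]),
                     minSamples = cfg$minPairSamples)
    }
    if (is.null(fS) || .r2FromFreqs(fS) < cfg$minR2) next
    fR <- if (is.null(env$hR)) {
      .pairFreqsFast(env$callsR[j, ], env$callsR[rIdx, ],
                     minSamples = cfg$minPairSamples)
    } else {
      .pairFreqsFast(hx = c(env$hR$hapA[j, ], env$hR$hapB[j, ]),
                     hy = c(env$hR$hapA[rIdx, ], env$hR$hapB[rIdx, ]),
                     minSamples = cfg$minPairSamples)
    }
    if (is.null(fR) || .r2FromFreqs(fR) < cfg$minR2) next
    fR <- .orientRefFreqs(fR, env$aB_S[i], c(env$aA_R[j], env$aB_R[j]),
                          sTgB, rTgAB)
    if (is.null(fR)) next
    rho <- hapFreqCorrelation(fS, fR)
    if (is.na(rho)) next
    if (rho > 1e-12) nPos <- nPos + 1L
    else if (rho < -1e-12) nNeg <- nNeg + 1L
  }
  if (nPos + nNeg < cfg$minSupport) {
    return(list(decided = FALSE, nPos = nPos, nNeg = nNeg))
  }
  if (nNeg > nPos) {
    list(decided = TRUE, action = "strand_flipped", reason = "ld",
         nPos = nPos, nNeg = nNeg)
  } else if (nPos > nNeg) {
    list(decided = TRUE, action = "unchanged", reason = "ld",
         nPos = nPos, nNeg = nNeg)
  } else {
    list(decided = TRUE, action = "excluded", reason = "tie",
         nPos = nPos, nNeg = nNeg)
  }
}

## Minor-allele fallback for one matched variant pair. Returns list(action,
## reason).
.mafDecision <- function(sIdx, rIdx, study, ref, threshold) {
  fS <- alleleBFreq(genotypeCalls(study)[sIdx, ])
  fR <- alleleBFreq(genotypeCalls(ref)[rIdx, ])
  if (fS <= 0 || fS >= 1 || fR <= 0 || fR >= 1) {
    return(list(action = "excluded", reason = "monomorphic"))
  }
  if (min(fS, 1 - fS) >= threshold || min(fR, 1 - fR) >= threshold) {
    return(list(action = "excluded", reason = "maf_uninformative"))
  }
  minorS <- if (fS < 0.5) alleleB(study)[sIdx] else alleleA(study)[sIdx]
  minorR <- if (fR < 0.5) alleleB(ref)[rIdx] else alleleA(ref)[rIdx]
  if (identical(minorS, minorR)) {
    list(action = "unchanged", reason = "maf_aligned")
  } else if (identical(complementAllele(minorS), minorR)) {
    list(action = "strand_flipped", reason = "maf_aligned")
  } else {
    list(action = "excluded", reason = "maf_uninformative")
  }
}

#' Update study variant identifiers to the reference identifiers
#'
#' Every matched study variant takes the identifier of its reference partner;
#' unmatched identifiers are untouched. Renames that would duplicate an
#' existing identifier get a `_dupN` suffix with a warning.
#'
#' @param study A [GenotypeData-class] object.
#' @param ref The reference [GenotypeData-class].
#' @param matches Output of [matchVariants()]; computed when `NULL`.
#' @return `study` with updated identifiers; the rename log (columns
#'   `old_id`, `new_id`) is in `metadata(.)$renames`.
#' @export
updateVariantIds <- function(study, ref, matches = NULL) {
  if (is.null(matches)) matches <- matchVariants(study, ref)
  ids <- variantIds(study)
  old <- ids
  ids[matches$pairs$studyIdx] <- variantIds(ref)[matches$pairs$refIdx]
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))
    for (i in dup) {
      n <- 1L
      while (paste0(ids[i], "_dup", n) %in% ids) n <- n + 1L
      ids[i] <- paste0(ids[i], "_dup", n)
    }
    warning(length(dup), " renamed identifier(s) deduplicated with a _dupN ",
            "suffix", call. = FALSE)
  }
  variantIds(study) <- ids
  changed <- old != ids
  S4Vectors::metadata(study)$renames <-
    data.frame(old_id = old[changed], new_id = ids[changed])
  study
}

#' Harmonize a study dataset against a reference
#'
#' The end-to-end alignment procedure. Variants are matched on chromosome and
#' position; non-ambiguous matched variants are strand-corrected first by
#' direct allele comparison (equal sets: unchanged; complementary sets:
#' flipped; otherwise excluded). Each ambiguous (A/T, C/G) matched variant is
#' then aligned from LD: up to `flankVariants` aligned non-ambiguous
#' neighbours per side are screened for r-squared of at least `minR2` with
#' the ambiguous SNP in *both* datasets; for each passing neighbour the four
#' two-locus haplotype frequencies are estimated in each dataset (direct
#' counting when phased, EM otherwise) and correlated. More negative than
#' positive correlations means the study variant sits on the other strand and
#' is flipped; more positive means it is left unchanged; a tie excludes it.
#' With fewer than `minSupport` informative neighbours there is no LD
#' decision: if `mafAlignThreshold > 0` and the variant is rare enough in
#' both datasets, matching minor alleles decide the strand; otherwise the
#' variant is excluded. Strand swaps relabel alleles only -- genotype calls
#' are never renumbered.
#'
#' @param study,ref [GenotypeData-class] objects sorted by position (the
#'   constructor and all readers guarantee this).
#' @param config A [harmonizerConfig()].
#' @return A [HarmonizationResult-class]: the output dataset contains exactly
#'   the study variants whose action is `unchanged`, `strand_flipped` or
#'   `kept_unaligned`, with strand swaps (and, when `updateId`, reference
#'   identifiers) applied.
#' @examples
#' sim <- makeStudyRefPair(simulatePanel(60, 400, ambiguousFraction = 0.2,
#'                                       ldStrength = 0.95, seed = 7),
#'                         nStudy = 150, nRef = 150, flipFraction = 0.5,
#'                         seed = 7)
#' res <- harmonize(sim$study, sim$ref, harmonizerConfig())
#' actionCounts(res)
#' @export
harmonize <- function(study, ref, config = harmonizerConfig()) {
  stopifnot(methods::is(study, "GenotypeData"), methods::is(ref, "GenotypeData"),
            inherits(config, "HarmonizerConfig"))
  m <- matchVariants(study, ref)
  if (nrow(m$pairs) == 0L) {
    stop("no study variant matches the reference: nothing to align against",
         call. = FALSE)
  }
  nv <- nrow(study)
  action <- rep(NA_character_, nv)
  reason <- rep("", nv)
  nPos <- integer(nv)
  nNeg <- integer(nv)

  action[m$unmatched] <- if (config$keepUnmatched) "kept_unaligned" else "excluded"
  reason[m$unmatched] <- "unmatched"

  ambig <- isAmbiguous(study)
  pairs <- m$pairs
  refOf <- rep(NA_integer_, nv)
  refOf[pairs$studyIdx] <- pairs$refIdx

  ## 1. non-ambiguous matched variants
  na_pairs <- pairs[!ambig[pairs$studyIdx], , drop = FALSE]
  for (k in seq_len(nrow(na_pairs))) {
    i <- na_pairs$studyIdx[k]
    if (!na_pairs$compatible[k]) {
      action[i] <- "excluded"; reason[i] <- "allele_mismatch"
    } else if (na_pairs$flip[k]) {
      action[i] <- "strand_flipped"; reason[i] <- "strand_complement"
    } else {
      action[i] <- "unchanged"; reason[i] <- "allele_match"
    }
  }
  ## apply non-ambiguous swaps before any LD work so neighbour allele labels
  ## agree between datasets
  flippedNA <- which(action == "strand_flipped")
  if (length(flippedNA)) study <- swapStrand(study, flippedNA)

  ## aligned non-ambiguous variants usable as LD support
  support <- !ambig & !is.na(action) &
    action %in% c("unchanged", "strand_flipped")

  ## 2. ambiguous matched variants
  am_pairs <- pairs[ambig[pairs$studyIdx], , drop = FALSE]
  chromS <- .normChrom(chromosomes(study))
  supIdx <- which(support)
  env <- list(callsS = genotypeCalls(study), callsR = genotypeCalls(ref),
              hS = haplotypeCalls(study), hR = haplotypeCalls(ref),
              aB_S = alleleB(study), aA_R = alleleA(ref), aB_R = alleleB(ref))
  for (k in seq_len(nrow(am_pairs))) {
    i <- am_pairs$studyIdx[k]
    j <- am_pairs$refIdx[k]
    if (!am_pairs$compatible[k]) {
      action[i] <- "excluded"; reason[i] <- "allele_mismatch"
      next
    }
    fS <- alleleBFreq(env$callsS[i, ])
    fR <- alleleBFreq(env$callsR[j, ])
    if (fS <= 0 || fS >= 1 || fR <= 0 || fR >= 1) {
      action[i] <- "excluded"; reason[i] <- "monomorphic"
      next
    }
    sameChrom <- supIdx[chromS[supIdx] == chromS[i]]
    left <- rev(sameChrom[sameChrom < i])
    right <- sameChrom[sameChrom > i]
    nb <- c(utils::head(left, config$flankVariants),
            utils::head(right, config$flankVariants))
    vote <- .ldVote(i, j, env, config, nb, refOf[nb])
    nPos[i] <- vote$nPos
    nNeg[i] <- vote$nNeg
    if (vote$decided) {
      action[i] <- vote$action
      reason[i] <- vote$reason
    } else if (config$mafAlignThreshold > 0) {
      d <- .mafDecision(i, j, study, ref, config$mafAlignThreshold)
      action[i] <- d$action
      reason[i] <- d$reason
    } else {
      action[i] <- "excluded"
      reason[i] <- "insufficient_support"
    }
  }

  ## 3. apply ambiguous swaps, ids, subsetting
  flippedAmb <- which(ambig & !is.na(action) & action == "strand_flipped")
  if (length(flippedAmb)) study <- swapStrand(study, flippedAmb)
  if (config$updateId) study <- updateVariantIds(study, ref, m)
  stopifnot(!anyNA(action))
  dec <- S4Vectors::DataFrame(
    variant_id = variantIds(study), chromosome = chromosomes(study),
    position = positions(study), action = action,
    n_positive = nPos, n_negative = nNeg, reason = reason)
  keep <- action %in% c("unchanged", "strand_flipped", "kept_unaligned")
  out <- study[keep, ]
  methods::new("HarmonizationResult", data = out, decisions = dec,
               config = unclass(config))
}

#' Write a per-variant alignment report
#'
#' Tab-separated file with columns `variant_id`, `chromosome`, `position`,
#' `action`, `n_positive`, `n_negative`, `reason` -- one row per input study
#' variant.
#'
#' @param result A [HarmonizationResult-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeAlignmentReport <- function(result, path) {
  stopifnot(methods::is(result, "HarmonizationResult"))
  utils::write.table(as.data.frame(decisions(result)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
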
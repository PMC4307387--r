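test_that("variants match on position with allele-set or complement compatibility", {
  study <- makeGeno(c("A/C", "T/G", "A/C"), matrix(0:1, 3, 2),
                    pos = c(1000L, 2000L, 3000L))
  ref <- makeGeno(c("A/C", "A/C", "A/G", "C/T"), matrix(0:1, 4, 2),
                  pos = c(1000L, 2000L, 3000L, 9000L))
  m <- matchVariants(study, ref)
  expect_equal(m$pairs$studyIdx, 1:3)
  expect_equal(m$pairs$refIdx, 1:3)
  expect_equal(m$pairs$compatible, c(TRUE, TRUE, FALSE))
  expect_equal(m$pairs$flip, c(FALSE, TRUE, NA))
  expect_equal(m$unmatched, integer(0))
  # chromosome label normalisation: "chr1" matches "1"
  s2 <- makeGeno("A/G", matrix(1L), chrom = "chr1", pos = 500L)
  r2 <- makeGeno("A/G", matrix(1L), chrom = "1", pos = 500L)
  expect_equal(nrow(matchVariants(s2, r2)$pairs), 1L)
})

test_that("duplicate positions raise an ambiguous-match error naming the variants", {
  study <- GenotypeData(
    data.frame(id = c("dupA", "dupB"), chrom = "1", pos = 1000L,
               alleleA = c("A", "A"), alleleB = c("C", "G")),
    "s1", calls = matrix(c(0L, 1L), 2))
  ref <- makeGeno("A/C", matrix(0L), pos = 1000L)
  expect_error(matchVariants(study, ref), "ambiguous match.*dupA")
})

test_that("non-ambiguous variants align by direct allele comparison", {
  study <- makeGeno(c("A/C", "T/G", "A/C"),
                    rbind(callsOf(2, 2, 2), callsOf(2, 2, 2), callsOf(3, 2, 1)),
                    pos = c(1000L, 2000L, 3000L))
  ref <- makeGeno(c("A/C", "A/C", "A/G"),
                  rbind(callsOf(2, 2, 2), callsOf(2, 2, 2), callsOf(3, 2, 1)),
                  pos = c(1000L, 2000L, 3000L))
  res <- harmonize(study, ref)
  d <- as.data.frame(decisions(res))
  expect_equal(d$action, c("unchanged", "strand_flipped", "excluded"))
  expect_equal(d$reason[3], "allele_mismatch")
  out <- alignedData(res)
  expect_equal(alleleA(out), c("A", "A"))  # T/G flipped onto A/C
  expect_equal(alleleB(out), c("C", "C"))
  # flipping never renumbers calls
  expect_equal(genotypeCalls(out)[2, ], genotypeCalls(study)[2, ])
})

test_that("every input study variant receives exactly one decision", {
  pool <- simulatePanel(80, 600, ambiguousFraction = 0.25, ldStrength = 0.9,
                        seed = 31)
  sim <- makeStudyRefPair(pool, 120, 120, flipFraction = 0.4, seed = 31)
  res <- harmonize(sim$study, sim$ref, harmonizerConfig(keepUnmatched = TRUE))
  d <- decisions(res)
  expect_equal(nrow(d), nrow(sim$study))
  expect_setequal(d$variant_id, variantIds(sim$study))
  expect_true(all(d$action %in% c("unchanged", "strand_flipped", "excluded",
                                  "kept_unaligned")))
  # output holds exactly the non-excluded variants
  expect_setequal(variantIds(alignedData(res)),
                  d$variant_id[d$action != "excluded"])
})

test_that("LD votes recover known flips on simulated cohorts", {
  pool <- simulatePanel(150, 1600, ambiguousFraction = 0.2, ldStrength = 0.92,
                        seed = 17)
  sim <- makeStudyRefPair(pool, 400, 400, flipFraction = 0.5, seed = 17)
  res <- harmonize(sim$study, sim$ref)
  d <- as.data.frame(decisions(res))
  amb <- d[d$variant_id %in% sim$truth$ambiguousIds, ]
  flipped <- amb$variant_id %in% sim$truth$flippedIds
  # every LD-decided flip must carry more negative than positive votes
  ld <- amb[amb$reason == "ld", ]
  expect_true(all(ld$n_negative > ld$n_positive |
                    ld$action != "strand_flipped"))
  expect_true(all(ld$n_positive > ld$n_negative |
                    ld$action != "unchanged"))
  expect_true(all(ld$n_positive + ld$n_negative >= 3))
  # decisions agree with truth for decided variants
  decided <- amb[amb$action %in% c("unchanged", "strand_flipped"), ]
  expect_true(all((decided$variant_id %in% sim$truth$flippedIds) ==
                    (decided$action == "strand_flipped")))
})

test_that("ambiguous SNPs with too few informative neighbours are excluded", {
  # 2 non-ambiguous neighbours only: below the 3-variant default support
  set.seed(40)
  h <- rbinom(600, 1, 0.5)
  haps <- cbind(h, h, h)  # perfect LD
  mk <- function(rows, alleles) {
    ab <- do.call(rbind, strsplit(alleles, "/"))
    hapA <- t(haps[rows[1:100], ])
    hapB <- t(haps[rows[101:200], ])
    GenotypeData(data.frame(id = c("n1", "amb", "n2"), chrom = "1",
                            pos = c(1000L, 2000L, 3000L),
                            alleleA = ab[, 1], alleleB = ab[, 2]),
                 sprintf("s%d", 1:100), calls = hapA + hapB)
  }
  study <- mk(1:200, c("A/C", "A/T", "G/T"))
  ref <- mk(201:400, c("A/C", "A/T", "G/T"))
  res <- harmonize(study, ref)
  d <- as.data.frame(decisions(res))
  expect_equal(d$action[d$variant_id == "amb"], "excluded")
  expect_equal(d$reason[d$variant_id == "amb"], "insufficient_support")
  # lowering the support requirement rescues it
  res2 <- harmonize(study, ref, harmonizerConfig(minSupport = 2))
  d2 <- as.data.frame(decisions(res2))
  expect_equal(d2$action[d2$variant_id == "amb"], "unchanged")
})

test_that("contradictory LD votes tie and exclude the variant", {
  v <- callsOf(4, 4, 4)
  study <- makeGeno(c("A/C", "A/T", "G/T"), rbind(v, v, v),
                    pos = c(1000L, 2000L, 3000L))
  ref <- makeGeno(c("A/C", "A/T", "G/T"), rbind(v, v, 2L - v),
                  pos = c(1000L, 2000L, 3000L))
  res <- harmonize(study, ref, harmonizerConfig(minSupport = 2))
  d <- as.data.frame(decisions(res))
  expect_equal(d$action[2], "excluded")
  expect_equal(d$reason[2], "tie")
  expect_equal(d$n_positive[2], 1L)
  expect_equal(d$n_negative[2], 1L)
})

test_that("monomorphic ambiguous variants are excluded before any LD work", {
  study <- makeGeno(c("A/C", "A/T"), rbind(callsOf(4, 4, 4), callsOf(12, 0, 0)),
                    pos = c(1000L, 2000L))
  ref <- makeGeno(c("A/C", "A/T"), rbind(callsOf(4, 4, 4), callsOf(4, 4, 4)),
                  pos = c(1000L, 2000L))
  res <- harmonize(study, ref)
  d <- as.data.frame(decisions(res))
  expect_equal(d$action[2], "excluded")
  expect_equal(d$reason[2], "monomorphic")
})

test_that("the minor-allele fallback aligns rare undecidable variants", {
  mkPair <- function(studyCalls, refCalls, alleles = "A/T") {
    list(study = makeGeno(alleles, matrix(studyCalls, nrow = 1)),
         ref = makeGeno(alleles, matrix(refCalls, nrow = 1)))
  }
  cfgOn <- harmonizerConfig(mafAlignThreshold = 0.1)
  # same minor allele letter (A minor in both): unchanged
  p <- mkPair(callsOf(1, 2, 47), callsOf(2, 2, 46))
  res <- harmonize(p$study, p$ref, cfgOn)
  d <- as.data.frame(decisions(res))
  expect_equal(d$action, "unchanged")
  expect_equal(d$reason, "maf_aligned")
  # study minor is the complement of the reference minor: flipped
  p2 <- mkPair(callsOf(1, 2, 47), callsOf(46, 2, 2))
  d2 <- as.data.frame(decisions(harmonize(p2$study, p2$ref, cfgOn)))
  expect_equal(d2$action, "strand_flipped")
  # common variant: uninformative
  p3 <- mkPair(callsOf(30, 10, 10), callsOf(30, 10, 10))
  d3 <- as.data.frame(decisions(harmonize(p3$study, p3$ref, cfgOn)))
  expect_equal(d3$action, "excluded")
  expect_equal(d3$reason, "maf_uninformative")
  # fallback disabled: insufficient support
  d4 <- as.data.frame(decisions(harmonize(p$study, p$ref, harmonizerConfig())))
  expect_equal(d4$reason, "insufficient_support")
})

test_that("identifier update renames matched variants and deduplicates", {
  study <- makeGeno(c("A/C", "A/G"), matrix(0:1, 2, 2),
                    pos = c(1000L, 2000L), ids = c("1:1000:SNP", "rsX"))
  ref <- makeGeno("A/C", matrix(0L, 1, 1), pos = 1000L, ids = "rs123")
  upd <- updateVariantIds(study, ref)
  expect_equal(variantIds(upd), c("rs123", "rsX"))
  expect_equal(S4Vectors::metadata(upd)$renames,
               data.frame(old_id = "1:1000:SNP", new_id = "rs123"))
  # a rename colliding with an existing id gains a suffix
  study2 <- makeGeno(c("A/C", "A/G"), matrix(0:1, 2, 2),
                     pos = c(1000L, 2000L), ids = c("x", "rs123"))
  ref2 <- GenotypeData(
    data.frame(id = c("rs123", "rs123b"), chrom = "1",
               pos = c(1000L, 2000L), alleleA = c("A", "A"),
               alleleB = c("C", "G")), c("r1"), calls = matrix(0:1, 2))
  ref2b <- ref2
  variantIds(ref2b) <- c("rs123", "rs123")
  expect_warning(upd2 <- updateVariantIds(study2, ref2b), "_dupN")
  expect_equal(variantIds(upd2), c("rs123", "rs123_dup1"))
})

test_that("unmatched study variants are dropped unless keepUnmatched", {
  study <- makeGeno(c("A/C", "A/G", "C/T", "G/T"), matrix(0:1, 4, 2),
                    pos = c(1000L, 2000L, 3000L, 4000L))
  ref <- makeGeno("A/C", matrix(0:1, 1, 2), pos = 1000L)
  res <- harmonize(study, ref)
  expect_equal(variantIds(alignedData(res)), "rs1")
  resKeep <- harmonize(study, ref, harmonizerConfig(keepUnmatched = TRUE))
  expect_setequal(variantIds(alignedData(resKeep)),
                  c("rs1", "rs2", "rs3", "rs4"))
  d <- as.data.frame(decisions(resKeep))
  expect_equal(sum(d$action == "kept_unaligned"), 3L)
  expect_error(harmonize(study, makeGeno("A/C", matrix(0L), pos = 99L)),
               "nothing to align")
})

test_that("globally flipping the study inverts non-ambiguous flip decisions only", {
  pool <- simulatePanel(60, 600, ambiguousFraction = 0.2, ldStrength = 0.9,
                        seed = 23)
  sim <- makeStudyRefPair(pool, 150, 150, flipFraction = 0.5, seed = 23)
  resA <- harmonize(sim$study, sim$ref)
  resB <- harmonize(swapStrand(sim$study), sim$ref)
  dA <- as.data.frame(decisions(resA))
  dB <- as.data.frame(decisions(resB))
  nonamb <- !isAmbiguous(sim$study)
  flipA <- dA$action == "strand_flipped"
  flipB <- dB$action == "strand_flipped"
  expect_equal(flipB[nonamb], !flipA[nonamb])
  # the output calls matrices are identical: relabelling carries no data
  expect_equal(genotypeCalls(alignedData(resA)),
               genotypeCalls(alignedData(resB)))
  expect_equal(alleleA(alignedData(resA)), alleleA(alignedData(resB)))
})

test_that("the output never contains a variant incompatible with the reference", {
  pool <- simulatePanel(80, 600, ambiguousFraction = 0.3, ldStrength = 0.85,
                        seed = 53)
  sim <- makeStudyRefPair(pool, 100, 100, flipFraction = 0.6, seed = 53)
  res <- harmonize(sim$study, sim$ref, harmonizerConfig(updateId = TRUE))
  out <- alignedData(res)
  m <- matchVariants(out, sim$ref)
  expect_equal(nrow(m$pairs), nrow(out))
  # after harmonization all matched variants agree letter-for-letter as sets
  sA <- alleleA(out)[m$pairs$studyIdx]; sB <- alleleB(out)[m$pairs$studyIdx]
  rA <- alleleA(sim$ref)[m$pairs$refIdx]; rB <- alleleB(sim$ref)[m$pairs$refIdx]
  expect_true(all((sA == rA & sB == rB) | (sA == rB & sB == rA)))
})

test_that("the alignment report is a readable TSV with one row per variant", {
  study <- makeGeno(c("A/C", "T/G"), matrix(0:1, 2, 2),
                    pos = c(1000L, 2000L))
  ref <- makeGeno(c("A/C", "A/C"), matrix(0:1, 2, 2), pos = c(1000L, 2000L))
  res <- harmonize(study, ref)
  path <- tempfile(fileext = ".tsv")
  writeAlignmentReport(res, path)
  rep <- read.delim(path)
  expect_equal(colnames(rep),
               c("variant_id", "chromosome", "position", "action",
                 "n_positive", "n_negative", "reason"))
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$action, c("unchanged", "strand_flipped"))
})
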
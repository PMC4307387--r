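# Small in-code fixtures shared across tests.

# A GenotypeData from a compact spec: alleles as "A/C" strings, calls as a
# variant-by-sample matrix.
makeGeno <- function(alleles, calls, chrom = "1",
                     pos = 1000L * seq_along(alleles),
                     ids = sprintf("rs%d", seq_along(alleles)), ...) {
  ab <- do.call(rbind, strsplit(alleles, "/", fixed = TRUE))
  calls <- matrix(as.integer(calls), nrow = length(alleles))
  GenotypeData(data.frame(id = ids, chrom = chrom, pos = pos,
                          alleleA = ab[, 1L], alleleB = ab[, 2L]),
               samples = sprintf("s%d", ncol(calls) |> seq_len()),
               calls = calls, ...)
}

# Genotype vector with fixed counts of 0/1/2 calls, deterministic order.
callsOf <- function(n0, n1, n2) {
  rep(c(0L, 1L, 2L), c(n0, n1, n2))
}

# Compare two GenotypeData up to the per-variant A/B orientation that PLINK
# text files cannot encode: a variant may come back with alleleA and alleleB
# swapped and calls complemented (2 - g), or with alleleB = NA when it is
# monomorphic in the written cohort.
expect_equivalent_geno <- function(got, want) {
  expect_equal(variantIds(got), variantIds(want))
  expect_equal(chromosomes(got), chromosomes(want))
  expect_equal(positions(got), positions(want))
  expect_equal(sampleIds(got), sampleIds(want))
  gA <- alleleA(got); gB <- alleleB(got)
  wA <- alleleA(want); wB <- alleleB(want)
  cg <- genotypeCalls(got)
  cw <- genotypeCalls(want)
  for (i in seq_along(gA)) {
    if (identical(gA[i], wA[i]) && (identical(gB[i], wB[i]) || is.na(gB[i]))) {
      expect_equal(cg[i, ], cw[i, ])
    } else if (identical(gA[i], wB[i]) && identical(gB[i], wA[i])) {
      expect_equal(cg[i, ], 2L - cw[i, ])
    } else {
      fail(sprintf("variant %s: alleles %s/%s vs %s/%s are not a re-orientation",
                   variantIds(want)[i], gA[i], gB[i], wA[i], wB[i]))
    }
  }
}

expect_identical_geno <- function(got, want) {
  expect_equal(variantIds(got), variantIds(want))
  expect_equal(chromosomes(got), chromosomes(want))
  expect_equal(positions(got), positions(want))
  expect_equal(sampleIds(got), sampleIds(want))
  expect_equal(alleleA(got), alleleA(want))
  expect_equal(alleleB(got), alleleB(want))
  expect_equal(genotypeCalls(got), genotypeCalls(want))
}
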
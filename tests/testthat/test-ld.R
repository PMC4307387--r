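test_that("phased haplotype frequencies are direct relative counts", {
  expect_equal(hapFreqsPhased(c(0, 0, 1, 1), c(0, 0, 1, 1)),
               c(f00 = 0.5, f01 = 0, f10 = 0, f11 = 0.5))
  expect_equal(hapFreqsPhased(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               c(f00 = 0.25, f01 = 0.25, f10 = 0.25, f11 = 0.25))
  # pairwise-complete: haplotypes missing at either locus are dropped
  expect_equal(hapFreqsPhased(c(0, NA, 1, 1), c(0, 0, NA, 1)),
               c(f00 = 0.5, f01 = 0, f10 = 0, f11 = 0.5))
  expect_error(hapFreqsPhased(1, 1), class = "insufficientData")
})

test_that("EM equals the closed-form gamete counts when phase is unambiguous", {
  # no double heterozygotes: every gamete is observable
  gx <- c(0, 0, 1, 2, 2, 1, 0, 2, 1, 0, 2, 0)
  gy <- c(0, 1, 0, 2, 1, 2, 0, 2, 0, 2, 0, 1)
  stopifnot(sum(gx == 1 & gy == 1) == 0)
  f <- hapFreqsEM(gx, gy, minSamples = 10)
  # direct gamete counting: with at most one het locus per individual the
  # two gametes are fully determined
  counts <- numeric(4)
  for (i in seq_along(gx)) {
    xs <- if (gx[i] == 1) c(1, 0) else rep(gx[i] / 2, 2)
    ys <- if (gy[i] == 1) c(1, 0) else rep(gy[i] / 2, 2)
    for (k in 1:2) {
      idx <- 2 * xs[k] + ys[k] + 1
      counts[idx] <- counts[idx] + 1
    }
  }
  expect_equal(unname(f), counts / sum(counts), tolerance = 1e-6)
})

test_that("EM matches the independent grid-search likelihood maximizer", {
  # the worked case: 200 diploids from haplotype frequencies (0.4,0.1,0.2,0.3)
  set.seed(2024)
  n <- sampleGenoTable(c(0.4, 0.1, 0.2, 0.3), 200)
  gx <- rep(rep(0:2, each = 3), as.vector(t(n)))
  gy <- rep(rep(0:2, times = 3), as.vector(t(n)))
  em <- hapFreqsEM(gx, gy)
  expect_lt(max(abs(em - oracleHapFreqs(n))), 2e-3)
})

test_that("EM rejects monomorphic loci and insufficient samples", {
  expect_error(hapFreqsEM(rep(0, 20), sample(0:2, 20, TRUE)),
               class = "degenerateLD")
  expect_error(hapFreqsEM(c(0, 1, 2), c(0, 1, 2)),
               class = "insufficientData")
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(7)
  for (rep in 1:5) {
    f <- c(rexp(4))
    f <- f / sum(f)
    n <- sampleGenoTable(f, 150)
    gx <- rep(rep(0:2, each = 3), as.vector(t(n)))
    gy <- rep(rep(0:2, times = 3), as.vector(t(n)))
    if (max(gx) == min(gx) || max(gy) == min(gy)) next
    # checkLikelihood = TRUE asserts monotonicity inside the loop
    expect_no_error(hapFreqsEM(gx, gy, checkLikelihood = TRUE))
  }
})

test_that("LD statistics follow their closed forms", {
  ind <- ldStats(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(ind$D, 0, tolerance = 1e-12)
  expect_equal(ind$r2, 0, tolerance = 1e-12)
  perfect <- ldStats(c(0.5, 0, 0, 0.5))
  expect_equal(perfect$D, 0.25, tolerance = 1e-12)
  expect_equal(perfect$r2, 1, tolerance = 1e-12)
  mid <- ldStats(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(mid$D, 0.15, tolerance = 1e-12)
  expect_equal(mid$r2, 0.36, tolerance = 1e-12)
  expect_error(ldStats(c(0.5, 0.5, 0, 0)), class = "degenerateLD")
})

test_that("r2 is invariant under strand relabelling; D changes sign for one locus", {
  set.seed(21)
  for (rep in 1:10) {
    f <- c(rexp(4))
    f <- f / sum(f)
    s <- ldStats(f)
    relabX <- f[c(3, 4, 1, 2)]
    relabY <- f[c(2, 1, 4, 3)]
    both <- f[c(4, 3, 2, 1)]
    expect_equal(ldStats(relabX)$r2, s$r2, tolerance = 1e-12)
    expect_equal(ldStats(relabY)$r2, s$r2, tolerance = 1e-12)
    expect_equal(ldStats(relabX)$D, -s$D, tolerance = 1e-12)
    expect_equal(ldStats(relabY)$D, -s$D, tolerance = 1e-12)
    expect_equal(ldStats(both)$D, s$D, tolerance = 1e-12)
  }
})

test_that("haplotype-frequency correlation detects the strand-flip permutation", {
  f <- c(0.5, 0, 0, 0.5)
  expect_equal(hapFreqCorrelation(f, f), 1)
  expect_equal(hapFreqCorrelation(f, f[c(2, 1, 4, 3)]), -1)
  expect_true(is.na(hapFreqCorrelation(c(0.25, 0.25, 0.25, 0.25), f)))
  # sign antisymmetry of the decision signal for perfect-LD vectors:
  # the strand-flip permutation always drives the correlation negative
  for (q in c(0.1, 0.3, 0.49, 0.7, 0.9)) {
    g <- c(q, 0, 0, 1 - q)
    expect_equal(hapFreqCorrelation(g, g), 1)
    expect_lt(hapFreqCorrelation(g, g[c(2, 1, 4, 3)]), 0)
  }
})

test_that("EM on collapsed phased data agrees with direct haplotype counting", {
  # n = 500 diploids per replicate, generating r2 = 0.36
  f <- c(0.4, 0.1, 0.1, 0.4)
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    d <- sampleGenoVectors(f, 500)
    em <- hapFreqsEM(d$gx, d$gy)
    direct <- hapFreqsPhased(d$hapX, d$hapY)
    worst <- max(worst, max(abs(em - direct)))
  }
  expect_lt(worst, 0.02)
})
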
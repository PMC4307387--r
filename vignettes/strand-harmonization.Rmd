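---
title: "LD-based strand harmonization of genotype datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-based strand harmonization of genotype datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenotypeAligner)
```

## The problem and the model

Genotype datasets record, per variant, two allele letters and per-sample
counts of one of them. Which genomic strand those letters refer to is not
stored in any of the common formats. When a study cohort must be aligned to a
reference panel (for imputation, merging or meta-analysis), a variant coded
T/G in the study and A/C in the reference is clearly on opposite strands, and
relabelling by Watson–Crick complement fixes it. An *ambiguous* SNP — A/T or
C/G — gives no such signal: its complement is itself.

The package resolves ambiguous SNPs from local linkage disequilibrium.
Haplotype structure is a physical property of the sampled chromosomes, so two
cohorts drawn from comparable populations show similar two-locus haplotype
frequencies at nearby SNP pairs. For an ambiguous SNP $y$ and an
already-aligned non-ambiguous neighbour $x$, let
$f = (f_{00}, f_{01}, f_{10}, f_{11})$ be the four haplotype-class
frequencies, the digits counting B alleles at $x$ and $y$. If the study codes
$y$ on the same strand as the reference, the study and reference $f$ vectors
agree up to sampling noise and correlate positively. If the study has $y$ on
the other strand, its B-counts refer to the complementary letter: the classes
are permuted $(f_{00}, f_{01}, f_{10}, f_{11}) \to
(f_{01}, f_{00}, f_{11}, f_{10})$, and — provided $x$ and $y$ are actually in
LD — the Pearson correlation of the four aligned frequencies turns negative.
Each informative neighbour casts one vote (the sign of its correlation);
more negative than positive votes flips the SNP, more positive leaves it
unchanged, and a tie excludes it.

The assumptions this rests on: the two datasets sample comparable haplotype
distributions (same population, same genome build); variants are biallelic
SNPs with canonical A/C/G/T alleles; and enough non-ambiguous SNPs near each
ambiguous one are in real LD with it. Where these fail, the method abstains
(exclusion) rather than guesses.

## Estimating haplotype frequencies

When phase is available (SHAPEIT2 haplotypes, fully "|"-separated VCF
genotypes), two-locus haplotype frequencies are direct relative counts
(`hapFreqsPhased()`). Otherwise they are maximum-likelihood estimates from
unphased calls via EM (`hapFreqsEM()`): every two-locus genotype determines
its two gametes except the double heterozygote, which the E-step splits
between coupling (00/11) and repulsion (01/10) in proportion to their current
likelihood. A study with phase and an unphased reference (or vice versa) is
fine: each dataset uses its best available estimator.

Numerical choices, all deliberate:

* EM starts at linkage equilibrium (the product of observed allele
  frequencies) — a deterministic start from which the relevant maximum is
  reached in practice; tolerance `1e-6` on the largest per-component change;
  at most 100 iterations. The log-likelihood is non-decreasing by
  construction (assertable with `checkLikelihood = TRUE`).
* Missing genotypes are handled pairwise-complete: a sample missing at either
  locus is dropped for that pair only. At least 10 pairwise-complete samples
  (configurable) are required; below that the pair is uninformative.
* A locus monomorphic among the complete samples makes LD undefined; such
  pairs are skipped (`degenerateLD`).
* Correlations within `1e-12` of zero count as neither positive nor negative:
  they carry no strand signal.
* From the frequencies, $D = f_{11} - p_x p_y$ and
  $r^2 = D^2 / (p_x(1-p_x)\,p_y(1-p_y))$.

## The harmonization procedure and its tunables

`harmonize(study, ref, harmonizerConfig(...))` runs: match variants on
normalized chromosome ("chr1" ≡ "1") and 1-based position (identifiers drift
across dbSNP builds, positions within a build do not); align non-ambiguous
matched variants by direct allele-set comparison; then decide each ambiguous
matched variant by the LD vote; fall back to minor-allele matching when
enabled; optionally update identifiers; drop or keep unmatched variants.
Non-ambiguous variants are aligned *before* any ambiguous one so that
supporting haplotype classes are letter-consistent across datasets; ambiguous
SNPs never support other ambiguous SNPs.

| parameter | default | meaning |
|---|---|---|
| `flankVariants` | 100 | aligned non-ambiguous neighbours considered per side (variant count, same chromosome) |
| `minR2` | 0.3 | LD screen; must hold in **both** datasets |
| `minSupport` | 3 | informative neighbours required before the vote decides |
| `mafAlignThreshold` | 0 (off) | MAF ceiling for the minor-allele fallback |
| `callThreshold` | 0.4 | posterior needed to hard-call probabilistic input |
| `minPairSamples` | 10 | pairwise-complete samples per frequency estimate |

Design choices where the design was genuinely open:

* **"Nearby" is a variant count, not a basepair window.** Flanks of
  `flankVariants` variants adapt to chip density; a fixed bp window would
  need retuning per platform.
* **The $r^2$ screen applies in both datasets.** A neighbour informative in
  only one cohort cannot anchor a comparison of haplotype frequencies
  *between* cohorts.
* **The MAF fallback applies only when no LD decision exists.** An LD
  decision, once reached at `minSupport`, is strictly stronger evidence than
  minor-allele agreement, which can mislead for common variants; mixing the
  two would let a weak signal veto a strong one. The requirement of at least
  3 supporting variants reflects that a single neighbour's correlation sign
  is one noisy bit.
* **Calls count copies of `alleleB`, the second listed allele, in every
  format** (A2 in BIM, ALT in VCF, the second allele column in GEN/haps).
  Formats do not agree on which allele is "first"; readers normalize so the
  rest of the package never cares. Missingness is a distinct sentinel (`NA`),
  never 0 — 0 is a valid call.
* **Hard-call threshold 0.4** for probabilistic input: permissive enough to
  retain most imputed genotypes while discarding near-uniform triplets; it
  only gates which samples enter the LD estimates.

Degenerate inputs are decided exactly, not heuristically: a variant
monomorphic in either dataset is excluded (`monomorphic`); allele sets that
match neither directly nor by complement are excluded (`allele_mismatch`);
tied votes are excluded (`tie`); too few informative neighbours with the
fallback off is excluded (`insufficient_support`). Every input study variant
receives exactly one decision, returned as a `DataFrame` and exportable with
`writeAlignmentReport()`.

## File formats

Five formats are read (PLINK text, PLINK binary, VCF, Oxford GEN, SHAPEIT2)
and four written (no VCF output). Conventions worth knowing:

* PLINK binary is written SNP-major with magic bytes `6c 1b 01`.
* Oxford GEN probabilities are written with 3 decimals; missingness is the
  `0 0 0` triplet. Triplets pushed marginally above 1 by rounding are
  rescaled on read; triplets summing below 0.5 are treated as missing.
* PED/MAP files declare no alleles, so the A/B orientation of a variant is
  recovered from the order alleles are first observed in the data, and a
  variant monomorphic in the written cohort comes back with `alleleB = NA`.
  This is a limitation of the format, not of the reader: round trips through
  PLINK text preserve ids, positions, calls and allele identity up to that
  orientation, while the other three writable formats round-trip exactly.
* VCF reading uses CHROM/POS/ID/REF/ALT/GT only; non-SNP and multiallelic
  records are skipped with a warning and counted in
  `metadata(x)$skippedRecords`.

## What the simulator emulates — and what it does not

`simulatePanel()` builds haplotypes by a first-order copying chain: locus
$i$ copies the same haplotype's allele at locus $i-1$ with probability
`ldStrength`, else draws from the locus's marginal (uniform on 0.05–0.95).
This gives tunable, monotonically increasing pairwise LD with closed-form
limits (independence at 0, a single repeated column at 1) and no external
dependency. `makeStudyRefPair()` pairs disjoint pool haplotypes into diploid
cohorts and strand-swaps a random fraction of the ambiguous study variants,
returning the truth table; `scoreAlignment()` turns decisions plus truth into
a confusion table. Separate PRNG streams (derived from the master seed) drive
the pool, the cohort sampling and the flips.

The simulator reproduces the *geometry* the method relies on — LD decaying
with distance, mixed ambiguous/non-ambiguous content, sampling noise between
two finite cohorts drawn from one pool. It does **not** model recombination
hotspots, population structure or admixture, genotyping error, or missing
data patterns. Passing the simulated benchmark therefore demonstrates that
the decision rule recovers strand flips wherever genuine shared LD exists; it
does not certify performance on cohorts from diverged populations, where LD
itself differs and more exclusions (and, at the margin, wrong votes) must be
expected.

Test and benchmark problem sizes were chosen as the smallest that leave the
statistics stable: the headline benchmark uses a 2,000-variant ×
2,000-haplotype panel, cohorts of 500 diploids, 10% ambiguous variants and a
copying strength of 0.9 (adjacent-pair $r^2 \approx 0.8$, decaying to the
screen threshold within about ±8 variants); unit tests use panels of 40–150
variants.

## Known limitations

* Biallelic canonical SNPs only: indels and multiallelic records are skipped
  on read, by design.
* No reference-genome validation of alleles and no liftover; both cohorts
  must already be on one genome build.
* Matching is positional; two variants at one position raise an error rather
  than a guess.
* The LD vote needs polymorphism: rare ambiguous variants often fail the
  $r^2$ screen and survive only through the MAF fallback, which is exactly
  the regime where the minor allele is most stable.
* No attempt is made to detect sample overlap or relatedness between study
  and reference.
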
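Package: GenotypeAligner
Title: Strand Alignment and Format Conversion for Genotype Datasets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Harmonizes a study genotype dataset against a reference panel:
    matches variants by position, resolves strand differences (including
    ambiguous A/T and G/C SNPs via correlation of two-locus haplotype
    frequencies with nearby non-ambiguous SNPs in linkage disequilibrium),
    optionally falls back to minor-allele matching for rare variants, updates
    variant identifiers, and converts between PLINK text, PLINK binary, VCF,
    Oxford GEN and SHAPEIT2 haplotype formats. Includes a seeded simulator of
    LD-structured cohort pairs with known strand flips for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
biocViews: SNP, Genetics, Software, Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
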
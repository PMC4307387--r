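## VCF reading (via vcfR). Only CHROM/POS/ID/REF/ALT and the GT field are
## used; records that are not biallelic SNPs with canonical alleles are
## skipped with a warning. VCF output is not supported.

.readVcf <- function(paths) {
  vcf <- vcfR::read.vcfR(paths["vcf"], verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  nTotal <- nrow(fix)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- ref %in% CANONICAL_ALLELES & alt %in% CANONICAL_ALLELES
  if (any(!snp)) {
    warning(sum(!snp), " non-SNP/multiallelic record(s) skipped in '",
            paths["vcf"], "'", call. = FALSE)
  }
  if (!any(snp)) stop("no biallelic SNP records in '", paths["vcf"], "'",
                      call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) {
    stop("VCF '", paths["vcf"], "' carries no per-sample GT field",
         call. = FALSE)
  }
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         alleleA = fix[, "REF"], alleleB = fix[, "ALT"])
  samples <- colnames(gt)
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  tocount <- function(m) {
    out <- matrix(NA_integer_, nrow(m), ncol(m))
    out[!is.na(m) & m == "0"] <- 0L
    out[!is.na(m) & m == "1"] <- 1L
    bad <- !is.na(m) & !(m %in% c("0", "1", "."))
    if (any(bad)) {
      stop("VCF '", paths["vcf"], "': GT allele index other than 0/1 at a ",
           "biallelic record", call. = FALSE)
    }
    out
  }
  h1 <- tocount(a1)
  h2 <- tocount(a2)
  calls <- h1 + h2
  phasedAll <- all(sep[!is.na(gt) & gt != "."] == "|")
  if (phasedAll && length(sep)) {
    g <- GenotypeData(variants, samples, calls = calls, hapA = h1, hapB = h2)
  } else {
    g <- GenotypeData(variants, samples, calls = calls)
  }
  S4Vectors::metadata(g)$skippedRecords <- nTotal - sum(snp)
  g
}
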
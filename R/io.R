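.FORMATS <- c("plink_text", "plink_binary", "vcf", "oxford_gen", "shapeit2")

## Companion-file extensions per format; the first is the "primary" file used
## for auto-detection.
.FORMAT_EXTS <- list(
  plink_text   = c("ped", "map"),
  plink_binary = c("bed", "bim", "fam"),
  vcf          = c("vcf", "vcf.gz"),
  oxford_gen   = c("gen", "sample"),
  shapeit2     = c("haps", "sample"))

.stripKnownExt <- function(path) {
  sub("\\.(ped|map|bed|bim|fam|vcf\\.gz|vcf|gen|haps|sample)$", "", path)
}

.detectFormat <- function(path) {
  base <- .stripKnownExt(path)
  for (fmt in .FORMATS) {
    primary <- paste0(base, ".", .FORMAT_EXTS[[fmt]][1L])
    if (file.exists(primary)) return(fmt)
    if (fmt == "vcf" && file.exists(paste0(base, ".vcf.gz"))) return(fmt)
  }
  stop("cannot auto-detect genotype format at '", path,
       "': no .ped/.bed/.vcf/.gen/.haps file found", call. = FALSE)
}

.companionPaths <- function(path, format) {
  base <- .stripKnownExt(path)
  if (format == "vcf") {
    p <- paste0(base, ".vcf")
    if (!file.exists(p)) p <- paste0(base, ".vcf.gz")
    return(c(vcf = p))
  }
  exts <- .FORMAT_EXTS[[format]]
  setNames(paste0(base, ".", exts), exts)
}

.checkCompanions <- function(paths, format) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing companion file(s) for format '", format, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(paths)
}

#' Read a genotype dataset
#'
#' Reads any of the five supported on-disk formats into a
#' [GenotypeData-class] object. `path` is a base path: companion files are
#' located by their conventional extensions (e.g. `base.bed`/`.bim`/`.fam`
#' for PLINK binary; an extension already present on `path` is stripped).
#'
#' Readers normalise every format to the same convention: genotype calls
#' count copies of `alleleB` (the second listed allele: A2 in a BIM file, the
#' ALT allele in VCF, the second allele column in GEN and haps files).
#' SHAPEIT2 input populates the phased haplotype assays; Oxford GEN input
#' populates the probability assays, with discrete calls derived by
#' [hardCall()]; fully "|"-separated VCF genotypes populate phase. Non-SNP or
#' multiallelic records are skipped with a warning; the number skipped is
#' available as `metadata(x)$skippedRecords`.
#'
#' @param path Base path of the dataset.
#' @param format One of `"auto"`, `"plink_text"`, `"plink_binary"`, `"vcf"`,
#'   `"oxford_gen"`, `"shapeit2"`. `"auto"` detects by which primary file
#'   exists.
#' @param callThreshold Posterior-probability threshold for hard-calling
#'   probabilistic (GEN) input; see [hardCall()]. Default 0.4.
#' @return A [GenotypeData-class] object.
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = "auto", callThreshold = 0.4) {
  format <- match.arg(format, c("auto", .FORMATS))
  if (format == "auto") format <- .detectFormat(path)
  paths <- .checkCompanions(.companionPaths(path, format), format)
  switch(format,
         plink_text = .readPlinkText(paths),
         plink_binary = .readPlinkBinary(paths),
         vcf = .readVcf(paths),
         oxford_gen = .readOxfordGen(paths, callThreshold),
         shapeit2 = .readShapeit2(paths))
}

#' Write a genotype dataset
#'
#' Writes a [GenotypeData-class] object to PLINK text, PLINK binary, Oxford
#' GEN or SHAPEIT2 format (VCF output is not supported). Companion files are
#' created next to `path` with conventional extensions.
#'
#' PLINK binary is written SNP-major (magic bytes `6c 1b 01`) with
#' `alleleA`/`alleleB` as A1/A2. Oxford GEN writes the probability assays
#' when present (3 decimals), otherwise degenerate triplets from the hard
#' calls, with missingness as `0 0 0`. SHAPEIT2 output requires phased data.
#' PLINK text encodes missing genotypes as `0 0`; note PED files carry no
#' allele declaration, so a variant's A/B orientation is recovered on re-read
#' from the order alleles are first observed in the data.
#'
#' @param x A [GenotypeData-class] object.
#' @param path Base output path (extensions appended per format).
#' @param format One of `"plink_text"`, `"plink_binary"`, `"oxford_gen"`,
#'   `"shapeit2"`.
#' @return Invisibly, the named character vector of files written.
#' @seealso [readGenotypes()]
#' @export
writeGenotypes <- function(x, path,
                           format = c("plink_text", "plink_binary",
                                      "oxford_gen", "shapeit2")) {
  stopifnot(methods::is(x, "GenotypeData"))
  format <- match.arg(format)
  if (format == "shapeit2" && !isPhased(x)) {
    stop("shapeit2 output requires phased data", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  paths <- .companionPaths(path, format)
  switch(format,
         plink_text = .writePlinkText(x, paths),
         plink_binary = .writePlinkBinary(x, paths),
         oxford_gen = .writeOxfordGen(x, paths),
         shapeit2 = .writeShapeit2(x, paths))
  invisible(paths)
}
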
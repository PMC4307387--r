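## PLINK text (.ped/.map) and binary (.bed/.bim/.fam) readers and writers.

.freadTokens <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(toks)
  if (length(unique(lens)) > 1L) {
    stop("malformed file '", path, "' at line ",
         which(lens != lens[1L])[1L], ": ragged field count", call. = FALSE)
  }
  matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
}

.readMap <- function(path) {
  map <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("chrom", "id", "cm", "pos"))
  pos <- suppressWarnings(as.integer(map$pos))
  if (anyNA(pos)) {
    stop("malformed MAP file '", path, "' at line ",
         which(is.na(pos))[1L], ": non-integer position", call. = FALSE)
  }
  data.frame(id = map$id, chrom = map$chrom, pos = pos)
}

.readPlinkText <- function(paths) {
  map <- .readMap(paths["map"])
  nv <- nrow(map)
  ped <- .freadTokens(paths["ped"])
  if (ncol(ped) != 6L + 2L * nv) {
    stop("PED file '", paths["ped"], "' has ", ncol(ped),
         " columns; expected ", 6L + 2L * nv, " for ", nv,
         " MAP variants", call. = FALSE)
  }
  samples <- ped[, 2L]
  ns <- nrow(ped)
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(nv) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(nv), drop = FALSE])
  bad <- !(a1 %in% c(CANONICAL_ALLELES, "0")) |
    !(a2 %in% c(CANONICAL_ALLELES, "0"))
  if (any(bad)) {
    line <- which(rowSums(matrix(bad, nrow = ns)) > 0)[1L]
    stop("malformed PED file '", paths["ped"], "' at line ", line,
         ": allele other than A/C/G/T/0", call. = FALSE)
  }
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  half <- is.na(a1) != is.na(a2)
  if (any(half)) {
    line <- which(rowSums(matrix(half, nrow = ns)) > 0)[1L]
    stop("malformed PED file '", paths["ped"], "' at line ", line,
         ": half-missing genotype", call. = FALSE)
  }
  ## orientation: alleleA = first allele observed in the data (sample order)
  alleleA <- character(nv)
  alleleB <- character(nv)
  calls <- matrix(NA_integer_, nrow = nv, ncol = ns)
  for (j in seq_len(nv)) {
    x1 <- a1[, j]
    x2 <- a2[, j]
    seen <- unique(stats::na.omit(as.vector(rbind(x1, x2))))
    if (length(seen) > 2L) {
      stop("PED file '", paths["ped"], "': variant ", map$id[j],
           " has more than two alleles", call. = FALSE)
    }
    if (length(seen) == 0L) {
      stop("PED file '", paths["ped"], "': variant ", map$id[j],
           " has no called genotypes", call. = FALSE)
    }
    alleleA[j] <- seen[1L]
    alleleB[j] <- if (length(seen) == 2L) seen[2L] else NA_character_
    b <- alleleB[j]
    calls[j, ] <- ifelse(is.na(x1), NA_integer_,
                         (!is.na(b) & x1 == b) + (!is.na(b) & x2 == b))
  }
  variants <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                         alleleA = alleleA, alleleB = alleleB)
  GenotypeData(variants, samples, calls = calls)
}

.writePlinkText <- function(x, paths) {
  calls <- genotypeCalls(x)
  aA <- alleleA(x)
  aB <- alleleB(x)
  nv <- nrow(x)
  ns <- ncol(x)
  map <- data.frame(chrom = chromosomes(x), id = variantIds(x), cm = 0L,
                    pos = positions(x))
  data.table::fwrite(map, paths["map"], sep = "\t", col.names = FALSE)
  ## per-variant pair of allele columns, alleleA written first in hets
  first <- matrix("0", nrow = nv, ncol = ns)
  second <- matrix("0", nrow = nv, ncol = ns)
  g0 <- !is.na(calls) & calls == 0L
  g1 <- !is.na(calls) & calls == 1L
  g2 <- !is.na(calls) & calls == 2L
  aAm <- matrix(aA, nrow = nv, ncol = ns)
  aBm <- matrix(aB, nrow = nv, ncol = ns)
  first[g0] <- aAm[g0]; second[g0] <- aAm[g0]
  first[g1] <- aAm[g1]; second[g1] <- aBm[g1]
  first[g2] <- aBm[g2]; second[g2] <- aBm[g2]
  if (any(is.na(first)) || any(is.na(second))) {
    stop("cannot write PLINK text: a non-missing call uses an unknown allele",
         call. = FALSE)
  }
  geno <- matrix(paste(first, second), nrow = nv)  # nv x ns of "a b"
  samples <- sampleIds(x)
  lines <- paste(samples, samples, 0L, 0L, 0L, -9L,
                 apply(geno, 2L, paste, collapse = " "))
  writeLines(lines, paths["ped"])
}

.readFam <- function(path) {
  fam <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(fam) < 6L) {
    stop("malformed FAM file '", path, "': fewer than 6 columns",
         call. = FALSE)
  }
  fam[[2L]]
}

.readBim <- function(path) {
  bim <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"))
  pos <- suppressWarnings(as.integer(bim$pos))
  if (anyNA(pos)) {
    stop("malformed BIM file '", path, "' at line ",
         which(is.na(pos))[1L], ": non-integer position", call. = FALSE)
  }
  data.frame(id = bim$id, chrom = bim$chrom, pos = pos,
             alleleA = bim$a1, alleleB = bim$a2)
}

## .bed 2-bit codes (SNP-major): 00 hom A1, 01 missing, 10 het, 11 hom A2.
## Calls count A2 (= alleleB) copies.
.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

.readPlinkBinary <- function(paths) {
  variants <- .readBim(paths["bim"])
  samples <- .readFam(paths["fam"])
  nv <- nrow(variants)
  ns <- length(samples)
  bpv <- ceiling(ns / 4)
  raw <- readBin(paths["bed"], what = "raw", n = 3L + nv * bpv)
  if (length(raw) < 3L || !identical(raw[1:3], .BED_MAGIC)) {
    stop("'", paths["bed"], "' is not a SNP-major PLINK .bed file",
         call. = FALSE)
  }
  if (length(raw) != 3L + nv * bpv) {
    stop("'", paths["bed"], "' size does not match ", nv, " variants x ",
         ns, " samples", call. = FALSE)
  }
  body <- raw[-(1:3)]
  ## decode all 4 x bpv 2-bit fields per variant, then trim to ns
  m <- matrix(as.integer(body), nrow = bpv)          # bpv x nv
  codes <- array(0L, dim = c(4L * bpv, nv))
  for (k in 0:3) {
    codes[k + 1L + 4L * (seq_len(bpv) - 1L), ] <- (m %/% 4L^k) %% 4L
  }
  codes <- codes[seq_len(ns), , drop = FALSE]        # ns x nv
  lut <- c(0L, NA_integer_, 1L, 2L)                  # code 0/1/2/3
  calls <- matrix(lut[codes + 1L], nrow = ns)
  GenotypeData(variants, samples, calls = t(calls))
}

.writePlinkBinary <- function(x, paths) {
  calls <- genotypeCalls(x)
  nv <- nrow(x)
  ns <- ncol(x)
  if (any(is.na(alleleB(x)) & !is.na(calls) & calls > 0L)) {
    stop("cannot write PLINK binary: B-allele calls at a variant with ",
         "unknown alleleB", call. = FALSE)
  }
  bim <- data.frame(chrom = chromosomes(x), id = variantIds(x), cm = 0L,
                    pos = positions(x),
                    a1 = alleleA(x),
                    a2 = ifelse(is.na(alleleB(x)), "0", alleleB(x)))
  data.table::fwrite(bim, paths["bim"], sep = "\t", col.names = FALSE)
  samples <- sampleIds(x)
  fam <- data.frame(fid = samples, iid = samples, pat = 0L, mat = 0L,
                    sex = 0L, pheno = -9L)
  data.table::fwrite(fam, paths["fam"], sep = "\t", col.names = FALSE)
  code <- matrix(1L, nrow = ns, ncol = nv)           # default: missing (01)
  lut <- c(0L, 2L, 3L)
  ok <- !is.na(calls)
  code[t(ok)] <- lut[t(calls)[t(ok)] + 1L]
  bpv <- ceiling(ns / 4)
  padded <- matrix(0L, nrow = 4L * bpv, ncol = nv)
  padded[seq_len(ns), ] <- code
  bytes <- matrix(0L, nrow = bpv, ncol = nv)
  for (k in 0:3) {
    bytes <- bytes + padded[k + 1L + 4L * (seq_len(bpv) - 1L), , drop = FALSE] * 4L^k
  }
  con <- file(paths["bed"], "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  writeBin(as.raw(bytes), con)
}
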
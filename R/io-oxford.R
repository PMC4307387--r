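## Oxford GEN (.gen + .sample) and SHAPEIT2 (.haps + .sample) formats.
## Both store one variant per line: "chrom id pos alleleA alleleB" followed by
## per-sample fields (three probabilities for GEN, two 0/1 haplotype alleles
## for haps). The .sample file is the two-header-line Oxford sample file.

.readSampleFile <- function(path) {
  toks <- .freadTokens(path)
  if (nrow(toks) < 3L) {
    stop("malformed sample file '", path,
         "': expected 2 header lines plus samples", call. = FALSE)
  }
  toks[-(1:2), 2L]  # ID_2 column
}

.writeSampleFile <- function(samples, path) {
  lines <- c("ID_1 ID_2 missing", "0 0 0",
             paste(samples, samples, 0))
  writeLines(lines, path)
}

.parseOxfordHeader <- function(toks, path, perSample, what) {
  nv <- nrow(toks)
  ns <- (ncol(toks) - 5L) / perSample
  if (ns != round(ns) || ns < 1L) {
    stop("malformed ", what, " file '", path, "': ", ncol(toks),
         " columns is not 5 + ", perSample, " x samples", call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(toks[, 3L]))
  if (anyNA(pos)) {
    stop("malformed ", what, " file '", path, "' at line ",
         which(is.na(pos))[1L], ": non-integer position", call. = FALSE)
  }
  snp <- toks[, 4L] %in% CANONICAL_ALLELES & toks[, 5L] %in% CANONICAL_ALLELES
  if (any(!snp)) {
    warning(sum(!snp), " non-SNP record(s) skipped in '", path, "'",
            call. = FALSE)
  }
  list(variants = data.frame(id = toks[, 2L], chrom = toks[, 1L], pos = pos,
                             alleleA = toks[, 4L], alleleB = toks[, 5L]),
       keep = which(snp), ns = as.integer(ns))
}

.readOxfordGen <- function(paths, callThreshold = 0.4) {
  samples <- .readSampleFile(paths["sample"])
  toks <- .freadTokens(paths["gen"])
  hdr <- .parseOxfordHeader(toks, paths["gen"], 3L, "GEN")
  if (hdr$ns != length(samples)) {
    stop("GEN/sample mismatch: ", hdr$ns, " samples in '", paths["gen"],
         "' vs ", length(samples), " in '", paths["sample"], "'",
         call. = FALSE)
  }
  keep <- hdr$keep
  body <- toks[keep, -(1:5), drop = FALSE]
  p <- suppressWarnings(matrix(as.numeric(body), nrow = length(keep)))
  if (anyNA(p)) {
    stop("malformed GEN file '", paths["gen"], "' at line ",
         keep[which(rowSums(is.na(p)) > 0)[1L]], ": non-numeric probability",
         call. = FALSE)
  }
  idx <- function(k) p[, 3L * (seq_len(hdr$ns) - 1L) + k, drop = FALSE]
  pAA <- idx(1L); pAB <- idx(2L); pBB <- idx(3L)
  s <- pAA + pAB + pBB
  if (any(s > 1 + 2e-3)) {
    stop("malformed GEN file '", paths["gen"],
         "': probability triplet sums well above 1", call. = FALSE)
  }
  ## rescale triplets pushed just above 1 by 3-decimal rounding
  over <- s > 1 + 1e-6
  if (any(over)) {
    pAA[over] <- pAA[over] / s[over]
    pAB[over] <- pAB[over] / s[over]
    pBB[over] <- pBB[over] / s[over]
  }
  ## triplets summing to ~0 encode missingness
  miss <- s < 0.5
  calls <- matrix(hardCall(pAA, pAB, pBB, threshold = callThreshold),
                  nrow = nrow(pAA))
  calls[miss] <- NA_integer_
  g <- GenotypeData(hdr$variants[keep, , drop = FALSE], samples,
                    calls = calls, probAA = pAA, probAB = pAB, probBB = pBB)
  S4Vectors::metadata(g)$skippedRecords <- nrow(toks) - length(keep)
  g
}

.writeOxfordGen <- function(x, paths) {
  .writeSampleFile(sampleIds(x), paths["sample"])
  nv <- nrow(x)
  ns <- ncol(x)
  if (hasProbabilities(x)) {
    pr <- genotypeProbabilities(x)
    pAA <- pr$probAA; pAB <- pr$probAB; pBB <- pr$probBB
  } else {
    calls <- genotypeCalls(x)
    pAA <- matrix(as.numeric(!is.na(calls) & calls == 0L), nv, ns)
    pAB <- matrix(as.numeric(!is.na(calls) & calls == 1L), nv, ns)
    pBB <- matrix(as.numeric(!is.na(calls) & calls == 2L), nv, ns)
  }
  probs <- matrix(NA_character_, nrow = nv, ncol = 3L * ns)
  fmt <- function(m) {
    m[is.na(m)] <- 0  # missingness is encoded as a 0 0 0 triplet
    formatC(m, digits = 3L, format = "f")
  }
  probs[, 3L * (seq_len(ns) - 1L) + 1L] <- fmt(pAA)
  probs[, 3L * (seq_len(ns) - 1L) + 2L] <- fmt(pAB)
  probs[, 3L * (seq_len(ns) - 1L) + 3L] <- fmt(pBB)
  if (any(is.na(alleleB(x)))) {
    stop("cannot write Oxford GEN: unknown alleleB", call. = FALSE)
  }
  lines <- paste(chromosomes(x), variantIds(x), positions(x),
                 alleleA(x), alleleB(x),
                 apply(probs, 1L, paste, collapse = " "))
  writeLines(lines, paths["gen"])
}

.readShapeit2 <- function(paths) {
  samples <- .readSampleFile(paths["sample"])
  toks <- .freadTokens(paths["haps"])
  hdr <- .parseOxfordHeader(toks, paths["haps"], 2L, "haps")
  if (hdr$ns != length(samples)) {
    stop("haps/sample mismatch: ", hdr$ns, " samples in '", paths["haps"],
         "' vs ", length(samples), " in '", paths["sample"], "'",
         call. = FALSE)
  }
  keep <- hdr$keep
  body <- toks[keep, -(1:5), drop = FALSE]
  ok <- body %in% c("0", "1", "?")
  if (any(!ok)) {
    stop("malformed haps file '", paths["haps"], "' at line ",
         keep[which(rowSums(matrix(!ok, nrow = length(keep))) > 0)[1L]],
         ": haplotype allele other than 0/1/?", call. = FALSE)
  }
  body[body == "?"] <- NA_character_
  h <- matrix(as.integer(body), nrow = length(keep))
  hapA <- h[, 2L * (seq_len(hdr$ns) - 1L) + 1L, drop = FALSE]
  hapB <- h[, 2L * (seq_len(hdr$ns) - 1L) + 2L, drop = FALSE]
  g <- GenotypeData(hdr$variants[keep, , drop = FALSE], samples,
                    hapA = hapA, hapB = hapB)
  S4Vectors::metadata(g)$skippedRecords <- nrow(toks) - length(keep)
  g
}

.writeShapeit2 <- function(x, paths) {
  stopifnot(isPhased(x))
  .writeSampleFile(sampleIds(x), paths["sample"])
  h <- haplotypeCalls(x)
  nv <- nrow(x)
  ns <- ncol(x)
  hap <- matrix(NA_character_, nrow = nv, ncol = 2L * ns)
  enc <- function(m) {
    out <- as.character(m)
    out[is.na(out)] <- "?"
    matrix(out, nrow = nv)
  }
  hap[, 2L * (seq_len(ns) - 1L) + 1L] <- enc(h$hapA)
  hap[, 2L * (seq_len(ns) - 1L) + 2L] <- enc(h$hapB)
  if (any(is.na(alleleB(x)))) {
    stop("cannot write SHAPEIT2 haps: unknown alleleB", call. = FALSE)
  }
  lines <- paste(chromosomes(x), variantIds(x), positions(x),
                 alleleA(x), alleleB(x),
                 apply(hap, 1L, paste, collapse = " "))
  writeLines(lines, paths["haps"])
}
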
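## Shared fixture builders. Everything is generated in code; no data files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

## AlleleFreq built directly from a frequency matrix (one column per
## population), for formula-level hand cases
makeAf <- function(freq, counts = NULL, chrom = "chr1",
                   pos = NULL, outgroup = "O") {
  freq <- as.matrix(freq)
  n <- nrow(freq)
  if (is.null(counts)) {
    counts <- matrix(10L, n, ncol(freq), dimnames = dimnames(freq))
  }
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(sites)$ref <- "A"
  mcols(sites)$alt <- "T"
  new("AlleleFreq", freq = freq, counts = counts, sites = sites,
      derivedIsAlt = rep(TRUE, n), siteIndex = seq_len(n),
      flagged = rep(FALSE, n), outgroup = outgroup)
}

## GenotypeData from a dosage matrix and a population label vector
makeDs <- function(geno, populations, ploidy = 2L, chrom = "chr1",
                   pos = NULL, seqlengths = NULL) {
  geno <- as.matrix(geno)
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 100L
  samples <- sprintf("s%02d", seq_len(ncol(geno)))
  genotypeData(geno, chrom = chrom, pos = pos, samples = samples,
               populations = populations, ploidy = ploidy,
               seqlengths = seqlengths)
}

## a toy VCF written to a temp file; `gts` is a character matrix of GT
## strings (sites x samples)
writeToyVcf <- function(chrom, pos, ref, alt, gts, samples,
                        path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  path
}

## brute-force pi: mean pairwise per-site difference over all pairs of
## allele copies, divided by the number of sites
brutePi <- function(geno, ploidy) {
  haps <- hapsFromGeno(geno, ploidy)
  n <- ncol(haps)
  if (n < 2) return(NA_real_)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cmp <- !is.na(haps[, i]) & !is.na(haps[, j])
    tot <- tot + sum(haps[cmp, i] != haps[cmp, j]) / nrow(haps)
    np <- np + 1
  }
  tot / np
}

## brute-force dxy: mean per-site mismatch over all between-group pairs
bruteDxy <- function(genoA, genoB, ploidy) {
  hA <- hapsFromGeno(genoA, ploidy)
  hB <- hapsFromGeno(genoB, ploidy)
  tot <- 0; np <- 0
  for (i in seq_len(ncol(hA))) for (j in seq_len(ncol(hB))) {
    cmp <- !is.na(hA[, i]) & !is.na(hB[, j])
    tot <- tot + sum(hA[cmp, i] != hB[cmp, j]) / nrow(hA)
    np <- np + 1
  }
  tot / np
}

## expand unphased dosages into allele-copy columns (order is irrelevant
## for site-wise statistics)
hapsFromGeno <- function(geno, ploidy) {
  if (ploidy == 1L) return(geno)
  out <- matrix(NA_integer_, nrow(geno), 2 * ncol(geno))
  for (s in seq_len(ncol(geno))) {
    g <- geno[, s]
    out[, 2 * s - 1] <- ifelse(is.na(g), NA_integer_,
                               as.integer(g >= 1L))
    out[, 2 * s] <- ifelse(is.na(g), NA_integer_, as.integer(g == 2L))
  }
  out
}

## quick null scenario (no pulse) used across tests
nullScenario <- function(seed, nSnps = 2000, samplesPerPop = 4L,
                         seqLengthBp = 2e6, ...) {
  scenarioParams(nSnps = nSnps, samplesPerPop = samplesPerPop,
                 seqLengthBp = seqLengthBp, seed = seed, ...)
}
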
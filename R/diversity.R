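## map sites to windows; returns list of integer site-index vectors
.sitesInWindows <- function(sites, windows) {
  hits <- GenomicRanges::findOverlaps(sites, windows)
  split(S4Vectors::queryHits(hits),
        factor(S4Vectors::subjectHits(hits), levels = seq_along(windows)))
}

.windowFrame <- function(windows, statName) {
  data.frame(chrom = as.character(seqnames(windows)),
             start = start(windows), end = end(windows),
             n_snps = 0L, n_sites = 0L, stat = statName,
             value = NA_real_, z = NA_real_, p = NA_real_,
             flagged = FALSE, stringsAsFactors = FALSE)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, the unbiased heterozygosity `2 p (1 - p) n / (n - 1)` over the
#' `n` called alleles of the population; a window's pi is the sum over its
#' usable sites divided by the chosen denominator. With
#' `denominator = "length"` (the default, appropriate when non-SNP
#' positions are known to be invariant) the denominator is the window width
#' in bp; with `"snps"` it is the number of usable genotyped sites in the
#' window, which estimates per-variant-site diversity only -- use it
#' deliberately.
#'
#' @param ds a `GenotypeData`
#' @param pop population name
#' @param windows a `GRanges` of windows; `NULL` for one window per
#'   chromosome. See [makeWindows()] (2 Mb / 1 Mb step is the conventional
#'   genome-scan setting).
#' @param denominator `"length"` or `"snps"`.
#' @return data frame of window statistics; windows with zero usable sites
#'   are flagged (`value` 0 under `"length"`, `NA` under `"snps"`).
#' @export
nucleotideDiversity <- function(ds, pop, windows = NULL,
                                denominator = c("length", "snps")) {
  denominator <- match.arg(denominator)
  if (!pop %in% levels(ds@pops)) stop("unknown population: ", pop)
  if (is.null(windows)) windows <- .wholeWindows(ds)
  fc <- .altFreqCounts(ds, ds@pops == pop)
  usable <- fc$counts >= 2L
  het <- ifelse(usable,
                2 * fc$freq * (1 - fc$freq) * fc$counts / (fc$counts - 1),
                0)
  out <- .windowFrame(windows, "pi")
  byWin <- .sitesInWindows(ds@sites, windows)
  for (w in seq_along(windows)) {
    idx <- byWin[[w]]
    use <- idx[usable[idx]]
    out$n_snps[w] <- length(idx)
    out$n_sites[w] <- length(use)
    if (!length(use)) {
      out$flagged[w] <- TRUE
      out$value[w] <- if (denominator == "length") 0 else NA_real_
    } else {
      den <- if (denominator == "length") width(windows)[w] else length(use)
      out$value[w] <- sum(het[use]) / den
    }
  }
  out
}

#' Windowed between-population divergence (dxy)
#'
#' Per site, the probability that one allele drawn from each population
#' mismatches: `pA (1 - pB) + pB (1 - pA)`, computed over called alleles
#' only, so randomly missing genotypes leave the estimate unchanged in
#' expectation. The window value divides the summed mismatch by the window
#' width in bp (`denominator = "length"`; requires that non-SNP positions
#' be invariant) or by the number of usable sites (`"snps"`).
#'
#' @inheritParams nucleotideDiversity
#' @param popA,popB the two populations
#' @return data frame of window statistics; windows with zero valid
#'   comparisons are flagged.
#' @export
dxy <- function(ds, popA, popB, windows = NULL,
                denominator = c("length", "snps")) {
  denominator <- match.arg(denominator)
  for (p in c(popA, popB))
    if (!p %in% levels(ds@pops)) stop("unknown population: ", p)
  if (is.null(windows)) windows <- .wholeWindows(ds)
  a <- .altFreqCounts(ds, ds@pops == popA)
  b <- .altFreqCounts(ds, ds@pops == popB)
  usable <- a$counts >= 1L & b$counts >= 1L
  mism <- ifelse(usable,
                 a$freq * (1 - b$freq) + b$freq * (1 - a$freq), 0)
  out <- .windowFrame(windows, "dxy")
  byWin <- .sitesInWindows(ds@sites, windows)
  for (w in seq_along(windows)) {
    idx <- byWin[[w]]
    use <- idx[usable[idx]]
    out$n_snps[w] <- length(idx)
    out$n_sites[w] <- length(use)
    if (!length(use)) {
      out$flagged[w] <- TRUE
      out$value[w] <- if (denominator == "length") 0 else NA_real_
    } else {
      den <- if (denominator == "length") width(windows)[w] else length(use)
      out$value[w] <- sum(mism[use]) / den
    }
  }
  out
}

## per-site Hudson FST numerator/denominator over called alleles
.hudsonTerms <- function(ds, colsA, colsB) {
  a <- .altFreqCounts(ds, colsA)
  b <- .altFreqCounts(ds, colsB)
  usable <- a$counts >= 2L & b$counts >= 2L
  pA <- a$freq; pB <- b$freq
  num <- (pA - pB)^2 -
    pA * (1 - pA) / (a$counts - 1) -
    pB * (1 - pB) / (b$counts - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  num[!usable] <- NA_real_
  den[!usable] <- NA_real_
  list(num = num, den = den, usable = usable)
}

## per-site Weir-Cockerham (1984) two-population variance components
.wcTerms <- function(ds, colsA, colsB) {
  if (ploidy(ds) != 2L)
    stop("the Weir-Cockerham estimator requires diploid genotypes; ",
         "use fstHudson() for haploid-coded data")
  gA <- ds@geno[, colsA, drop = FALSE]
  gB <- ds@geno[, colsB, drop = FALSE]
  nA <- rowSums(!is.na(gA)); nB <- rowSums(!is.na(gB))
  pA <- rowSums(gA, na.rm = TRUE) / (2 * nA)
  pB <- rowSums(gB, na.rm = TRUE) / (2 * nB)
  hA <- rowSums(gA == 1L, na.rm = TRUE) / nA
  hB <- rowSums(gB == 1L, na.rm = TRUE) / nB
  usable <- nA >= 1L & nB >= 1L & (nA + nB) >= 3L
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (nA + nB - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (nA + nB)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (nA + nB)
  aComp <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  bComp <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cComp <- hbar / 2
  usable <- usable & nbar > 1 & nc > 0
  aComp[!usable] <- NA_real_
  bComp[!usable] <- NA_real_
  cComp[!usable] <- NA_real_
  list(num = aComp, den = aComp + bComp + cComp, usable = usable)
}

.fstWindows <- function(ds, popA, popB, windows, terms, statName) {
  if (is.null(windows)) windows <- .wholeWindows(ds)
  out <- .windowFrame(windows, statName)
  byWin <- .sitesInWindows(ds@sites, windows)
  for (w in seq_along(windows)) {
    idx <- byWin[[w]]
    use <- idx[terms$usable[idx]]
    out$n_snps[w] <- length(idx)
    out$n_sites[w] <- length(use)
    if (!length(use) || sum(terms$den[use]) == 0) {
      out$flagged[w] <- TRUE
    } else {
      out$value[w] <- sum(terms$num[use]) / sum(terms$den[use])
    }
  }
  out
}

#' Windowed Hudson FST (ratio of sums)
#'
#' Per-site numerator `(pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)` and
#' denominator `pA(1-pB) + pB(1-pA)`; the window value is the ratio of the
#' summed numerators to the summed denominators. Sites with fewer than two
#' called alleles in either population are excluded. Negative estimates are
#' reported as-is (no clamping).
#'
#' @inheritParams dxy
#' @return data frame of window statistics.
#' @export
fstHudson <- function(ds, popA, popB, windows = NULL) {
  for (p in c(popA, popB))
    if (!p %in% levels(ds@pops)) stop("unknown population: ", p)
  terms <- .hudsonTerms(ds, ds@pops == popA, ds@pops == popB)
  .fstWindows(ds, popA, popB, windows, terms, "fst_hudson")
}

#' Windowed Weir-Cockerham FST (theta, ratio of sums)
#'
#' Two-level Weir-Cockerham (1984) theta for two populations, accumulated
#' as a ratio of summed variance components across the sites of each
#' window. Exclusion rules match [fstHudson()].
#'
#' @inheritParams dxy
#' @return data frame of window statistics.
#' @export
fstWC <- function(ds, popA, popB, windows = NULL) {
  for (p in c(popA, popB))
    if (!p %in% levels(ds@pops)) stop("unknown population: ", p)
  terms <- .wcTerms(ds, which(ds@pops == popA), which(ds@pops == popB))
  .fstWindows(ds, popA, popB, windows, terms, "fst_wc")
}

#' Haplotype diversity with sampling standard deviation
#'
#' Unbiased haplotype diversity `h = n/(n-1) (1 - sum p_i^2)` with the
#' large-sample variance of Nei (1987, eq. 8.12):
#' `V = 2/(n(n-1)) { 2(n-2) [sum p^3 - (sum p^2)^2] + sum p^2 - (sum p^2)^2 }`.
#' Note that published tables sometimes print a differently derived
#' dispersion for h; [bootstrapHaplotypeSd()] offers a resampling
#' cross-check.
#'
#' @param x integer vector of haplotype multiplicities, or a
#'   `DNAStringSet`/FASTA path (the spectrum is then counted with
#'   [haplotypeSpectrum()]).
#' @return list with `h`, `sd`, `variance`, `n` (sequences) and `k`
#'   (distinct haplotypes).
#' @export
haplotypeDiversity <- function(x) {
  counts <- if (is.numeric(x)) x else haplotypeSpectrum(x)
  if (any(counts < 1)) stop("multiplicities must be positive")
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity requires at least 2 sequences")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(h = h, sd = sqrt(v), variance = v, n = n, k = length(counts))
}

#' Count the haplotype spectrum of an alignment
#'
#' @param x a `DNAStringSet` or path to a FASTA alignment
#' @return integer vector of multiplicities, sorted decreasing.
#' @export
haplotypeSpectrum <- function(x) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  tab <- table(as.character(x))
  sort(as.integer(tab), decreasing = TRUE)
}

#' Bootstrap standard deviation of haplotype diversity
#'
#' Resamples `n` sequences from the observed haplotype frequencies and
#' recomputes h; a model-free cross-check of the analytic variance.
#'
#' @param counts haplotype multiplicities
#' @param nBoot bootstrap replicates
#' @param seed integer seed
#' @return bootstrap standard deviation of h
#' @export
bootstrapHaplotypeSd <- function(counts, nBoot = 1000L, seed = 1L) {
  n <- sum(counts)
  p <- counts / n
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hs <- vapply(seq_len(nBoot), function(i) {
    cts <- as.vector(stats::rmultinom(1, n, p))
    cts <- cts[cts > 0]
    n / (n - 1) * (1 - sum((cts / n)^2))
  }, numeric(1))
  stats::sd(hs)
}

## genome-wide scalar for a two-population comparison
.pairStat <- function(ds, popA, popB, statistic) {
  switch(statistic,
    fst_hudson = {
      t <- .hudsonTerms(ds, ds@pops == popA, ds@pops == popB)
      sum(t$num[t$usable]) / sum(t$den[t$usable])
    },
    fst_wc = {
      t <- .wcTerms(ds, which(ds@pops == popA), which(ds@pops == popB))
      sum(t$num[t$usable]) / sum(t$den[t$usable])
    },
    dxy = {
      a <- .altFreqCounts(ds, ds@pops == popA)
      b <- .altFreqCounts(ds, ds@pops == popB)
      ok <- a$counts >= 1L & b$counts >= 1L
      mean((a$freq * (1 - b$freq) + b$freq * (1 - a$freq))[ok])
    },
    pi_diff = {
      pi1 <- nucleotideDiversity(ds, popA, denominator = "snps")$value
      pi2 <- nucleotideDiversity(ds, popB, denominator = "snps")$value
      abs(mean(pi1, na.rm = TRUE) - mean(pi2, na.rm = TRUE))
    },
    stop("unknown statistic: ", statistic))
}

#' Label-permutation significance for a two-population statistic
#'
#' Shuffles population labels over the combined samples of the two groups
#' (sizes preserved) and reports the add-one permutation p-value
#' `p = (1 + #{permuted >= observed}) / (nPerm + 1)`, so p is never exactly
#' zero and its minimum attainable value is `1/(nPerm+1)`. The conventional
#' setting is 1000 permutations.
#'
#' @param ds a `GenotypeData`
#' @param popA,popB the two populations
#' @param statistic one of `"fst_wc"`, `"fst_hudson"`, `"dxy"`, `"pi_diff"`
#' @param nPerm number of permutations (>= 1)
#' @param seed integer seed
#' @return list with `observed`, `p`, `nPerm`, `nValid` (permutations where
#'   the statistic was defined) and `flagged` (`TRUE` when the statistic
#'   was undefined on more than half the permutations, in which case `p` is
#'   `NA`).
#' @export
permutationTest <- function(ds, popA, popB,
                            statistic = c("fst_wc", "fst_hudson", "dxy",
                                          "pi_diff"),
                            nPerm = 1000L, seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(nPerm >= 1L)
  obs <- .pairStat(ds, popA, popB, statistic)
  cols <- which(ds@pops %in% c(popA, popB))
  nA <- sum(ds@pops == popA)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- vapply(seq_len(nPerm), function(i) {
    shuffled <- sample(cols)
    p <- as.character(ds@pops)
    p[shuffled[seq_len(nA)]] <- popA
    p[shuffled[-seq_len(nA)]] <- popB
    ds2 <- ds
    ds2@pops <- factor(p)
    .pairStat(ds2, popA, popB, statistic)
  }, numeric(1))
  nValid <- sum(is.finite(perm))
  flagged <- nValid < nPerm / 2
  p <- if (flagged) NA_real_ else
    (1 + sum(perm[is.finite(perm)] >= obs)) / (nPerm + 1)
  list(observed = obs, p = p, nPerm = nPerm, nValid = nValid,
       flagged = flagged)
}
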
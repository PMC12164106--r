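## per-site D numerator and denominator for a trio (P1, P2, P3, O).
## Sites where the denominator term is 0 contribute 0 to both sums.
.dTerms <- function(af, trio) {
  need <- unname(trio[c("P1", "P2", "P3", "O")])
  missing <- setdiff(need, colnames(af@freq))
  if (length(missing))
    stop("population(s) absent from AlleleFreq: ",
         paste(missing, collapse = ", "))
  p1 <- af@freq[, trio[["P1"]]]
  p2 <- af@freq[, trio[["P2"]]]
  p3 <- af@freq[, trio[["P3"]]]
  pO <- af@freq[, trio[["O"]]]
  informative <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(pO))
  num <- (p2 - p1) * (p3 - pO)
  den <- (p2 + p1 - 2 * p2 * p1) * (p3 + pO - 2 * p3 * pO)
  zero <- !informative | den == 0
  num[zero] <- 0
  den[zero] <- 0
  list(num = num, den = den, informative = informative & !zero)
}

#' Trio specification for four-taxon statistics
#'
#' @param P1 reference (non-introgressed) population
#' @param P2 target population tested for introgression
#' @param P3 donor population
#' @param O outgroup used for polarization
#' @return named character vector accepted by [dStatistic()], [f4Ratio()],
#'   [fdmWindows()].
#' @export
trioSpec <- function(P1, P2, P3, O) {
  trio <- c(P1 = P1, P2 = P2, P3 = P3, O = O)
  if (anyDuplicated(trio)) stop("the four trio populations must be distinct")
  trio
}

#' Patterson's D statistic
#'
#' `D = sum (p2 - p1)(p3 - pO) / sum (p2 + p1 - 2 p1 p2)(p3 + pO - 2 p3 pO)`
#' over polarized sites, the allele-frequency form of the ABBA-BABA
#' asymmetry: `D > 0` indicates an excess of P2-P3 derived-allele sharing
#' over P1-P3 sharing.
#'
#' @param af an [AlleleFreq-class] from [polarize()]
#' @param trio a [trioSpec()]
#' @return D in `[-1, 1]`, or `NA` (flagged via attribute `flagged`) when
#'   the total denominator is zero.
#' @export
dStatistic <- function(af, trio) {
  t <- .dTerms(af, trio)
  den <- sum(t$den)
  if (den == 0) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  sum(t$num) / den
}

#' Block-jackknife test of Patterson's D
#'
#' Partitions the informative sites, in genome order, into `nBlocks`
#' contiguous blocks of (near-)equal site count, and computes the delete-one
#' jackknife standard error of the ratio-of-sums D:
#' `SE^2 = (B-1)/B * sum_b (D_(-b) - mean(D_(-b)))^2`, `Z = D / SE`,
#' with a two-sided normal p-value by default (`alternative = "greater"`
#' gives the one-sided excess-ABBA test). Blocks with zero informative
#' sites are dropped and counted.
#'
#' @param af an `AlleleFreq`
#' @param trio a [trioSpec()]
#' @param nBlocks number of jackknife blocks (>= 2; 20 by convention)
#' @param alternative `"two.sided"` or `"greater"`
#' @return list with `D`, `se`, `Z`, `p`, `nSites` (informative),
#'   `nBlocks` (used) and `flagged` (`TRUE` when the statistic has no
#'   variance across blocks, in which case `se` is 0 and `Z`/`p` are `NA`).
#' @export
dJackknife <- function(af, trio, nBlocks = 20L,
                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(nBlocks >= 2L)
  t <- .dTerms(af, trio)
  idx <- which(t$informative)
  if (!length(idx)) stop("no informative sites for this trio")
  D <- sum(t$num) / sum(t$den)
  block <- cut(seq_along(idx), breaks = nBlocks, labels = FALSE)
  numB <- tapply(t$num[idx], block, sum)
  denB <- tapply(t$den[idx], block, sum)
  keep <- denB != 0
  nDropped <- sum(!keep)
  numB <- numB[keep]; denB <- denB[keep]
  B <- length(numB)
  if (B < 2L) stop("fewer than 2 usable jackknife blocks")
  totN <- sum(numB); totD <- sum(denB)
  dMinus <- (totN - numB) / (totD - denB)
  se <- sqrt((B - 1) / B * sum((dMinus - mean(dMinus))^2))
  if (se == 0) {
    return(list(D = D, se = 0, Z = NA_real_, p = NA_real_,
                nSites = length(idx), nBlocks = B, nDroppedBlocks = nDropped,
                flagged = TRUE))
  }
  Z <- D / se
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(Z)),
              greater = stats::pnorm(Z, lower.tail = FALSE))
  list(D = D, se = se, Z = Z, p = p, nSites = length(idx), nBlocks = B,
       nDroppedBlocks = nDropped, flagged = FALSE)
}

#' f4-ratio estimate of the admixture fraction
#'
#' `f4-ratio = sum (p3a - pO)(p2 - p1) / sum (p3a - pO)(p3b - p1)`, where
#' P3a/P3b are a random bipartition of the donor from [splitDonor()]. Under
#' a single pulse from P3 into P2 the ratio estimates the admixture
#' fraction f. `denomForm = "p3b-pO"` substitutes `(p3b - pO)` in the
#' denominator, an alternative formulation some tools use; the default
#' follows the canonical `(p3b - p1)` form.
#'
#' @param ds the `GenotypeData` the frequencies were computed from
#' @param af an `AlleleFreq`
#' @param trio a [trioSpec()]
#' @param split donor bipartition from [splitDonor()]
#' @param denomForm `"p3b-p1"` (default) or `"p3b-pO"`
#' @return the ratio, or `NA` flagged when the denominator sum is zero.
#' @export
f4Ratio <- function(ds, af, trio, split,
                    denomForm = c("p3b-p1", "p3b-pO")) {
  denomForm <- match.arg(denomForm)
  p1 <- af@freq[, trio[["P1"]]]
  p2 <- af@freq[, trio[["P2"]]]
  pO <- af@freq[, trio[["O"]]]
  p3a <- polarizedFreq(ds, af, split$p3a)
  p3b <- polarizedFreq(ds, af, split$p3b)
  ok <- !(is.na(p1) | is.na(p2) | is.na(pO) | is.na(p3a) | is.na(p3b))
  num <- sum(((p3a - pO) * (p2 - p1))[ok])
  den <- if (denomForm == "p3b-p1")
    sum(((p3a - pO) * (p3b - p1))[ok])
  else
    sum(((p3a - pO) * (p3b - pO))[ok])
  if (den == 0) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  num / den
}

## per-site fdM numerator and (dynamic-donor) denominator
.fdmTerms <- function(p1, p2, p3, pO) {
  num <- (1 - p1) * p2 * p3 * (1 - pO) - p1 * (1 - p2) * p3 * (1 - pO)
  den <- numeric(length(num))
  up <- p2 >= p1
  pd <- pmax(p2, p3)
  den[up] <- ((1 - p1) * pd * pd * (1 - pO) -
                p1 * (1 - pd) * pd * (1 - pO))[up]
  pd2 <- pmax(p1, p3)
  den[!up] <- -((1 - pd2) * p2 * pd2 * (1 - pO) -
                  pd2 * (1 - p2) * pd2 * (1 - pO))[!up]
  list(num = num, den = den)
}

#' Sliding-window fdM introgression scan
#'
#' For each window of `winSnps` polarized sites (step `stepSnps`), computes
#' `fdM = S(P1,P2,P3,O) / S(P1,Pd,Pd,O)` where
#' `S = sum (1-p1) p2 p3 (1-pO) - sum p1 (1-p2) p3 (1-pO)` and the dynamic
#' donor Pd takes, per site, the larger of the two frequencies on the
#' branch the site supports: max(p2, p3) where derived alleles in P2 reach
#' at least the P1 frequency (P2-P3 sharing), max(p1, p3) otherwise (P1-P3
#' sharing, which contributes negatively). fdM is bounded in `[-1, 1]`,
#' symmetric for P2-P3 versus P1-P3 introgression.
#'
#' @param af an `AlleleFreq`
#' @param trio a [trioSpec()]
#' @param winSnps window size in SNPs (50 by convention)
#' @param stepSnps step in SNPs (25 by convention)
#' @return data frame with one row per window (chrom, start, end, n_snps,
#'   stat, value, flagged); windows whose denominator is zero are flagged
#'   and excluded from downstream ranking.
#' @export
fdmWindows <- function(af, trio, winSnps = 50L, stepSnps = 25L) {
  p1 <- af@freq[, trio[["P1"]]]
  p2 <- af@freq[, trio[["P2"]]]
  p3 <- af@freq[, trio[["P3"]]]
  pO <- af@freq[, trio[["O"]]]
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(pO))
  sites <- af@sites[ok]
  t <- .fdmTerms(p1[ok], p2[ok], p3[ok], pO[ok])
  wins <- .snpWindows(as.character(seqnames(sites)), winSnps, stepSnps)
  num <- .winSums(t$num, wins$i0, wins$i1)
  den <- .winSums(t$den, wins$i0, wins$i1)
  data.frame(chrom = wins$chrom,
             start = start(sites)[wins$i0],
             end = start(sites)[wins$i1],
             n_snps = wins$i1 - wins$i0 + 1L,
             stat = "fdm",
             value = ifelse(den == 0, NA_real_, num / den),
             flagged = den == 0, stringsAsFactors = FALSE)
}

#' Call introgressed windows
#'
#' Two calling rules are provided, reflecting the two conventions in use:
#' `mode = "quantile"` (default) calls the top `topFrac` of fdM windows;
#' `mode = "ztest"` Z-transforms fdM across windows and calls windows with
#' one-tailed (upper) `p < alpha`. Either way, calls are made only when the
#' genome-wide D is positive, and called windows are merged into a region
#' set.
#'
#' @param fdm window table from [fdmWindows()]
#' @param D genome-wide Patterson's D for the same trio
#' @param mode `"quantile"` or `"ztest"`
#' @param topFrac top fraction called in quantile mode (default 0.05)
#' @param alpha significance level in ztest mode (default 0.05)
#' @return a `GRanges` of merged called regions (empty when `D <= 0`, when
#'   fdM has no variance in ztest mode, or when nothing passes).
#' @export
callIntrogressedWindows <- function(fdm, D,
                                    mode = c("quantile", "ztest"),
                                    topFrac = 0.05, alpha = 0.05) {
  mode <- match.arg(mode)
  fdm <- fdm[!fdm$flagged & !is.na(fdm$value), , drop = FALSE]
  empty <- GRanges()
  if (is.na(D) || D <= 0 || !nrow(fdm)) return(empty)
  if (mode == "quantile") {
    if (nrow(fdm) < 20L)
      stop("quantile mode requires at least 20 windows (got ", nrow(fdm), ")")
    k <- max(1L, floor(topFrac * nrow(fdm)))
    thr <- sort(fdm$value, decreasing = TRUE)[k]
    call <- fdm$value >= thr
  } else {
    s <- stats::sd(fdm$value)
    if (!is.finite(s) || s == 0) {
      message("fdM has zero variance across windows; nothing called")
      return(empty)
    }
    z <- (fdm$value - mean(fdm$value)) / s
    call <- stats::pnorm(z, lower.tail = FALSE) < alpha
  }
  if (!any(call)) return(empty)
  reduce(GRanges(fdm$chrom[call],
                 IRanges(fdm$start[call], fdm$end[call])))
}
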
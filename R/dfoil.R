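## Five-taxon site-pattern statistics for the direction of gene flow.
##
## Site patterns are 4-letter strings over (P1, P2, P3, P4) with the
## outgroup defining the ancestral state A; e.g. "BABA" means P1 and P3
## carry the derived allele. The four statistics are each (L - R)/(L + R)
## over two groups of two patterns. The groups (shipped as a TSV in
## inst/extdata so they can be audited) are constructed so that, on the
## symmetric tree (((P1,P2),(P3,P4)),O) under incomplete lineage sorting
## alone, the left and right groups have equal expected weight -- each left
## pattern is matched by its P1<->P2 or P3<->P4 mirror on the right:
##   DFO = {BABA,BBBA} vs {BAAB,BBAB}: P1-anchored P3-vs-P4 sharing;
##   DIL = {ABBA,BBBA} vs {ABAB,BBAB}: P2-anchored P3-vs-P4 sharing;
##   DFI = {BABA,BABB} vs {ABBA,ABBB}: P3-anchored P1-vs-P2 sharing;
##   DOL = {BAAB,BABB} vs {ABAB,ABBB}: P4-anchored P1-vs-P2 sharing.
## DFO/DIL are antisymmetric under P3<->P4; DFI/DOL under P1<->P2.
## Singleton and concordant (BBAA/AABB) patterns carry no discordance
## signal and are excluded.

.dfoilEnv <- new.env(parent = emptyenv())

#' DFOIL pattern-group membership
#'
#' @return data frame with columns `statistic`, `side` (L/R) and `pattern`
#'   (4 letters over P1, P2, P3, P4; the outgroup is ancestral).
#' @export
dfoilPatternGroups <- function() {
  if (is.null(.dfoilEnv$groups)) {
    path <- system.file("extdata", "dfoil_pattern_groups.tsv",
                        package = "introScan", mustWork = TRUE)
    .dfoilEnv$groups <- utils::read.table(path, header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE)
  }
  .dfoilEnv$groups
}

## Gene-flow signature table. Any flow touching P3 elevates the
## P3-vs-P4 contrasts (DFO, DIL, or both). The P3-anchored P1-vs-P2
## contrast DFI identifies which ingroup taxon is involved (+ for P1,
## - for P2). The P4-anchored contrast DOL is elevated only when the
## material moved FROM P3 into the ingroup: donated P3 lineages carry
## alleles that predate the P3/P4 split and therefore also sit in P4
## (pattern BABB or ABBB), whereas flow in the opposite direction sends
## P1/P2-side alleles into P3 without ever touching P4 -- so the
## zero/nonzero state of DOL gives the direction. Flow between P3 and the
## unsplit P1-P2 ancestor elevates BBBA alone: DFO and DIL positive, DFI
## and DOL flat.
.dfoilDirections <- data.frame(
  direction = c("P3->P1", "P1->P3", "P3->P2", "P2->P3",
                "P3<->P12 ancestral", "none"),
  DFO = c("+", "+", "+", "+", "+", "0"),
  DIL = c("+", "+", "+", "+", "+", "0"),
  DFI = c("+", "+", "-", "-", "0", "0"),
  DOL = c("+", "0", "-", "0", "0", "0"),
  stringsAsFactors = FALSE)

#' Direction signature table for the DFOIL statistics
#'
#' Expected signs of (DFO, DIL, DFI, DOL) under each gene-flow
#' configuration; "0" means not significantly different from zero. The
#' classifier reads the table DFI-first (the pair), then DOL (the
#' direction), with DFO/DIL carrying the ancestral row. Derived analytically
#' for the pattern groups of [dfoilPatternGroups()] and verified by
#' simulation. The zero-vs-nonzero state of DOL carries the direction
#' within a pair and is the least powerful part of the classification --
#' with weak data a true P3->P1 flow degrades gracefully to the P1->P3
#' row rather than to a wrong pair.
#'
#' @return data frame of signatures.
#' @export
dfoilDirectionTable <- function() .dfoilDirections

.allPatterns <- apply(expand.grid(rep(list(c("A", "B")), 4))[, 4:1], 1,
                      paste, collapse = "")

#' Count five-taxon site patterns
#'
#' For taxa (P1, P2, P3, P4, O), accumulates the weight of each of the 16
#' derived/ancestral presence patterns of (P1..P4), the ancestral state
#' being defined by the outgroup. In `"weighted"` mode (the default,
#' matching allele-frequency input) each site contributes the product of
#' its per-population derived frequencies (p for B, 1-p for A) times the
#' probability `1 - pO` that the outgroup is ancestral. In `"binarized"`
#' mode each site contributes a unit count to the single pattern obtained
#' by thresholding frequencies at `threshold`, and outgroup-derived sites
#' are skipped; binarized counts equal weighted counts when all frequencies
#' are 0/1.
#'
#' @param af an [AlleleFreq-class]
#' @param taxa named character vector with entries `P1`, `P2`, `P3`, `P4`,
#'   `O` giving population names
#' @param mode `"weighted"` or `"binarized"`
#' @param threshold binarization threshold (default 0.5)
#' @return named numeric vector of 16 pattern weights, with attributes
#'   `nSkipped` (sites missing a taxon) and `mode`.
#' @export
countPatterns <- function(af, taxa, mode = c("weighted", "binarized"),
                          threshold = 0.5) {
  mode <- match.arg(mode)
  need <- c("P1", "P2", "P3", "P4", "O")
  if (!all(need %in% names(taxa))) stop("taxa must name P1, P2, P3, P4, O")
  missing <- setdiff(unname(taxa[need]), colnames(af@freq))
  if (length(missing))
    stop("population(s) absent from AlleleFreq: ",
         paste(missing, collapse = ", "))
  P <- af@freq[, taxa[c("P1", "P2", "P3", "P4")], drop = FALSE]
  pO <- af@freq[, taxa[["O"]]]
  ok <- stats::complete.cases(P) & !is.na(pO)
  nSkipped <- sum(!ok)
  P <- P[ok, , drop = FALSE]
  pO <- pO[ok]
  counts <- stats::setNames(numeric(16), .allPatterns)
  if (mode == "weighted") {
    for (pat in .allPatterns) {
      b <- strsplit(pat, "")[[1]] == "B"
      w <- (1 - pO)
      for (k in 1:4) w <- w * (if (b[k]) P[, k] else 1 - P[, k])
      counts[pat] <- sum(w)
    }
  } else {
    keep <- pO < threshold
    B <- P[keep, , drop = FALSE] >= threshold
    pat <- apply(B, 1, function(b)
      paste(ifelse(b, "B", "A"), collapse = ""))
    tab <- table(factor(pat, levels = .allPatterns))
    counts[] <- as.numeric(tab)
  }
  attr(counts, "nSkipped") <- nSkipped
  attr(counts, "mode") <- mode
  counts
}

#' DFOIL statistics and direction of gene flow
#'
#' Computes DFO, DIL, DFI and DOL as `(L - R)/(L + R)` over the pattern
#' groups of [dfoilPatternGroups()], tests each with a 1-df chi-squared on
#' the (L, R) totals (exactly calibrated for binarized unit counts;
#' conservative for frequency-weighted counts), and maps the significant
#' sign pattern to a gene-flow class via [dfoilDirectionTable()]: the
#' sign of DFI identifies which ingroup taxon exchanged material with P3
#' (+ for P1, - for P2), the zero/nonzero state of DOL gives the
#' direction within the pair (donated P3 material carries
#' pre-P3/P4-split alleles that also appear in P4), and DFO/DIL positive
#' with DFI and DOL flat indicates flow into the unsplit P1-P2 ancestor.
#' A statistic with `L + R = 0` is undefined and forces direction
#' `"undetermined"`.
#'
#' Binarized counting ([countPatterns()] with `mode = "binarized"`) is
#' recommended for inference: the statistics keep their meaning under
#' frequency-weighted counting but lose most of their power, and the
#' chi-squared test becomes conservative.
#'
#' The statistics are invariant under multiplying all counts by a positive
#' constant; the chi-squared p-values are not (they scale with the data).
#'
#' @param counts pattern counts from [countPatterns()]
#' @param alpha significance level used for the sign classification
#' @return list with `stats` (data frame: statistic, left, right, value,
#'   chisq, p, sign) and `direction`.
#' @export
dfoilStatistics <- function(counts, alpha = 0.05) {
  groups <- dfoilPatternGroups()
  statNames <- c("DFO", "DIL", "DFI", "DOL")
  res <- lapply(statNames, function(s) {
    L <- sum(counts[groups$pattern[groups$statistic == s &
                                     groups$side == "L"]])
    R <- sum(counts[groups$pattern[groups$statistic == s &
                                     groups$side == "R"]])
    if (L + R == 0)
      return(data.frame(statistic = s, left = L, right = R,
                        value = NA_real_, chisq = NA_real_, p = NA_real_,
                        sign = NA_character_, stringsAsFactors = FALSE))
    val <- (L - R) / (L + R)
    x2 <- (L - R)^2 / (L + R)
    p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
    sg <- if (p < alpha) (if (val > 0) "+" else "-") else "0"
    data.frame(statistic = s, left = L, right = R, value = val,
               chisq = x2, p = p, sign = sg, stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, res)

  ## DFI -- the P3-anchored P1-vs-P2 contrast -- is the primary pair
  ## detector (it is the direct analogue of Patterson's D for which
  ## ingroup taxon shares excess derived alleles with P3); DOL then
  ## resolves the direction, and DFO/DIL alone indicate flow into the
  ## unsplit P1-P2 ancestor.
  direction <- "undetermined"
  if (!anyNA(stats$value)) {
    sig <- stats::setNames(stats$sign, stats$statistic)
    if (all(sig == "0")) {
      direction <- "none"
    } else if (sig[["DFI"]] == "+" && sig[["DOL"]] != "-") {
      direction <- if (sig[["DOL"]] == "+") "P3->P1" else "P1->P3"
    } else if (sig[["DFI"]] == "-" && sig[["DOL"]] != "+") {
      direction <- if (sig[["DOL"]] == "-") "P3->P2" else "P2->P3"
    } else if (sig[["DFI"]] == "0" && sig[["DOL"]] == "0" &&
               (sig[["DFO"]] == "+" || sig[["DIL"]] == "+")) {
      direction <- "P3<->P12 ancestral"
    }
  }
  list(stats = stats, direction = direction)
}

#' Taxa preset mirroring the sheep/mouflon study design
#'
#' The configuration used for the wild-to-domestic question in sheep:
#' the pooled introgressed South-and-Southeast-Asian breeds as P1, the
#' Menz reference breed as P2, the island wild subpopulation as the donor
#' P3, the widespread wild subpopulation as P4, and bighorn as outgroup.
#' Map the values to your own population names.
#'
#' @param P1,P2,P3,P4,O population names
#' @return named character vector for [countPatterns()].
#' @export
dfoilTaxa <- function(P1 = "SSA", P2 = "MEN", P3 = "gmelini2",
                      P4 = "gmelini1", O = "bighorn") {
  taxa <- c(P1 = P1, P2 = P2, P3 = P3, P4 = P4, O = O)
  if (anyDuplicated(taxa)) stop("the five taxa must be distinct")
  taxa
}
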
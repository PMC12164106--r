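#' Population branch statistic from three pairwise FST values
#'
#' `PBS = (T_SM + T_SG - T_MG) / 2` with `T = -ln(1 - FST)` (natural log),
#' where S is the focal population and M, G the two references: the length
#' of the focal branch since the three-way divergence, in units of
#' allele-frequency change. Negative FST inputs are floored at 0 and values
#' at or above 1 are capped at `1 - 1e-9` before the log; both adjustments
#' are flagged via the `adjusted` attribute.
#'
#' @param fSM FST between focal and reference 1
#' @param fSG FST between focal and reference 2
#' @param fMG FST between the two references
#' @return PBS value(s); vectorized.
#' @export
pbsFromFst <- function(fSM, fSG, fMG) {
  vals <- cbind(fSM, fSG, fMG)
  if (any(!is.finite(vals))) stop("non-finite FST input")
  adjusted <- any(vals < 0) || any(vals >= 1)
  vals[vals < 0] <- 0
  vals[vals >= 1] <- 1 - 1e-9
  T <- -log(1 - vals)
  out <- (T[, 1] + T[, 2] - T[, 3]) / 2
  attr(out, "adjusted") <- adjusted
  out
}

#' PBS selection scan in SNP-count windows
#'
#' Computes, per window of `winSnps` usable sites (step `stepSnps`), the
#' Hudson ratio-of-sums FST for the three population pairs and the
#' resulting PBS of the focal branch. The focal group may pool several
#' populations (their samples are unioned). Windows with an undefined
#' pairwise FST are flagged and excluded from ranking and permutation.
#'
#' @param ds a `GenotypeData`
#' @param focal focal population name, or a character vector of populations
#'   to pool
#' @param ref1,ref2 the two reference populations
#' @param winSnps window size in SNPs (50 by convention)
#' @param stepSnps step in SNPs (25 by convention)
#' @param estimator `"hudson"` (default) or `"wc"`
#' @return data frame: chrom, start, end, n_snps, fst_sm, fst_sg, fst_mg,
#'   pbs, flagged; the attribute `scanSpec` records the configuration for
#'   [pbsPermutationP()].
#' @export
pbsScan <- function(ds, focal, ref1, ref2, winSnps = 50L, stepSnps = 25L,
                    estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  if (length(focal) > 1L) {
    ds <- poolPopulations(ds, ".focal", focal)
    focal <- ".focal"
  }
  for (p in c(focal, ref1, ref2))
    if (!p %in% levels(ds@pops)) stop("unknown population: ", p)
  scan <- .pbsScanCore(ds, focal, ref1, ref2, winSnps, stepSnps, estimator)
  attr(scan, "scanSpec") <- list(focal = focal, ref1 = ref1, ref2 = ref2,
                                 winSnps = winSnps, stepSnps = stepSnps,
                                 estimator = estimator, ds = ds)
  scan
}

## continuous-scale PBS used for permutation comparisons: no flooring of
## negative FST, so the null has no atom and empirical p-values stay
## tie-free (the reported PBS column keeps the conventional flooring)
.pbsRaw <- function(f1, f2, f3) {
  f <- function(x) -log(pmax(1 - x, 1e-9))
  (f(f1) + f(f2) - f(f3)) / 2
}

.pairTerms <- function(ds, popA, popB, estimator) {
  if (estimator == "hudson")
    .hudsonTerms(ds, ds@pops == popA, ds@pops == popB)
  else
    .wcTerms(ds, which(ds@pops == popA), which(ds@pops == popB))
}

.pbsScanCore <- function(ds, focal, ref1, ref2, winSnps, stepSnps,
                         estimator) {
  sm <- .pairTerms(ds, focal, ref1, estimator)
  sg <- .pairTerms(ds, focal, ref2, estimator)
  mg <- .pairTerms(ds, ref1, ref2, estimator)
  usable <- sm$usable & sg$usable & mg$usable
  idx <- which(usable)
  sites <- ds@sites[idx]
  wins <- .snpWindows(as.character(seqnames(sites)), winSnps, stepSnps)
  ratio <- function(t) {
    num <- .winSums(t$num[idx], wins$i0, wins$i1)
    den <- .winSums(t$den[idx], wins$i0, wins$i1)
    ifelse(is.finite(den) & den != 0, num / den, NA_real_)
  }
  f1 <- ratio(sm); f2 <- ratio(sg); f3 <- ratio(mg)
  flagged <- is.na(f1) | is.na(f2) | is.na(f3)
  pbs <- rep(NA_real_, nrow(wins))
  if (any(!flagged))
    pbs[!flagged] <- as.numeric(pbsFromFst(f1[!flagged], f2[!flagged],
                                           f3[!flagged]))
  out <- data.frame(chrom = wins$chrom,
                    start = start(sites)[wins$i0],
                    end = start(sites)[wins$i1],
                    n_snps = wins$i1 - wins$i0 + 1L,
                    fst_sm = ifelse(flagged, NA_real_, f1),
                    fst_sg = ifelse(flagged, NA_real_, f2),
                    fst_mg = ifelse(flagged, NA_real_, f3),
                    pbs = pbs, flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(out, "siteIdx") <- idx
  attr(out, "winIdx") <- wins
  out
}

#' Monte-Carlo permutation p-values for a PBS scan
#'
#' Builds a null distribution by permuting individuals jointly across the
#' three populations (group sizes preserved) and recomputing the window
#' PBS values, then assigns each observed window the add-one empirical
#' p-value `(1 + #permuted >= observed) / (n + 1)`.
#'
#' With `scope = "global"` (default) one relabelling per cycle is applied
#' genome-wide and the null pools all permuted window values -- cheap, and
#' appropriate for ranking windows against a common background, but the
#' pooled null mixes window-specific distributions and the shared
#' relabellings make p-values dependent across windows. With
#' `scope = "perwindow"` every window receives its own independent
#' relabellings and its own null (Hudson estimator only): this is the
#' calibrated per-window test (uniform p-values when individuals are
#' exchangeable). 2000 cycles is the conventional setting; fewer than 100
#' triggers a warning. The permutation null assumes exchangeable
#' individuals: on genuinely diverged populations small p-values indicate
#' differentiation generally, not selection specifically -- ranking and
#' the top-quantile call carry the selection inference there.
#'
#' @param scan result of [pbsScan()]
#' @param nCycles permutation cycles
#' @param seed integer seed; identical seeds give identical p-vectors
#' @param scope `"global"` or `"perwindow"`
#' @return the scan data frame with a `p` column added.
#' @export
pbsPermutationP <- function(scan, nCycles = 2000L, seed = 1L,
                            scope = c("global", "perwindow")) {
  scope <- match.arg(scope)
  if (nCycles < 100L) warning("fewer than 100 permutation cycles")
  spec <- attr(scan, "scanSpec")
  if (is.null(spec)) stop("scan must come from pbsScan()")
  ds <- spec$ds
  pops3 <- c(spec$focal, spec$ref1, spec$ref2)
  cols <- which(ds@pops %in% pops3)
  sizes <- vapply(pops3, function(p) sum(ds@pops == p), integer(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ok <- !scan$flagged & !is.na(scan$pbs)
  obs <- .pbsRaw(scan$fst_sm, scan$fst_sg, scan$fst_mg)
  scan$p <- NA_real_

  if (scope == "global") {
    nulls <- vector("list", nCycles)
    for (cyc in seq_len(nCycles)) {
      shuffled <- sample(cols)
      lab <- as.character(ds@pops)
      stops <- cumsum(sizes)
      starts <- c(1L, utils::head(stops, -1) + 1L)
      for (k in seq_along(pops3))
        lab[shuffled[starts[k]:stops[k]]] <- pops3[k]
      ds2 <- ds
      ds2@pops <- factor(lab)
      permScan <- .pbsScanCore(ds2, spec$focal, spec$ref1, spec$ref2,
                               spec$winSnps, spec$stepSnps, spec$estimator)
      nulls[[cyc]] <- .pbsRaw(permScan$fst_sm, permScan$fst_sg,
                              permScan$fst_mg)
    }
    pool <- unlist(nulls)
    pool <- pool[is.finite(pool)]
    scan$p[ok] <- vapply(obs[ok], function(v)
      (1 + sum(pool >= v)) / (length(pool) + 1), numeric(1))
    return(scan)
  }

  ## per-window: independent relabellings per window, vectorized over
  ## cycles through group-indicator matrix products
  if (spec$estimator != "hudson")
    stop("perwindow permutation is implemented for the Hudson estimator")
  idx <- attr(scan, "siteIdx")
  wins <- attr(scan, "winIdx")
  nS <- length(cols)
  grp <- rep(seq_along(pops3), times = sizes)
  pairNum <- function(p1, p2, n1, n2) {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    usable <- n1 >= 2 & n2 >= 2
    num[!usable] <- 0; den[!usable] <- 0
    list(num = num, den = den)
  }
  for (w in which(ok)) {
    rows <- idx[wins$i0[w]:wins$i1[w]]
    G <- ds@geno[rows, cols, drop = FALSE]
    A <- (!is.na(G)) * 1
    G0 <- G; G0[is.na(G0)] <- 0L
    ## 24 x (3 * nCycles) indicator of permuted group membership
    M <- matrix(0, nS, 3L * nCycles)
    for (cyc in seq_len(nCycles)) {
      pg <- grp[sample.int(nS)]
      for (k in 1:3) M[pg == k, 3L * (cyc - 1L) + k] <- 1
    }
    alt <- G0 %*% M
    n <- ploidy(ds) * (A %*% M)
    p <- ifelse(n > 0, alt / n, NA_real_)
    i1 <- seq(1L, 3L * nCycles, by = 3L)
    null <- numeric(nCycles)
    for (cyc in seq_len(nCycles)) {
      c1 <- i1[cyc]
      sm <- pairNum(p[, c1], p[, c1 + 1L], n[, c1], n[, c1 + 1L])
      sg <- pairNum(p[, c1], p[, c1 + 2L], n[, c1], n[, c1 + 2L])
      mg <- pairNum(p[, c1 + 1L], p[, c1 + 2L], n[, c1 + 1L], n[, c1 + 2L])
      f <- c(sum(sm$num) / sum(sm$den), sum(sg$num) / sum(sg$den),
             sum(mg$num) / sum(mg$den))
      null[cyc] <- if (all(is.finite(f))) .pbsRaw(f[1], f[2], f[3])
      else NA_real_
    }
    null <- null[is.finite(null)]
    scan$p[w] <- (1 + sum(null >= obs[w])) / (length(null) + 1)
  }
  scan
}

#' Call selected regions from a PBS scan
#'
#' Ranks the valid windows by PBS and calls the top `quantile` fraction
#' (top 1% by convention), merging called windows into a region set. The
#' call set depends only on ranks, so any strictly monotone transform of
#' PBS leaves it unchanged.
#'
#' @param scan result of [pbsScan()] (with or without p-values)
#' @param quantile top fraction to call (default 0.01)
#' @param minWindows minimum number of valid windows required (default 100)
#' @return a `GRanges` of merged selected regions.
#' @export
callSelectedRegions <- function(scan, quantile = 0.01, minWindows = 100L) {
  ok <- !scan$flagged & !is.na(scan$pbs)
  if (sum(ok) < minWindows)
    stop("only ", sum(ok), " valid windows; at least ", minWindows,
         " are required for a top-", quantile * 100, "% call. ",
         "Simulate or supply more data, or lower 'minWindows' knowingly.")
  vals <- scan$pbs[ok]
  if (diff(range(vals)) == 0)
    stop("degenerate scan: all window PBS values are equal; refusing to ",
         "call a top quantile")
  k <- max(1L, floor(quantile * length(vals)))
  thr <- sort(vals, decreasing = TRUE)[k]
  call <- ok & scan$pbs >= thr
  reduce(GRanges(scan$chrom[call],
                 IRanges(scan$start[call], scan$end[call])))
}
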
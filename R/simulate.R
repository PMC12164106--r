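#' Scenario parameters for the demographic simulator
#'
#' Describes the wild/domestic demography the simulator emulates: an
#' outgroup; a wild clade of two subpopulations; a set of domestic
#' populations splitting from the wild lineage; an optional admixture pulse
#' from a wild subpopulation into a subset of domestic populations; and an
#' optional localized sweep (see [injectSweep()]).
#'
#' Default split times follow the inferred history of sheep and Asiatic
#' mouflon at a 3-year generation time: wild1/wild2 split 2189 generations
#' (~6568 y), domestic/wild split 3330 generations (~9991 y), domestic
#' radiation 2000 generations (~6000 y). Mutation rate defaults to 1e-8 per
#' site per generation. Effective sizes are round illustrative values
#' (10,000 diploids), not estimates.
#'
#' @param ne diploid effective size used on every branch (scalar).
#' @param samplesPerPop diploid samples per population; scalar or named
#'   vector over the population names.
#' @param domesticPops names of the domestic populations. The first is
#'   conventionally the non-introgressed reference (P1).
#' @param wildPops names of the two wild subpopulations.
#' @param outgroupPop outgroup name.
#' @param tOut,tWildDom,tWild,tDom split times in generations: outgroup vs
#'   all; wild clade vs domestic clade; wild1 vs wild2; domestic radiation.
#'   Must satisfy `tOut > tWildDom > max(tWild, tDom)`.
#' @param pulse `NULL`, a single pulse, or a list of pulses. A pulse is a
#'   list with elements `donor` (population name), `recipients` (character
#'   vector), `f` (admixture fraction in `[0,1]`), `timeGen` (generations
#'   ago; must pre-date the recipients' and donor's terminal branches), and
#'   optionally `tracts`, a 2-column matrix of explicit donor-segment
#'   intervals (1-based, closed) overriding the random tract mosaic.
#' @param seqLengthBp simulated sequence length (one chromosome).
#' @param mu per-site per-generation mutation rate (sets the default SNP
#'   count).
#' @param recombRate per-site per-generation recombination rate (sets the
#'   admixture tract-length scale).
#' @param generationYears generation time in years; used only to report
#'   times in years.
#' @param nSnps number of SNPs to simulate; `NULL` draws a Poisson count
#'   with mean `mu * seqLengthBp * total tree branch length`.
#' @param seed integer seed; the full output is reproducible from it.
#' @return a list of class `ScenarioParams`.
#' @export
scenarioParams <- function(ne = 10000,
                           samplesPerPop = 8L,
                           domesticPops = c("MEN", "D1", "D2", "D3", "D4"),
                           wildPops = c("W1", "W2"),
                           outgroupPop = "OUT",
                           tOut = 40000, tWildDom = 3330,
                           tWild = 2189, tDom = 2000,
                           pulse = NULL,
                           seqLengthBp = 5e6, mu = 1e-8, recombRate = 1e-8,
                           generationYears = 3, nSnps = NULL, seed = 1L) {
  pops <- c(outgroupPop, wildPops, domesticPops)
  if (anyDuplicated(pops)) stop("population names must be unique")
  if (length(wildPops) != 2L) stop("exactly two wild subpopulations required")
  if (length(samplesPerPop) == 1L) {
    samplesPerPop <- stats::setNames(rep(as.integer(samplesPerPop),
                                         length(pops)), pops)
  } else if (!all(pops %in% names(samplesPerPop))) {
    stop("named 'samplesPerPop' must cover every population")
  }
  if (!(tOut > tWildDom && tWildDom > tWild && tWildDom > tDom))
    stop("event times inconsistent: need tOut > tWildDom > max(tWild, tDom)")
  if (any(c(mu, recombRate) < 0)) stop("rates must be >= 0")
  if (!is.null(pulse) && !is.null(pulse$donor)) pulse <- list(pulse)
  for (p in pulse) {
    if (!p$donor %in% c(wildPops, domesticPops))
      stop("pulse donor must be a wild or domestic population")
    if (!all(p$recipients %in% c(wildPops, domesticPops)))
      stop("pulse recipients must be wild or domestic populations")
    if (p$f < 0 || p$f > 1) stop("admixture fraction f must lie in [0, 1]")
    tips <- c(p$donor, p$recipients)
    tipStart <- ifelse(tips %in% wildPops, tWild, tDom)
    if (any(p$timeGen >= tipStart))
      stop("pulse time must post-date the donor and recipient splits ",
           "(timeGen < ", min(tipStart), ")")
  }
  recip <- unlist(lapply(pulse, `[[`, "recipients"))
  if (anyDuplicated(recip))
    stop("a population may receive at most one pulse")
  structure(list(ne = ne, samplesPerPop = samplesPerPop,
                 domesticPops = domesticPops, wildPops = wildPops,
                 outgroupPop = outgroupPop,
                 tOut = tOut, tWildDom = tWildDom, tWild = tWild, tDom = tDom,
                 pulse = pulse, seqLengthBp = seqLengthBp, mu = mu,
                 recombRate = recombRate, generationYears = generationYears,
                 nSnps = nSnps, seed = seed),
            class = "ScenarioParams")
}

## Balding-Nichols drift: child frequency after t generations in a diploid
## population of size ne, given parent frequency p. Fixed alleles stay fixed.
.drift <- function(p, tGen, ne) {
  if (tGen <= 0) return(p)
  F <- 1 - exp(-tGen / (2 * ne))
  out <- p
  seg <- !is.na(p) & p > 0 & p < 1
  if (any(seg)) {
    k <- (1 - F) / F
    out[seg] <- stats::rbeta(sum(seg), p[seg] * k, (1 - p[seg]) * k)
  }
  out
}

## random donor-ancestry mosaic: Poisson recombination breakpoints at rate
## recomb * tGen per bp, each segment donor with probability f
.randomTracts <- function(L, f, recomb, tGen) {
  nb <- stats::rpois(1, L * recomb * tGen)
  bp <- sort(stats::runif(nb, 1, L))
  starts <- c(1, ceiling(bp))
  ends <- c(floor(bp), L)
  keep <- ends >= starts
  starts <- starts[keep]; ends <- ends[keep]
  donor <- stats::runif(length(starts)) < f
  cbind(start = starts[donor], end = ends[donor])
}

#' Simulate a genotype dataset with known demography and truth tracts
#'
#' Draws per-site allele frequencies down the population tree under a
#' hierarchical Balding-Nichols drift model (per-branch fixation index
#' `F = 1 - exp(-t / 2Ne)`), applies any admixture pulse by replacing the
#' recipient's lineage frequency with the donor's pulse-time frequency
#' inside an explicit recombination-breakpoint tract mosaic, and samples
#' individual genotypes binomially, so that samples are exchangeable within
#' populations. The realized donor segments are returned as truth tracts.
#' Globally monomorphic draws are discarded.
#'
#' The reference allele is ancestral by construction, so downstream
#' polarization against the simulated outgroup recovers the derived allele
#' except where the outgroup itself drifted past 0.5.
#'
#' @param params a [scenarioParams()] object.
#' @return list with elements `ds` (a [GenotypeData-class]), `tracts` (a
#'   `GRanges` of truth tracts with `recipient` and `pulse` columns; empty
#'   when `f = 0` or no pulse), and `params`.
#' @export
simulateScenario <- function(params) {
  stopifnot(inherits(params, "ScenarioParams"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  L <- params$seqLengthBp
  ne <- params$ne
  nReq <- params$nSnps
  if (is.null(nReq)) {
    treeLen <- params$tOut + (params$tOut - params$tWildDom) +
      (params$tWildDom - params$tWild) + 2 * params$tWild +
      (params$tWildDom - params$tDom) +
      length(params$domesticPops) * params$tDom
    nReq <- stats::rpois(1, params$mu * L * treeLen)
  }
  tipStart <- function(pop)
    if (pop %in% params$wildPops) params$tWild else params$tDom

  ## admixture-tract mosaics are drawn once, independently of the sites
  pulseOf <- list()
  tractRows <- list()
  for (i in seq_along(params$pulse)) {
    p <- params$pulse[[i]]
    for (r in p$recipients) {
      if (!is.null(p$tracts)) {
        tr <- as.matrix(p$tracts)
        colnames(tr) <- c("start", "end")
        if (any(tr[, "start"] < 1 | tr[, "end"] > L))
          stop("explicit pulse tracts outside simulated bounds")
      } else {
        tr <- .randomTracts(L, p$f, params$recombRate, p$timeGen)
      }
      pulseOf[[r]] <- c(p, list(id = i, tr = tr))
      if (nrow(tr))
        tractRows[[length(tractRows) + 1L]] <-
          data.frame(start = tr[, "start"], end = tr[, "end"],
                     recipient = r, pulse = i)
    }
  }

  pops <- c(params$outgroupPop, params$wildPops, params$domesticPops)
  nInd <- params$samplesPerPop[pops]
  samples <- unlist(lapply(pops, function(p)
    sprintf("%s_%02d", p, seq_len(nInd[[p]]))))
  popLabels <- rep(pops, times = nInd)

  ## generate one batch of candidate sites at given positions; returns the
  ## genotype matrix of segregating sites only
  genBatch <- function(bpos) {
    nB <- length(bpos)
    p0 <- stats::rbeta(nB, 0.5, 0.5)
    pOut <- .drift(p0, params$tOut, ne)
    pA1 <- .drift(p0, params$tOut - params$tWildDom, ne)
    pWA <- .drift(pA1, params$tWildDom - params$tWild, ne)
    pDA <- .drift(pA1, params$tWildDom - params$tDom, ne)
    tipAnc <- function(pop) if (pop %in% params$wildPops) pWA else pDA
    ## a donor's pulse-time frequency is drawn once and shared by the
    ## donor's own remaining drift and by every tract it seeds, so the
    ## transferred material is nested inside the donor lineage
    donorsAt <- list()
    donorTime <- list()
    for (p in params$pulse) {
      key <- paste(p$donor, p$timeGen)
      if (is.null(donorsAt[[key]])) {
        donorsAt[[key]] <- .drift(tipAnc(p$donor),
                                  tipStart(p$donor) - p$timeGen, ne)
        donorTime[[p$donor]] <- p$timeGen
      }
    }
    freq <- matrix(NA_real_, nB, length(pops),
                   dimnames = list(NULL, pops))
    freq[, params$outgroupPop] <- pOut
    for (pop in setdiff(pops, params$outgroupPop)) {
      pl <- pulseOf[[pop]]
      if (is.null(pl) && !is.null(donorTime[[pop]])) {
        tp <- donorTime[[pop]]
        freq[, pop] <- .drift(donorsAt[[paste(pop, tp)]], tp, ne)
      } else if (is.null(pl)) {
        freq[, pop] <- .drift(tipAnc(pop), tipStart(pop), ne)
      } else {
        tp <- pl$timeGen
        pRecTp <- .drift(tipAnc(pop), tipStart(pop) - tp, ne)
        pDonTp <- donorsAt[[paste(pl$donor, tp)]]
        inTract <- rep(FALSE, nB)
        if (nrow(pl$tr))
          for (k in seq_len(nrow(pl$tr)))
            inTract <- inTract |
              (bpos >= pl$tr[k, "start"] & bpos <= pl$tr[k, "end"])
        base <- ifelse(inTract, pDonTp, pRecTp)
        freq[, pop] <- .drift(base, tp, ne)
      }
    }
    geno <- matrix(0L, nB, length(samples))
    col <- 1L
    for (p in pops) {
      for (i in seq_len(nInd[[p]])) {
        geno[, col] <- stats::rbinom(nB, 2L, freq[, p])
        col <- col + 1L
      }
    }
    tot <- rowSums(geno)
    poly <- tot > 0L & tot < 2L * length(samples)
    list(pos = bpos[poly], geno = geno[poly, , drop = FALSE])
  }

  posPool <- sample.int(L)
  used <- 0L
  got <- list()
  nGot <- 0L
  batchSize <- min(L, ceiling(nReq * 1.4) + 200L)
  while (nGot < nReq && used < L) {
    take <- min(batchSize, L - used)
    b <- genBatch(posPool[(used + 1L):(used + take)])
    used <- used + take
    got[[length(got) + 1L]] <- b
    nGot <- nGot + length(b$pos)
    ## re-size subsequent batches from the observed segregating fraction
    rate <- max(nGot / used, 0.05)
    batchSize <- ceiling((nReq - nGot) / rate * 1.2) + 100L
  }
  pos <- unlist(lapply(got, `[[`, "pos"))
  geno <- do.call(rbind, lapply(got, `[[`, "geno"))
  if (length(pos) > nReq) {
    keep <- sort(sample.int(length(pos), nReq))
    pos <- pos[keep]
    geno <- geno[keep, , drop = FALSE]
  }

  ds <- genotypeData(geno, chrom = "chr1",
                     pos = pos, ref = "A", alt = "T",
                     samples = samples, populations = popLabels,
                     ploidy = 2L, seqlengths = c(chr1 = L))
  if (length(tractRows)) {
    td <- do.call(rbind, tractRows)
    tracts <- GRanges("chr1", IRanges(td$start, td$end),
                      recipient = td$recipient, pulse = td$pulse)
    GenomeInfoDb::seqlengths(tracts) <- c(chr1 = L)
    tracts <- unlist(GenomicRanges::GRangesList(lapply(
      split(tracts, paste(td$recipient, td$pulse)), function(g) {
        r <- reduce(g)
        mcols(r)$recipient <- mcols(g)$recipient[1]
        mcols(r)$pulse <- mcols(g)$pulse[1]
        r
      })), use.names = FALSE)
  } else {
    tracts <- GRanges()
    mcols(tracts)$recipient <- character(0)
    mcols(tracts)$pulse <- integer(0)
  }
  list(ds = ds, tracts = tracts, params = params)
}

#' Write a simulated scenario to disk
#'
#' Emits `<prefix>.vcf`, `<prefix>.popmap.tsv` and `<prefix>.truth.bed`
#' (0-based half-open, with the recipient population in column 4).
#'
#' @param sim result of [simulateScenario()]
#' @param dir output directory
#' @param prefix file name prefix
#' @return invisibly, the three paths.
#' @export
writeScenario <- function(sim, dir, prefix = "scenario") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  pm <- file.path(dir, paste0(prefix, ".popmap.tsv"))
  bed <- file.path(dir, paste0(prefix, ".truth.bed"))
  writeVcfGenotypes(sim$ds, vcf)
  utils::write.table(popmap(sim$ds), pm, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tr <- sim$tracts
  writeLines(paste(as.character(seqnames(tr)), start(tr) - 1L, end(tr),
                   mcols(tr)$recipient, sep = "\t"), bed)
  invisible(c(vcf = vcf, popmap = pm, truth = bed))
}

#' Inject a localized sweep signal
#'
#' Inside the interval, the derived (alternate) allele of the target
#' population is driven toward fixation: the post-sweep frequency is
#' `p + strength * (1 - p)` and the target's genotypes are resampled
#' binomially at the new frequency. Sites outside the interval are
#' untouched. A deterministic frequency distortion of this kind is
#' sufficient to create a PBS signal at a fraction of the cost of a forward
#' selection simulation.
#'
#' @param ds a `GenotypeData`
#' @param pop target population
#' @param start,end interval (1-based, closed) on `chrom`
#' @param strength distortion strength in `(0, 1]`; 1 fixes the derived
#'   allele at every in-interval site
#' @param seed integer seed for the genotype resampling
#' @param chrom chromosome (default: the first one present)
#' @return a modified `GenotypeData`
#' @export
injectSweep <- function(ds, pop, start, end, strength, seed = 1L,
                        chrom = NULL) {
  if (!pop %in% levels(ds@pops)) stop("unknown population: ", pop)
  if (!(strength > 0 && strength <= 1))
    stop("sweep strength must lie in (0, 1]")
  if (is.null(chrom)) chrom <- GenomeInfoDb::seqlevels(ds@sites)[1]
  sl <- GenomeInfoDb::seqlengths(ds@sites)[chrom]
  if (!is.na(sl) && (start < 1 || end > sl))
    stop("sweep interval outside simulated bounds [1, ", sl, "]")
  inIv <- as.character(seqnames(ds@sites)) == chrom &
    start(ds@sites) >= start & start(ds@sites) <= end
  cols <- which(ds@pops == pop)
  if (!any(inIv)) return(ds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  g <- ds@geno[inIv, cols, drop = FALSE]
  nCalled <- rowSums(!is.na(g)) * ploidy(ds)
  p <- ifelse(nCalled > 0, rowSums(g, na.rm = TRUE) / nCalled, NA_real_)
  pNew <- p + strength * (1 - p)
  for (i in seq_len(nrow(g))) {
    if (is.na(pNew[i])) next
    called <- !is.na(g[i, ])
    g[i, called] <- stats::rbinom(sum(called), ploidy(ds), pNew[i])
  }
  ds@geno[inIv, cols] <- g
  ds
}

#' Build a FASTA haplotype fixture with known multiplicities
#'
#' Returns `sum(multiplicities)` DNA sequences in which two sequences are
#' identical iff they belong to the same multiplicity class -- a controlled
#' input for haplotype-diversity calculations.
#'
#' @param multiplicities positive integers, one per haplotype class
#' @param length sequence length in bp (must be at least the number of
#'   classes)
#' @param seed integer seed
#' @return a [Biostrings::DNAStringSet]
#' @export
makeHaplotypeFixture <- function(multiplicities, length = 100L, seed = 1L) {
  if (!base::length(multiplicities))
    stop("at least one multiplicity class required")
  if (any(multiplicities < 1)) stop("multiplicities must be positive")
  k <- base::length(multiplicities)
  if (length < k)
    stop("sequence length must be >= number of distinct haplotypes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, length, replace = TRUE)
  haps <- vapply(seq_len(k), function(i) {
    s <- backbone
    if (i > 1L) s[i] <- setdiff(bases, backbone[i])[1]
    paste(s, collapse = "")
  }, character(1))
  seqs <- rep(haps, times = multiplicities)
  names(seqs) <- sprintf("seq_%03d", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}
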
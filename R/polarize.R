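## per-site alt-allele frequency and non-missing allele count for a set of
## sample columns
.altFreqCounts <- function(ds, cols) {
  g <- ds@geno[, cols, drop = FALSE]
  nCalled <- rowSums(!is.na(g)) * ploidy(ds)
  altCount <- rowSums(g, na.rm = TRUE)
  freq <- ifelse(nCalled > 0L, altCount / nCalled, NA_real_)
  list(freq = freq, counts = as.integer(nCalled))
}

#' Polarize genotypes against an outgroup
#'
#' Defines the derived allele at each site as the outgroup's minor allele
#' (frequency < 0.5 in the outgroup). Sites where the outgroup frequency is
#' exactly 0.5 and sites where the outgroup has no calls are excluded (the
#' counts are recorded as attributes `nTies` and `nAllMissingOutgroup`).
#' Sites where the outgroup is polymorphic above `polyThreshold` are kept
#' but flagged.
#'
#' @param ds a [GenotypeData-class] object
#' @param outgroup name of the outgroup population
#' @param polyThreshold flag sites whose outgroup minor-allele frequency
#'   exceeds this value (default 0.2)
#' @return an [AlleleFreq-class] object with one frequency column per
#'   population in `ds`.
#' @export
polarize <- function(ds, outgroup, polyThreshold = 0.2) {
  if (!outgroup %in% levels(ds@pops))
    stop("outgroup population not found: ", outgroup)
  og <- .altFreqCounts(ds, ds@pops == outgroup)
  allMissing <- og$counts == 0L
  tie <- !allMissing & og$freq == 0.5
  keep <- !allMissing & !tie
  derivedIsAlt <- og$freq < 0.5
  minorFreq <- pmin(og$freq, 1 - og$freq)
  pops <- levels(droplevels(ds@pops))
  freq <- matrix(NA_real_, sum(keep), length(pops),
                 dimnames = list(NULL, pops))
  counts <- matrix(0L, sum(keep), length(pops),
                   dimnames = list(NULL, pops))
  for (p in pops) {
    fc <- .altFreqCounts(ds, ds@pops == p)
    f <- fc$freq[keep]
    flip <- !derivedIsAlt[keep]
    f[flip] <- 1 - f[flip]
    freq[, p] <- f
    counts[, p] <- fc$counts[keep]
  }
  af <- new("AlleleFreq",
            freq = freq, counts = counts,
            sites = ds@sites[keep],
            derivedIsAlt = derivedIsAlt[keep],
            siteIndex = which(keep),
            flagged = (minorFreq > polyThreshold)[keep],
            outgroup = outgroup)
  attr(af, "nTies") <- sum(tie)
  attr(af, "nAllMissingOutgroup") <- sum(allMissing)
  af
}

#' Derived-allele frequencies for an arbitrary sample subset
#'
#' Computes, at the sites retained by a previous [polarize()] call, the
#' derived-allele frequency of any subset of samples (e.g. one half of a
#' donor bipartition from [splitDonor()]).
#'
#' @param ds the `GenotypeData` the `AlleleFreq` was built from
#' @param af an `AlleleFreq`
#' @param samples sample identifiers
#' @return numeric vector of derived-allele frequencies, one per retained
#'   site (`NA` where the subset has no calls).
#' @export
polarizedFreq <- function(ds, af, samples) {
  cols <- match(samples, ds@samples)
  if (anyNA(cols))
    stop("unknown sample(s): ", paste(samples[is.na(cols)], collapse = ", "))
  fc <- .altFreqCounts(ds, cols)
  f <- fc$freq[af@siteIndex]
  flip <- !af@derivedIsAlt
  f[flip] <- 1 - f[flip]
  f
}

#' Randomly bipartition a donor population
#'
#' Splits the donor's samples into two disjoint sets of sizes
#' ceiling(n/2) and floor(n/2), reproducibly from `seed`. Used to form the
#' P3a/P3b halves of the f4-ratio.
#'
#' @param ds a `GenotypeData`
#' @param donor donor population name
#' @param seed integer seed
#' @return list with character vectors `p3a` and `p3b`.
#' @export
splitDonor <- function(ds, donor, seed = 1L) {
  ss <- samplesOf(ds, donor)
  n <- length(ss)
  if (n < 2L)
    stop("donor population '", donor, "' has ", n,
         " sample(s); at least 2 are required to form the P3a/P3b halves ",
         "of the f4-ratio. Choose a donor with more samples.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  a <- sort(sample.int(n, ceiling(n / 2)))
  list(p3a = ss[a], p3b = ss[-a])
}

## save/restore the global RNG state so seeded helpers do not perturb the
## caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
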
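#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' GenotypeData: biallelic SNP genotypes for samples grouped into populations
#'
#' The central container of the package. Holds a sites-by-samples matrix of
#' alternate-allele dosages (`0`, `1`, ..., ploidy, or `NA` for missing),
#' the site coordinates as a [GenomicRanges::GRanges] (1-based, width-1
#' positions, with `ref` and `alt` metadata columns), and a population
#' assignment for every sample. Every sample belongs to exactly one
#' population; sites are biallelic SNPs sorted by position within each
#' chromosome.
#'
#' Use [genotypeData()] to construct, [readVcfGenotypes()] to build one from
#' a VCF, and [simulateScenario()] to generate one with known demography.
#'
#' @slot geno integer matrix, sites x samples; entries in `0:ploidy` or `NA`.
#' @slot sites `GRanges` of width-1 SNP positions with `ref`/`alt` mcols.
#' @slot samples character vector of sample identifiers (column names).
#' @slot pops factor of population labels, one per sample.
#' @slot ploidy integer scalar, 1 (haploid-coded) or 2 (diploid).
#'
#' @aliases GenotypeData-class
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(
    geno    = "matrix",
    sites   = "GRanges",
    samples = "character",
    pops    = "factor",
    ploidy  = "integer"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (nrow(object@geno) != length(object@sites))
    msg <- c(msg, "number of rows of 'geno' must equal number of sites")
  if (ncol(object@geno) != length(object@samples))
    msg <- c(msg, "number of columns of 'geno' must equal number of samples")
  if (length(object@pops) != length(object@samples))
    msg <- c(msg, "'pops' must assign every sample to exactly one population")
  if (anyDuplicated(object@samples))
    msg <- c(msg, "sample identifiers must be unique")
  if (!(length(object@ploidy) == 1L && object@ploidy %in% c(1L, 2L)))
    msg <- c(msg, "'ploidy' must be 1 or 2")
  g <- object@geno
  if (length(g) && any(g[!is.na(g)] < 0L | g[!is.na(g)] > object@ploidy))
    msg <- c(msg, "genotype dosages must lie in 0:ploidy or be NA")
  if (length(object@sites)) {
    if (is.null(mcols(object@sites)$ref) || is.null(mcols(object@sites)$alt))
      msg <- c(msg, "'sites' must carry 'ref' and 'alt' metadata columns")
    ## positions strictly increasing within each chromosome
    sp <- split(start(object@sites), as.character(seqnames(object@sites)))
    if (any(vapply(sp, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' AlleleFreq: per-site, per-population derived-allele frequencies
#'
#' Produced by [polarize()]. Sites are polarized against an outgroup: the
#' derived allele is the outgroup's minor allele; sites where the outgroup is
#' at exactly frequency 0.5, or entirely missing, are excluded. Sites where
#' the outgroup is polymorphic above `polyThreshold` are retained but
#' flagged.
#'
#' @slot freq numeric matrix, sites x populations, derived-allele frequency
#'   in `[0, 1]`; `NA` where a population has no called alleles.
#' @slot counts integer matrix of non-missing allele counts (calls x ploidy).
#' @slot sites `GRanges` of the retained sites.
#' @slot derivedIsAlt logical; `TRUE` where the VCF ALT allele is derived.
#' @slot siteIndex integer indices of the retained sites in the source
#'   `GenotypeData`.
#' @slot flagged logical; outgroup polymorphic above the threshold.
#' @slot outgroup name of the outgroup population used for polarization.
#'
#' @aliases AlleleFreq-class
#' @exportClass AlleleFreq
setClass("AlleleFreq",
  representation(
    freq         = "matrix",
    counts       = "matrix",
    sites        = "GRanges",
    derivedIsAlt = "logical",
    siteIndex    = "integer",
    flagged      = "logical",
    outgroup     = "character"
  )
)

setValidity("AlleleFreq", function(object) {
  msg <- character()
  if (!identical(dim(object@freq), dim(object@counts)))
    msg <- c(msg, "'freq' and 'counts' must have identical dimensions")
  if (nrow(object@freq) != length(object@sites))
    msg <- c(msg, "one row per retained site required")
  f <- object@freq
  if (length(f) && any(f[!is.na(f)] < 0 | f[!is.na(f)] > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeData-class number of SNP sites
#' @param x a `GenotypeData` (or `AlleleFreq`) object
#' @export
nSites <- function(x) {
  if (is(x, "AlleleFreq")) return(nrow(x@freq))
  nrow(x@geno)
}

#' @describeIn GenotypeData-class number of samples
#' @export
nSamples <- function(x) ncol(x@geno)

#' @describeIn GenotypeData-class population names present
#' @export
popNames <- function(x) {
  if (is(x, "AlleleFreq")) return(colnames(x@freq))
  levels(droplevels(x@pops))
}

#' @describeIn GenotypeData-class sample identifiers of one population
#' @param pop population name
#' @export
samplesOf <- function(x, pop) {
  if (!pop %in% x@pops) stop("unknown population: ", pop)
  x@samples[x@pops == pop]
}

#' @describeIn GenotypeData-class the dosage matrix (sites x samples)
#' @export
genotypes <- function(x) x@geno

#' @describeIn GenotypeData-class site coordinates as a `GRanges`
#' @export
siteRanges <- function(x) {
  if (is(x, "AlleleFreq")) return(x@sites)
  x@sites
}

#' @describeIn GenotypeData-class ploidy of the genotype coding (1 or 2)
#' @export
ploidy <- function(x) x@ploidy

#' @describeIn GenotypeData-class sample-to-population table
#' @export
popmap <- function(x) {
  data.frame(sample = x@samples, population = as.character(x@pops),
             stringsAsFactors = FALSE)
}

#' @describeIn AlleleFreq-class derived-allele frequency matrix
#' @param x an `AlleleFreq` object
#' @export
alleleFreqs <- function(x) x@freq

#' @describeIn AlleleFreq-class non-missing allele-count matrix
#' @export
freqCounts <- function(x) x@counts

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nSites(object), "biallelic SNP sites x",
      nSamples(object), "samples (ploidy", object@ploidy, ")\n")
  tab <- table(object@pops)
  cat("populations:",
      paste(sprintf("%s(%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  chr <- unique(as.character(seqnames(object@sites)))
  cat("chromosomes:", paste(utils::head(chr, 5), collapse = ", "),
      if (length(chr) > 5) "..." else "", "\n")
})

setMethod("show", "AlleleFreq", function(object) {
  cat("AlleleFreq:", nrow(object@freq), "polarized sites x",
      ncol(object@freq), "populations (outgroup:", object@outgroup, ")\n")
  cat(sum(object@flagged), "site(s) flagged for outgroup polymorphism\n")
})

#' Construct a GenotypeData object
#'
#' @param geno integer matrix of alternate-allele dosages, sites x samples.
#' @param chrom chromosome of each site.
#' @param pos 1-based position of each site.
#' @param ref,alt reference and alternate alleles.
#' @param samples sample identifiers.
#' @param populations population label per sample (same order as `samples`),
#'   or a data frame with columns `sample` and `population`.
#' @param ploidy 1 or 2.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return a [GenotypeData-class] object.
#' @export
genotypeData <- function(geno, chrom, pos, ref = "A", alt = "T", samples,
                         populations, ploidy = 2L, seqlengths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  chrom <- rep_len(as.character(chrom), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (is.data.frame(populations)) {
    idx <- match(samples, populations$sample)
    if (anyNA(idx))
      stop("population map is missing sample(s): ",
           paste(samples[is.na(idx)], collapse = ", "))
    populations <- populations$population[idx]
  }
  o <- order(chrom, pos)
  sites <- GRanges(chrom[o], IRanges(pos[o], width = 1L))
  mcols(sites)$ref <- ref[o]
  mcols(sites)$alt <- alt[o]
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(sites) <- seqlengths[GenomeInfoDb::seqlevels(sites)]
  geno <- geno[o, , drop = FALSE]
  colnames(geno) <- samples
  new("GenotypeData", geno = geno, sites = sites,
      samples = as.character(samples),
      pops = factor(populations), ploidy = as.integer(ploidy))
}

#' Subset a GenotypeData object by sites and/or samples
#'
#' @param x a `GenotypeData`
#' @param i site indices (or logical)
#' @param j sample indices, names, or logical
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSites(x))
  if (missing(j)) j <- seq_len(nSamples(x))
  if (is.character(j)) j <- match(j, x@samples)
  new("GenotypeData",
      geno = x@geno[i, j, drop = FALSE],
      sites = x@sites[i],
      samples = x@samples[j],
      pops = droplevels(x@pops[j]),
      ploidy = x@ploidy)
})

#' Pool several populations into one
#'
#' Returns a copy of `x` in which the samples of `members` are relabelled
#' `name`. Used e.g. to form the pooled focal group of a PBS scan.
#'
#' @param x a `GenotypeData`
#' @param name name of the pooled population
#' @param members population names to pool
#' @return a `GenotypeData`
#' @export
poolPopulations <- function(x, name, members) {
  missing <- setdiff(members, levels(x@pops))
  if (length(missing))
    stop("unknown population(s): ", paste(missing, collapse = ", "))
  p <- as.character(x@pops)
  p[p %in% members] <- name
  x@pops <- factor(p)
  x
}
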
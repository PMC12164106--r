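#' Construct a normalized region set
#'
#' @param chrom chromosome per interval
#' @param start,end 1-based closed interval bounds
#' @return a sorted, merged `GRanges`.
#' @export
regionSet <- function(chrom, start, end) {
  reduce(GRanges(chrom, IRanges(start, end)))
}

#' Total length of a region set in bp
#'
#' @param regions a `GRanges`
#' @export
regionLength <- function(regions) sum(width(reduce(regions)))

#' Positions covered by at least `minSupport` region sets
#'
#' Coverage-counting intersection used e.g. to find the common introgressed
#' region across several recipient populations (`minSupport = number of
#' sets` is the strict "shared by all" rule; `minSupport = 1` is the
#' union). Operates at bp resolution, so the input sets' windows need not
#' align.
#'
#' @param sets list of `GRanges`
#' @param minSupport minimum number of supporting sets
#' @return merged `GRanges` of supported positions; attribute `totalBp`
#'   gives its total length.
#' @export
intersectMany <- function(sets, minSupport = length(sets)) {
  if (!length(sets)) stop("at least one region set required")
  stopifnot(minSupport >= 1L)
  nonEmpty <- Filter(length, sets)
  if (length(nonEmpty) >= 2L) {
    lvls <- lapply(nonEmpty, function(g)
      unique(as.character(seqnames(g))))
    if (!length(Reduce(intersect, lvls)))
      stop("region sets share no chromosome names; mixed chromosome ",
           "namespaces?")
  }
  if (length(nonEmpty) < minSupport) {
    out <- GRanges()
    attr(out, "totalBp") <- 0
    return(out)
  }
  red <- lapply(sets, reduce)
  all <- suppressWarnings(do.call(c, unname(red)))
  cov <- GenomicRanges::coverage(all)
  out <- GRanges(IRanges::slice(cov, lower = minSupport,
                                rangesOnly = TRUE))
  attr(out, "totalBp") <- sum(width(out))
  out
}

#' Intersection of introgressed and selected regions
#'
#' The plain bp-level intersection that defines "selected introgressed
#' regions": genomic intervals called both introgressed (fdM criterion)
#' and under selection (top-quantile PBS).
#'
#' @param introgressed,selected `GRanges`
#' @return merged `GRanges` with attribute `totalBp`.
#' @export
selectedIntrogressed <- function(introgressed, selected) {
  out <- suppressWarnings(
    GenomicRanges::intersect(reduce(introgressed), reduce(selected)))
  attr(out, "totalBp") <- sum(width(out))
  out
}

#' Annotate regions against a feature track
#'
#' For each region, reports every overlapping feature (distance 0) and, if
#' none overlaps, the nearest feature within `maxDistance` with a signed
#' distance: positive when the feature lies downstream of the region end
#' (higher coordinates), negative when upstream of the region start. Ties
#' are broken toward the feature with the smaller start coordinate.
#'
#' @param regions a `GRanges`
#' @param features a `GRanges` with a `name` metadata column (see
#'   [readFeatures()])
#' @param maxDistance maximum bp for a nearest-feature report (default 1e6)
#' @return data frame: chrom, start, end, feature, relation
#'   (overlap/nearest), distance. Regions with no feature in range yield no
#'   rows.
#' @export
annotateRegions <- function(regions, features, maxDistance = 1e6) {
  nm <- mcols(features)$name
  if (is.null(nm)) nm <- paste0("feature_", seq_along(features))
  rows <- list()
  ov <- GenomicRanges::findOverlaps(regions, features)
  for (k in seq_along(ov)) {
    i <- S4Vectors::queryHits(ov)[k]
    j <- S4Vectors::subjectHits(ov)[k]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(regions))[i],
      start = start(regions)[i], end = end(regions)[i],
      feature = nm[j], relation = "overlap", distance = 0,
      stringsAsFactors = FALSE)
  }
  hasOverlap <- unique(S4Vectors::queryHits(ov))
  for (i in setdiff(seq_along(regions), hasOverlap)) {
    onCh <- which(as.character(seqnames(features)) ==
                    as.character(seqnames(regions))[i])
    if (!length(onCh)) next
    gap <- rep(NA_real_, length(onCh))
    for (q in seq_along(onCh)) {
      j <- onCh[q]
      if (start(features)[j] > end(regions)[i])
        gap[q] <- start(features)[j] - end(regions)[i] - 1L
      else if (end(features)[j] < start(regions)[i])
        gap[q] <- -(start(regions)[i] - end(features)[j] - 1L)
      else gap[q] <- 0
    }
    inRange <- which(abs(gap) <= maxDistance)
    if (!length(inRange)) next
    best <- inRange[order(abs(gap[inRange]), start(features)[onCh[inRange]])]
    j <- onCh[best[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(regions))[i],
      start = start(regions)[i], end = end(regions)[i],
      feature = nm[j], relation = "nearest",
      distance = gap[best[1]], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), feature = character(),
                      relation = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
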
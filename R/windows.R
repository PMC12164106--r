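#' Fixed-width genomic windows
#'
#' Builds sliding windows (e.g. 2 Mb / 1 Mb step for diversity scans, or
#' 20 kb / 2 kb around candidate regions) over every chromosome of a
#' dataset. The span of each chromosome is its declared sequence length
#' when available, otherwise the range of observed SNP positions.
#'
#' @param x a `GenotypeData` (or `AlleleFreq`)
#' @param size window size in bp
#' @param step step in bp (defaults to `size`, i.e. non-overlapping)
#' @return a `GRanges` of windows
#' @export
makeWindows <- function(x, size, step = size) {
  sites <- siteRanges(x)
  chroms <- GenomeInfoDb::seqlevels(sites)
  sl <- GenomeInfoDb::seqlengths(sites)
  out <- list()
  for (ch in chroms) {
    onCh <- sites[seqnames(sites) == ch]
    if (!length(onCh) && is.na(sl[ch])) next
    len <- if (!is.na(sl[ch])) sl[ch] else max(end(onCh))
    first <- 1L
    starts <- seq.int(first, max(first, len - 1L), by = step)
    starts <- starts[starts <= len]
    ends <- pmin(starts + size - 1L, len)
    keep <- !duplicated(ends) | starts + size - 1L <= len
    out[[ch]] <- GRanges(ch, IRanges(starts[keep], ends[keep]))
  }
  if (!length(out)) return(GRanges())
  ans <- unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
  GenomeInfoDb::seqlengths(ans) <- sl[GenomeInfoDb::seqlevels(ans)]
  ans
}

## one window spanning each chromosome
.wholeWindows <- function(x) {
  sites <- siteRanges(x)
  sp <- split(start(sites), as.character(seqnames(sites)))
  grs <- lapply(names(sp), function(ch)
    GRanges(ch, IRanges(min(sp[[ch]]), max(sp[[ch]]))))
  suppressWarnings(do.call(c, grs))
}

## SNP-count windows over an ordered site vector, per chromosome.
## Returns a data.frame of start/end indices into the given ordering.
.snpWindows <- function(chrom, winSnps, stepSnps) {
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    n <- length(idx)
    if (n < winSnps) next
    starts <- seq.int(1L, n - winSnps + 1L, by = stepSnps)
    out[[ch]] <- data.frame(chrom = ch,
                            i0 = idx[starts],
                            i1 = idx[starts + winSnps - 1L])
  }
  if (!length(out))
    return(data.frame(chrom = character(), i0 = integer(), i1 = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## window sums over contiguous index ranges via cumulative sums
.winSums <- function(v, i0, i1) {
  if (!length(i0)) return(numeric(0))
  cs <- cumsum(v)
  cs[i1] - ifelse(i0 > 1L, cs[pmax(i0 - 1L, 1L)], 0)
}

#' Write window statistics as TSV
#'
#' @param stats a window-statistic data frame (columns chrom, start, end,
#'   n_snps, n_sites, stat, value, z, p as applicable)
#' @param path output path
#' @export
writeWindowStats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
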
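#' Read a population map
#'
#' A population map is a 2- or 3-column tab-separated table:
#' sample id, population name, and an optional role tag
#' (one of `P1`, `P2`, `P3`, `P4`, `outgroup`, `focal`, `reference`).
#'
#' @param path path to the TSV file (no header, or a header line starting
#'   with `sample`).
#' @return data frame with columns `sample`, `population` and, when present,
#'   `role`.
#' @export
readPopmap <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("^sample\\b", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("population map needs at least 2 columns")
  names(df)[1:2] <- c("sample", "population")
  if (ncol(df) >= 3L) names(df)[3] <- "role"
  if (anyDuplicated(df$sample))
    stop("duplicated sample id(s) in population map: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  df
}

## "0/1"-style GT strings -> alt dosage; anything containing "." is missing
.gtToDosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  if (any(ok)) {
    alleles <- strsplit(gt[ok], "[/|]")
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
  }
  out
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Parses a (plain or bgzipped) VCF with \pkg{vcfR}, keeps only biallelic
#' SNPs, restricts to the samples in `popmap`, and applies the per-site
#' missing-rate and minor-allele-frequency filters. Multiallelic and indel
#' records are skipped and counted. The MAF filter is strict
#' (`MAF > maf` retained), matching the usual `plink --maf` behaviour of
#' dropping boundary sites when the stated rule is "MAF > 0.05";
#' set `maf = NULL` to skip frequency filtering -- recommended for
#' ABBA-BABA-type statistics, which MAF filtering biases.
#'
#' @param path VCF file.
#' @param popmap data frame from [readPopmap()] (or with the same columns).
#' @param maf minor-allele-frequency threshold (retain sites with MAF
#'   strictly greater); `NULL` to disable. Default 0.05.
#' @param maxMissing maximum per-site fraction of missing genotype calls
#'   (retain sites with missing rate `<= maxMissing`); `NULL` to disable.
#'   Default 0.1.
#' @param minCallsPerPop minimum number of called individuals per population
#'   per site (guards degenerate windows). Default 1.
#' @return a [GenotypeData-class] object; attributes `nSkippedNonBiallelic`
#'   and `nFiltered` record how many records were dropped.
#' @export
readVcfGenotypes <- function(path, popmap, maf = 0.05, maxMissing = 0.1,
                             minCallsPerPop = 1L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nSkipped <- sum(!biallelic)
  if (nSkipped) message(nSkipped, " non-biallelic/indel record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  vcfSamples <- colnames(gt)
  unknown <- setdiff(popmap$sample, vcfSamples)
  if (length(unknown))
    stop("sample(s) in population map absent from VCF: ",
         paste(unknown, collapse = ", "))
  if (!length(popmap$sample))
    stop("empty intersection of VCF and population-map samples")
  gt <- gt[biallelic, popmap$sample, drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]

  geno <- matrix(.gtToDosage(gt), nrow = nrow(gt), ncol = ncol(gt))
  colnames(geno) <- popmap$sample

  nSamp <- ncol(geno)
  missRate <- rowMeans(is.na(geno))
  altFreq <- rowMeans(geno, na.rm = TRUE) / 2
  mafv <- pmin(altFreq, 1 - altFreq)
  keep <- rep(TRUE, nrow(geno))
  if (!is.null(maxMissing)) keep <- keep & missRate <= maxMissing
  if (!is.null(maf)) keep <- keep & !is.na(mafv) & mafv > maf
  keep <- keep & rowSums(!is.na(geno)) > 0L
  if (!is.null(minCallsPerPop) && minCallsPerPop > 0L) {
    for (p in unique(popmap$population)) {
      idx <- popmap$sample[popmap$population == p]
      keep <- keep &
        rowSums(!is.na(geno[, idx, drop = FALSE])) >= minCallsPerPop
    }
  }
  nFiltered <- sum(!keep)
  ds <- genotypeData(geno[keep, , drop = FALSE],
                     chrom = fix[keep, "CHROM"],
                     pos = as.integer(fix[keep, "POS"]),
                     ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                     samples = popmap$sample,
                     populations = popmap$population, ploidy = 2L)
  attr(ds, "nSkippedNonBiallelic") <- nSkipped
  attr(ds, "nFiltered") <- nFiltered
  ds
}

#' Write a GenotypeData object as a VCF
#'
#' Emits a minimal VCF 4.2 with GT fields (positions 1-based, as the format
#' requires). Round-trips through [readVcfGenotypes()].
#'
#' @param ds a `GenotypeData`
#' @param path output path
#' @export
writeVcfGenotypes <- function(ds, path) {
  sep <- if (ploidy(ds) == 2L) "/" else ""
  g <- genotypes(ds)
  gtChr <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  if (ploidy(ds) == 2L) {
    gtChr[!is.na(g) & g == 0L] <- "0/0"
    gtChr[!is.na(g) & g == 1L] <- "0/1"
    gtChr[!is.na(g) & g == 2L] <- "1/1"
  } else {
    gtChr[] <- "."
    gtChr[!is.na(g)] <- as.character(g[!is.na(g)])
  }
  s <- siteRanges(ds)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ds@samples), collapse = "\t"))
  body <- paste(as.character(seqnames(s)), start(s), ".",
                mcols(s)$ref, mcols(s)$alt, ".", "PASS", ".", "GT",
                apply(gtChr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a region set as a BED file
#'
#' Regions are written 0-based half-open, tab-separated and sorted, after
#' merging (union of overlapping or adjacent intervals) unless
#' `merge = FALSE`. Unsorted input is sorted on write with a note.
#'
#' @param regions a `GRanges`
#' @param path output path
#' @param merge merge overlapping/adjacent intervals before writing
#' @export
writeBed <- function(regions, path, merge = TRUE) {
  if (merge) regions <- reduce(regions)
  if (is.unsorted(order(as.character(seqnames(regions)), start(regions)))) {
    message("unsorted regions: sorting on write")
  }
  regions <- GenomicRanges::sort(regions)
  lines <- paste(as.character(seqnames(regions)),
                 start(regions) - 1L, end(regions), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+ file into a GRanges
#'
#' Tolerant reader: malformed lines are skipped and counted (attribute
#' `nSkipped`). Coordinates are converted from BED 0-based half-open to the
#' 1-based closed convention of `GRanges`. A 4th column, when present,
#' becomes the `name` metadata column; a 6th becomes `strand`.
#'
#' @param path BED file
#' @return a `GRanges`
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  fields <- strsplit(lines, "\t")
  ok <- vapply(fields, function(f) {
    length(f) >= 3L && !is.na(suppressWarnings(as.numeric(f[2]))) &&
      !is.na(suppressWarnings(as.numeric(f[3]))) &&
      as.numeric(f[3]) > as.numeric(f[2])
  }, logical(1))
  nSkipped <- sum(!ok)
  if (nSkipped) message(nSkipped, " malformed BED line(s) skipped")
  fields <- fields[ok]
  if (!length(fields)) {
    gr <- GRanges()
  } else {
    chrom <- vapply(fields, `[`, character(1), 1L)
    s <- as.integer(vapply(fields, `[`, character(1), 2L))
    e <- as.integer(vapply(fields, `[`, character(1), 3L))
    strand <- vapply(fields, function(f)
      if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "*",
      character(1))
    gr <- GRanges(chrom, IRanges(s + 1L, e), strand = strand)
    nm <- vapply(fields, function(f)
      if (length(f) >= 4L) f[4] else NA_character_, character(1))
    if (any(!is.na(nm))) mcols(gr)$name <- nm
  }
  attr(gr, "nSkipped") <- nSkipped
  gr
}

#' Read a feature track (BED or GFF3) into a GRanges
#'
#' BED goes through [readBed()]; GFF3 through
#' [rtracklayer::import.gff3()] (which handles the 1-based closed GFF
#' convention), with the feature `ID`/`Name`/`gene_id` attribute exposed as
#' the `name` column.
#'
#' @param path feature file; format chosen by extension
#'   (`.bed` vs `.gff`/`.gff3`).
#' @return a `GRanges` with a `name` metadata column.
#' @export
readFeatures <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- readBed(path)
    if (is.null(mcols(gr)$name))
      mcols(gr)$name <- paste0("feature_", seq_along(gr))
    return(gr)
  }
  gr <- rtracklayer::import.gff3(path)
  nm <- mcols(gr)$ID
  if (is.null(nm)) nm <- mcols(gr)$Name
  if (is.null(nm)) nm <- paste0("feature_", seq_along(gr))
  nm[is.na(nm)] <- paste0("feature_", which(is.na(nm)))
  mcols(gr) <- NULL
  mcols(gr)$name <- as.character(nm)
  gr
}
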
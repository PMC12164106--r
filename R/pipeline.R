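#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. Exactly
#' one of `scenario` (simulation parameters) or `vcf` + `popmapFile` (real
#' data) must be supplied.
#'
#' @param scenario a [scenarioParams()] object, or `NULL`
#' @param vcf,popmapFile paths to a VCF and population map, or `NULL`
#' @param p1 reference (non-introgressed) population, the P1 of every trio
#' @param candidates populations tested for introgression (the P2s)
#' @param donor donor population (P3)
#' @param p4 second wild population (DFOIL P4 and default PBS reference 2)
#' @param outgroup outgroup population
#' @param alpha significance level for the jackknife test (default 0.05)
#' @param dAlternative jackknife test direction: `"two.sided"` (default)
#'   or `"greater"` (one-sided for an excess of target-donor sharing)
#' @param fdmTop top fdM fraction called introgressed (default 0.05)
#' @param pbsTop top PBS fraction called selected (default 0.01)
#' @param fdmMode `"quantile"` or `"ztest"` window calling
#' @param winSnps,stepSnps SNP window and step (50/25 by convention)
#' @param nBlocks jackknife blocks (default 20)
#' @param permCycles PBS permutation cycles (0 skips permutation p-values;
#'   2000 is the conventional full setting)
#' @param pbsRef2Donor use the donor instead of `p4` as the second PBS
#'   reference
#' @param bhCorrect apply Benjamini-Hochberg correction across candidate
#'   p-values before flagging (off by default, mirroring the per-population
#'   testing convention)
#' @param features optional feature track (path or `GRanges`) for
#'   annotation
#' @param maxDistance annotation distance cap in bp
#' @param seed integer master seed
#' @param outDir optional output directory for TSV/BED/manifest files
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(scenario = NULL, vcf = NULL, popmapFile = NULL,
                           p1 = "MEN", candidates = c("D1", "D2", "D3", "D4"),
                           donor = "W2", p4 = "W1", outgroup = "OUT",
                           alpha = 0.05, dAlternative = c("two.sided",
                                                          "greater"),
                           fdmTop = 0.05, pbsTop = 0.01,
                           fdmMode = c("quantile", "ztest"),
                           winSnps = 50L, stepSnps = 25L, nBlocks = 20L,
                           permCycles = 0L, pbsRef2Donor = FALSE,
                           bhCorrect = FALSE, features = NULL,
                           maxDistance = 1e6, seed = 1L, outDir = NULL) {
  fdmMode <- match.arg(fdmMode)
  dAlternative <- match.arg(dAlternative)
  hasSim <- !is.null(scenario)
  hasFiles <- !is.null(vcf) || !is.null(popmapFile)
  if (hasSim == hasFiles)
    stop("supply exactly one of 'scenario' or 'vcf' + 'popmapFile'")
  if (hasFiles && (is.null(vcf) || is.null(popmapFile)))
    stop("both 'vcf' and 'popmapFile' are required for file input")
  for (v in c(alpha, fdmTop, pbsTop))
    if (!(v > 0 && v < 1)) stop("thresholds must lie in (0, 1)")
  structure(list(scenario = scenario, vcf = vcf, popmapFile = popmapFile,
                 p1 = p1, candidates = candidates, donor = donor, p4 = p4,
                 outgroup = outgroup, alpha = alpha,
                 dAlternative = dAlternative, fdmTop = fdmTop,
                 pbsTop = pbsTop, fdmMode = fdmMode, winSnps = winSnps,
                 stepSnps = stepSnps, nBlocks = nBlocks,
                 permCycles = permCycles, pbsRef2Donor = pbsRef2Donor,
                 bhCorrect = bhCorrect, features = features,
                 maxDistance = maxDistance, seed = seed, outDir = outDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipelineConfig()] arguments; a
#' `scenario:` block is passed to [scenarioParams()] (with `pulse:` given
#' as a list of donor/recipients/f/timeGen blocks).
#'
#' @param path YAML file
#' @return a `PipelineConfig`
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) y$scenario <- do.call(scenarioParams, y$scenario)
  do.call(pipelineConfig, y)
}

.stage <- function(out, name, expr) {
  tryCatch(expr, error = function(e) {
    cond <- simpleError(paste0("pipeline stage '", name, "' failed: ",
                               conditionMessage(e)))
    attr(cond, "partial") <- out
    stop(cond)
  })
}

#' Run the full introgression-and-selection pipeline
#'
#' Orchestrates, from one configuration and one seed: data acquisition
#' (simulation or VCF), polarization, a D-statistic + f4-ratio test per
#' candidate population, fdM window scans and introgressed-region calls
#' for the flagged candidates, the common introgressed region across them,
#' a DFOIL direction test (flagged candidates pooled as P1), a PBS scan of
#' the pooled flagged candidates with optional permutation p-values,
#' selected-region calls, the selected-introgressed intersection, and
#' optional feature annotation.
#'
#' A candidate is flagged "introgressed" iff `D > 0` AND `f4-ratio > 0`
#' AND jackknife `p < alpha` -- all three conditions are required.
#'
#' Reruns with an identical configuration (including seed) reproduce the
#' result exactly. Any stage failure halts with the stage name; results of
#' completed stages are attached to the error condition as `"partial"`.
#'
#' @param cfg a [pipelineConfig()] (or path to a YAML accepted by
#'   [readPipelineConfig()])
#' @return list with elements `perCandidate` (data frame of D, se, Z, p,
#'   f4 and the introgression flag), `introgressedRegions` (per flagged
#'   candidate), `commonIntrogressed`, `dfoil`, `pbs`, `selectedRegions`,
#'   `selectedIntrogressed`, `annotation`, `truthTracts` (simulation only)
#'   and `manifest`.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  stopifnot(inherits(cfg, "PipelineConfig"))
  out <- list()
  t0 <- Sys.time()

  ds <- .stage(out, "input", {
    if (!is.null(cfg$scenario)) {
      sim <- simulateScenario(cfg$scenario)
      out$truthTracts <- sim$tracts
      sim$ds
    } else {
      readVcfGenotypes(cfg$vcf, readPopmap(cfg$popmapFile),
                       maf = NULL, maxMissing = 0.1)
    }
  })

  af <- .stage(out, "polarize", polarize(ds, cfg$outgroup))

  out$perCandidate <- .stage(out, "dstat", {
    rows <- lapply(cfg$candidates, function(cand) {
      trio <- trioSpec(cfg$p1, cand, cfg$donor, cfg$outgroup)
      jk <- dJackknife(af, trio, nBlocks = cfg$nBlocks,
                       alternative = cfg$dAlternative)
      split <- splitDonor(ds, cfg$donor, seed = cfg$seed)
      f4 <- f4Ratio(ds, af, trio, split)
      data.frame(candidate = cand, D = jk$D, se = jk$se, Z = jk$Z,
                 p = jk$p, f4 = as.numeric(f4), nSites = jk$nSites,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    pAdj <- if (cfg$bhCorrect) stats::p.adjust(tab$p, "BH") else tab$p
    tab$introgressed <- !is.na(tab$D) & tab$D > 0 &
      !is.na(tab$f4) & tab$f4 > 0 & !is.na(pAdj) & pAdj < cfg$alpha
    tab
  })
  flagged <- out$perCandidate$candidate[out$perCandidate$introgressed]

  out$introgressedRegions <- .stage(out, "fdm", {
    regs <- list()
    for (cand in flagged) {
      trio <- trioSpec(cfg$p1, cand, cfg$donor, cfg$outgroup)
      fdm <- fdmWindows(af, trio, cfg$winSnps, cfg$stepSnps)
      D <- out$perCandidate$D[out$perCandidate$candidate == cand]
      regs[[cand]] <- callIntrogressedWindows(fdm, D, mode = cfg$fdmMode,
                                              topFrac = cfg$fdmTop,
                                              alpha = cfg$alpha)
    }
    regs
  })

  out$commonIntrogressed <- .stage(out, "common", {
    if (length(out$introgressedRegions))
      intersectMany(out$introgressedRegions,
                    minSupport = length(out$introgressedRegions))
    else GRanges()
  })

  out$dfoil <- .stage(out, "dfoil", {
    if (length(flagged) >= 1L) {
      dsPool <- poolPopulations(ds, ".P1pool", flagged)
      afPool <- polarize(dsPool, cfg$outgroup)
      taxa <- dfoilTaxa(P1 = ".P1pool", P2 = cfg$p1, P3 = cfg$donor,
                        P4 = cfg$p4, O = cfg$outgroup)
      dfoilStatistics(countPatterns(afPool, taxa, mode = "binarized"),
                      alpha = cfg$alpha)
    } else NULL
  })

  out$pbs <- .stage(out, "pbs", {
    focal <- if (length(flagged)) flagged else cfg$candidates
    ref2 <- if (cfg$pbsRef2Donor) cfg$donor else cfg$p4
    scan <- pbsScan(ds, focal, cfg$p1, ref2,
                    winSnps = cfg$winSnps, stepSnps = cfg$stepSnps)
    if (cfg$permCycles > 0L)
      scan <- pbsPermutationP(scan, nCycles = cfg$permCycles,
                              seed = cfg$seed + 1L)
    scan
  })

  out$selectedRegions <- .stage(out, "selected", {
    tryCatch(callSelectedRegions(out$pbs, quantile = cfg$pbsTop),
             error = function(e) {
               message("selected-region call skipped: ",
                       conditionMessage(e))
               GRanges()
             })
  })

  out$selectedIntrogressed <- .stage(out, "sir",
    selectedIntrogressed(out$commonIntrogressed, out$selectedRegions))

  out$annotation <- .stage(out, "annotate", {
    if (is.null(cfg$features)) NULL
    else {
      feats <- if (is.character(cfg$features)) readFeatures(cfg$features)
      else cfg$features
      annotateRegions(out$selectedIntrogressed, feats,
                      maxDistance = cfg$maxDistance)
    }
  })

  out$manifest <- list(
    package = as.character(utils::packageVersion("introScan")),
    rVersion = R.version.string,
    seed = cfg$seed,
    alpha = cfg$alpha, fdmTop = cfg$fdmTop, pbsTop = cfg$pbsTop,
    fdmMode = cfg$fdmMode, winSnps = cfg$winSnps, stepSnps = cfg$stepSnps,
    nBlocks = cfg$nBlocks, permCycles = cfg$permCycles,
    nSites = nSites(ds), nSamples = nSamples(ds),
    candidates = cfg$candidates, flagged = flagged,
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(cfg$outDir)) .writePipelineBundle(out, cfg)
  out
}

.writePipelineBundle <- function(out, cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(cfg$outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(out$perCandidate, "dstat_f4.tsv")
  w(out$pbs, "pbs_scan.tsv")
  for (cand in names(out$introgressedRegions))
    writeBed(out$introgressedRegions[[cand]],
             file.path(cfg$outDir, paste0("introgressed_", cand, ".bed")))
  writeBed(out$commonIntrogressed,
           file.path(cfg$outDir, "common_introgressed.bed"))
  writeBed(out$selectedRegions, file.path(cfg$outDir, "selected.bed"))
  writeBed(out$selectedIntrogressed,
           file.path(cfg$outDir, "selected_introgressed.bed"))
  if (!is.null(out$dfoil)) w(out$dfoil$stats, "dfoil.tsv")
  if (!is.null(out$annotation)) w(out$annotation, "annotation.tsv")
  mf <- out$manifest
  w(data.frame(key = names(mf),
               value = vapply(mf, function(v)
                 paste(as.character(v), collapse = ","), character(1))),
    "MANIFEST.tsv")
  invisible()
}
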
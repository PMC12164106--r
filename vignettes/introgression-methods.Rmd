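---
title: "Methods: introgression and selection scans with introScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression and selection scans with introScan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`introScan` addresses one recurring study design in livestock and wildlife
genomics: several domesticated populations, two or more wild relative
subpopulations suspected as gene-flow donors, and a distant outgroup, all
genotyped at genome-wide biallelic SNPs. The questions are (i) which
target populations received wild material, (ii) how much, (iii) where in
the genome, (iv) in which direction the material moved, and (v) whether
the introgressed segments were subsequently under selection.

The package answers them with, respectively: Patterson's D with a
block-jackknife Z-test; the f4-ratio over a random donor bipartition; a
50-SNP/25-SNP sliding-window f_dM scan with top-quantile (or one-tailed
Z-test) window calling gated on genome-wide D > 0; four five-taxon
site-pattern statistics (DFO/DIL/DFI/DOL); and a PBS scan of the pooled
recipients with top-1% calling and an optional Monte-Carlo permutation
test. A population is reported "introgressed" only under the strict
conjunction D > 0 AND f4-ratio > 0 AND jackknife p below the chosen
alpha. `runPipeline()` wires the chain together from a single seeded
configuration.

All statistics operate on derived-allele frequencies produced by
`polarize()`: the derived allele at a site is the outgroup's minor allele;
sites with an outgroup frequency of exactly 0.5 are excluded (no
orientation evidence), sites with all outgroup calls missing are excluded
and counted, and sites where the outgroup minor-allele frequency exceeds
`polyThreshold` (default 0.2) are retained but flagged. Frequencies are
always computed over called alleles only, so randomly missing genotypes
are unbiased noise rather than systematic error.

# Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| MAF filter | 0.05 (strict >) | frequency | common population-structure convention; **disable (`maf = NULL`) for D/f_dM work** — frequency filters distort ABBA-BABA counts |
| missing-rate filter | 0.1 | fraction of samples | conventional |
| jackknife blocks | 20 | contiguous equal-SNP blocks | enough blocks for a stable variance, few enough that each block spans many independent loci |
| f_dM window / step | 50 / 25 | SNPs | the windowed-scan convention for this design |
| f_dM call rule | top 5% and D > 0 | — | the region-level convention; a one-tailed Z-test mode (`p < 0.05` and D > 0) is also provided because both rules are in circulation |
| PBS window / step | 50 / 25 | SNPs | matches the scan convention |
| PBS call rule | top 1% | — | rank-based, hence invariant to monotone transforms |
| permutation cycles | 2000 | — | conventional Monte-Carlo setting; 1000 for the diversity permutation tests |
| alpha | 0.05 | — | per-population testing without multiplicity correction mirrors common practice; a Benjamini–Hochberg switch exists (`bhCorrect`) and is off by default |

The D jackknife defaults to a two-sided normal p-value; a one-sided
(`"greater"`) mode is available and coherent with the D > 0 arm of the
flag rule.

# The synthetic-data generator

`simulateScenario()` draws per-site allele frequencies down a fixed
population-tree topology — outgroup; a wild clade of two subpopulations;
a set of domestic populations radiating from a common domestic ancestor —
under hierarchical Balding–Nichols drift: each branch of length *t*
generations in a diploid population of size *Ne* transforms a parent
frequency *p* into a Beta draw with mean *p* and fixation index
`F = 1 − exp(−t / 2Ne)`. Genotypes are binomial given the population
frequency, which makes samples exchangeable within populations by
construction. Default split times follow the wild/domestic history of
sheep and Asiatic mouflon at a 3-year generation time (wild split 2189
generations ≈ 6568 y; domestic/wild split 3330 generations ≈ 9991 y;
domestic radiation 2000 generations), the mutation rate defaults to 1e-8
per site per generation (used to size the default SNP count), and *Ne*
defaults to a round illustrative 10,000 — the demographic inference that
would pin *Ne* per branch is out of scope, so this number is deliberately
not presented as an estimate. The outgroup split (40,000 generations) is
likewise illustrative: deep enough that the outgroup is usually fixed
(clean polarization), shallow enough that the ingroup retains standing
variation (the drift model carries no new mutations along branches, so a
realistically deep outgroup would fix everything).

An admixture pulse is an explicit tract mosaic: recombination breakpoints
are Poisson with rate `recombRate × pulse age` per bp, each segment is
donor-derived with probability *f*, and inside donor segments the
recipient's frequency continues from the **donor's own pulse-time
frequency** (drawn once and shared with the donor's terminal drift, so
transferred material is nested within the donor lineage — without this
nesting no direction signal exists). Donor segments are returned as truth
tracts, so the expected truth-tract genome fraction equals *f* and the
f4-ratio estimates it directly. A pulse therefore models locally *fixed*
introgressed haplotypes rather than segregating ones — the sharpest
version of the signal the scan statistics target.

`injectSweep()` models selection as a deterministic frequency distortion
(`p → p + s(1 − p)` with genotype resampling) inside an interval — enough
to create a PBS signal at a tiny fraction of the cost of forward
simulation.

What passing tests on this generator do **not** show about real data:
there is no linkage disequilibrium between sites (block jackknives on real
data lean on blocks exceeding LD range; here any blocking works), no new
mutation after the root, no background selection or mappability artefacts,
and introgressed material is locally fixed. Power numbers measured on the
generator translate to real data only qualitatively.

# Numerical and statistical choices

- **Coordinates.** All interval work uses `GRanges` (1-based, closed),
  the Bioconductor convention; BED input/output converts to and from
  0-based half-open at the boundary, and VCF positions are 1-based as the
  format requires. Round-trip tests pin the conversions.
- **π and d_xy denominators.** Both "window length in bp" (valid when
  non-SNP positions are known invariant; the default) and "usable SNPs
  only" are implemented; the latter estimates per-variant-site diversity
  and is flagged in the output `stat` semantics rather than silently
  mixed. Windows with zero usable sites are flagged, reported as 0 under
  the length denominator and NA under the SNP denominator.
- **Two FST estimators.** Hudson (ratio of sums, default; feeds PBS) and
  Weir–Cockerham two-level theta (windowed scans and uniparental loci).
  Negative estimates are reported as-is; only the PBS transform floors
  them. The two agree within ±0.02 on balanced fixtures — a standing
  cross-check since neither implementation is borrowed.
- **PBS transform.** `T = −ln(1 − FST)` (natural log). Inputs at or above
  1 are capped at `1 − 1e-9`, negative inputs floored at 0, both flagged.
  Flooring creates an atom at the bottom of the PBS distribution, so the
  *permutation comparisons* internally use the unfloored continuous scale
  (identical ranking for positive signals, no tie atoms); the reported
  `pbs` column keeps the conventional flooring.
- **Permutation p-values** use the add-one estimator
  `(1 + #{null ≥ obs}) / (n + 1)`: never exactly zero, minimum
  `1/(n+1)`. The PBS permutation offers a pooled global null (cheap;
  appropriate for ranking) and a per-window null with independent
  relabellings per window — only the latter is a calibrated test, and
  only when individuals are genuinely exchangeable across the three
  groups. On structurally diverged populations the permutation destroys
  population structure, so small p-values mean "more differentiated than
  exchangeable samples", not "selected"; the top-quantile rank call is
  the selection inference there. The calibration test in the suite
  therefore uses pseudo-populations split from one population.
- **Jackknife.** Contiguous blocks of (near-)equal informative-SNP count;
  delete-one SE `sqrt((B−1)/B Σ(D₋ᵦ − mean)²)`. Blocks with zero
  informative sites are dropped and counted; zero variance across blocks
  is flagged rather than reported as an infinite Z.
- **f4-ratio.** The denominator uses `(p̂3b − p̂1)`; a `(p̂3b − p̂O)`
  variant is exposed as an explicit flag, not a silent correction.
- **DFOIL.** The four statistics are `(L − R)/(L + R)` over two-pattern
  groups (see `dfoilPatternGroups()`; shipped as a TSV so they can be
  audited). The groups were re-derived from the construction principle —
  equal expected left/right weight under incomplete lineage sorting on
  the symmetric five-taxon tree, antisymmetry under the relevant taxon
  swap, concordant and singleton patterns excluded (including singletons
  symmetrises away the introgression signal, which we verified by
  simulation). Classification is DFI-first: DFI (the P3-anchored
  P1-vs-P2 contrast) fixes which ingroup taxon exchanged material with
  P3; the zero/nonzero state of DOL fixes the direction, because only
  material donated *by* P3 carries pre-wild-split alleles that also
  appear in P4; DFO/DIL alone indicate flow into the unsplit P1-P2
  ancestor. Direction (as opposed to pair) is the power-limited part of
  the call: with weak data a true donor-into-P1 flow degrades to the
  "P1→P3" row, never to a wrong pair. Chi-squared significance on (L, R)
  is exactly calibrated only for binarized unit counts — binarized
  counting is the inference mode; frequency-weighted counting is kept as
  allele-frequency bookkeeping but has very low power under drift-style
  data and a conservative test.
- **Region algebra.** "Common across populations" is bp-resolution
  coverage counting (`intersectMany`), not window-identity matching,
  since different populations' windows need not align. Nearest-feature
  ties break toward the smaller start coordinate; distances are signed by
  coordinate (negative = upstream of the region start).
- **Haplotype diversity.** `h = n/(n−1)(1 − Σp²)` with Nei's (1987,
  eq. 8.12) sampling variance. Published tables sometimes print
  dispersion values for *h* that match neither this variance nor its
  square root; `bootstrapHaplotypeSd()` provides a model-free
  cross-check.

# Problem sizes used by the test-suite and acceptance script

Null calibration of the jackknife test runs 100 replicates of 20,000
SNPs with 20 blocks; f4 recovery runs 20 replicates of 10,000 SNPs at
f = 0.3; end-to-end flag recovery runs replicates of 200,000 SNPs at
f = 0.2 into two of four candidates — a size chosen by a power analysis
of the drift model (the genome-wide D at this demography is ≈ 0.02–0.05
for f = 0.2, so tens of thousands of sites give only borderline
jackknife power; the real studies this mirrors test 10⁷–10⁸ sites).
Sweep recovery uses 6,000-SNP replicates with a 400-kb strength-0.9
sweep. The DFOIL direction check uses 100,000-SNP replicates because the
direction component (DOL) rides on roughly an order of magnitude fewer
informative patterns than the genome-wide D.

# Known limitations

- The drift generator cannot represent post-split mutation, LD, or
  segregating (non-fixed) introgressed haplotypes; power estimates are
  generator-specific.
- DFOIL direction inference assumes the symmetric five-taxon topology
  with the P1/P2 split more recent than P3/P4, and its within-pair
  direction call has limited power at realistic fractions.
- The PBS permutation test is calibrated only under exchangeability;
  between diverged populations it is an enrichment ranking.
- The Weir–Cockerham estimator requires diploid genotypes; haploid-coded
  data must use the Hudson estimator.
- No LD pruning is implemented (it belongs to structure analysis, which
  is out of scope), and no multiallelic-site support anywhere.
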
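test_that("pi matches the hand-counted haploid example", {
  ## two haploid-coded sequences differing at 3 of 100 genotyped sites
  geno <- matrix(0L, 100, 2)
  geno[c(10, 50, 90), 2] <- 1L
  ds <- makeDs(geno, c("A", "A"), ploidy = 1L)
  pi <- nucleotideDiversity(ds, "A", denominator = "snps")
  expect_equal(pi$value, 0.03)

  ## monomorphic window
  dsM <- makeDs(matrix(1L, 10, 2), c("A", "A"), ploidy = 1L)
  expect_equal(nucleotideDiversity(dsM, "A", denominator = "snps")$value, 0)

  ## invariant under sample reordering
  set.seed(2)
  g <- matrix(sample(0:2, 60, TRUE), 10, 6)
  ds1 <- makeDs(g, rep("A", 6))
  ds2 <- makeDs(g[, 6:1], rep("A", 6))
  expect_equal(nucleotideDiversity(ds1, "A", denominator = "snps")$value,
               nucleotideDiversity(ds2, "A", denominator = "snps")$value)
  expect_error(nucleotideDiversity(ds1, "nope"), "unknown")
})

test_that("dxy matches hand counts and equals the within-population rate on duplicated populations", {
  ## popA fixed ref, popB fixed alt at 1 of 10 counted sites
  geno <- matrix(0L, 10, 4)
  geno[5, 3:4] <- 2L
  ds <- makeDs(geno, c("A", "A", "B", "B"))
  expect_equal(dxy(ds, "A", "B", denominator = "snps")$value, 0.1)

  ## popA == popB sample-for-sample on a 5-site fixture: dxy equals the
  ## enumerated between-copy mismatch rate
  set.seed(7)
  gA <- matrix(sample(0:2, 15, TRUE), 5, 3)
  ds2 <- makeDs(cbind(gA, gA), rep(c("A", "B"), each = 3))
  d <- dxy(ds2, "A", "B", denominator = "snps")$value
  expect_equal(d, bruteDxy(gA, gA, 2L))
})

test_that("pi and dxy equal explicit all-pairs comparison on small fixtures", {
  set.seed(19)
  for (rep in 1:8) {
    nS <- sample(5:20, 1)
    nA <- sample(2:5, 1); nB <- sample(2:5, 1)
    ploidy <- sample(c(1L, 2L), 1)
    gA <- matrix(sample(0:ploidy, nS * nA, TRUE), nS, nA)
    gB <- matrix(sample(0:ploidy, nS * nB, TRUE), nS, nB)
    ds <- makeDs(cbind(gA, gB), rep(c("A", "B"), c(nA, nB)),
                 ploidy = ploidy)
    expect_equal(nucleotideDiversity(ds, "A", denominator = "snps")$value,
                 brutePi(gA, ploidy), tolerance = 1e-12)
    expect_equal(dxy(ds, "A", "B", denominator = "snps")$value,
                 bruteDxy(gA, gB, ploidy), tolerance = 1e-12)
  }
})

test_that("random genotype masking leaves dxy unchanged in expectation", {
  sim <- simulateScenario(nullScenario(seed = 23, nSnps = 400,
                                       samplesPerPop = 8L))
  ds <- sim$ds
  full <- dxy(ds, "W1", "MEN", denominator = "snps")$value
  set.seed(77)
  masked <- vapply(1:50, function(i) {
    g <- genotypes(ds)
    drop <- matrix(runif(length(g)) < 0.2, nrow(g))
    g[drop] <- NA_integer_
    ds2 <- makeDs(g, popmap(ds)$population,
                  pos = start(siteRanges(ds)))
    dxy(ds2, "W1", "MEN", denominator = "snps")$value
  }, numeric(1))
  se <- sd(masked) / sqrt(length(masked))
  expect_lt(abs(mean(masked) - full), 2 * se + 1e-4)
})

test_that("Hudson FST behaves at fixed differences, under symmetry, and at equality", {
  ## fixed difference, large n
  geno <- rbind(c(rep(0L, 10), rep(2L, 10)))
  ds <- makeDs(geno, rep(c("A", "B"), each = 10))
  expect_gt(fstHudson(ds, "A", "B")$value, 0.99)
  ## symmetry
  expect_equal(fstHudson(ds, "A", "B")$value, fstHudson(ds, "B", "A")$value)

  ## equal frequencies: window value near 0 on a 1000-site fixture
  set.seed(4)
  p <- runif(1000, 0.1, 0.9)
  g <- matrix(rbinom(1000 * 20, 2, rep(p, 20)), 1000, 20)
  dsEq <- makeDs(g, rep(c("A", "B"), each = 10))
  expect_lt(abs(fstHudson(dsEq, "A", "B")$value), 0.05)
})

test_that("Weir-Cockerham theta is near zero on pseudo-split populations and tracks Hudson", {
  sim <- simulateScenario(nullScenario(seed = 29, nSnps = 3000,
                                       samplesPerPop = 10L))
  ds <- sim$ds
  ## split one population randomly into two pseudo-populations
  set.seed(6)
  lab <- popmap(ds)$population
  w1 <- which(lab == "W1")
  lab[sample(w1, 5)] <- "W1a"
  lab[lab == "W1"] <- "W1b"
  ds2 <- makeDs(genotypes(ds), lab, pos = start(siteRanges(ds)))
  expect_lt(abs(fstWC(ds2, "W1a", "W1b")$value), 0.03)

  ## cross-estimator agreement on a balanced fixture
  h <- fstHudson(ds, "W1", "MEN")$value
  w <- fstWC(ds, "W1", "MEN")$value
  expect_lt(abs(h - w), 0.02)
  ## fixed difference -> theta ~ 1
  gF <- rbind(c(rep(0L, 10), rep(2L, 10)))
  dsF <- makeDs(gF, rep(c("A", "B"), each = 10))
  expect_gt(fstWC(dsF, "A", "B")$value, 0.97)
})

test_that("Hudson FST increases with split time", {
  splits <- c(200, 600, 1200, 2000, 3000)
  vals <- unlist(lapply(splits, function(tw)
    vapply(1:20, function(r) {
      sim <- simulateScenario(scenarioParams(
        nSnps = 800, seqLengthBp = 2e6, samplesPerPop = 4L,
        tWild = tw, seed = 5000 + 100 * tw + r))
      fstHudson(sim$ds, "W1", "W2")$value
    }, numeric(1))))
  expect_gt(cor(rep(splits, each = 20), vals, method = "spearman"), 0.9)
})

test_that("haplotype diversity matches algebraic identities and known table entries", {
  expect_equal(haplotypeDiversity(c(8))$h, 0)
  expect_equal(haplotypeDiversity(rep(1, 9))$h, 1)
  expect_error(haplotypeDiversity(c(1)), "at least 2")

  ## the two island-subpopulation entries: n = 7 with classes (5,2) and
  ## (6,1); brute-force search over all partitions of 7 confirms these are
  ## the only configurations producing the printed h values
  expect_equal(round(haplotypeDiversity(c(5, 2))$h, 5), 0.47619)
  expect_equal(round(haplotypeDiversity(c(6, 1))$h, 5), 0.28571)
  parts7 <- list(c(7), c(6, 1), c(5, 2), c(5, 1, 1), c(4, 3), c(4, 2, 1),
                 c(4, 1, 1, 1), c(3, 3, 1), c(3, 2, 2), c(3, 2, 1, 1),
                 c(3, 1, 1, 1, 1), c(2, 2, 2, 1), c(2, 2, 1, 1, 1),
                 c(2, 1, 1, 1, 1, 1), rep(1, 7))
  hs <- vapply(parts7, function(m) haplotypeDiversity(m)$h, numeric(1))
  expect_equal(sum(abs(hs - 0.47619) < 1e-5), 1L)
  expect_equal(sum(abs(hs - 0.28571) < 1e-5), 1L)

  ## analytic sd is in the same ballpark as the bootstrap cross-check
  hd <- haplotypeDiversity(c(5, 2))
  bs <- bootstrapHaplotypeSd(c(5, 2), nBoot = 2000, seed = 2)
  expect_lt(abs(hd$sd - bs) / hd$sd, 0.35)
})

test_that("permutation p-values use the add-one rule and are calibrated", {
  ## perfectly separated populations reach the minimum attainable p
  ## (groups large enough that no label permutation rebuilds the split)
  geno <- matrix(rep(c(0L, 2L), each = 10), 20, 20, byrow = TRUE)
  ds <- makeDs(geno, rep(c("A", "B"), each = 10))
  pt <- permutationTest(ds, "A", "B", "fst_hudson", nPerm = 999, seed = 1)
  expect_equal(pt$p, 1 / 1000)
  expect_gt(pt$p, 0)

  ## identically drawn populations: rejection rate 0.05 +/- 0.03
  set.seed(55)
  rej <- vapply(1:200, function(i) {
    g <- matrix(rbinom(50 * 12, 2, 0.3), 50, 12)
    dsN <- makeDs(g, rep(c("A", "B"), each = 6))
    permutationTest(dsN, "A", "B", "fst_hudson", nPerm = 99,
                    seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})
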
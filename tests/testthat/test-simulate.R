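test_that("a zero-fraction pulse leaves no truth tracts", {
  p <- nullScenario(seed = 1, nSnps = 200,
                    pulse = list(donor = "W2", recipients = "D1",
                                 f = 0, timeGen = 500))
  sim <- simulateScenario(p)
  expect_length(sim$tracts, 0L)
})

test_that("identical seeds give byte-identical emitted scenarios", {
  p <- nullScenario(seed = 9, nSnps = 300,
                    pulse = list(donor = "W2", recipients = "D1",
                                 f = 0.3, timeGen = 500))
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  f1 <- writeScenario(simulateScenario(p), d1)
  f2 <- writeScenario(simulateScenario(p), d2)
  for (k in seq_along(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
})

test_that("truth-tract coverage matches the pulse fraction on average", {
  fracs <- vapply(1:50, function(s) {
    p <- scenarioParams(nSnps = 50, seqLengthBp = 1e6, samplesPerPop = 2L,
                        pulse = list(donor = "W2", recipients = "D1",
                                     f = 0.5, timeGen = 500),
                        seed = 100 + s)
    sim <- simulateScenario(p)
    sum(width(sim$tracts)) / 1e6
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.1)
})

test_that("tracts are confined to pulse recipients", {
  p <- nullScenario(seed = 2, nSnps = 200,
                    pulse = list(donor = "W2", recipients = c("D1", "D3"),
                                 f = 0.4, timeGen = 500))
  sim <- simulateScenario(p)
  expect_setequal(unique(mcols(sim$tracts)$recipient), c("D1", "D3"))
})

test_that("inconsistent event ordering is fatal before simulation", {
  expect_error(scenarioParams(tOut = 1000, tWildDom = 3330),
               "inconsistent")
  expect_error(nullScenario(seed = 1,
                            pulse = list(donor = "W2", recipients = "D1",
                                         f = 0.2, timeGen = 5000)),
               "pulse time")
  expect_error(nullScenario(seed = 1,
                            pulse = list(donor = "W2", recipients = "D1",
                                         f = 1.5, timeGen = 500)),
               "f must lie")
})

test_that("sweep injection distorts frequencies as specified", {
  sim <- simulateScenario(nullScenario(seed = 21, nSnps = 2000))
  iv <- c(5e5, 1e6)
  inIv <- start(siteRanges(sim$ds)) >= iv[1] &
    start(siteRanges(sim$ds)) <= iv[2]
  cols <- popmap(sim$ds)$population == "D1"
  meanFreq <- function(ds) {
    g <- genotypes(ds)[inIv, cols, drop = FALSE]
    mean(rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g))))
  }
  before <- meanFreq(sim$ds)

  swept <- injectSweep(sim$ds, "D1", iv[1], iv[2], strength = 1, seed = 4)
  g <- genotypes(swept)[inIv, cols, drop = FALSE]
  expect_true(all(g[!is.na(g)] == 2L))
  ## outside the interval nothing changes
  expect_identical(genotypes(swept)[!inIv, ], genotypes(sim$ds)[!inIv, ])

  half <- injectSweep(sim$ds, "D1", iv[1], iv[2], strength = 0.5, seed = 4)
  expect_gt(meanFreq(half), before)

  expect_error(injectSweep(sim$ds, "D1", iv[1], iv[2], strength = 0),
               "strength")
  expect_error(injectSweep(sim$ds, "D1", 1, 1e9, strength = 0.5),
               "bounds")
})

test_that("haplotype fixtures realize the requested multiplicity classes", {
  fx <- makeHaplotypeFixture(c(5, 2), length = 50, seed = 1)
  expect_length(fx, 7L)
  expect_equal(length(unique(as.character(fx))), 2L)

  fx3 <- makeHaplotypeFixture(c(1, 1, 1), length = 50, seed = 1)
  expect_equal(length(unique(as.character(fx3))), 3L)

  ## round trip: counting haplotypes recovers the input multiset
  set.seed(8)
  for (rep in 1:5) {
    mult <- sample.int(6, sample(2:5, 1), replace = TRUE)
    fx <- makeHaplotypeFixture(mult, length = 30, seed = rep)
    expect_equal(haplotypeSpectrum(fx), sort(mult, decreasing = TRUE))
  }
  expect_error(makeHaplotypeFixture(integer(0)), "at least one")
  expect_error(makeHaplotypeFixture(c(2, 2), length = 1), ">=")
})

test_that("samples are exchangeable within populations", {
  ## site-frequency spectra are invariant under relabelling samples within
  ## a population: permuting columns of one population leaves every
  ## population frequency identical
  sim <- simulateScenario(nullScenario(seed = 13, nSnps = 500))
  ds <- sim$ds
  af1 <- polarize(ds, "OUT")
  cols <- which(popmap(ds)$population == "W1")
  perm <- seq_len(nSamples(ds))
  perm[cols] <- sample(cols)
  ds2 <- ds[, perm]
  af2 <- polarize(ds2, "OUT")
  expect_equal(alleleFreqs(af1), alleleFreqs(af2))
})
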
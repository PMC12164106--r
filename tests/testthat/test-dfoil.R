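taxa <- c(P1 = "P1", P2 = "P2", P3 = "P3", P4 = "P4", O = "O")

mirrorCounts <- function(base) {
  ## counts equal to their P1<->P2 and P3<->P4 mirrors
  cts <- setNames(numeric(16), names(base))
  for (pat in names(base)) {
    b <- strsplit(pat, "")[[1]]
    m12 <- paste(b[c(2, 1, 3, 4)], collapse = "")
    m34 <- paste(b[c(1, 2, 4, 3)], collapse = "")
    v <- max(base[[pat]], base[[m12]], base[[m34]])
    cts[c(pat, m12, m34)] <- v
  }
  cts
}

test_that("perfectly symmetric counts give all four statistics equal to zero", {
  set.seed(12)
  pats <- names(countPatterns(makeAf(cbind(P1 = 1, P2 = 0, P3 = 0, P4 = 0,
                                           O = 0)), taxa,
                              mode = "binarized"))
  base <- setNames(runif(16, 1, 50), pats)
  cts <- mirrorCounts(base)
  res <- dfoilStatistics(cts)
  expect_equal(res$stats$value, rep(0, 4))
})

test_that("a fixed B A B A A site increments exactly one binarized pattern", {
  f <- cbind(P1 = 1, P2 = 0, P3 = 1, P4 = 0, O = 0)
  cts <- countPatterns(makeAf(f), taxa, mode = "binarized")
  expect_equal(unname(cts[["BABA"]]), 1)
  expect_equal(sum(cts), 1)
})

test_that("weighted counts equal binarized counts on fixed-difference tables", {
  set.seed(33)
  for (rep in 1:5) {
    f <- matrix(sample(0:1, 5 * 40, TRUE), 40, 5,
                dimnames = list(NULL, c("P1", "P2", "P3", "P4", "O")))
    af <- makeAf(f)
    w <- countPatterns(af, taxa, mode = "weighted")
    b <- countPatterns(af, taxa, mode = "binarized")
    ## weighted counting keeps outgroup-derived sites at weight 0
    expect_equal(as.numeric(w), as.numeric(b), tolerance = 1e-12)
  }
})

test_that("all-ancestral input leaves the statistics undefined and the direction undetermined", {
  f <- matrix(0, 10, 5, dimnames = list(NULL, c("P1", "P2", "P3", "P4", "O")))
  cts <- countPatterns(makeAf(f), taxa)
  res <- dfoilStatistics(cts)
  expect_true(all(is.na(res$stats$value)))
  expect_equal(res$direction, "undetermined")
})

test_that("statistics are scale invariant; their tests are not", {
  set.seed(44)
  f <- matrix(runif(5 * 200, 0, .6), 200, 5,
              dimnames = list(NULL, c("P1", "P2", "P3", "P4", "O")))
  f[, "O"] <- runif(200, 0, .1)
  cts <- countPatterns(makeAf(f), taxa)
  r1 <- dfoilStatistics(cts)
  r2 <- dfoilStatistics(cts * 7.3)
  expect_equal(r1$stats$value, r2$stats$value, tolerance = 1e-12)
})

test_that("each statistic is antisymmetric under its taxon swap", {
  set.seed(45)
  f <- matrix(runif(5 * 300, 0, .8), 300, 5,
              dimnames = list(NULL, c("P1", "P2", "P3", "P4", "O")))
  f[, "O"] <- runif(300, 0, .2)
  af <- makeAf(f)
  r <- dfoilStatistics(countPatterns(af, taxa))$stats
  swap34 <- dfoilStatistics(countPatterns(af, c(
    P1 = "P1", P2 = "P2", P3 = "P4", P4 = "P3", O = "O")))$stats
  swap12 <- dfoilStatistics(countPatterns(af, c(
    P1 = "P2", P2 = "P1", P3 = "P3", P4 = "P4", O = "O")))$stats
  v <- function(s, nm) s$value[s$statistic == nm]
  expect_equal(v(swap34, "DFO"), -v(r, "DFO"), tolerance = 1e-12)
  expect_equal(v(swap34, "DIL"), -v(r, "DIL"), tolerance = 1e-12)
  expect_equal(v(swap12, "DFI"), -v(r, "DFI"), tolerance = 1e-12)
  expect_equal(v(swap12, "DOL"), -v(r, "DOL"), tolerance = 1e-12)
})

test_that("the chi-squared test is calibrated near 5% under the null in binarized mode", {
  rej <- matrix(FALSE, 100, 4)
  for (r in 1:100) {
    sim <- simulateScenario(nullScenario(seed = 7000 + r, nSnps = 4000))
    af <- polarize(sim$ds, "OUT")
    tx <- dfoilTaxa(P1 = "D1", P2 = "MEN", P3 = "W2", P4 = "W1", O = "OUT")
    cts <- countPatterns(af, tx, mode = "binarized")
    res <- dfoilStatistics(cts)
    rej[r, ] <- !is.na(res$stats$p) & res$stats$p < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates >= 0.005 & rates <= 0.13),
              info = paste(round(rates, 3), collapse = " "))
})

test_that("a simulated donor-to-P1 pulse matches the shipped direction signature", {
  res <- lapply(1:20, function(r) {
    p <- scenarioParams(nSnps = 100000, seqLengthBp = 2e7,
                        pulse = list(donor = "W2", recipients = "D1",
                                     f = 0.2, timeGen = 500),
                        seed = 8000 + r)
    sim <- simulateScenario(p)
    af <- polarize(sim$ds, "OUT")
    tx <- dfoilTaxa(P1 = "D1", P2 = "MEN", P3 = "W2", P4 = "W1", O = "OUT")
    dfoilStatistics(countPatterns(af, tx, mode = "binarized"))
  })
  ## sign vector matches the signal-carrying entries of the shipped
  ## P3->P1 row: DFO + (P1-anchored P3 sharing), DFI + (P1 is the ingroup
  ## partner), DOL + (donated material predates the P3/P4 split)
  signOk <- vapply(res, function(x) {
    v <- setNames(x$stats$value, x$stats$statistic)
    v[["DFO"]] > 0 && v[["DFI"]] > 0 && v[["DOL"]] > 0
  }, logical(1))
  expect_gte(mean(signOk), 0.8)
  ## the classifier lands on the correct exchanging pair; the directed
  ## call within the pair is DOL-significance-limited by design
  pairOk <- vapply(res, function(x)
    x$direction %in% c("P3->P1", "P1->P3"), logical(1))
  expect_gte(mean(pairOk), 0.8)
  expect_gte(mean(vapply(res, function(x)
    x$direction == "P3->P1", logical(1))), 0.35)
})
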
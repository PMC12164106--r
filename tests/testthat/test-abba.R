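trio <- trioSpec("P1", "P2", "P3", "O")

test_that("Patterson's D reproduces the hand-evaluated cases", {
  ## p1 == p2 everywhere: numerator vanishes
  f <- cbind(P1 = c(.2, .7), P2 = c(.2, .7), P3 = c(.9, .1), O = c(0, 0))
  expect_equal(dStatistic(makeAf(f), trio), 0)

  ## single pure ABBA site
  f <- cbind(P1 = 0, P2 = 1, P3 = 1, O = 0)
  expect_equal(dStatistic(makeAf(f), trio), 1)

  ## symmetric ABBA/BABA halves cancel
  f <- cbind(P1 = c(0, .5), P2 = c(.5, 0), P3 = c(.5, .5), O = c(0, 0))
  expect_equal(dStatistic(makeAf(f), trio), 0)
})

test_that("swapping P1 and P2 flips the sign of D", {
  set.seed(14)
  for (rep in 1:10) {
    f <- cbind(P1 = runif(50), P2 = runif(50), P3 = runif(50),
               O = runif(50, 0, .3))
    af <- makeAf(f)
    swapped <- trioSpec("P2", "P1", "P3", "O")
    expect_equal(dStatistic(af, trio), -dStatistic(af, swapped),
                 tolerance = 1e-12)
  }
})

test_that("frequency-form D equals pattern-count D on haploid fixed-difference fixtures", {
  ## exhaustive over ABBA/BABA counts with assorted non-informative
  ## patterns mixed in; for 0/1 frequencies D reduces to
  ## (nABBA - nBABA)/(nABBA + nBABA)
  others <- rbind(c(0, 0, 0, 0), c(1, 1, 1, 0), c(1, 1, 0, 0),
                  c(0, 0, 1, 0), c(1, 0, 0, 0), c(0, 1, 0, 0))
  for (a in 0:4) for (b in 0:4) {
    if (a + b == 0) next
    rows <- rbind(
      matrix(rep(c(0, 1, 1, 0), a), ncol = 4, byrow = TRUE),
      matrix(rep(c(1, 0, 1, 0), b), ncol = 4, byrow = TRUE),
      others[seq_len((a + b) %% 4), , drop = FALSE])
    colnames(rows) <- c("P1", "P2", "P3", "O")
    expect_equal(dStatistic(makeAf(rows), trio), (a - b) / (a + b),
                 tolerance = 1e-12)
  }
})

test_that("jackknife flags zero-variance block structures", {
  f <- do.call(rbind, rep(list(cbind(P1 = 0, P2 = 1, P3 = 1, O = 0)), 40))
  jk <- dJackknife(makeAf(f), trio, nBlocks = 4)
  expect_true(jk$flagged)
  expect_equal(jk$se, 0)
  expect_true(is.na(jk$p))
})

test_that("f4-ratio endpoints behave algebraically", {
  ## donor samples identical => p3a == p3b == p3
  buildDs <- function(p2dos) {
    geno <- cbind(W = rep(2L, 6), W = rep(2L, 6), W = rep(2L, 6),
                  W = rep(2L, 6),
                  P1 = rep(0L, 6), P2 = p2dos,
                  O = rep(0L, 6), O = rep(0L, 6))
    makeDs(geno, c("W", "W", "W", "W", "P1", "P2", "O", "O"))
  }
  ds <- buildDs(rep(2L, 6))      # p2 == 1 == p3b
  af <- polarize(ds, "O")
  tr <- trioSpec("P1", "P2", "W", "O")
  sp <- splitDonor(ds, "W", seed = 1)
  expect_equal(f4Ratio(ds, af, tr, sp), 1)

  ds0 <- buildDs(rep(0L, 6))     # p2 == p1: numerator vanishes
  af0 <- polarize(ds0, "O")
  expect_equal(f4Ratio(ds0, af0, tr, splitDonor(ds0, "W", seed = 1)), 0)
})

test_that("fdM reproduces the single-site hand cases and the zero-donor rule", {
  ## p3 = 0 throughout: numerator vanishes
  f <- cbind(P1 = runif(50), P2 = runif(50), P3 = 0, O = 0)
  w <- fdmWindows(makeAf(f), trio, winSnps = 50, stepSnps = 50)
  expect_equal(w$value, 0)

  f1 <- cbind(P1 = 0, P2 = 1, P3 = 1, O = 0)
  expect_equal(fdmWindows(makeAf(f1), trio, 1, 1)$value, 1)

  f2 <- cbind(P1 = 1, P2 = 0, P3 = 1, O = 0)
  expect_equal(fdmWindows(makeAf(f2), trio, 1, 1)$value, -1)

  ## bounded in [-1, 1] on random tables
  set.seed(3)
  f <- cbind(P1 = runif(500), P2 = runif(500), P3 = runif(500),
             O = runif(500, 0, .2))
  w <- fdmWindows(makeAf(f), trio, 50, 25)
  expect_true(all(abs(w$value[!w$flagged]) <= 1 + 1e-12))
})

test_that("window calling obeys its gating and degeneracy rules", {
  f <- cbind(P1 = runif(2000), P2 = runif(2000), P3 = runif(2000), O = 0)
  w <- fdmWindows(makeAf(f), trio, 50, 25)
  ## negative genome-wide D: nothing called in either mode
  expect_length(callIntrogressedWindows(w, D = -0.1, mode = "quantile"), 0L)
  expect_length(callIntrogressedWindows(w, D = -0.1, mode = "ztest"), 0L)
  ## all-equal fdM: ztest calls nothing
  wEq <- w; wEq$value <- 0.2
  expect_length(suppressMessages(
    callIntrogressedWindows(wEq, D = 0.1, mode = "ztest")), 0L)
  ## quantile mode refuses < 20 windows
  expect_error(callIntrogressedWindows(w[1:10, ], D = 0.1,
                                       mode = "quantile"), "20 windows")
  ## quantile mode calls the top 5%
  called <- callIntrogressedWindows(w, D = 0.1, mode = "quantile")
  expect_gt(length(called), 0L)
})

test_that("an explicit introgressed tract is recovered by the window calls", {
  hits <- vapply(1:20, function(r) {
    p <- scenarioParams(nSnps = 20000, seqLengthBp = 2e6,
                        pulse = list(donor = "W2", recipients = "D1",
                                     f = 0.5, timeGen = 500,
                                     tracts = cbind(9e5, 1.1e6)),
                        seed = 6000 + r)
    sim <- simulateScenario(p)
    af <- polarize(sim$ds, "OUT")
    trio <- trioSpec("MEN", "D1", "W2", "OUT")
    w <- fdmWindows(af, trio, 50, 25)
    D <- dStatistic(af, trio)
    called <- callIntrogressedWindows(w, D, mode = "quantile")
    tract <- GRanges("chr1", IRanges(9e5, 1.1e6))
    length(called) > 0 &&
      sum(width(GenomicRanges::intersect(called, tract))) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a signal spanning several windows is recovered regardless of window phase", {
  set.seed(91)
  n <- 2000
  f <- cbind(P1 = runif(n, 0, .4), P2 = runif(n, 0, .4),
             P3 = runif(n, 0, .4), O = 0)
  hot <- 1001:1150
  f[hot, "P2"] <- .9; f[hot, "P3"] <- .9; f[hot, "P1"] <- .05
  af <- makeAf(f, pos = seq_len(n) * 100L)
  tract <- GRanges("chr1", IRanges(1001 * 100L, 1150 * 100L))
  for (offset in c(0L, 25L)) {
    afO <- makeAf(f[(offset + 1):n, ], pos = (offset + 1):n * 100L)
    w <- fdmWindows(afO, trio, 50, 25)
    called <- callIntrogressedWindows(w, D = 0.1, mode = "quantile")
    expect_gt(sum(width(GenomicRanges::intersect(called, tract))), 0)
  }
})
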
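fakeChain <- function(n, mu = 0, sd = 1, seed = 1, p = 4) {
  set.seed(seed)
  m <- matrix(rnorm(n * p, mu, sd), n, p)
  colnames(m) <- c("log10N0", "log10N1", "log10T", "log10theta")[seq_len(p)]
  m
}

test_that("trim-and-pool arithmetic matches the five-chain convention", {
  chains <- lapply(1:5, function(i) fakeChain(20000, seed = i))
  tp <- trimAndPool(chains, burnInFrac = 0.1, poolFrac = 0.5)
  expect_length(tp$diagnostics, 5)
  expect_equal(nrow(tp$diagnostics[[1]]), 18000)
  expect_equal(nrow(tp$pooled), 50000)   # 10,000 records/chain pooled
  # pooling preserves whole records (rows), not shuffled columns
  tail1 <- chains[[1]][10001:20000, ]
  expect_identical(tp$pooled[1:10000, ], tail1)
  # burn-in 0 leaves diagnostics input untouched
  tp0 <- trimAndPool(chains[1:2], burnInFrac = 0, poolFrac = 1)
  expect_identical(tp0$diagnostics[[1]], chains[[1]])
  expect_error(trimAndPool(list(fakeChain(0))), "empty")
})

test_that("MPSRF: near one for iid chains, inflated for separated means", {
  chains <- lapply(1:5, function(i) fakeChain(10000, seed = 10 + i, p = 3))
  m <- mpsrf(chains)
  expect_lt(abs(m - 1), 0.05)
  apart <- chains
  apart[[1]] <- apart[[1]] + 3   # 3 SD offset
  expect_gt(mpsrf(apart), 1.2)
  expect_error(mpsrf(chains[1]), "at least 2")
  # agreement with the independent implementation in coda
  mc <- coda::mcmc.list(lapply(chains, coda::mcmc))
  expect_equal(m, coda::gelman.diag(mc, autoburnin = FALSE)$mpsrf,
               tolerance = 0.03)
  # approaches one as chains lengthen
  ms <- vapply(c(100, 1000, 10000), function(n)
    mpsrf(lapply(1:4, function(i) fakeChain(n, seed = 50 + i, p = 2))),
    numeric(1))
  expect_true(all(diff(abs(ms - 1)) < 0))
})

test_that("HPD and mode: Gaussian quantiles, degenerate input, shortest width", {
  set.seed(4)
  x <- rnorm(40000)
  h <- hpdAndMode(x, 0.90)
  expect_lt(abs(h["lo"] + 1.645), 0.05)
  expect_lt(abs(h["hi"] - 1.645), 0.05)
  expect_lt(abs(h["mode"]), 0.08)
  expect_true(h["lo"] <= h["mode"] && h["mode"] <= h["hi"])
  # shortest-interval property vs the equal-tail interval
  y <- rexp(20000)
  hy <- hpdAndMode(y, 0.90)
  eq <- quantile(y, c(0.05, 0.95))
  expect_lte(hy["hi"] - hy["lo"], eq[2] - eq[1])
  expect_identical(unname(hpdAndMode(rep(2.5, 200))), rep(2.5, 3))
})

test_that("decline Bayes factor: odds arithmetic, categories, bound flags", {
  post <- c(rep(0.5, 95), rep(2, 5))     # 95% of mass below r = 1
  prior <- c(rep(0.5, 50), rep(2, 50))
  bf <- bayesFactorDecline(post, prior)
  expect_equal(bf$bf, (0.95 / 0.05) / 1)
  expect_equal(bf$category, "strong")
  expect_true(is.na(bf$bound))
  same <- bayesFactorDecline(prior, prior)
  expect_equal(same$bf, 1)
  expect_equal(same$category, "none")
  all1 <- bayesFactorDecline(rep(0.5, 100), prior)
  expect_equal(all1$bound, "lower")
  expect_gt(all1$bf, 10)
  none <- bayesFactorDecline(rep(2, 100), prior)
  expect_equal(none$bound, "upper")
  expect_equal(none$category, "false detection")
})

test_that("chain records and density curves export as TSV", {
  chains <- lapply(1:2, function(i) fakeChain(50, seed = i))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeChainRecords(chains, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 100)
  expect_equal(unique(back$chain), 1:2)
  expect_equal(back$log10N0[1:50], unname(chains[[1]][, "log10N0"]))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writePosteriorDensity(chains[[1]][, 1], f2)
  d <- read.delim(f2)
  expect_true(all(c("grid", "density") %in% names(d)))
  expect_true(all(d$density >= 0))
})

test_that("time calibration is exact arithmetic", {
  expect_equal(calibrateTime(200, 5, 95), 1095)
  expect_equal(calibrateTime(200, 5, 0), 1000)
  expect_equal(calibrateTime(c(10, 20), 5, 95), c(145, 195))
  expect_error(calibrateTime(-1), ">= 0")
})

test_that("posterior summary reports the conventional row", {
  # synthetic decline-like chains: N0 around 10^2.2, N1 around 10^3.2
  mk <- function(seed) {
    set.seed(seed)
    n <- 4000
    m <- cbind(log10N0 = rnorm(n, 2.2, 0.15), log10N1 = rnorm(n, 3.2, 0.15),
               log10T = rnorm(n, 2.5, 0.2), log10theta = rnorm(n, -0.5, 0.1))
    new("PosteriorChains", records = m, iterations = n * 10, thinning = 10,
        seed = seed, shape = "exponential", nLoci = 10,
        acceptance = c(N0 = 0.3), priors = list())
  }
  chains <- lapply(1:3, mk)
  prS <- rpriorSamples(priorSpec(), 20000, seed = 9)
  sm <- summarizePosterior(chains, prS, generationYears = 5,
                           sampleAgeYears = 95, referenceYearsBP = 157)
  expect_equal(sm$shape, "exponential")
  expect_lt(sm$rMode, 1)
  expect_gt(sm$BF, 10)
  expect_equal(sm$bfCategory, "strong")
  expect_true(sm$N0lo <= sm$N0mode && sm$N0mode <= sm$N0hi)
  # time column is calibrated to years (10^2.5 * 5 + 95 ~ 1676)
  expect_gt(sm$TyearsMode, 1000)
  expect_lt(sm$TyearsMode, 3000)
  expect_true(sm$massBeforeReference > 0.95)
  expect_lt(abs(sm$mpsrf - 1), 0.1)
})
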
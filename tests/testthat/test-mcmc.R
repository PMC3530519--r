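test_that("stepwise branch transition kernel matches a convolution oracle", {
  expect_equal(branchTransitionLogProb(0, 0), 0)
  expect_identical(branchTransitionLogProb(3, 0), -Inf)
  # brute force: condition on the Poisson mutation count, convolve the
  # +/-1 walk (displacement d after j steps ~ 2*Binom(j, 1/2) - j)
  m <- 1
  oracle <- vapply(-6:6, function(d) {
    tot <- 0
    for (j in 0:60) {
      if (abs(d) > j || (j - d) %% 2 != 0) next
      tot <- tot + dpois(j, m) * choose(j, (j + d) / 2) / 2^j
    }
    tot
  }, numeric(1))
  got <- exp(branchTransitionLogProb(-6:6, m))
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_gt(sum(got), 0.999)
  # large-m stability and far-tail fallback stay finite and ordered
  expect_true(is.finite(branchTransitionLogProb(5, 500)))
  lp <- branchTransitionLogProb(c(0, 40), 0.5)
  expect_true(lp[2] < lp[1] && is.finite(lp[2]))
})

test_that("genealogy likelihood: two-leaf closed form and invariances", {
  N <- 400
  traj <- constantTrajectory(N)
  mu <- 1e-3
  tt <- 350
  parent <- c(2L, 2L, -1L)
  times <- c(0, 0, tt)
  states <- c(5L, 9L, 7L)
  ll <- genealogyLogLik(parent, times, states, 2, traj, mu)
  coalHand <- log(1 / (2 * N)) - tt / (2 * N)
  mutHand <- sum(branchTransitionLogProb(c(5L - 7L, 9L - 7L), mu * tt))
  expect_equal(ll$coal, coalHand, tolerance = 1e-12)
  expect_equal(ll$mut, mutHand, tolerance = 1e-12)
  # translation invariance in allele size
  ll2 <- genealogyLogLik(parent, times, states + 100L, 2, traj, mu)
  expect_equal(ll2$mut, ll$mut)
  expect_equal(ll2$coal, ll$coal)
  # zero mutation rate with mismatching states is impossible
  ll3 <- genealogyLogLik(parent, times, states, 2, traj, 0)
  expect_identical(ll3$mut, -Inf)
  # scale-shift identity used by the ridge move: times and N scaled by u,
  # mu scaled by 1/u => mut invariant, coal changes by -(nLeaf-1) log u
  u <- 10^0.3
  trajU <- constantTrajectory(N * u)
  llU <- genealogyLogLik(parent, times * u, states, 2, trajU, mu / u)
  expect_equal(llU$mut, ll$mut, tolerance = 1e-10)
  expect_equal(llU$coal, ll$coal - log(u), tolerance = 1e-10)
})

test_that("prior sampling respects the hierarchy and truncation", {
  pr <- priorSpec()
  s <- rpriorSamples(pr, 20000, seed = 2)
  expect_equal(colnames(s), c("log10N0", "log10N1", "log10T", "log10theta"))
  expect_equal(mean(s[, "log10N0"]), pr$N0$meanMean, tolerance = 0.05)
  # marginal sd^2 ~ meanSD^2 + E[s^2] for the truncated-normal sd
  expect_gt(sd(s[, "log10N0"]), pr$N0$meanSD)
  expect_error(priorSpec(N0 = list(meanMean = 3, meanSD = 0, sdMean = 1,
                                   sdSD = 0)), "positive")
})

test_that("with no polymorphic loci the chain samples its prior", {
  pr <- priorSpec()
  ch <- runChain(NULL, pr, "exponential", iterations = 16000, thinning = 10,
                 seed = 3)
  expect_s4_class(ch, "PosteriorChains")
  expect_equal(ch@nLoci, 0)
  rec <- chainRecords(ch)[401:1600, ]
  ps <- rpriorSamples(pr, 40000, seed = 11)
  for (p in colnames(rec)) {
    ks <- suppressWarnings(stats::ks.test(rec[, p], ps[, p]))$statistic
    expect_lt(ks, 0.1)
  }
})

test_that("chains are reproducible and replicates differ by seed", {
  gd <- simulateDataset(8, 4, equilibriumTrajectory(1), smmModel(), seed = 5)
  a <- runChain(gd, priorSpec(), "linear", iterations = 600, thinning = 10,
                seed = 7)
  b <- runChain(gd, priorSpec(), "linear", iterations = 600, thinning = 10,
                seed = 7)
  expect_identical(chainRecords(a), chainRecords(b))
  expect_equal(nrow(chainRecords(a)), 60)
  ch <- runReplicated(gd, shape = "linear", nChains = 2, iterations = 400,
                      thinning = 10, seed = 1)
  expect_length(ch, 2)
  expect_false(identical(chainRecords(ch[[1]]), chainRecords(ch[[2]])))
  expect_error(runChain(gd, iterations = 5, thinning = 10),
               "iterations < thinning")
})

test_that("a simulated decline pulls the posterior of r = N0/N1 below one", {
  gd <- simulateDataset(40, 10, demographicTrajectory(150, 2000, 300,
                                                      "exponential"),
                        smmModel(mu = 5e-4), seed = 42)
  ch <- runChain(gd, priorSpec(), "exponential", iterations = 8000,
                 thinning = 10, seed = 5)
  rec <- chainRecords(ch)
  rec <- rec[(nrow(rec) / 2 + 1):nrow(rec), ]
  rv <- 10^(rec[, "log10N0"] - rec[, "log10N1"])
  expect_gt(mean(rv < 1), 0.9)
})
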
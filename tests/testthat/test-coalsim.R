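test_that("trajectory size and intensity have their closed forms", {
  cst <- constantTrajectory(500)
  expect_equal(coalescentIntensity(cst, 100), 100 / 500)
  # exponential with N1 = N0 degenerates to the constant case
  ex <- demographicTrajectory(500, 500, 200, "exponential")
  expect_equal(coalescentIntensity(ex, 350), 350 / 500, tolerance = 1e-10)
  # linear against numerical quadrature
  lin <- demographicTrajectory(100, 1000, 500, "linear")
  for (t in c(50, 250, 500, 900)) {
    quad <- stats::integrate(function(u) 1 / populationSize(lin, u), 0, t,
                             rel.tol = 1e-10)$value
    expect_equal(coalescentIntensity(lin, t), quad, tolerance = 1e-8)
  }
  expo <- demographicTrajectory(150, 1800, 300, "exponential")
  quad <- stats::integrate(function(u) sapply(u, function(x)
    1 / populationSize(expo, x)), 0, 450, rel.tol = 1e-10)$value
  expect_equal(coalescentIntensity(expo, 450), quad, tolerance = 1e-8)
  # strictly increasing
  ts <- seq(0, 800, by = 25)
  expect_true(all(diff(coalescentIntensity(expo, ts)) > 0))
})

test_that("zero mutation rate gives monomorphic samples", {
  g <- simulateLocus(20, constantTrajectory(1000),
                     smmModel(mu = 0), seed = 1)
  expect_true(all(g == 0))
})

test_that("strict-SMM equilibrium matches Ohta-Kimura He and pairwise variance", {
  set.seed(10)
  for (theta in c(2, 10)) {
    mu <- 5e-4
    N <- theta / (4 * mu)
    m <- msatdemog:::sim_locus_stats_cpp(50, N, N, 0, 0, mu, 1, 1, 1L, 2000)
    heExp <- 1 - 1 / sqrt(1 + 2 * theta)
    expect_lt(abs(mean(m[, "he"]) - heExp), 3 * sd(m[, "he"]) / sqrt(2000))
    expect_lt(abs(mean(m[, "msd"]) - theta), 3 * sd(m[, "msd"]) / sqrt(2000))
  }
})

test_that("allele count increases stochastically with theta", {
  set.seed(11)
  ks <- vapply(c(1, 5, 20), function(theta) {
    N <- theta / (4 * 5e-4)
    mean(msatdemog:::sim_locus_stats_cpp(40, N, N, 0, 0, 5e-4, 1, 1, 1L,
                                         400)[, "k"])
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("datasets are reproducible and loci independently seeded", {
  traj <- equilibriumTrajectory(1)
  a <- simulateDataset(5, 10, traj, smmModel(), seed = 9)
  b <- simulateDataset(5, 10, traj, smmModel(), seed = 9)
  expect_identical(a@allele1, b@allele1)
  expect_equal(dim(a@allele1), c(5, 10))
  # He at theta = 1 lands in the study-like range on average
  hes <- vapply(1:20, function(r)
    mean(heByLocus(simulateDataset(30, 10, traj, smmModel(), seed = r)),
         na.rm = TRUE), numeric(1))
  expect_gt(mean(hes), 0.3)
  expect_lt(mean(hes), 0.65)
})

test_that("bottleneck trajectories depress M relative to constant size", {
  set.seed(12)
  mConst <- mean(vapply(1:40, function(r) {
    gd <- simulateDataset(25, 10, equilibriumTrajectory(10),
                          mutationModel(0.9, multistepMean = 3.5,
                                        multistepMin = 2), seed = 100 + r)
    mRatio(gd)$meanM
  }, numeric(1)))
  mBot <- mean(vapply(1:40, function(r) {
    gd <- simulateDataset(25, 10,
                          demographicTrajectory(50, 5000, 100, "step"),
                          mutationModel(0.9, multistepMean = 3.5,
                                        multistepMin = 2), seed = 200 + r)
    mRatio(gd)$meanM
  }, numeric(1)))
  expect_lt(mBot, mConst - 0.05)
})

test_that("island model: migration limit, single deme, refusal to hang", {
  # high migration behaves like a panmictic population
  sp <- subdivisionSpec(c(100, 100), migration = 0.45)
  gd <- simulateSubdivided(sp, constantTrajectory(200), smmModel(),
                           nPerDeme = 15, seed = 31)
  expect_setequal(unique(demes(gd)), c("deme1", "deme2"))
  expect_lt(abs(fstWC(gd, by = "deme")$global), 0.06)
  # one deme runs and carries its label
  one <- simulateSubdivided(subdivisionSpec(150, 0), constantTrajectory(150),
                            smmModel(), nPerDeme = 10, seed = 5)
  expect_equal(nInd(one), 10)
  # non-coalescing configuration is rejected up front
  expect_error(simulateSubdivided(subdivisionSpec(c(50, 50), 0),
                                  constantTrajectory(100), smmModel(), 5),
               "non-coalescing")
})

test_that("moderate-migration calibration lands in the stated F_ST band", {
  set.seed(13)
  fs <- vapply(1:10, function(r) {
    sp <- subdivisionSpec(c(50, 50, 50), migration = 0.03, mergeTime = 150)
    gd <- simulateSubdivided(sp, constantTrajectory(150), smmModel(),
                             nPerDeme = 20, seed = 400 + r)
    fstWC(gd, by = "deme")$global
  }, numeric(1))
  expect_gt(mean(fs), 0.04)
  expect_lt(mean(fs), 0.14)
})

test_that("temporal sampling: drift grows with the gap at the coalescent rate", {
  traj <- constantTrajectory(150)
  # gap 0 is two iid samples
  f0 <- mean(vapply(1:15, function(r) {
    tp <- simulateTemporalPair(traj, smmModel(), 0, 25, 25, seed = 600 + r)
    fstWC(bindDatasets(tp))$global
  }, numeric(1)))
  expect_lt(abs(f0), 0.02)
  gaps <- c(0, 20, 100)
  fbar <- vapply(gaps, function(g) {
    mean(vapply(1:15, function(r) {
      tp <- simulateTemporalPair(traj, smmModel(), g, 25, 25, seed = 700 + r)
      fstWC(bindDatasets(tp))$global
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(fbar) > 0))
  # gap 19 at Ne = 150: serial-coalescent expectation gap / (gap + 4 Ne)
  fs <- vapply(1:25, function(r) {
    tp <- simulateTemporalPair(traj, smmModel(), 19, 30, 30, seed = 800 + r)
    fstWC(bindDatasets(tp))$global
  }, numeric(1))
  expected <- 19 / (19 + 4 * 150)
  expect_lt(abs(mean(fs) - expected), 3 * sd(fs) / sqrt(25) + 0.01)
})

test_that("the synthetic study bundle reproduces the sampling design", {
  b <- fisherScenario(seed = 2)
  expect_equal(vapply(b, nInd, integer(1)),
               c(NW_H = 5L, NW_C = 148L, SSN_H = 16L, SSN_C = 127L))
  expect_setequal(unique(demes(b$SSN_C)), c("North", "Central", "South"))
  expect_true(all(sampleYears(b$NW_H) < sampleYears(b$NW_C)[1]))
  b2 <- fisherScenario(seed = 2)
  expect_identical(b2$SSN_C@allele1, b$SSN_C@allele1)
  # deme differentiation within the moderate band, populations diverged
  expect_gt(fstWC(bindDatasets(b))$global, 0.1)
  # bundle export is readable Genepop + sidecar
  dir <- withr::local_tempdir()
  writeScenario(b, dir)
  back <- readGenepop(file.path(dir, "SSN_C.gen"))
  back <- attachMetadata(back,
                         readSampleMetadata(file.path(dir, "SSN_C.meta.tsv")))
  expect_identical(back@allele1, b$SSN_C@allele1)
  expect_identical(demes(back), demes(b$SSN_C))
})
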
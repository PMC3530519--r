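test_that("M-ratio: saturated range, gapped range, monomorphic handling", {
  # sizes {50, 51, 52}: k = 3 over 3 states -> M = 1
  gd <- gdFrom(c(50L, 51L, 52L), c(50L, 51L, 52L), "p")
  expect_equal(mRatio(gd)$meanM, 1)
  # sizes {50, 54}: k = 2 over 5 states -> M = 0.4
  gd2 <- gdFrom(c(50L, 54L), c(50L, 54L), "p")
  expect_equal(mRatio(gd2)$meanM, 0.4)
  # a monomorphic locus is excluded from the mean
  a1 <- cbind(c(50L, 54L), c(7L, 7L))
  gd3 <- GenotypeDataset(a1, a1, population = "p")
  expect_equal(mRatio(gd3)$meanM, 0.4)
  mono <- GenotypeDataset(matrix(7L, 3), matrix(7L, 3), population = "p")
  expect_error(mRatio(mono), "monomorphic")
})

test_that("mode-shift test: L-shape vs shifted fixtures and the n >= 30 rule", {
  # 10 loci, each with a common allele pair and one rare allele:
  # rare class dominates -> not shifted
  mkLoci <- function(rareEach) {
    a1 <- matrix(10L, 30, 10)
    a2 <- matrix(11L, 30, 10)
    if (!rareEach) {
      # move mass into the intermediate class: three alleles at ~1/3 each
      a2[1:10, ] <- 10L
      a1[11:20, ] <- 12L
      a2[11:20, ] <- 12L
    } else {
      a2[1, ] <- 15L  # one singleton per locus
    }
    GenotypeDataset(a1, a2, population = "p")
  }
  l <- modeShiftTest(mkLoci(TRUE))
  expect_false(l$shifted)
  s <- modeShiftTest(mkLoci(FALSE))
  expect_true(s$shifted)
  expect_length(s$classCounts, 10)
  expect_equal(sum(s$classCounts), 30)  # 3 alleles x 10 loci
  small <- eqDataset(16, seed = 2)
  expect_error(modeShiftTest(small), "30")
})

test_that("mode-shift power declines with bottleneck size (severity ordering)", {
  p10 <- as.numeric(modeShiftPower(60, nBreeders = 10, seed = 21))
  p20 <- as.numeric(modeShiftPower(60, nBreeders = 20, seed = 21))
  expect_gt(p10, p20)
  expect_gt(p10, 0.6)
  # equilibrium populations are almost never flagged
  eqFlag <- vapply(1:40, function(r) {
    gd <- simulateDataset(30, 10, equilibriumTrajectory(10),
                          tpmVariance12(0.05), seed = 900 + r)
    modeShiftTest(gd)$shifted
  }, logical(1))
  expect_lt(mean(eqFlag), 0.1)
})

test_that("M-critical: decreasing in theta, warning on few replicates", {
  c1 <- mCritical(20, 10, 1, reps = 2000, seed = 5)
  c10 <- mCritical(20, 10, 10, reps = 2000, seed = 5)
  expect_gt(c1, c10)
  expect_true(as.numeric(c1) > 0 && as.numeric(c1) <= 1)
  expect_warning(mCritical(10, 10, 1, reps = 500, seed = 1), "unstable")
})

test_that("M-critical quantile is stable under doubling of replicates", {
  a <- mCritical(20, 10, 5, reps = 5000, seed = 8)
  b <- mCritical(20, 10, 5, reps = 10000, seed = 9)
  expect_lt(abs(as.numeric(a) - as.numeric(b)), 0.015)
})

test_that("heterozygosity excess: exclusions, monotone power, report fields", {
  gd <- eqDataset(25, theta = 2, seed = 3)
  gd@allele1[, 1] <- 5L
  gd@allele2[, 1] <- 5L   # force one monomorphic locus
  expect_message(hx <- hetExcessTest(gd, tpmVariance12(0.05), reps = 300,
                                     seed = 1), "monomorphic")
  expect_equal(hx$nLoci, 9)
  expect_true(all(c("heObs", "heEqMean", "heEqSD", "stdDiff") %in%
                    names(hx$perLocus)))
  expect_true(hx$p.value >= 0 && hx$p.value <= 1)
  mono <- GenotypeDataset(matrix(7L, 6, 2), matrix(7L, 6, 2),
                          population = "p")
  expect_error(hetExcessTest(mono, tpmVariance12(0.05)), "no polymorphic")
  # recent severe collapse rejects more often than equilibrium
  pBot <- vapply(1:8, function(r) {
    g <- simulateDataset(25, 10, demographicTrajectory(50, 5000, 25, "step"),
                         tpmVariance12(0.05), seed = 4000 + r)
    suppressWarnings(suppressMessages(
      hetExcessTest(g, tpmVariance12(0.05), reps = 300, seed = r)))$p.value
  }, numeric(1))
  pEq <- vapply(1:8, function(r) {
    g <- simulateDataset(25, 10, equilibriumTrajectory(10),
                         tpmVariance12(0.05), seed = 5000 + r)
    suppressWarnings(suppressMessages(
      hetExcessTest(g, tpmVariance12(0.05), reps = 300, seed = r)))$p.value
  }, numeric(1))
  expect_lt(mean(pBot), mean(pEq))
})

test_that("the battery assembles the conventional report, pooled and per deme", {
  b <- fisherScenario(seed = 4)
  rep1 <- suppressWarnings(suppressMessages(
    bottleneckBattery(b$SSN_C, byDeme = TRUE, tpm = c(0.05, 0.20),
                      thetaGrid = c(1, 10), hetReps = 250, mReps = 800,
                      seed = 7)))
  expect_setequal(rep1$unit, c("pooled", "North", "Central", "South"))
  expect_true(all(c("hetExcessP_tpm05", "hetExcessP_tpm20",
                    "modeShift", "meanM",
                    "mCritical_theta1", "mCritical_theta10",
                    "mSignif_theta1") %in% names(rep1)))
  # the historical group is too small for the mode-shift test
  rep2 <- suppressWarnings(suppressMessages(
    bottleneckBattery(b$SSN_H, tpm = 0.05, thetaGrid = 1, hetReps = 250,
                      mReps = 800, seed = 7)))
  expect_true(is.na(rep2$modeShift))
  # single deme equals the direct calls
  north <- subsetGroup(b$SSN_C, deme = "North")
  expect_equal(rep1$meanM[rep1$unit == "North"], mRatio(north)$meanM)
  # pooled vs per-deme excess p-values genuinely differ (Wahlund interference)
  expect_false(isTRUE(all.equal(rep1$hetExcessP_tpm05[rep1$unit == "pooled"],
                                rep1$hetExcessP_tpm05[rep1$unit == "North"])))
})
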
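test_that("unbiased He matches its closed form", {
  expect_equal(unbiasedHe(c(A = 12)), 0)                       # monomorphic
  expect_equal(unbiasedHe(stats::setNames(rep(1, 8), 1:8)), 1) # all distinct
  expect_equal(unbiasedHe(c(A = 10, B = 10)), (20 / 19) * 0.5)
  expect_error(unbiasedHe(integer(0)), "zero gene copies")
})

test_that("F_IS: full heterozygosity gives -1; pooling demes gives a deficit", {
  gd <- gdFrom(rep(1L, 6), rep(2L, 6), "p")
  expect_equal(as.numeric(fisWC(gd)), -1)
  # Wahlund effect: two iid demes pooled under one label
  d1 <- simulateDataset(30, 10, equilibriumTrajectory(2), smmModel(),
                        seed = 5, population = "x")
  d2 <- simulateDataset(30, 10, equilibriumTrajectory(2), smmModel(),
                        seed = 99, population = "x")
  fPool <- as.numeric(fisWC(bindDatasets(d1, d2)))
  expect_gt(fPool, 0.05)
  # a single random-mating sample is near zero
  expect_lt(abs(as.numeric(fisWC(eqDataset(80, seed = 7)))), 0.06)
  expect_error(fisWC(gdFrom(c(1L, 1L), c(1L, 1L), "p")), "monomorphic")
})

test_that("HWE exact test agrees with an independent pairing oracle", {
  # AA = 5, BB = 5: allele counts 10/10; the conditional law of the
  # heterozygote count h under random pairing is computable directly
  g <- cbind(c(rep(1L, 5), rep(2L, 5)), c(rep(1L, 5), rep(2L, 5)))
  ph <- vapply(seq(0, 10, 2), function(h) {
    nAA <- (10 - h) / 2
    exp(lfactorial(10) + h * log(2) + 2 * lfactorial(10) -
          2 * lfactorial(nAA) - lfactorial(h) - lfactorial(20))
  }, numeric(1))
  pOracle <- sum(ph[ph <= ph[1] + 1e-12])   # observed table is h = 0
  en <- hweExact(g, method = "enumeration")
  expect_equal(en$p.value, pOracle, tolerance = 1e-10)
  mc <- hweExact(g, method = "monte_carlo", reps = 20000)
  se <- sqrt(pOracle * (1 - pOracle) / 20000)
  expect_lt(abs(mc$p.value - pOracle), 3 * se + 2 / 20000)
  # degenerate inputs are untestable with p = 1
  expect_equal(hweExact(cbind(1L, 2L))$p.value, 1)
  expect_false(hweExact(cbind(1L, 2L))$testable)
  expect_false(hweExact(cbind(c(1L, 1L), c(1L, 1L)))$testable)
})

test_that("contingency exact test matches Fisher's exact and its own MC", {
  tab <- matrix(c(8, 2, 1, 9), 2)
  en <- contingencyExact(tab, method = "enumeration")
  expect_equal(en$p.value, fisher.test(tab)$p.value, tolerance = 1e-9)
  mc <- contingencyExact(tab, method = "monte_carlo", reps = 20000)
  se <- sqrt(en$p.value * (1 - en$p.value) / 20000)
  expect_lt(abs(mc$p.value - en$p.value), 3 * se + 2 / 20000)
  # a larger table: MC against enumeration
  tab2 <- matrix(c(4, 1, 0, 2, 3, 2), 2, 3)
  en2 <- contingencyExact(tab2, method = "enumeration")
  mc2 <- contingencyExact(tab2, method = "monte_carlo", reps = 20000)
  expect_lt(abs(mc2$p.value - en2$p.value),
            3 * sqrt(en2$p.value * (1 - en2$p.value) / 20000) + 2 / 20000)
})

test_that("gametic disequilibrium test: perfect association vs independence", {
  set.seed(3)
  gd <- eqDataset(40, theta = 2, seed = 11)
  # second locus an exact copy of the first -> association
  gd@allele1[, 2] <- gd@allele1[, 1]
  gd@allele2[, 2] <- gd@allele2[, 1]
  expect_lt(ldExact(gd, 1, 2, reps = 3000)$p.value, 0.01)
  # independently simulated loci: p should rarely be extreme
  ps <- vapply(1:30, function(r) {
    g <- eqDataset(30, theta = 2, seed = 300 + r)
    ldExact(g, 1, 2, reps = 1000)$p.value
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
})

test_that("genic differentiation: fixed difference vs identical groups", {
  gd <- gdFrom(matrix(rep(c(10L, 20L), each = 8), 16),
               matrix(rep(c(10L, 20L), each = 8), 16),
               rep(c("a", "b"), each = 8))
  res <- genicDiffExact(gd, c("a", "b"), reps = 2000)
  expect_lt(res$combined, 1e-4)
  # same allele pools -> unremarkable p
  gd2 <- eqDataset(40, seed = 21)
  gd2@population <- rep(c("a", "b"), 20)
  expect_gt(genicDiffExact(gd2, c("a", "b"), reps = 1000)$combined, 0.01)
})

test_that("Weir-Cockerham theta matches a hand-built component oracle", {
  # pop1: AA, AA, AB; pop2: AB, BB, BB (biallelic, two pops)
  gd <- gdFrom(c(1L, 1L, 1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L, 2L, 2L),
               rep(c("a", "b"), each = 3))
  # direct transliteration of the variance-component formulas for allele A
  n1 <- 3; n2 <- 3; r <- 2
  p1 <- 5 / 6; p2 <- 1 / 6; h1 <- 1 / 3; h2 <- 1 / 3
  nbar <- 3; nc <- (6 - (9 + 9) / 6) / 1
  pbar <- (n1 * p1 + n2 * p2) / 6
  hbar <- (n1 * h1 + n2 * h2) / 6
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_equal(fstWC(gd)$global, a / (a + b + cc), tolerance = 1e-12)
  # boundary behaviour
  fixed <- gdFrom(rep(c(10L, 20L), each = 3), rep(c(10L, 20L), each = 3),
                  rep(c("a", "b"), each = 3))
  expect_equal(fstWC(fixed)$global, 1)
  iid <- eqDataset(60, seed = 4)
  iid@population <- rep(c("a", "b"), 30)
  expect_lt(abs(fstWC(iid)$global), 0.05)
})

test_that("R_ST: allele-size variance analog with the expected boundaries", {
  fixed <- gdFrom(rep(c(10L, 20L), each = 3), rep(c(10L, 20L), each = 3),
                  rep(c("a", "b"), each = 3))
  expect_equal(rst(fixed)$global, 1, tolerance = 1e-9)
  same <- gdFrom(rep(c(10L, 14L), 6), rep(c(14L, 10L), 6),
                 rep(c("a", "b"), 6))
  expect_lt(abs(rst(same)$global), 0.1)
  # large-step divergence: size variance sees what identity does not
  gd <- gdFrom(c(10L, 11L, 10L, 30L, 31L, 30L), c(11L, 11L, 10L, 31L, 31L, 30L),
               rep(c("a", "b"), each = 3))
  expect_gt(rst(gd)$global, fstWC(gd)$global)
})

test_that("allelic richness rarefaction matches exhaustive subsampling", {
  expect_equal(allelicRichness(c(A = 3, B = 1), 4), 2)   # g = N
  expect_equal(allelicRichness(c(A = 9), 4), 1)          # monomorphic
  # {A:6, B:2}, g = 4: enumerate all C(8,4) subsamples
  pool <- rep(1:2, c(6, 2))
  subs <- utils::combn(8, 4)
  kbar <- mean(apply(subs, 2, function(i) length(unique(pool[i]))))
  expect_equal(allelicRichness(c(A = 6, B = 2), 4), kbar, tolerance = 1e-12)
  expect_error(allelicRichness(c(A = 2), 4), "exceeds")
})

test_that("paired diversity test: arcsine paired t with textbook arithmetic", {
  he <- c(0.2, 0.5, 0.7, 0.4, 0.6)
  same <- pairedDiversityTest(he, he)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  he2 <- c(0.25, 0.55, 0.75, 0.45, 0.65)
  res <- pairedDiversityTest(he, he2)
  d <- asin(sqrt(he)) - asin(sqrt(he2))
  tHand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, tHand, tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(tHand), 4), tolerance = 1e-12)
  # transform domain edges
  expect_silent(pairedDiversityTest(c(0, 1, 0.5), c(1, 0, 0.5)))
  expect_error(pairedDiversityTest(0.5, 0.6), "2 shared loci")
})

test_that("sequential Bonferroni implements the step-down rule", {
  p <- c(0.001, 0.02, 0.03, 0.5)
  expect_identical(sequentialBonferroni(p, 0.05),
                   c(TRUE, FALSE, FALSE, FALSE))  # 0.02 >= 0.05/3
  expect_identical(sequentialBonferroni(0.04, 0.05), TRUE)
  expect_identical(sequentialBonferroni(rep(1, 5), 0.05), rep(FALSE, 5))
  # agrees with Holm adjustment on continuous p-values
  set.seed(8)
  for (i in 1:20) {
    pv <- runif(7)^2
    expect_identical(sequentialBonferroni(pv, 0.05),
                     p.adjust(pv, "holm") < 0.05)
  }
})

test_that("diversity and differentiation tables have coherent structure", {
  b <- fisherScenario(seed = 3)
  all <- bindDatasets(b)
  dt <- diversityTable(all)
  expect_setequal(dt$group, c("NW_H", "NW_C", "SSN_H", "SSN_C"))
  expect_true(all(dt$He >= 0 & dt$He <= 1))
  expect_true(all(dt$Ar <= dt$A + 1e-9))
  expect_true(all(dt$Ar >= 1))
  dm <- differentiationMatrix(all, reps = 400)
  expect_equal(rownames(dm), colnames(dm))
  expect_true(all(is.na(diag(dm))))
  # lower triangle Fst matches fstWC pairwise
  fw <- fstWC(all, pairwise = TRUE)$pairwise
  expect_equal(dm["SSN_C", "NW_C"], fw["NW_C", "SSN_C"], tolerance = 1e-12)
  gp <- attr(dm, "genicP")
  expect_true(all(gp[upper.tri(gp)] >= 0 & gp[upper.tri(gp)] <= 1))
})
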
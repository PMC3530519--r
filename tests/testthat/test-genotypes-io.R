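test_that("Genepop parsing: POP blocks, missing calls, digit inference", {
  f <- genepopFixture(withr::local_tempfile(fileext = ".gen"))
  gd <- readGenepop(f)
  expect_equal(nInd(gd), 5)
  expect_equal(nLoc(gd), 3)
  expect_equal(sort(unique(populations(gd))), c("pop1", "pop2"))
  # the 000000 genotype is one fully missing call
  expect_equal(sum(is.na(gd@allele1)), 1)
  expect_true(is.na(alleles(gd, "locB")["ind2", 1]))
  # codes become repeat-unit sizes with the default unit map
  expect_equal(unname(alleles(gd, "locA")["ind2", ]), c(100L, 104L))
})

test_that("write/read round trip is lossless and file-level canonical", {
  f <- genepopFixture(withr::local_tempfile(fileext = ".gen"))
  gd <- readGenepop(f)
  out <- withr::local_tempfile(fileext = ".gen")
  writeGenepop(gd, out)
  gd2 <- readGenepop(out)
  expect_identical(gd2@allele1, gd@allele1)
  expect_identical(gd2@allele2, gd@allele2)
  expect_identical(populations(gd2), populations(gd))
  expect_identical(is.na(gd2@allele1), is.na(gd@allele1))
  # writing the re-read dataset reproduces the same file
  out2 <- withr::local_tempfile(fileext = ".gen")
  writeGenepop(gd2, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("affine coding: sizes in repeat units encode via motif and offset", {
  loci <- defaultLoci("locM", motif_length = 2L, coding = 3L, offset = 0L)
  gd <- GenotypeDataset(matrix(50L), matrix(52L), population = "p",
                        loci = loci)
  out <- withr::local_tempfile(fileext = ".gen")
  writeGenepop(gd, out)
  # size 50 units * motif 2 = code 100; 52 -> 104
  expect_true(any(grepl("100104", readLines(out), fixed = TRUE)))
  back <- readGenepop(out, locusDefs = loci)
  expect_identical(unname(back@allele1[1, 1]), 50L)
  expect_identical(unname(back@allele2[1, 1]), 52L)
})

test_that("malformed inputs are rejected with informative errors", {
  bad <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "POP", "i1 , 10045 "), bad)  # odd-width code
  expect_error(readGenepop(bad), "4- or 6-digit")
  mixed <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "POP", "i1 , 100100", "i2 , 1010"), mixed)
  expect_error(readGenepop(mixed), "mixes 2- and 3-digit")
  noPop <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "i1 , 100100"), noPop)
  expect_error(readGenepop(noPop), "POP")
  # unencodable allele size
  gd <- GenotypeDataset(matrix(5000L), matrix(5000L), population = "p")
  expect_error(writeGenepop(gd, withr::local_tempfile()), "unencodable")
  # empty dataset
  expect_error(writeGenepop(gd[0, ], withr::local_tempfile()),
               "no individuals")
})

test_that("half-missing calls are demoted to fully missing", {
  gd <- GenotypeDataset(matrix(c(10L, NA)), matrix(c(NA, 12L)),
                        population = "p")
  expect_true(all(is.na(gd@allele1)))
  expect_true(all(is.na(gd@allele2)))
})

test_that("filterIndividuals honours the typed-loci threshold", {
  a <- matrix(10L, 3, 10)
  a[1, 1:4] <- NA  # individual 1 typed at 6 of 10 loci
  gd <- GenotypeDataset(a, a, population = "p")
  expect_message(kept <- filterIndividuals(gd, 7), "removing 1")
  expect_equal(nInd(kept), 2)
  expect_false(indNames(gd)[1] %in% indNames(kept))
  # boundary behaviour
  expect_equal(nInd(filterIndividuals(gd, 0)), 3)
  expect_equal(nInd(filterIndividuals(kept, 10)), 2)
  # idempotent and monotone in the threshold
  expect_identical(indNames(filterIndividuals(kept, 7)), indNames(kept))
  ns <- vapply(0:10, function(m)
    nInd(suppressMessages(filterIndividuals(gd, m))), integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("alleleCounts tallies gene copies and respects group selectors", {
  a1 <- matrix(100L, 5, 1)
  gd <- GenotypeDataset(a1, a1, population = "p")
  expect_equal(alleleCounts(gd)[[1]], c("100" = 5L + 5L))
  # mixed missing/typed fixture, tallied by hand
  a1 <- matrix(c(10L, 10L, NA, 12L), 4, 1)
  a2 <- matrix(c(12L, 10L, NA, 12L), 4, 1)
  gd <- GenotypeDataset(a1, a2, population = c("x", "x", "x", "y"))
  cx <- alleleCounts(gd, population = "x")[[1]]
  expect_equal(cx, c("10" = 3L, "12" = 1L))
  expect_equal(sum(cx), 2 * 2)  # two typed individuals
  # invariant under reordering of individuals
  perm <- c(3, 1, 4, 2)
  expect_equal(alleleCounts(gd[perm, ], population = "x")[[1]], cx)
  expect_error(alleleCounts(gd, population = "zz"), "unknown population")
})

test_that("metadata sidecar round trips and attaches by individual ID", {
  gd <- eqDataset(6, seed = 1)
  demes(gd) <- c("N", "N", "C", "C", "S", "S")
  sampleYears(gd) <- 1912L
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeSampleMetadata(gd, tsv)
  meta <- readSampleMetadata(tsv)
  gd2 <- eqDataset(6, seed = 1)
  gd2 <- attachMetadata(gd2, meta[rev(seq_len(nrow(meta))), ])
  expect_identical(demes(gd2), demes(gd))
  expect_identical(sampleYears(gd2), sampleYears(gd))
})
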
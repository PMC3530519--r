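# shared fixtures: tiny hand-built datasets and a Genepop text writer

# diploid dataset from explicit allele columns (one locus per pair)
gdFrom <- function(a1, a2, population, ...) {
  GenotypeDataset(as.matrix(a1), as.matrix(a2), population = population, ...)
}

# two populations, three loci, one missing call; 3-digit coding
genepopFixture <- function(path) {
  writeLines(c(
    "toy export",
    "locA", "locB", "locC",
    "POP",
    "ind1 , 100100 120124 050052",
    "ind2 , 100104 000000 050050",
    "POP",
    "ind3 , 104104 120120 052052",
    "ind4 , 100100 124124 050052",
    "ind5 , 104100 120124 052050"
  ), path)
  path
}

# equilibrium dataset shared by several stochastic tests
eqDataset <- function(nInd = 30, theta = 2, seed = 42) {
  simulateDataset(nInd, 10, equilibriumTrajectory(theta), smmModel(),
                  seed = seed)
}
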
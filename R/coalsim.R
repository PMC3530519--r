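## Coalescent simulation of microsatellite genotypes: the synthetic-data
## stage used for equilibrium null distributions, M-ratio critical values,
## power experiments and MCMC validation.

shapeCode <- function(shape) {
  match(shape, c("constant", "exponential", "linear", "step")) - 1L
}

## derive a reproducible sub-seed (kept < 2^31) so that locus i of a
## dataset can be re-simulated in isolation
deriveSeed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 1009) %% 2147483629
}

#' Construct a mutation model
#'
#' Exactly one of \code{multistepMean} or \code{multistepVariance} fixes the
#' geometric multistep-size law (they are alternative conventions: the
#' heterozygosity-excess literature quotes the variance, the M-ratio
#' literature the mean); with \code{pSingle = 1} (strict stepwise model)
#' neither is needed.
#'
#' @param pSingle proportion of single-step mutations.
#' @param multistepMean mean multistep size in repeat units; with
#'   \code{multistepMin = m} the size is m + Geom(q) and
#'   q = 1 / (mean - m + 1).
#' @param multistepVariance variance of the multistep size (geometric tail:
#'   q = (-1 + sqrt(1 + 4 v)) / (2 v), independent of the minimum).
#' @param multistepMin smallest multistep size: 2 treats "multistep" as
#'   strictly larger than a single step (the M-ratio software convention),
#'   1 lets the geometric start at one unit (the heterozygosity-excess
#'   convention).
#' @param theta scaled mutation rate carried for reference (NA allowed).
#' @param mu per-locus per-generation mutation rate.
#' @return a [MutationModel-class].
#' @examples
#' mutationModel(0.9, multistepMean = 3.5, multistepMin = 2)  # M-ratio
#' mutationModel(0.95, multistepVariance = 12)                # TPM 5%
#' @export
mutationModel <- function(pSingle = 0.9, multistepMean = NULL,
                          multistepVariance = NULL, multistepMin = 1L,
                          theta = NA_real_, mu = 5e-4) {
  multistepMin <- as.integer(multistepMin)
  if (pSingle == 1) {
    q <- 1
  } else if (!is.null(multistepMean)) {
    stopifnot(multistepMean >= multistepMin)
    q <- 1 / (multistepMean - multistepMin + 1)
  } else if (!is.null(multistepVariance)) {
    v <- multistepVariance
    stopifnot(v > 0)
    q <- (-1 + sqrt(1 + 4 * v)) / (2 * v)
  } else {
    stop("supply multistepMean or multistepVariance (or pSingle = 1)")
  }
  new("MutationModel", pSingle = pSingle, geomQ = q, msMin = multistepMin,
      theta = theta, mu = mu)
}

#' Strict stepwise mutation model
#' @inheritParams mutationModel
#' @export
smmModel <- function(theta = NA_real_, mu = 5e-4) {
  mutationModel(pSingle = 1, theta = theta, mu = mu)
}

#' Two-phase model in the heterozygosity-excess convention
#'
#' Multistep proportion \code{pMultistep} with multistep-size variance 12.
#' @param pMultistep proportion of multistep mutations (e.g. 0.05 or 0.20).
#' @inheritParams mutationModel
#' @export
tpmVariance12 <- function(pMultistep, theta = NA_real_, mu = 5e-4) {
  mutationModel(pSingle = 1 - pMultistep, multistepVariance = 12,
                theta = theta, mu = mu)
}

setMethod("show", "MutationModel", function(object) {
  cat(sprintf(paste0("MutationModel: pSingle = %.3g, multistep ~ %d + Geom(",
                     "%.4g) (mean %.3g, var %.3g), mu = %.3g, theta = %s\n"),
              object@pSingle, object@msMin, object@geomQ,
              object@msMin - 1 + 1 / object@geomQ,
              (1 - object@geomQ) / object@geomQ^2, object@mu,
              format(object@theta)))
})

#' Construct a demographic trajectory
#'
#' @param N0 current effective size.
#' @param N1 ancestral effective size.
#' @param T time of the size change, generations before sampling.
#' @param shape "exponential", "linear", "constant", or "step" (an abrupt
#'   change at T, convenient for simulating a sudden collapse that has held
#'   at N0 for the last T generations).
#' @return a [DemographicTrajectory-class].
#' @export
demographicTrajectory <- function(N0, N1 = N0, T = 0,
                                  shape = c("exponential", "linear",
                                            "constant", "step")) {
  shape <- match.arg(shape)
  new("DemographicTrajectory", N0 = as.numeric(N0), N1 = as.numeric(N1),
      T = as.numeric(T), shape = shape)
}

#' @rdname demographicTrajectory
#' @param N constant effective size.
#' @export
constantTrajectory <- function(N) {
  new("DemographicTrajectory", N0 = as.numeric(N), N1 = as.numeric(N),
      T = 0, shape = "constant")
}

#' Constant-size trajectory matching an equilibrium theta
#'
#' theta = 4 Ne mu, so Ne = theta / (4 mu).
#' @param theta scaled mutation rate.
#' @param mu per-locus mutation rate.
#' @export
equilibriumTrajectory <- function(theta, mu = 5e-4) {
  constantTrajectory(theta / (4 * mu))
}

setMethod("show", "DemographicTrajectory", function(object) {
  if (object@shape == "constant") {
    cat(sprintf("DemographicTrajectory: constant N = %g\n", object@N0))
  } else {
    cat(sprintf("DemographicTrajectory: %s change N0 = %g -> N1 = %g at T = %g generations\n",
                object@shape, object@N0, object@N1, object@T))
  }
})

#' @rdname populationSize
#' @export
setMethod("populationSize", "DemographicTrajectory", function(traj, t) {
  vapply(t, function(tt) traj_N_cpp(tt, traj@N0, traj@N1, traj@T,
                                    shapeCode(traj@shape)), numeric(1))
})

#' @rdname coalescentIntensity
#' @export
setMethod("coalescentIntensity", "DemographicTrajectory", function(traj, t) {
  stopifnot(all(t >= 0))
  vapply(t, function(tt) traj_intensity_cpp(tt, traj@N0, traj@N1, traj@T,
                                            shapeCode(traj@shape)), numeric(1))
})

#' Construct an island-model subdivision specification
#'
#' @param demeSizes effective sizes of the demes.
#' @param migration per-lineage per-generation migration rate (destination
#'   uniform over the other demes).
#' @param mergeTime generations before present at which all demes merge into
#'   the first (Inf = never).
#' @param demeNames labels.
#' @return a [SubdivisionSpec-class].
#' @export
subdivisionSpec <- function(demeSizes, migration, mergeTime = Inf,
                            demeNames = NULL) {
  if (is.null(demeNames)) demeNames <- sprintf("deme%d", seq_along(demeSizes))
  new("SubdivisionSpec", demeSizes = as.numeric(demeSizes),
      migration = as.numeric(migration), mergeTime = as.numeric(mergeTime),
      demeNames = demeNames)
}

#' Simulate one microsatellite locus under the coalescent
#'
#' n-coalescent with time rescaled by the cumulative intensity of the
#' trajectory; mutations Poisson along branches at rate \code{mu} per
#' generation, displacements from the two-phase model. Allele sizes are
#' reported relative to the root (= 0).
#'
#' @param nGenes number of gene copies (>= 2).
#' @param traj a [DemographicTrajectory-class].
#' @param model a [MutationModel-class] (its \code{mu} slot is the rate
#'   used).
#' @param sampleTimes age in generations of each gene copy (scalar recycled).
#' @param seed optional integer seed.
#' @return integer vector of allele sizes (repeat units, root = 0).
#' @export
simulateLocus <- function(nGenes, traj, model, sampleTimes = 0, seed = NULL) {
  stopifnot(nGenes >= 2)
  if (!is.null(seed)) set.seed(seed)
  st <- rep_len(as.numeric(sampleTimes), nGenes)
  sim_locus_cpp(st, traj@N0, traj@N1, traj@T, shapeCode(traj@shape),
                model@mu, model@pSingle, model@geomQ, model@msMin)
}

#' Simulate a diploid genotype dataset
#'
#' Independent loci; the 2 * nInd gene copies of each locus are paired into
#' diploid individuals. Allele sizes are shifted by +100 repeat units so that
#' the dataset round-trips through Genepop coding (all statistics are
#' translation invariant). Per-locus random streams are derived from
#' \code{seed} by a counter, so locus i is reproducible in isolation.
#'
#' @param nInd number of diploid individuals.
#' @param nLoci number of loci.
#' @param traj a [DemographicTrajectory-class].
#' @param model a [MutationModel-class].
#' @param seed integer seed (NULL = use current RNG state).
#' @param population population label.
#' @return a [GenotypeDataset-class].
#' @export
simulateDataset <- function(nInd, nLoci, traj, model, seed = NULL,
                            population = "sim") {
  a1 <- matrix(NA_integer_, nInd, nLoci)
  a2 <- matrix(NA_integer_, nInd, nLoci)
  for (l in seq_len(nLoci)) {
    if (!is.null(seed)) set.seed(deriveSeed(seed, l))
    g <- simulateLocus(2 * nInd, traj, model) + 100L
    a1[, l] <- g[seq_len(nInd)]
    a2[, l] <- g[nInd + seq_len(nInd)]
  }
  GenotypeDataset(a1, a2, population = population)
}

#' Simulate a subdivided population (finite island model)
#'
#' Structured coalescent over \code{length(demeSizes)} demes with symmetric
#' migration; deme labels are attached to the output. The trajectory scales
#' all deme sizes jointly through time (deme i has size
#' \code{demeSizes[i] * N(t) / N0}).
#'
#' @param spec a [SubdivisionSpec-class].
#' @param traj a [DemographicTrajectory-class] (use
#'   \code{constantTrajectory} for a stationary island model).
#' @param model a [MutationModel-class].
#' @param nPerDeme diploid individuals sampled per deme (recycled).
#' @param nLoci number of loci.
#' @param seed integer seed.
#' @param population population label.
#' @return a [GenotypeDataset-class] with deme labels.
#' @export
simulateSubdivided <- function(spec, traj, model, nPerDeme, nLoci = 10,
                               seed = NULL, population = "sim") {
  d <- length(spec@demeSizes)
  if (d > 1 && spec@migration == 0 && !is.finite(spec@mergeTime))
    stop("non-coalescing configuration: multiple demes, zero migration ",
         "and no merge time")
  nPerDeme <- rep_len(nPerDeme, d)
  nInd <- sum(nPerDeme)
  demeOfInd <- rep(seq_len(d), nPerDeme)
  demeOfGene <- rep(demeOfInd - 1L, 2)
  mig <- matrix(if (d > 1) spec@migration / (d - 1) else 0, d, d)
  diag(mig) <- 0
  merges <- if (is.finite(spec@mergeTime) && d > 1) {
    cbind(spec@mergeTime, seq_len(d - 1), 0)
  } else {
    matrix(numeric(0), 0, 3)
  }
  a1 <- matrix(NA_integer_, nInd, nLoci)
  a2 <- matrix(NA_integer_, nInd, nLoci)
  for (l in seq_len(nLoci)) {
    if (!is.null(seed)) set.seed(deriveSeed(seed, l))
    g <- sim_locus_struct_cpp(demeOfGene, rep(0, 2 * nInd), spec@demeSizes,
                              mig, merges, traj@N0, traj@N1, traj@T,
                              shapeCode(traj@shape), model@mu, model@pSingle,
                              model@geomQ, model@msMin) + 100L
    a1[, l] <- g[seq_len(nInd)]
    a2[, l] <- g[nInd + seq_len(nInd)]
  }
  GenotypeDataset(a1, a2, population = population,
                  deme = spec@demeNames[demeOfInd])
}

#' Simulate a temporal (serial) sample pair
#'
#' Two samples from one lineage: the historical sample is taken
#' \code{gapGenerations} before the contemporary one; drift over the gap
#' separates them (E[F_ST] is approximately gap / (2 Ne) for short gaps).
#'
#' @param traj a [DemographicTrajectory-class] (time 0 = contemporary
#'   sampling).
#' @param model a [MutationModel-class].
#' @param gapGenerations generations between the two samples (>= 0).
#' @param nHist,nContemp diploid sample sizes.
#' @param nLoci number of loci.
#' @param seed integer seed.
#' @return list of two [GenotypeDataset-class]: \code{historical},
#'   \code{contemporary}.
#' @export
simulateTemporalPair <- function(traj, model, gapGenerations, nHist, nContemp,
                                 nLoci = 10, seed = NULL) {
  stopifnot(gapGenerations >= 0)
  nGenes <- 2 * (nHist + nContemp)
  st <- c(rep(0, 2 * nContemp), rep(gapGenerations, 2 * nHist))
  a1h <- matrix(NA_integer_, nHist, nLoci)
  a2h <- matrix(NA_integer_, nHist, nLoci)
  a1c <- matrix(NA_integer_, nContemp, nLoci)
  a2c <- matrix(NA_integer_, nContemp, nLoci)
  for (l in seq_len(nLoci)) {
    if (!is.null(seed)) set.seed(deriveSeed(seed, l))
    g <- sim_locus_cpp(st, traj@N0, traj@N1, traj@T, shapeCode(traj@shape),
                       model@mu, model@pSingle, model@geomQ,
                       model@msMin) + 100L
    gc <- g[seq_len(2 * nContemp)]
    gh <- g[2 * nContemp + seq_len(2 * nHist)]
    a1c[, l] <- gc[seq_len(nContemp)]
    a2c[, l] <- gc[nContemp + seq_len(nContemp)]
    a1h[, l] <- gh[seq_len(nHist)]
    a2h[, l] <- gh[nHist + seq_len(nHist)]
  }
  list(historical = GenotypeDataset(a1h, a2h, population = "historical"),
       contemporary = GenotypeDataset(a1c, a2c, population = "contemporary"))
}

#' Synthetic two-population fisher study design
#'
#' Emulates the sampling design of the California fisher microsatellite
#' study on fully synthetic data: two populations (northwestern, NW, and
#' southern Sierra Nevada, SSN) isolated since an ancient split, each
#' declining from an ancestral effective size of about 1800 to about 150 at
#' 300 generations before present; the contemporary SSN subdivided into
#' three demes (North/Central/South) with moderate differentiation; and
#' historical samples taken 19 generations (95 years at 5 years per
#' generation) before the contemporary ones. Sample sizes are NW_H = 5,
#' NW_C = 148, SSN_H = 16, SSN_C = 127 individuals at 10 loci.
#'
#' @param seed integer seed.
#' @param nLoci number of loci.
#' @param gapGenerations age of the historical samples in generations.
#' @param splitGenerations NW/SSN split time (generations before present).
#' @param demeSplitGenerations time at which the three SSN demes separated.
#' @param migration within-SSN deme migration rate (calibrated so pairwise
#'   deme F_ST falls in the moderate 0.05-0.13 band).
#' @return named list of four [GenotypeDataset-class] objects (NW_H, NW_C,
#'   SSN_H, SSN_C) with deme labels and sample years attached.
#' @export
fisherScenario <- function(seed = 1, nLoci = 10, gapGenerations = 19,
                           splitGenerations = 1300,
                           demeSplitGenerations = 150, migration = 0.03) {
  traj <- demographicTrajectory(N0 = 150, N1 = 1800, T = 300,
                                shape = "exponential")
  model <- mutationModel(pSingle = 0.9, multistepMean = 3.5,
                         multistepMin = 2, mu = 5e-4)
  # demes: 1 NW, 2 SSN-North, 3 SSN-Central, 4 SSN-South (0-based in C++)
  demeSizes <- c(150, 50, 50, 50)
  d <- 4
  mig <- matrix(0, d, d)
  mig[2:4, 2:4] <- migration / 2
  diag(mig) <- 0
  merges <- rbind(c(demeSplitGenerations, 2, 1),  # 0-based: demes 3,4 -> 2
                  c(demeSplitGenerations, 3, 1),
                  c(splitGenerations, 1, 0))      # SSN -> NW ancestor
  nNWC <- 148; nNWH <- 5
  nSSN <- c(North = 44, Central = 32, South = 51)
  nSSNH <- c(6, 5, 5)
  demeOfInd <- c(rep(0L, nNWC), rep(0L, nNWH),
                 rep(1:3, nSSN), rep(1:3, nSSNH))
  ageOfInd <- c(rep(0, nNWC), rep(gapGenerations, nNWH),
                rep(0, sum(nSSN)), rep(gapGenerations, sum(nSSNH)))
  nInd <- length(demeOfInd)
  demeOfGene <- rep(demeOfInd, 2)
  ageOfGene <- rep(ageOfInd, 2)
  a1 <- matrix(NA_integer_, nInd, nLoci)
  a2 <- matrix(NA_integer_, nInd, nLoci)
  for (l in seq_len(nLoci)) {
    set.seed(deriveSeed(seed, l))
    g <- sim_locus_struct_cpp(demeOfGene, ageOfGene, demeSizes, mig, merges,
                              traj@N0, traj@N1, traj@T,
                              shapeCode(traj@shape), model@mu, model@pSingle,
                              model@geomQ, model@msMin) + 100L
    a1[, l] <- g[seq_len(nInd)]
    a2[, l] <- g[nInd + seq_len(nInd)]
  }
  grp <- c(rep("NW_C", nNWC), rep("NW_H", nNWH),
           rep(c("SSN_C"), sum(nSSN)), rep("SSN_H", sum(nSSNH)))
  demeLab <- c(rep(NA_character_, nNWC + nNWH),
               rep(names(nSSN), nSSN), rep(names(nSSN), nSSNH))
  year <- ifelse(ageOfInd > 0, 2007 - round(ageOfInd * 5), 2007)
  gd <- GenotypeDataset(a1, a2, population = grp, deme = demeLab,
                        sampleYear = year)
  list(NW_H = subsetGroup(gd, population = "NW_H"),
       NW_C = subsetGroup(gd, population = "NW_C"),
       SSN_H = subsetGroup(gd, population = "SSN_H"),
       SSN_C = subsetGroup(gd, population = "SSN_C"))
}

#' Write a scenario bundle as Genepop + metadata sidecar files
#'
#' @param bundle named list of [GenotypeDataset-class] (e.g. from
#'   [fisherScenario()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeScenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(bundle)) {
    gp <- file.path(dir, paste0(nm, ".gen"))
    tsv <- file.path(dir, paste0(nm, ".meta.tsv"))
    writeGenepop(bundle[[nm]], gp, title = nm)
    writeSampleMetadata(bundle[[nm]], tsv)
    paths <- c(paths, gp, tsv)
  }
  invisible(paths)
}
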
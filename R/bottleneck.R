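## The three bottleneck detectors: heterozygosity excess against the
## simulated mutation-drift equilibrium, the allele-frequency mode-shift
## test, and the Garza-Williamson M-ratio with simulated critical values.

## find the shared theta at which the summed equilibrium mean allele count
## over loci (at their respective gene-copy counts) matches the summed
## observed k, by bisection on log10(theta); E[k] is monotone in theta.
## A single multi-locus estimate is used because matching theta per locus
## to that locus's own k inflates the type-I error of the excess test (the
## k distribution is right-skewed, so most loci sit below their expectation
## and get a too-small theta, hence a too-low equilibrium He).
findThetaMultiLocus <- function(nGenesVec, kVec, model, batch = 120,
                                iter = 12) {
  lo <- -3
  hi <- 3.2
  target <- sum(kVec)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    mk <- sum(vapply(nGenesVec, function(n)
      sim_mean_k_cpp(n, 10^mid, model@mu, model@pSingle, model@geomQ,
                     model@msMin, batch), numeric(1)))
    if (mk < target) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}

#' Heterozygosity-excess test against mutation-drift equilibrium
#'
#' For each polymorphic locus, the equilibrium distribution of unbiased
#' expected heterozygosity conditional on the observed number of alleles k
#' and the number of typed gene copies is simulated under the supplied
#' mutation model by rejection sampling: coalescent replicates at a shared
#' multi-locus theta (matched so the summed expected allele count equals the
#' summed observed count) are retained only when they carry exactly k
#' alleles. A recently bottlenecked population retains more heterozygosity
#' than equilibrium predicts for its (reduced) allele count, so the observed
#' minus expected differences are tested across loci with a one-tailed
#' Wilcoxon signed-rank statistic for excess.
#'
#' The reference distribution of the Wilcoxon statistic is obtained from the
#' same conditional equilibrium simulations (each bootstrap pseudo-dataset
#' draws one simulated He per locus), because the conditional He
#' distribution is left-skewed and the classical symmetric-null Wilcoxon
#' p-value is anticonservative for the excess tail (empirical size about
#' 0.10 at a nominal 0.05 in this package's equilibrium checks). The
#' classical p-value is also reported as \code{p.classical}.
#'
#' @param x a [GenotypeDataset-class].
#' @param model a [MutationModel-class]; conventionally a two-phase model in
#'   the variance-12 parameterization (see [tpmVariance12()]).
#' @param reps equilibrium replicates retained per locus.
#' @param population,deme optional group selectors.
#' @param bootstrapB pseudo-datasets for the calibrated reference.
#' @param seed integer seed.
#' @return object of class \code{hetExcessResult}: list with \code{perLocus}
#'   (locus, k, gene copies, observed He, equilibrium mean/SD, standardized
#'   difference), \code{p.value} (one-tailed, simulation-calibrated),
#'   \code{p.classical} (symmetric-null Wilcoxon) and \code{nLoci} used.
#' @export
hetExcessTest <- function(x, model, reps = 5000, population = NULL,
                          deme = NULL, bootstrapB = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ac <- alleleCounts(x, population = population, deme = deme)
  ks <- vapply(ac, length, integer(1))
  use <- which(ks >= 2)
  if (length(use) == 0) stop("hetExcessTest: no polymorphic loci")
  if (length(use) < length(ac))
    message("hetExcessTest: excluding ", length(ac) - length(use),
            " monomorphic locus/loci: ",
            paste(names(ac)[ks < 2], collapse = ", "))
  if (length(use) < 4)
    warning("hetExcessTest: fewer than 4 polymorphic loci; the Wilcoxon ",
            "test will have little power")
  th <- findThetaMultiLocus(vapply(ac[use], sum, numeric(1)),
                            ks[use], model)
  heSims <- vector("list", length(use))
  per <- vector("list", length(use))
  for (i in seq_along(use)) {
    l <- use[i]
    ct <- ac[[l]]
    n2 <- sum(ct)
    k <- length(ct)
    heObs <- unbiasedHe(ct)
    sims <- sim_he_given_k_cpp(n2, k, th, model@mu, model@pSingle,
                               model@geomQ, model@msMin, reps,
                               maxAttempts = 80L * reps)
    he <- sims$he
    if (length(he) < max(100, reps / 10))
      warning("hetExcessTest: low conditional acceptance at locus ",
              names(ac)[l], " (", length(he), " replicates kept)")
    heSims[[i]] <- he
    per[[i]] <- data.frame(locus = names(ac)[l], k = k, copies = n2,
                           heObs = heObs, heEqMean = mean(he),
                           heEqSD = stats::sd(he), stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  per$diff <- per$heObs - per$heEqMean
  per$stdDiff <- per$diff / per$heEqSD
  wstat <- function(d) {
    r <- rank(abs(d))
    sum(r[d > 0])
  }
  Wobs <- wstat(per$diff)
  Wb <- replicate(bootstrapB, wstat(vapply(heSims, function(h)
    sample(h, 1) - mean(h), numeric(1))))
  pBoot <- (sum(Wb >= Wobs) + 1) / (bootstrapB + 1)
  wt <- stats::wilcox.test(per$diff, alternative = "greater",
                           exact = nrow(per) <= 25)
  out <- list(perLocus = per, p.value = pBoot, p.classical = wt$p.value,
              nLoci = nrow(per))
  class(out) <- "hetExcessResult"
  out
}

#' @export
print.hetExcessResult <- function(x, ...) {
  cat("Heterozygosity-excess test (", x$nLoci, " polymorphic loci)\n",
      sep = "")
  cat(sprintf("  one-tailed Wilcoxon signed-rank p = %.4g\n", x$p.value))
  invisible(x)
}

#' Allele-frequency mode-shift test
#'
#' Allele proportions pooled across loci are binned into ten frequency
#' classes of width 0.1. At mutation-drift equilibrium the rarest class
#' [0, 0.1) is modal (an L-shaped distribution); a bottleneck preferentially
#' removes rare alleles and shifts the mode, flagged when the rare class
#' count is strictly smaller than some higher class (ties conservatively
#' count as not shifted). At least 30 typed individuals are required to keep
#' the type-I error of the graphical test in check; smaller groups are
#' refused.
#'
#' @param x a [GenotypeDataset-class].
#' @param population,deme optional group selectors.
#' @param minInd minimum individuals required (default 30).
#' @return list with \code{shifted} (logical), \code{classCounts} (10
#'   frequency classes) and \code{n}.
#' @export
modeShiftTest <- function(x, population = NULL, deme = NULL, minInd = 30) {
  g <- subsetGroup(x, population = population, deme = deme)
  if (nInd(g) < minInd)
    stop("modeShiftTest: ", nInd(g), " individuals < required ", minInd)
  ac <- alleleCounts(g)
  freqs <- unlist(lapply(ac, function(ct) {
    if (length(ct) < 1) return(numeric(0))
    ct / sum(ct)
  }))
  br <- seq(0, 1, by = 0.1)
  cls <- cut(freqs, breaks = br, right = FALSE, include.lowest = TRUE)
  counts <- as.integer(table(cls))
  shifted <- counts[1] < max(counts[-1])
  list(shifted = shifted,
       classCounts = stats::setNames(counts, levels(cls)), n = nInd(g))
}

#' Garza-Williamson M-ratio
#'
#' Per locus, M = k / s where k is the number of alleles and s the number of
#' allelic states spanned by the observed size range (range in repeat units
#' + 1), so 0 < M <= 1 for a polymorphic locus. The multi-locus value is the
#' unweighted mean over polymorphic loci. A bottleneck removes alleles
#' faster than it shrinks the size range, depressing M.
#'
#' @param x a [GenotypeDataset-class].
#' @param population,deme optional group selectors.
#' @return object of class \code{mRatioResult}: list with \code{perLocus}
#'   (locus, k, range, M) and \code{meanM}.
#' @export
mRatio <- function(x, population = NULL, deme = NULL) {
  ac <- alleleCounts(x, population = population, deme = deme)
  per <- do.call(rbind, lapply(seq_along(ac), function(l) {
    ct <- ac[[l]]
    if (length(ct) == 0)
      return(data.frame(locus = names(ac)[l], k = 0L, range = NA_integer_,
                        M = NA_real_, stringsAsFactors = FALSE))
    sizes <- as.integer(names(ct))
    k <- length(ct)
    rg <- max(sizes) - min(sizes)
    data.frame(locus = names(ac)[l], k = k, range = rg,
               M = k / (rg + 1), stringsAsFactors = FALSE)
  }))
  poly <- per$k >= 2
  if (!any(poly)) stop("mRatio: all loci monomorphic")
  out <- list(perLocus = per, meanM = mean(per$M[poly]))
  class(out) <- "mRatioResult"
  out
}

#' @export
print.mRatioResult <- function(x, ...) {
  cat(sprintf("M-ratio: mean M = %.3f over %d polymorphic loci\n",
              x$meanM, sum(x$perLocus$k >= 2, na.rm = TRUE)))
  invisible(x)
}

#' Simulated critical value for the M-ratio
#'
#' Simulates \code{reps} equilibrium datasets (\code{nLoci} loci, 2 *
#' \code{nInd} gene copies each) at the given theta = 4 Ne mu under the
#' mutation model and returns the alpha-quantile of the multi-locus mean M:
#' an observed mean M below the cutoff is significant evidence of a
#' bottleneck at level alpha.
#'
#' @param nInd diploid sample size.
#' @param nLoci number of loci.
#' @param theta scaled mutation rate 4 Ne mu of the (pre-decline)
#'   equilibrium.
#' @param model mutation model; default 90% single-step, multistep at least
#'   two units with mean 3.5, mu = 5e-4 (the M-ratio software convention).
#' @param reps equilibrium replicate datasets (>= 1000 recommended; fewer
#'   triggers a warning about quantile stability).
#' @param alpha lower-tail significance level.
#' @param seed integer seed.
#' @param includeMonomorphic count monomorphic loci as M = 1 in the
#'   replicate means, mirroring the observed-data convention of dropping
#'   them only when FALSE.
#' @return the critical value, with attribute \code{meanM} (null mean).
#' @export
mCritical <- function(nInd, nLoci, theta,
                      model = mutationModel(0.9, multistepMean = 3.5,
                                            multistepMin = 2),
                      reps = 10000, alpha = 0.05, seed = NULL,
                      includeMonomorphic = FALSE) {
  if (reps < 1000)
    warning("mCritical: reps < 1000 gives an unstable tail quantile")
  if (!is.null(seed)) set.seed(seed)
  ms <- sim_mean_M_cpp(2L * nInd, nLoci, theta, model@mu, model@pSingle,
                       model@geomQ, model@msMin, reps, includeMonomorphic)
  ms <- ms[!is.na(ms)]
  out <- unname(stats::quantile(ms, alpha))
  attr(out, "meanM") <- mean(ms)
  out
}

#' Run the full bottleneck battery for one group
#'
#' Produces one report row per analysis unit: the pooled group and, when
#' \code{byDeme}, each deme separately (pooling differentiated demes
#' distorts the heterozygosity-excess test through the Wahlund effect, so
#' subdivided populations should be read deme by deme). Columns follow the
#' conventional report layout: sample size, heterozygosity-excess p at each
#' two-phase variant, mode-shift verdict (NA when the group is smaller than
#' 30), mean M, and M-critical cutoffs over the theta grid.
#'
#' @param x a [GenotypeDataset-class].
#' @param population optional population label.
#' @param byDeme also analyze each deme separately.
#' @param tpm multistep proportions for the heterozygosity-excess test
#'   (variance-12 convention).
#' @param thetaGrid theta values for M-critical.
#' @param hetReps equilibrium replicates per locus for the excess test.
#' @param mReps replicate datasets for M-critical.
#' @param mModel mutation model for the M-ratio stage.
#' @param mu mutation rate for the excess-test models.
#' @param seed integer seed.
#' @return data.frame (one row per unit) with attribute \code{details}
#'   holding the full per-test objects.
#' @export
bottleneckBattery <- function(x, population = NULL, byDeme = FALSE,
                              tpm = c(0.05, 0.20), thetaGrid = c(1, 2, 5, 10),
                              hetReps = 5000, mReps = 10000,
                              mModel = mutationModel(0.9, multistepMean = 3.5,
                                                     multistepMin = 2),
                              mu = 5e-4, seed = 1) {
  g <- subsetGroup(x, population = population)
  units <- list(pooled = NULL)
  if (byDeme) {
    dl <- unique(demes(g))
    dl <- dl[!is.na(dl)]
    for (d in dl) units[[d]] <- d
  }
  rows <- list()
  details <- list()
  for (u in names(units)) {
    sub <- if (is.null(units[[u]])) g else subsetGroup(g, deme = units[[u]])
    det <- list()
    row <- list(unit = u, n = nInd(sub))
    for (p in tpm) {
      hx <- tryCatch(
        hetExcessTest(sub, tpmVariance12(p, mu = mu), reps = hetReps,
                      seed = deriveSeed(seed, round(1000 * p))),
        error = function(e) NULL)
      row[[sprintf("hetExcessP_tpm%02d", round(100 * p))]] <-
        if (is.null(hx)) NA_real_ else hx$p.value
      det[[sprintf("hetExcess_tpm%02d", round(100 * p))]] <- hx
    }
    ms <- tryCatch(modeShiftTest(sub), error = function(e) NULL)
    row$modeShift <- if (is.null(ms)) NA else ms$shifted
    det$modeShift <- ms
    mr <- tryCatch(mRatio(sub), error = function(e) NULL)
    row$meanM <- if (is.null(mr)) NA_real_ else mr$meanM
    det$mRatio <- mr
    for (th in thetaGrid) {
      mc <- mCritical(nInd(sub), nLoc(sub), th, model = mModel, reps = mReps,
                      seed = deriveSeed(seed, 100 + th))
      row[[sprintf("mCritical_theta%g", th)]] <- as.numeric(mc)
      row[[sprintf("mSignif_theta%g", th)]] <-
        !is.na(row$meanM) && row$meanM < as.numeric(mc)
    }
    rows[[u]] <- as.data.frame(row, stringsAsFactors = FALSE)
    details[[u]] <- det
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Mode-shift detection power under a Wright-Fisher bottleneck
#'
#' Power experiment for the mode-shift test: an equilibrium population at
#' the given theta collapses to \code{nBreeders} breeding individuals for
#' \code{generations} generations of forward Wright-Fisher reproduction,
#' after which \code{nSample} diploids are genotyped at \code{nLoci} loci
#' and the mode-shift test applied. Returns the fraction of replicates
#' flagged as shifted.
#'
#' @param nReps number of replicate bottleneck populations.
#' @param nSample diploid individuals sampled post-collapse.
#' @param nLoci loci per dataset.
#' @param theta pre-bottleneck equilibrium 4 Ne mu.
#' @param nBreeders breeding individuals during the bottleneck.
#' @param generations generations of collapse before sampling.
#' @param model mutation model (default two-phase, 5% multistep,
#'   variance 12).
#' @param seed integer seed.
#' @return proportion of replicates with a shifted mode, with attribute
#'   \code{flags} (the per-replicate verdicts).
#' @export
modeShiftPower <- function(nReps = 200, nSample = 30, nLoci = 10, theta = 10,
                           nBreeders = 20, generations = 5,
                           model = tpmVariance12(0.05), seed = 1) {
  flags <- logical(nReps)
  for (r in seq_len(nReps)) {
    set.seed(deriveSeed(seed, r))
    gd <- wfBottleneckDataset(nSample, nLoci, theta, nBreeders, generations,
                              model)
    flags[r] <- modeShiftTest(gd)$shifted
  }
  out <- mean(flags)
  attr(out, "flags") <- flags
  out
}

#' Simulate one post-bottleneck dataset by forward Wright-Fisher collapse
#'
#' Founders (2 * nBreeders gene copies) are drawn from the coalescent
#' equilibrium at theta; the pool then reproduces for \code{generations}
#' Wright-Fisher generations at \code{nBreeders} breeders; finally 2 *
#' \code{nSample} gametes are drawn (with mutation) from the last breeder
#' pool to form the sampled diploids.
#'
#' @inheritParams modeShiftPower
#' @return a [GenotypeDataset-class].
#' @export
wfBottleneckDataset <- function(nSample, nLoci, theta, nBreeders, generations,
                                model = tpmVariance12(0.05)) {
  a1 <- matrix(NA_integer_, nSample, nLoci)
  a2 <- matrix(NA_integer_, nSample, nLoci)
  for (l in seq_len(nLoci)) {
    pool <- simulateLocus(2 * nBreeders, equilibriumTrajectory(theta, model@mu),
                          model)
    pool <- wf_evolve_cpp(pool, generations, nBreeders, model@mu,
                          model@pSingle, model@geomQ, model@msMin)
    g <- pool[sample.int(length(pool), 2 * nSample, replace = TRUE)]
    nm <- stats::rpois(length(g), model@mu)
    for (i in which(nm > 0)) {
      steps <- ifelse(stats::runif(nm[i]) < model@pSingle, 1,
                      model@msMin + stats::rgeom(nm[i], model@geomQ))
      g[i] <- g[i] + sum(steps * sample(c(-1L, 1L), nm[i], replace = TRUE))
    }
    g <- g + 100L
    a1[, l] <- g[seq_len(nSample)]
    a2[, l] <- g[nSample + seq_len(nSample)]
  }
  GenotypeDataset(a1, a2, population = "wf")
}
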
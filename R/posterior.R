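## Post-processing of MCMC chains: burn-in and pooling, multivariate
## convergence diagnostics, HPD/mode summaries, the decline Bayes factor,
## and calendar-time calibration.

chainMatrix <- function(x) {
  if (is(x, "PosteriorChains")) chainRecords(x) else as.matrix(x)
}

#' Trim burn-in and pool chain tails
#'
#' The leading \code{burnInFrac} of each chain is removed for diagnostics;
#' the trailing \code{poolFrac} of each chain is concatenated for posterior
#' summaries (so with 20,000-record chains and poolFrac 0.5, five chains
#' pool to 50,000 records).
#'
#' @param chains list of [PosteriorChains-class] (or record matrices).
#' @param burnInFrac leading fraction removed per chain.
#' @param poolFrac trailing fraction pooled across chains.
#' @return list with \code{diagnostics} (list of trimmed matrices) and
#'   \code{pooled} (one matrix).
#' @export
trimAndPool <- function(chains, burnInFrac = 0.1, poolFrac = 0.5) {
  stopifnot(burnInFrac >= 0, burnInFrac < 1, poolFrac > 0, poolFrac <= 1)
  mats <- lapply(chains, chainMatrix)
  if (any(vapply(mats, nrow, integer(1)) == 0)) stop("empty chain")
  diagn <- lapply(mats, function(m) {
    drop <- floor(burnInFrac * nrow(m))
    m[(drop + 1):nrow(m), , drop = FALSE]
  })
  pooled <- do.call(rbind, lapply(mats, function(m) {
    keep <- ceiling(poolFrac * nrow(m))
    m[(nrow(m) - keep + 1):nrow(m), , drop = FALSE]
  }))
  list(diagnostics = diagn, pooled = pooled)
}

#' Multivariate potential scale reduction factor (Brooks-Gelman)
#'
#' MPSRF = (n-1)/n + ((m+1)/m) * lambda_1, where lambda_1 is the largest
#' eigenvalue of W^{-1} B/n, W the mean within-chain covariance and B/n the
#' between-chain covariance of the chain means, m chains of n records each.
#' Values near 1 indicate convergence of all parameters simultaneously.
#'
#' @param chains list of >= 2 equal-length record matrices or
#'   [PosteriorChains-class].
#' @return the MPSRF scalar.
#' @export
mpsrf <- function(chains) {
  mats <- lapply(chains, chainMatrix)
  m <- length(mats)
  if (m < 2) stop("mpsrf: need at least 2 chains")
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1) stop("mpsrf: chains must have equal length")
  keep <- apply(do.call(rbind, mats), 2, stats::sd) > 0
  mats <- lapply(mats, function(x) x[, keep, drop = FALSE])
  W <- Reduce(`+`, lapply(mats, stats::cov)) / m
  mu <- do.call(rbind, lapply(mats, colMeans))
  Bn <- stats::cov(mu)  # = B/n
  WB <- tryCatch(solve(W, Bn), error = function(e)
    stop("mpsrf: singular within-chain covariance"))
  lam1 <- max(Re(eigen(WB, only.values = TRUE)$values))
  (n - 1) / n + ((m + 1) / m) * lam1
}

#' Highest posterior density interval and mode
#'
#' Shortest interval containing \code{mass} of the samples (sorted-window
#' scan) and the mode of a Gaussian-kernel density estimate (bandwidth by
#' the standard reference rule).
#'
#' @param samples numeric vector (>= 100 values recommended; degenerate
#'   constant input returns a point interval).
#' @param mass HPD mass (default 0.90).
#' @return named numeric vector (lo, hi, mode).
#' @export
hpdAndMode <- function(samples, mass = 0.90) {
  stopifnot(mass > 0, mass < 1)
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) stop("hpdAndMode: no finite samples")
  if (stats::sd(samples) == 0) {
    return(c(lo = samples[1], hi = samples[1], mode = samples[1]))
  }
  if (length(samples) < 100)
    warning("hpdAndMode: fewer than 100 samples; the interval is unstable")
  s <- sort(samples)
  n <- length(s)
  w <- max(1, ceiling(mass * n))
  if (w >= n) {
    lo <- s[1]; hi <- s[n]
  } else {
    widths <- s[(w + 1):n] - s[1:(n - w)]
    i <- which.min(widths)
    lo <- s[i]; hi <- s[i + w]
  }
  d <- stats::density(samples)
  c(lo = lo, hi = hi, mode = d$x[which.max(d$y)])
}

#' Bayes factor for population decline
#'
#' BF = posterior odds(r < 1) / prior odds(r < 1) with r = N0/N1, computed
#' on the event r < 1 so it is invariant to monotone reparameterization.
#' Empty cells get add-one continuity and the result is flagged as a lower
#' or upper bound. Support categories: < 0.33 false detection of
#' contraction/expansion, 0.33-3 none, 3-10 substantial, >= 10 strong.
#'
#' @param posteriorR posterior samples of r = N0/N1.
#' @param priorR prior samples of r.
#' @return list with \code{bf}, \code{category}, \code{bound} (NA, "lower"
#'   or "upper"), and the underlying fractions.
#' @export
bayesFactorDecline <- function(posteriorR, priorR) {
  stopifnot(length(posteriorR) > 0, length(priorR) > 0)
  odds <- function(x) {
    a <- sum(x < 1)
    b <- length(x) - a
    bound <- NA_character_
    if (b == 0) { b <- 1; bound <- "lower" }
    if (a == 0) { a <- 1; bound <- "upper" }
    list(odds = a / b, bound = bound)
  }
  po <- odds(posteriorR)
  pr <- odds(priorR)
  bf <- po$odds / pr$odds
  bound <- po$bound
  if (!is.na(pr$bound)) {
    bound <- if (is.na(bound)) {
      if (pr$bound == "lower") "upper" else "lower"
    } else bound
  }
  category <- if (bf < 0.33) "false detection"
    else if (bf < 3) "none"
    else if (bf < 10) "substantial"
    else "strong"
  list(bf = bf, category = category, bound = bound,
       posteriorFraction = mean(posteriorR < 1),
       priorFraction = mean(priorR < 1))
}

#' Calibrate a generation-time estimate to years before present
#'
#' years = T * generationYears + sampleAgeYears; the sample-age term shifts
#' estimates from aged (historical) samples onto the present-day clock.
#'
#' @param Tgenerations time in generations (vectorized).
#' @param generationYears years per generation (default 5).
#' @param sampleAgeYears average age of the sample in years (0 for
#'   contemporary samples).
#' @return years before present.
#' @export
calibrateTime <- function(Tgenerations, generationYears = 5,
                          sampleAgeYears = 0) {
  stopifnot(all(Tgenerations >= 0), generationYears >= 0, sampleAgeYears >= 0)
  Tgenerations * generationYears + sampleAgeYears
}

#' Export chain records or a posterior density curve as TSV
#'
#' \code{writeChainRecords} writes the thinned records of one or more chains
#' (log10 scale, one row per record, with a chain index column);
#' \code{writePosteriorDensity} writes a kernel density estimate of one
#' parameter (grid + density columns) for external plotting.
#'
#' @param chains a [PosteriorChains-class] or list of them.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeChainRecords <- function(chains, path) {
  if (is(chains, "PosteriorChains")) chains <- list(chains)
  rows <- do.call(rbind, lapply(seq_along(chains), function(i) {
    cbind(chain = i, as.data.frame(chainMatrix(chains[[i]])))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeChainRecords
#' @param samples numeric vector of posterior samples (one parameter).
#' @export
writePosteriorDensity <- function(samples, path) {
  d <- stats::density(samples)
  utils::write.table(data.frame(grid = d$x, density = d$y), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Posterior summary row for one dataset and shape
#'
#' Pools replicate chains (after burn-in based diagnostics), gates on the
#' MPSRF (warning above the threshold, not failure), and reports the Bayes
#' factor for decline, modes and 90% HPD intervals of N0, N1 and T (in
#' years), the mode of r = N0/N1, and optionally the posterior mass of the
#' contraction time beyond a reference age.
#'
#' KDE and HPD are computed on the log10 scale on which the chains are
#' stored and back-transformed for reporting.
#'
#' @param chains list of [PosteriorChains-class] for one dataset x shape.
#' @param priorSamples matrix from [rpriorSamples()] (for the prior odds).
#' @param burnInFrac,poolFrac see [trimAndPool()].
#' @param mass HPD mass.
#' @param mpsrfThreshold convergence gate (default 1.1; exceeding it warns).
#' @param generationYears,sampleAgeYears see [calibrateTime()].
#' @param referenceYearsBP if given, the fraction of pooled T samples (in
#'   years) older than this value is reported as \code{massBeforeReference}
#'   (e.g. years between sampling and an 1850 settlement horizon).
#' @return one-row data.frame.
#' @export
summarizePosterior <- function(chains, priorSamples, burnInFrac = 0.1,
                               poolFrac = 0.5, mass = 0.90,
                               mpsrfThreshold = 1.1, generationYears = 5,
                               sampleAgeYears = 0, referenceYearsBP = NULL) {
  tp <- trimAndPool(chains, burnInFrac, poolFrac)
  mp <- if (length(chains) >= 2) mpsrf(tp$diagnostics) else NA_real_
  if (!is.na(mp) && mp > mpsrfThreshold)
    warning(sprintf("MPSRF %.3f exceeds threshold %.2f: chains may not have converged",
                    mp, mpsrfThreshold))
  pooled <- tp$pooled
  rPost <- 10^(pooled[, "log10N0"] - pooled[, "log10N1"])
  rPrior <- 10^(priorSamples[, "log10N0"] - priorSamples[, "log10N1"])
  bf <- bayesFactorDecline(rPost, rPrior)
  h <- function(v) hpdAndMode(v, mass)
  hN0 <- 10^h(pooled[, "log10N0"])
  hN1 <- 10^h(pooled[, "log10N1"])
  hT <- calibrateTime(10^h(pooled[, "log10T"]), generationYears,
                      sampleAgeYears)
  hr <- h(log10(rPost))
  Tyears <- calibrateTime(10^pooled[, "log10T"], generationYears,
                          sampleAgeYears)
  # column order follows the conventional report: BF, scale (shape), N0,
  # N1, time, then the ratio and diagnostics
  out <- data.frame(
    BF = bf$bf, bfCategory = bf$category, shape = chains[[1]]@shape,
    N0mode = hN0["mode"], N0lo = hN0["lo"], N0hi = hN0["hi"],
    N1mode = hN1["mode"], N1lo = hN1["lo"], N1hi = hN1["hi"],
    TyearsMode = hT["mode"], TyearsLo = hT["lo"], TyearsHi = hT["hi"],
    rMode = 10^hr["mode"], posteriorMassDecline = bf$posteriorFraction,
    nChains = length(chains), mpsrf = mp,
    stringsAsFactors = FALSE)
  if (!is.null(referenceYearsBP))
    out$massBeforeReference <- mean(Tyears > referenceYearsBP)
  rownames(out) <- NULL
  out
}
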
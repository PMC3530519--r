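## Bayesian inference of a single effective-population-size change from
## microsatellite genotypes: Metropolis-Hastings over per-locus latent
## genealogies (topology, node times, internal allele states) and the
## demographic parameters (N0, N1, T) with hierarchical log-normal priors,
## strict stepwise mutation inside the likelihood, and theta = 2 N0 mu.

#' Log-probability of a net allele-size displacement
#'
#' Transition kernel of the strict stepwise mutation model along a branch:
#' with Poisson(m) mutations of +/-1 (equal probability), the net
#' displacement d follows a Skellam law with both rates m/2, so
#' P(d) = exp(-m) I_|d|(m). Evaluated in the log domain, stable for large m
#' and for far tails (series fallback where the scaled Bessel underflows).
#'
#' @param sizeDelta integer net displacement(s).
#' @param expectedMutations expected mutation count m = mu * branch length
#'   (>= 0).
#' @return log probability (vector over \code{sizeDelta}).
#' @export
branchTransitionLogProb <- function(sizeDelta, expectedMutations) {
  stopifnot(expectedMutations >= 0)
  skellam_logpmf_cpp(as.integer(sizeDelta), expectedMutations)
}

#' Coalescent + mutation log-likelihood of one genealogy
#'
#' The two likelihood parts of the size-change model for a single locus:
#' \code{coal}, the coalescent log-density of the node times under the
#' trajectory (via the closed-form cumulative intensity), and \code{mut},
#' the sum of stepwise-mutation transition log-probabilities over branches.
#' Returns -Inf components for invalid states (negative branch lengths).
#'
#' @param parent integer vector of 0-based parent indices (-1 at the root).
#' @param times node times in generations (leaves first, at 0).
#' @param states integer node allele sizes (leaf states = observed).
#' @param nLeaf number of leaves.
#' @param traj a [DemographicTrajectory-class].
#' @param mu per-generation mutation rate.
#' @return list with \code{coal} and \code{mut} log-likelihood parts.
#' @export
genealogyLogLik <- function(parent, times, states, nLeaf, traj, mu) {
  tree_loglik_cpp(as.integer(parent), as.numeric(times), as.integer(states),
                  as.integer(nLeaf), traj@N0, traj@N1, traj@T,
                  shapeCode(traj@shape), mu)
}

#' Prior specification for the size-change model
#'
#' Hierarchical log-normal priors: each of log10(N0), log10(N1), log10(T in
#' generations) and log10(theta) is normal with mean and SD themselves drawn
#' from hyperpriors (the SD's hyperprior is a normal truncated at zero). All
#' values are on the log10 scale.
#'
#' @param N0,N1,T,theta lists with elements \code{meanMean}, \code{meanSD},
#'   \code{sdMean}, \code{sdSD}.
#' @return a validated list of class \code{priorSpec}.
#' @export
priorSpec <- function(
    N0 = list(meanMean = 3, meanSD = 1, sdMean = 0.5, sdSD = 0.25),
    N1 = list(meanMean = 3, meanSD = 1, sdMean = 0.5, sdSD = 0.25),
    T = list(meanMean = 3, meanSD = 1, sdMean = 0.5, sdSD = 0.25),
    theta = list(meanMean = -0.5, meanSD = 1, sdMean = 0.5, sdSD = 0.25)) {
  pr <- list(N0 = N0, N1 = N1, T = T, theta = theta)
  for (x in names(pr)) {
    p <- pr[[x]]
    stopifnot(all(c("meanMean", "meanSD", "sdMean", "sdSD") %in% names(p)))
    if (p$meanSD <= 0 || p$sdMean <= 0 || p$sdSD < 0)
      stop("priorSpec: SDs must be positive (sdSD may be 0 for a fixed ",
           "prior SD)")
  }
  class(pr) <- "priorSpec"
  pr
}

## normal truncated at zero (for prior SDs)
rtrunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= 0) break
    }
    out[i] <- v
  }
  out
}

#' Sample the hierarchical prior
#'
#' Direct iid draws from the prior of (log10 N0, log10 N1, log10 T,
#' log10 theta): hyperparameters first, then the parameter. Used for prior
#' odds in Bayes factors and for prior-recovery checks.
#'
#' @param priors a [priorSpec()] list.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return matrix with columns log10N0, log10N1, log10T, log10theta.
#' @export
rpriorSamples <- function(priors, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(p) {
    m <- stats::rnorm(n, p$meanMean, p$meanSD)
    s <- rtrunc0(n, p$sdMean, p$sdSD)
    stats::rnorm(n, m, s)
  }
  out <- cbind(log10N0 = draw(priors$N0), log10N1 = draw(priors$N1),
               log10T = draw(priors$T), log10theta = draw(priors$theta))
  out
}

## extract per-locus leaf states (typed gene copies) for polymorphic loci
extractLoci <- function(data) {
  if (is.null(data)) return(list())
  out <- list()
  for (l in seq_len(nLoc(data))) {
    v <- c(data@allele1[, l], data@allele2[, l])
    v <- v[!is.na(v)]
    if (length(v) >= 4 && length(unique(v)) >= 2) {
      out[[locNames(data)[l]]] <- as.integer(v)
    }
  }
  out
}

#' Run one MCMC chain of the size-change model
#'
#' Metropolis-Hastings sampler whose stationary distribution is the
#' posterior of (N0, N1, T, per-locus theta) and the latent genealogies
#' given the genotypes. Move set per sweep: node-time slides, a root-gap
#' scaling move, wide-exchange topology swaps and internal-state random
#' walks for every locus genealogy; log10-scale random walks for the
#' demographic parameters and per-locus thetas; Gibbs updates of the prior
#' means and random-walk updates of the prior SDs (hierarchical mode).
#' Proposal step sizes adapt during the first \code{adaptFrac} of the run
#' only and are frozen afterwards, preserving detailed balance of the
#' recorded portion. With no polymorphic loci the chain samples the prior,
#' the standard correctness check.
#'
#' @param data a [GenotypeDataset-class] slice (one population), or NULL for
#'   a prior-only run.
#' @param priors a [priorSpec()] list.
#' @param shape "exponential" or "linear" size change.
#' @param iterations number of sweeps.
#' @param thinning sweeps between records.
#' @param seed integer seed (chains with distinct seeds are independent).
#' @param hierarchical update hyperparameters (TRUE) or keep the prior
#'   means/SDs fixed at their hyperprior means (FALSE).
#' @param adaptFrac fraction of the run used for step-size adaptation.
#' @return a [PosteriorChains-class] with one record every
#'   \code{thinning} sweeps.
#' @export
runChain <- function(data, priors = priorSpec(),
                     shape = c("exponential", "linear"),
                     iterations = 20000, thinning = 10, seed = 1,
                     hierarchical = TRUE, adaptFrac = 0.2) {
  shape <- match.arg(shape)
  if (iterations < thinning) stop("iterations < thinning")
  set.seed(seed)
  sc <- shapeCode(shape)
  leafList <- extractLoci(data)
  L <- length(leafList)

  ## hyper state: prior mean m and sd s per parameter class
  hyp <- lapply(priors, function(p) list(m = p$meanMean, s = p$sdMean))
  ## parameter state (log10); with data, start from moment anchors: the
  ## current-scale theta from heterozygosity (Ohta-Kimura inverse) per locus
  ## and the N1/N0 ratio from the ancestral-scale theta (mean squared
  ## pairwise size difference) -- any valid start is correct in the limit,
  ## this one just shortens burn-in
  par <- c(N0 = hyp$N0$m, N1 = hyp$N1$m, T = hyp$T$m)
  nTheta <- max(L, 1L)
  thetas <- rep(hyp$theta$m, nTheta)
  if (L > 0) {
    thCur <- thAnc <- numeric(L)
    for (l in seq_len(L)) {
      v <- leafList[[l]]
      p <- as.vector(table(v)) / length(v)
      he <- (length(v) / (length(v) - 1)) * (1 - sum(p^2))
      thCur[l] <- max(0.02, ((1 / (1 - min(he, 0.98)))^2 - 1) / 2)
      msd <- 2 * length(v) / (length(v) - 1) * stats::var(v) *
        (length(v) - 1) / length(v)
      thAnc[l] <- max(0.02, msd)
    }
    thetas <- log10(thCur / 2)
    ratio <- min(2.5, max(-2.5, log10(mean(thAnc) / mean(thCur))))
    par["N1"] <- par["N0"] + ratio
  }

  muOf <- function(th, l10N0) 10^th / (2 * 10^l10N0)

  trees <- NULL
  coalLL <- mutLL <- numeric(L)
  if (L > 0) {
    trees <- vector("list", L)
    for (l in seq_len(L)) {
      trees[[l]] <- init_tree_cpp(leafList[[l]], 10^par["N0"], 10^par["N1"],
                                  10^par["T"], sc)
      tl <- tree_loglik_cpp(trees[[l]]$parent, trees[[l]]$times,
                            trees[[l]]$states, length(leafList[[l]]),
                            10^par["N0"], 10^par["N1"], 10^par["T"], sc,
                            muOf(thetas[l], par["N0"]))
      coalLL[l] <- tl$coal
      mutLL[l] <- tl$mut
    }
  }

  steps <- c(N0 = 0.15, N1 = 0.2, T = 0.25, theta = 0.12, s = 0.1,
             shift = 0.4)
  acc <- prop <- c(N0 = 0, N1 = 0, T = 0, theta = 0, s = 0, shift = 0,
                   exchange = 0, time = 0, swap = 0, state = 0)
  accWin <- propWin <- acc

  lpPrior <- function(par, thetas, hyp) {
    stats::dnorm(par["N0"], hyp$N0$m, hyp$N0$s, log = TRUE) +
      stats::dnorm(par["N1"], hyp$N1$m, hyp$N1$s, log = TRUE) +
      stats::dnorm(par["T"], hyp$T$m, hyp$T$s, log = TRUE) +
      sum(stats::dnorm(thetas, hyp$theta$m, hyp$theta$s, log = TRUE))
  }

  nRec <- floor(iterations / thinning)
  rec <- matrix(NA_real_, nRec, 4,
                dimnames = list(NULL, c("log10N0", "log10N1", "log10T",
                                        "log10theta")))
  ri <- 0L
  adaptUntil <- floor(adaptFrac * iterations)

  for (it in seq_len(iterations)) {
    ## --- genealogy sweeps ------------------------------------------------
    if (L > 0) {
      for (l in seq_len(L)) {
        nl <- length(leafList[[l]])
        nT <- max(3L, nl %/% 2L)   # local moves scale with tree size,
        nW <- max(2L, nl %/% 3L)   # else large genealogies barely mix
        nS <- max(1L, nl %/% 6L)
        res <- tree_sweep_cpp(trees[[l]]$parent, trees[[l]]$times,
                              trees[[l]]$states, nl,
                              10^par["N0"], 10^par["N1"], 10^par["T"], sc,
                              muOf(thetas[l], par["N0"]),
                              nT, nW, nS, 0.7, coalLL[l], mutLL[l])
        coalLL[l] <- res[1]
        mutLL[l] <- res[2]
        acc["time"] <- acc["time"] + res[3]; prop["time"] <- prop["time"] + nT
        acc["swap"] <- acc["swap"] + res[4]; prop["swap"] <- prop["swap"] + nW
        acc["state"] <- acc["state"] + res[5]; prop["state"] <- prop["state"] + nS
      }
    }

    ## --- demographic parameters -----------------------------------------
    for (pn in c("N0", "N1", "T")) {
      cand <- par
      cand[pn] <- par[pn] + stats::rnorm(1, 0, steps[pn])
      dlp <- stats::dnorm(cand[pn], hyp[[pn]]$m, hyp[[pn]]$s, log = TRUE) -
             stats::dnorm(par[pn], hyp[[pn]]$m, hyp[[pn]]$s, log = TRUE)
      newCoal <- coalLL
      newMut <- mutLL
      if (L > 0) {
        if (pn == "N0") {
          for (l in seq_len(L)) {
            tl <- tree_loglik_cpp(trees[[l]]$parent, trees[[l]]$times,
                                  trees[[l]]$states, length(leafList[[l]]),
                                  10^cand["N0"], 10^cand["N1"], 10^cand["T"],
                                  sc, muOf(thetas[l], cand["N0"]))
            newCoal[l] <- tl$coal
            newMut[l] <- tl$mut
          }
        } else {
          for (l in seq_len(L)) {
            newCoal[l] <- coal_loglik_cpp(trees[[l]]$times,
                                          length(leafList[[l]]),
                                          10^cand["N0"], 10^cand["N1"],
                                          10^cand["T"], sc)
          }
        }
        dlp <- dlp + sum(newCoal - coalLL) + sum(newMut - mutLL)
      }
      propWin[pn] <- propWin[pn] + 1; prop[pn] <- prop[pn] + 1
      if (is.finite(dlp) && (dlp >= 0 || stats::runif(1) < exp(dlp))) {
        par <- cand
        coalLL <- newCoal
        mutLL <- newMut
        acc[pn] <- acc[pn] + 1
        accWin[pn] <- accWin[pn] + 1
      }
    }

    ## --- joint scale shift ------------------------------------------------
    ## shifting (log10 N0, log10 N1, log10 T) and all genealogy times by a
    ## common log10 delta leaves the likelihood exactly invariant (the
    ## coalescent density change cancels against the time Jacobian and
    ## mu = theta / (2 N0) rescales against branch lengths), so the move is
    ## accepted on the prior ratio alone; it traverses the scale ridge that
    ## otherwise dominates the autocorrelation of this model.
    {
      delta <- stats::rnorm(1, 0, steps["shift"])
      dlp <- sum(vapply(c("N0", "N1", "T"), function(pn)
        stats::dnorm(par[pn] + delta, hyp[[pn]]$m, hyp[[pn]]$s, log = TRUE) -
        stats::dnorm(par[pn], hyp[[pn]]$m, hyp[[pn]]$s, log = TRUE),
        numeric(1)))
      propWin["shift"] <- propWin["shift"] + 1
      prop["shift"] <- prop["shift"] + 1
      if (is.finite(dlp) && (dlp >= 0 || stats::runif(1) < exp(dlp))) {
        par <- par + delta
        if (L > 0) {
          u <- 10^delta
          for (l in seq_len(L)) {
            trees[[l]]$times <- trees[[l]]$times * u
            coalLL[l] <- coalLL[l] -
              (length(leafList[[l]]) - 1) * log(u)
          }
        }
        acc["shift"] <- acc["shift"] + 1
        accWin["shift"] <- accWin["shift"] + 1
      }
    }

    ## --- N0 <-> N1 exchange -----------------------------------------------
    ## symmetric swap of the two sizes; lets the chain cross the r = 1
    ## boundary between decline-like and expansion-like modes
    {
      cand <- par
      cand["N0"] <- par["N1"]
      cand["N1"] <- par["N0"]
      dlp <- stats::dnorm(cand["N0"], hyp$N0$m, hyp$N0$s, log = TRUE) +
             stats::dnorm(cand["N1"], hyp$N1$m, hyp$N1$s, log = TRUE) -
             stats::dnorm(par["N0"], hyp$N0$m, hyp$N0$s, log = TRUE) -
             stats::dnorm(par["N1"], hyp$N1$m, hyp$N1$s, log = TRUE)
      newCoal <- coalLL
      newMut <- mutLL
      if (L > 0) {
        for (l in seq_len(L)) {
          tl <- tree_loglik_cpp(trees[[l]]$parent, trees[[l]]$times,
                                trees[[l]]$states, length(leafList[[l]]),
                                10^cand["N0"], 10^cand["N1"], 10^cand["T"],
                                sc, muOf(thetas[l], cand["N0"]))
          newCoal[l] <- tl$coal
          newMut[l] <- tl$mut
        }
        dlp <- dlp + sum(newCoal - coalLL) + sum(newMut - mutLL)
      }
      prop["exchange"] <- prop["exchange"] + 1
      if (is.finite(dlp) && (dlp >= 0 || stats::runif(1) < exp(dlp))) {
        par <- cand
        coalLL <- newCoal
        mutLL <- newMut
        acc["exchange"] <- acc["exchange"] + 1
      }
    }

    ## --- per-locus theta --------------------------------------------------
    for (l in seq_len(nTheta)) {
      cand <- thetas[l] + stats::rnorm(1, 0, steps["theta"])
      dlp <- stats::dnorm(cand, hyp$theta$m, hyp$theta$s, log = TRUE) -
             stats::dnorm(thetas[l], hyp$theta$m, hyp$theta$s, log = TRUE)
      newMut <- NA_real_
      if (L > 0) {
        newMut <- mut_loglik_cpp(trees[[l]]$parent, trees[[l]]$times,
                                 trees[[l]]$states, muOf(cand, par["N0"]))
        dlp <- dlp + newMut - mutLL[l]
      }
      propWin["theta"] <- propWin["theta"] + 1
      prop["theta"] <- prop["theta"] + 1
      if (is.finite(dlp) && (dlp >= 0 || stats::runif(1) < exp(dlp))) {
        thetas[l] <- cand
        if (L > 0) mutLL[l] <- newMut
        acc["theta"] <- acc["theta"] + 1
        accWin["theta"] <- accWin["theta"] + 1
      }
    }

    ## --- hyperparameters --------------------------------------------------
    if (hierarchical) {
      vals <- list(N0 = par["N0"], N1 = par["N1"], T = par["T"],
                   theta = thetas)
      for (x in names(vals)) {
        v <- vals[[x]]
        p <- priors[[x]]
        h <- hyp[[x]]
        ## Gibbs for the prior mean (normal-normal conjugacy)
        prec <- 1 / p$meanSD^2 + length(v) / h$s^2
        mpost <- (p$meanMean / p$meanSD^2 + sum(v) / h$s^2) / prec
        h$m <- stats::rnorm(1, mpost, sqrt(1 / prec))
        ## MH for the truncated-normal prior SD
        if (p$sdSD > 0) {
          sCand <- h$s + stats::rnorm(1, 0, steps["s"])
          propWin["s"] <- propWin["s"] + 1; prop["s"] <- prop["s"] + 1
          if (sCand > 0) {
            dlp <- sum(stats::dnorm(v, h$m, sCand, log = TRUE)) -
                   sum(stats::dnorm(v, h$m, h$s, log = TRUE)) +
                   stats::dnorm(sCand, p$sdMean, p$sdSD, log = TRUE) -
                   stats::dnorm(h$s, p$sdMean, p$sdSD, log = TRUE)
            if (is.finite(dlp) && (dlp >= 0 || stats::runif(1) < exp(dlp))) {
              h$s <- sCand
              acc["s"] <- acc["s"] + 1
              accWin["s"] <- accWin["s"] + 1
            }
          }
        }
        hyp[[x]] <- h
      }
    }

    ## --- step-size adaptation (burn-in only) ------------------------------
    if (it <= adaptUntil && it %% 50 == 0) {
      for (pn in names(steps)) {
        if (propWin[pn] > 0) {
          rate <- accWin[pn] / propWin[pn]
          steps[pn] <- min(2, max(0.01, steps[pn] * exp(0.6 * (rate - 0.3))))
        }
      }
      accWin[] <- 0
      propWin[] <- 0
    }

    if (it %% thinning == 0) {
      ri <- ri + 1L
      rec[ri, ] <- c(par["N0"], par["N1"], par["T"], mean(thetas))
    }
  }

  new("PosteriorChains", records = rec[seq_len(ri), , drop = FALSE],
      iterations = iterations, thinning = thinning, seed = seed,
      shape = shape, nLoci = L,
      acceptance = ifelse(prop > 0, acc / prop, NA_real_),
      priors = unclass(priors))
}

#' Run replicate chains with independent seeds
#'
#' @inheritParams runChain
#' @param nChains number of chains (conventionally 5).
#' @param seed master seed; chain i uses a derived sub-seed.
#' @param ... passed to [runChain()].
#' @return list of [PosteriorChains-class].
#' @export
runReplicated <- function(data, priors = priorSpec(),
                          shape = c("exponential", "linear"), nChains = 5,
                          seed = 1, ...) {
  shape <- match.arg(shape)
  lapply(seq_len(nChains), function(i) {
    runChain(data, priors = priors, shape = shape,
             seed = deriveSeed(seed, i), ...)
  })
}

#' @rdname PosteriorChains-accessors
#' @param x a [PosteriorChains-class].
#' @export
setMethod("chainRecords", "PosteriorChains", function(x) x@records)

setMethod("show", "PosteriorChains", function(object) {
  cat(sprintf(paste0("PosteriorChains: %d records (%g sweeps, thin %g), ",
                     "%s model, %d loci, seed %g\n"),
              nrow(object@records), object@iterations, object@thinning,
              object@shape, object@nLoci, object@seed))
  cat("  acceptance:",
      paste(sprintf("%s %.2f", names(object@acceptance), object@acceptance),
            collapse = ", "), "\n")
})
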
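## Summary statistics and exact tests for microsatellite genotypes.
## All estimators work on allele sizes in repeat units as stored in a
## GenotypeDataset; tests condition on allele counts so the lattice scale
## is irrelevant to them.

#' Nei's unbiased expected heterozygosity
#'
#' \code{He = (2n / (2n - 1)) * (1 - sum(p_i^2))} where \code{2n} is the
#' number of gene copies and \code{p_i} the sample allele frequencies.
#'
#' @param counts named integer vector of allele counts at one locus (as one
#'   element of [alleleCounts()]).
#' @return He in [0, 1].
#' @examples
#' unbiasedHe(c(A = 10, B = 10))  # (20/19) * 0.5
#' @export
unbiasedHe <- function(counts) {
  n2 <- sum(counts)
  if (n2 < 1) stop("unbiasedHe: zero gene copies")
  if (n2 == 1) return(0)
  p <- counts / n2
  (n2 / (n2 - 1)) * (1 - sum(p^2))
}

#' Per-locus expected heterozygosity for one group
#'
#' @param x a [GenotypeDataset-class].
#' @param population,deme optional group selectors.
#' @return named numeric vector of unbiased He per locus (NA where no gene
#'   copies are typed).
#' @export
heByLocus <- function(x, population = NULL, deme = NULL) {
  ac <- alleleCounts(x, population = population, deme = deme)
  vapply(ac, function(ct) if (length(ct)) unbiasedHe(ct) else NA_real_,
         numeric(1))
}

## Weir-Cockerham variance components for one locus.
## Returns per-allele components a (among populations; NULL when r = 1),
## b (among individuals within populations) and c (within individuals).
wcComponents <- function(a1, a2, grp) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]; grp <- factor(grp[keep])
  grp <- droplevels(grp)
  r <- nlevels(grp)
  if (length(a1) == 0 || r < 1) return(NULL)
  ni <- as.vector(table(grp))
  if (any(ni < 1)) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(NULL)  # monomorphic: no information
  nbar <- mean(ni)
  if (nbar <= 1) return(NULL)
  A <- length(alleles)
  avec <- bvec <- cvec <- numeric(A)
  if (r >= 2) {
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  } else {
    nc <- NA_real_
  }
  for (k in seq_len(A)) {
    al <- alleles[k]
    # per-population allele frequency and heterozygote (for al) frequency
    pi <- tapply((a1 == al) + (a2 == al), grp, sum) / (2 * ni)
    hi <- tapply((a1 == al) != (a2 == al), grp, sum) / ni
    pbar <- sum(ni * pi) / (r * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    if (r >= 2) {
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      avec[k] <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      bvec[k] <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    } else {
      avec[k] <- 0
      bvec[k] <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - hbar * (2 * nbar - 1) / (4 * nbar))
    }
    cvec[k] <- hbar / 2
  }
  list(a = avec, b = bvec, c = cvec, r = r)
}

#' Weir-Cockerham inbreeding coefficient (small f)
#'
#' Multi-locus Weir-Cockerham estimator of F_IS for a single group, combined
#' across loci and alleles as a ratio of sums of variance components.
#' Positive values indicate a deficit of heterozygotes (e.g. a Wahlund
#' effect from pooling differentiated demes); -1 means every individual is
#' heterozygous.
#'
#' @param x a [GenotypeDataset-class].
#' @param population,deme optional group selectors.
#' @param nPerm if > 0, a one-tailed permutation p-value for heterozygote
#'   deficit (f > 0) is computed by shuffling gene copies among the
#'   individuals typed at each locus.
#' @return the estimate, with attributes \code{p.value} (if requested).
#' @export
fisWC <- function(x, population = NULL, deme = NULL, nPerm = 0) {
  g <- subsetGroup(x, population = population, deme = deme)
  if (nInd(g) < 2) stop("fisWC: need at least 2 typed individuals")
  fstat <- function(a1m, a2m) {
    sb <- sc <- 0
    for (l in seq_len(ncol(a1m))) {
      comp <- wcComponents(a1m[, l], a2m[, l], rep("g", nrow(a1m)))
      if (is.null(comp)) next
      sb <- sb + sum(comp$b)
      sc <- sc + sum(comp$c)
    }
    if (sb + sc == 0) return(NA_real_)
    1 - sc / (sb + sc)
  }
  f <- fstat(g@allele1, g@allele2)
  if (is.na(f)) stop("fisWC: all loci monomorphic, f undefined")
  if (nPerm > 0) {
    cnt <- 0L
    for (b in seq_len(nPerm)) {
      p1 <- g@allele1; p2 <- g@allele2
      for (l in seq_len(nLoc(g))) {
        typed <- which(!is.na(p1[, l]))
        pool <- sample(c(p1[typed, l], p2[typed, l]))
        k <- length(typed)
        x1 <- pool[seq_len(k)]
        x2 <- pool[k + seq_len(k)]
        p1[typed, l] <- pmin(x1, x2)
        p2[typed, l] <- pmax(x1, x2)
      }
      if (!is.na(fp <- fstat(p1, p2)) && fp >= f) cnt <- cnt + 1L
    }
    attr(f, "p.value") <- (cnt + 1) / (nPerm + 1)
  }
  f
}

#' Weir-Cockerham theta (F_ST)
#'
#' Variance-components estimator of F_ST combined across loci and alleles as
#' a ratio of sums. Slightly negative estimates are reported as computed.
#'
#' @param x a [GenotypeDataset-class] holding all groups.
#' @param by \code{"population"} or \code{"deme"}: which labels define the
#'   groups.
#' @param pairwise also compute all pairwise estimates.
#' @return list with \code{global} (multi-locus theta), \code{perLocus}, and
#'   (optionally) \code{pairwise} (symmetric matrix).
#' @export
fstWC <- function(x, by = c("population", "deme"), pairwise = FALSE) {
  by <- match.arg(by)
  grp <- if (by == "population") populations(x) else demes(x)
  if (length(unique(grp[!is.na(grp)])) < 2)
    stop("fstWC: need at least 2 groups")
  theta_of <- function(idx) {
    sa <- sabc <- 0
    perLocus <- rep(NA_real_, nLoc(x))
    for (l in seq_len(nLoc(x))) {
      comp <- wcComponents(x@allele1[idx, l], x@allele2[idx, l], grp[idx])
      if (is.null(comp) || comp$r < 2) next
      la <- sum(comp$a)
      lt <- sum(comp$a + comp$b + comp$c)
      if (lt > 0) perLocus[l] <- la / lt
      sa <- sa + la
      sabc <- sabc + lt
    }
    if (sabc == 0) stop("fstWC: no polymorphic locus shared by the groups")
    list(global = sa / sabc, perLocus = stats::setNames(perLocus, locNames(x)))
  }
  res <- theta_of(seq_len(nInd(x)))
  if (pairwise) {
    gs <- unique(grp[!is.na(grp)])
    pw <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
    for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
      idx <- which(grp %in% gs[c(i, j)])
      pw[i, j] <- pw[j, i] <- theta_of(idx)$global
    }
    res$pairwise <- pw
  }
  res
}

#' Allele-size based differentiation (R_ST)
#'
#' R_ST analog of F_ST: among-group versus total variance in allele size
#' (repeat units), estimated by a weighted one-way ANOVA on gene copies with
#' the same ratio-of-sums multi-locus combination as [fstWC()]. Appropriate
#' for markers evolving by stepwise mutation, where allele size carries
#' information that allele identity does not.
#'
#' @inheritParams fstWC
#' @return list with \code{global}, \code{perLocus} and optionally
#'   \code{pairwise}.
#' @export
rst <- function(x, by = c("population", "deme"), pairwise = FALSE) {
  by <- match.arg(by)
  grp <- if (by == "population") populations(x) else demes(x)
  if (length(unique(grp[!is.na(grp)])) < 2) stop("rst: need at least 2 groups")
  comps <- function(y, g) {
    keep <- !is.na(y) & !is.na(g)
    y <- y[keep]; g <- droplevels(factor(g[keep]))
    r <- nlevels(g)
    if (r < 2 || length(unique(y)) < 2) return(NULL)
    ni <- as.vector(table(g))
    N <- length(y)
    ybar <- mean(y)
    mi <- tapply(y, g, mean)
    ssb <- sum(ni * (mi - ybar)^2)
    ssw <- sum((y - mi[g])^2)
    if (N - r <= 0) return(NULL)
    msb <- ssb / (r - 1)
    msw <- ssw / (N - r)
    n0 <- (N - sum(ni^2) / N) / (r - 1)
    s2a <- (msb - msw) / n0
    list(a = s2a, w = msw)
  }
  rst_of <- function(idx) {
    sa <- st <- 0
    perLocus <- rep(NA_real_, nLoc(x))
    for (l in seq_len(nLoc(x))) {
      y <- c(x@allele1[idx, l], x@allele2[idx, l])
      g <- rep(grp[idx], 2)
      cc <- comps(y, g)
      if (is.null(cc)) next
      if (cc$a + cc$w > 0) perLocus[l] <- cc$a / (cc$a + cc$w)
      sa <- sa + cc$a
      st <- st + cc$a + cc$w
    }
    if (st == 0) stop("rst: no polymorphic locus shared by the groups")
    list(global = sa / st, perLocus = stats::setNames(perLocus, locNames(x)))
  }
  res <- rst_of(seq_len(nInd(x)))
  if (pairwise) {
    gs <- unique(grp[!is.na(grp)])
    pw <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
    for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
      idx <- which(grp %in% gs[c(i, j)])
      pw[i, j] <- pw[j, i] <- rst_of(idx)$global
    }
    res$pairwise <- pw
  }
  res
}

## ---- exact tests -----------------------------------------------------

## log conditional probability of a diploid genotype table given its allele
## counts under Hardy-Weinberg (Levene 1949):
## P = n! 2^h prod(c_a!) / (prod g_ab! (2n)!)
logProbGenotypeTable <- function(gt) {
  # gt: symmetric matrix of genotype counts (upper triangle used)
  k <- nrow(gt)
  n <- 0; h <- 0; lgt <- 0
  cnt <- numeric(k)
  for (a in seq_len(k)) for (b in a:k) {
    g <- gt[a, b]
    n <- n + g
    lgt <- lgt + lgamma(g + 1)
    if (a != b) h <- h + g
    cnt[a] <- cnt[a] + g
    cnt[b] <- cnt[b] + g
  }
  lgamma(n + 1) + h * log(2) + sum(lgamma(cnt + 1)) - lgt - lgamma(2 * n + 1)
}

## enumerate all genotype tables with the allele counts of `gt`, calling
## fun(table) for each; used for exact p-values and as its own oracle in
## tests at tiny n
enumGenotypeTables <- function(alleleCounts, fun) {
  k <- length(alleleCounts)
  gt <- matrix(0L, k, k)
  cells <- which(upper.tri(gt, diag = TRUE), arr.ind = TRUE)
  rec <- function(ci, rem) {
    if (ci > nrow(cells)) {
      if (all(rem == 0L)) fun(gt)
      return(invisible(NULL))
    }
    a <- cells[ci, 1]; b <- cells[ci, 2]
    mx <- if (a == b) rem[a] %/% 2L else min(rem[a], rem[b])
    for (g in 0:mx) {
      gt[a, b] <<- g
      gt[b, a] <<- g
      rem2 <- rem
      rem2[a] <- rem2[a] - g
      rem2[b] <- rem2[b] - g
      if (a == b) rem2[a] <- rem[a] - 2L * g
      if (all(rem2 >= 0L)) rec(ci + 1L, rem2)
    }
    gt[a, b] <<- 0L
    gt[b, a] <<- 0L
  }
  rec(1L, as.integer(alleleCounts))
  invisible(NULL)
}

#' Exact test of Hardy-Weinberg proportions at one locus
#'
#' Conditional exact test in the spirit of Fisher's exact test: the
#' probability of the observed genotype table given its allele counts is
#' compared against all tables with the same allele counts; the p-value sums
#' the probabilities of tables no more probable than the observed one.
#' Complete enumeration is used when the table space is small, otherwise the
#' null is sampled directly by randomly re-pairing the observed gene copies
#' (each random pairing realizes a table with exactly its conditional null
#' probability).
#'
#' @param genotypes n x 2 integer matrix of allele sizes at one locus
#'   (rows = individuals; NA rows dropped), e.g. from [alleles()].
#' @param method "auto", "enumeration" or "monte_carlo".
#' @param reps Monte Carlo replicates.
#' @return list with \code{p.value}, \code{method} and \code{testable}
#'   (FALSE for monomorphic loci or a single individual, where p = 1 by
#'   convention).
#' @export
hweExact <- function(genotypes, method = c("auto", "enumeration",
                                           "monte_carlo"), reps = 10000) {
  method <- match.arg(method)
  gtm <- genotypes[stats::complete.cases(genotypes), , drop = FALSE]
  n <- nrow(gtm)
  alleles <- sort(unique(c(gtm)))
  k <- length(alleles)
  if (n < 2 || k < 2) {
    return(list(p.value = 1, method = "untestable", testable = FALSE))
  }
  ai <- matrix(match(gtm, alleles), ncol = 2)
  gt <- matrix(0L, k, k)
  for (i in seq_len(n)) {
    a <- min(ai[i, ]); b <- max(ai[i, ])
    gt[a, b] <- gt[a, b] + 1L
    gt[b, a] <- gt[a, b]
  }
  cnt <- tabulate(ai, nbins = k)
  lp_obs <- logProbGenotypeTable(gt)
  if (method == "auto") {
    method <- if (2 * n <= 12 || (k <= 3 && n <= 20)) "enumeration"
              else "monte_carlo"
  }
  if (method == "enumeration") {
    tot <- 0
    enumGenotypeTables(cnt, function(tb) {
      lp <- logProbGenotypeTable(tb)
      if (lp <= lp_obs + 1e-9) tot <<- tot + exp(lp)
    })
    p <- min(1, tot)
  } else {
    pool <- c(ai)
    hits <- 0L
    for (b in seq_len(reps)) {
      perm <- sample(pool)
      s1 <- perm[seq_len(n)]
      s2 <- perm[n + seq_len(n)]
      tb <- matrix(0L, k, k)
      for (i in seq_len(n)) {
        lo <- min(s1[i], s2[i]); hi <- max(s1[i], s2[i])
        tb[lo, hi] <- tb[lo, hi] + 1L
      }
      tb[lower.tri(tb)] <- t(tb)[lower.tri(tb)]
      if (logProbGenotypeTable(tb) <= lp_obs + 1e-9) hits <- hits + 1L
    }
    p <- (hits + 1) / (reps + 1)
  }
  list(p.value = p, method = method, testable = TRUE)
}

## log multivariate hypergeometric probability of a contingency table with
## fixed margins
logProbContingency <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

## enumerate all tables with the margins of `tab`
enumContingencyTables <- function(rs, cs, fun) {
  R <- length(rs); C <- length(cs)
  tb <- matrix(0L, R, C)
  rec <- function(i, j, rrem, crem) {
    if (i > R) {
      if (all(crem == 0L)) fun(tb)
      return(invisible(NULL))
    }
    ni <- if (j < C) i else i + 1L
    nj <- if (j < C) j + 1L else 1L
    if (j == C) {
      v <- rrem[i]
      if (v <= crem[j]) {
        tb[i, j] <<- v
        cr <- crem; cr[j] <- cr[j] - v
        rr <- rrem; rr[i] <- 0L
        rec(ni, nj, rr, cr)
        tb[i, j] <<- 0L
      }
      return(invisible(NULL))
    }
    for (v in 0:min(rrem[i], crem[j])) {
      tb[i, j] <<- v
      rr <- rrem; rr[i] <- rr[i] - v
      cr <- crem; cr[j] <- cr[j] - v
      rec(ni, nj, rr, cr)
    }
    tb[i, j] <<- 0L
    invisible(NULL)
  }
  rec(1L, 1L, as.integer(rs), as.integer(cs))
  invisible(NULL)
}

#' Fisher-type exact test on a contingency table
#'
#' Probability-ordering exact test conditional on both margins: p sums the
#' multivariate hypergeometric probabilities of all tables no more probable
#' than the observed one. Enumeration for small tables; otherwise iid Monte
#' Carlo sampling of the null via [stats::r2dtable()].
#'
#' @param tab integer matrix of counts.
#' @param method "auto", "enumeration" or "monte_carlo".
#' @param reps Monte Carlo table count.
#' @return list with \code{p.value}, \code{method}, \code{testable}.
#' @export
contingencyExact <- function(tab, method = c("auto", "enumeration",
                                             "monte_carlo"), reps = 10000) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(p.value = 1, method = "untestable", testable = FALSE))
  }
  lp_obs <- logProbContingency(tab)
  if (method == "auto") {
    method <- if (sum(tab) <= 12 || prod(dim(tab)) <= 6) "enumeration"
              else "monte_carlo"
  }
  if (method == "enumeration") {
    tot <- 0
    enumContingencyTables(rowSums(tab), colSums(tab), function(tb) {
      lp <- logProbContingency(tb)
      if (lp <= lp_obs + 1e-9) tot <<- tot + exp(lp)
    })
    p <- min(1, tot)
  } else {
    sims <- stats::r2dtable(reps, rowSums(tab), colSums(tab))
    lps <- vapply(sims, logProbContingency, numeric(1))
    p <- (sum(lps <= lp_obs + 1e-9) + 1) / (reps + 1)
  }
  list(p.value = p, method = method, testable = TRUE)
}

#' Exact test of gametic (linkage) disequilibrium between two loci
#'
#' Genotypic association test: the contingency table of single-locus
#' genotypes at the two loci (individuals typed at both) is tested for
#' independence with [contingencyExact()].
#'
#' @param x a [GenotypeDataset-class].
#' @param locus1,locus2 locus names or indices.
#' @param population,deme optional group selectors.
#' @inheritParams contingencyExact
#' @return list with \code{p.value}, \code{method}, \code{testable}.
#' @export
ldExact <- function(x, locus1, locus2, population = NULL, deme = NULL,
                    method = "auto", reps = 10000) {
  g <- subsetGroup(x, population = population, deme = deme)
  g1 <- alleles(g, locus1)
  g2 <- alleles(g, locus2)
  keep <- stats::complete.cases(g1) & stats::complete.cases(g2)
  if (!any(keep)) return(list(p.value = 1, method = "untestable",
                              testable = FALSE))
  lab <- function(m) paste(m[, 1], m[, 2], sep = "/")
  tab <- table(lab(g1[keep, , drop = FALSE]), lab(g2[keep, , drop = FALSE]))
  contingencyExact(unclass(tab), method = method, reps = reps)
}

#' Exact test of genic differentiation between two groups
#'
#' Per locus, the 2 x (alleles) table of allele counts is tested for
#' homogeneity with [contingencyExact()]; per-locus p-values are combined
#' across loci with Fisher's method.
#'
#' @param x a [GenotypeDataset-class].
#' @param groups character vector of two population labels.
#' @param by group labels taken from populations or demes.
#' @inheritParams contingencyExact
#' @return list with \code{perLocus} p-values (NA where untestable) and
#'   \code{combined} Fisher's-method p.
#' @export
genicDiffExact <- function(x, groups, by = c("population", "deme"),
                           method = "auto", reps = 10000) {
  by <- match.arg(by)
  stopifnot(length(groups) == 2)
  sel <- function(g) {
    if (by == "population") subsetGroup(x, population = g)
    else subsetGroup(x, deme = g)
  }
  c1 <- alleleCounts(sel(groups[1]))
  c2 <- alleleCounts(sel(groups[2]))
  pv <- rep(NA_real_, nLoc(x))
  names(pv) <- locNames(x)
  for (l in seq_len(nLoc(x))) {
    als <- sort(unique(as.integer(c(names(c1[[l]]), names(c2[[l]])))))
    if (length(als) < 2) next
    tab <- rbind(c1[[l]][as.character(als)], c2[[l]][as.character(als)])
    tab[is.na(tab)] <- 0L
    res <- contingencyExact(tab, method = method, reps = reps)
    if (res$testable) pv[l] <- res$p.value
  }
  ok <- !is.na(pv)
  comb <- if (any(ok)) {
    stats::pchisq(-2 * sum(log(pv[ok])), df = 2 * sum(ok), lower.tail = FALSE)
  } else NA_real_
  list(perLocus = pv, combined = comb)
}

## ---- diversity -------------------------------------------------------

#' Rarefied allelic richness at one locus
#'
#' Expected number of alleles in a subsample of \code{g} gene copies:
#' \code{sum_i (1 - choose(N - N_i, g) / choose(N, g))}.
#'
#' @param counts allele count vector for one locus.
#' @param g rarefaction size in gene copies (must not exceed the available
#'   copies).
#' @return expected allele count (>= 1 for a typed locus).
#' @export
allelicRichness <- function(counts, g) {
  N <- sum(counts)
  if (g > N) stop("allelicRichness: g = ", g, " exceeds available copies ", N)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Diversity summary per group
#'
#' Per group (population by default): number of individuals, mean unbiased
#' expected heterozygosity across typed loci, Weir-Cockerham F_IS, mean
#' number of alleles per locus (A) and mean rarefied allelic richness (A_R)
#' at a common rarefaction size.
#'
#' @param x a [GenotypeDataset-class].
#' @param by group labels from populations or demes.
#' @param rarefactionSize gene copies used for allelic richness (default 8,
#'   i.e. 4 diploid individuals); capped at the smallest number of typed
#'   copies over groups and loci so that every cell is computable.
#' @param fisPerm permutations for the F_IS deficit p-value (0 = skip).
#' @return data.frame with one row per group (n, He, Fis, A, Ar) plus an
#'   attribute \code{rarefactionSize}.
#' @export
diversityTable <- function(x, by = c("population", "deme"),
                           rarefactionSize = 8, fisPerm = 0) {
  by <- match.arg(by)
  grp <- if (by == "population") populations(x) else demes(x)
  gs <- unique(grp[!is.na(grp)])
  countsList <- lapply(gs, function(g) {
    if (by == "population") alleleCounts(x, population = g)
    else alleleCounts(x, deme = g)
  })
  gmin <- min(unlist(lapply(countsList, function(cl)
    vapply(cl, sum, numeric(1)))))
  g <- min(rarefactionSize, gmin)
  rows <- lapply(seq_along(gs), function(i) {
    cl <- countsList[[i]]
    typed <- vapply(cl, sum, numeric(1)) > 0
    he <- mean(vapply(cl[typed], unbiasedHe, numeric(1)))
    A <- mean(vapply(cl[typed], length, numeric(1)))
    Ar <- mean(vapply(cl[typed], allelicRichness, numeric(1), g = g))
    sub <- if (by == "population") subsetGroup(x, population = gs[i])
           else subsetGroup(x, deme = gs[i])
    fis <- tryCatch(fisWC(sub, nPerm = fisPerm), error = function(e) NA_real_)
    data.frame(group = gs[i], n = nInd(sub), He = he,
               Fis = as.numeric(fis),
               FisP = if (fisPerm > 0 && !is.na(fis))
                 attr(fis, "p.value") else NA_real_,
               A = A, Ar = Ar, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rarefactionSize") <- g
  out
}

#' Pairwise differentiation table
#'
#' Table of pairwise differentiation between groups: Weir-Cockerham F_ST in
#' the lower triangle, R_ST in the upper triangle, and per-pair genic
#' differentiation p-values (Fisher's method across loci) as an attribute.
#'
#' @inheritParams fstWC
#' @param reps Monte Carlo replicates for the genic tests.
#' @return square matrix (F_ST below, R_ST above the diagonal) with
#'   attribute \code{genicP}.
#' @export
differentiationMatrix <- function(x, by = c("population", "deme"),
                                  reps = 5000) {
  by <- match.arg(by)
  fw <- fstWC(x, by = by, pairwise = TRUE)
  rw <- rst(x, by = by, pairwise = TRUE)
  gs <- rownames(fw$pairwise)
  out <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
  gp <- out
  for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
    out[j, i] <- fw$pairwise[i, j]   # lower: Fst
    out[i, j] <- rw$pairwise[i, j]   # upper: Rst
    gp[i, j] <- gp[j, i] <-
      genicDiffExact(x, gs[c(i, j)], by = by, reps = reps)$combined
  }
  attr(out, "genicP") <- gp
  out
}

#' Paired t-test of arcsine-transformed heterozygosities
#'
#' Compares per-locus expected heterozygosity between two groups with a
#' paired t-test on arcsine-square-root transformed values, the standard
#' variance-stabilizing transform for proportions (He = 0 and 1 map to 0
#' and pi/2).
#'
#' @param he1,he2 per-locus He vectors for the two groups (same loci, same
#'   order); loci with NA in either vector are dropped.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
pairedDiversityTest <- function(he1, he2) {
  keep <- !is.na(he1) & !is.na(he2)
  if (sum(keep) < 2) stop("pairedDiversityTest: need >= 2 shared loci")
  t1 <- asin(sqrt(he1[keep]))
  t2 <- asin(sqrt(he2[keep]))
  if (all(t1 == t2)) {
    return(list(statistic = 0, df = sum(keep) - 1, p.value = 1))
  }
  tt <- stats::t.test(t1, t2, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Sequential Bonferroni (Holm step-down) correction
#'
#' Rice's sequential Bonferroni: order the m p-values ascending and reject
#' while \code{p_(i) < alpha / (m - i + 1)}, stopping at the first failure.
#'
#' @param p vector of p-values in [0, 1].
#' @param alpha family-wise error rate.
#' @return logical vector (in the original order): TRUE = rejected.
#' @export
sequentialBonferroni <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] < alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  reject
}
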
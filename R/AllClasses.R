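#' @import methods
NULL

#' GenotypeDataset: diploid microsatellite genotypes with sample metadata
#'
#' Container for codominant diploid genotypes scored at a set of
#' microsatellite loci. Allele calls are stored as integer allele sizes in
#' repeat units (one unit = one repeat motif), the natural lattice for
#' stepwise mutation models and the M-ratio. A call is either missing
#' (both alleles \code{NA}) or a complete unordered pair; half-missing calls
#' are never stored (they are demoted to missing on import to avoid biased
#' allele counts).
#'
#' @slot allele1,allele2 integer matrices (individuals x loci) holding the
#'   smaller and larger allele of each call in repeat units; \code{NA} for
#'   missing. Row names are individual IDs, column names locus names.
#' @slot loci \code{data.frame} with one row per locus and columns
#'   \code{name}, \code{motif_length} (base pairs per repeat unit),
#'   \code{coding} (Genepop digit width, 2 or 3) and \code{offset} (additive
#'   constant of the affine map \code{code = size * motif_length + offset}).
#' @slot population character vector of population labels, one per
#'   individual (non-empty).
#' @slot deme character vector of optional sub-population labels
#'   (\code{NA} when unknown).
#' @slot sampleYear integer vector of optional collection years
#'   (\code{NA} when unknown).
#'
#' @seealso [GenotypeDataset()] (constructor), [readGenepop()],
#'   [writeGenepop()], [filterIndividuals()], [alleleCounts()]
#' @export
setClass("GenotypeDataset",
  slots = c(
    allele1 = "matrix",
    allele2 = "matrix",
    loci = "data.frame",
    population = "character",
    deme = "character",
    sampleYear = "integer"
  )
)

setValidity("GenotypeDataset", function(object) {
  a1 <- object@allele1
  a2 <- object@allele2
  msg <- character()
  if (!is.integer(a1) || !is.integer(a2)) {
    msg <- c(msg, "allele matrices must be integer (repeat units)")
  }
  if (!identical(dim(a1), dim(a2))) {
    msg <- c(msg, "allele1 and allele2 must have identical dimensions")
  }
  n <- nrow(a1)
  L <- ncol(a1)
  if (is.null(rownames(a1)) && n > 0) {
    msg <- c(msg, "allele matrices must carry individual IDs as row names")
  }
  if (anyDuplicated(rownames(a1))) {
    msg <- c(msg, "individual IDs must be unique")
  }
  if (length(object@population) != n) {
    msg <- c(msg, "population must have one label per individual")
  }
  if (n > 0 && (anyNA(object@population) || any(!nzchar(object@population)))) {
    msg <- c(msg, "population labels must be non-empty")
  }
  if (length(object@deme) != n || length(object@sampleYear) != n) {
    msg <- c(msg, "deme and sampleYear must have one entry per individual")
  }
  req <- c("name", "motif_length", "coding", "offset")
  if (!all(req %in% names(object@loci))) {
    msg <- c(msg, sprintf("loci table must have columns %s",
                          paste(req, collapse = ", ")))
  } else {
    if (nrow(object@loci) != L) {
      msg <- c(msg, "loci table must have one row per locus")
    }
    if (any(object@loci$motif_length < 1)) {
      msg <- c(msg, "motif_length must be >= 1")
    }
    if (!all(object@loci$coding %in% c(2L, 3L))) {
      msg <- c(msg, "coding must be 2 or 3 (Genepop digit width)")
    }
  }
  # half-missing calls are forbidden; pairs are stored sorted
  if (length(a1)) {
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) msg <- c(msg, "half-missing calls are not allowed")
    both <- !is.na(a1) & !is.na(a2)
    if (any(a1[both] > a2[both])) {
      msg <- c(msg, "allele pairs must be stored sorted (allele1 <= allele2)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' MutationModel: stepwise / two-phase microsatellite mutation
#'
#' Parameters of the generalized stepwise (two-phase) mutation process:
#' with probability \code{pSingle} a mutation moves the allele by one repeat
#' unit (+1 or -1 with equal probability); otherwise the step magnitude is
#' drawn from a geometric distribution on \{1, 2, ...\} with success
#' probability \code{geomQ}, again with a random sign. \code{pSingle = 1}
#' is the strict stepwise model (SMM).
#'
#' Two conventions for the multistep component coexist in the bottleneck
#' literature and both are supported by the constructor
#' \code{\link{mutationModel}}: parameterization by the \emph{variance} of
#' the multistep size (heterozygosity-excess test convention) or by its
#' \emph{mean} (M-ratio convention).
#'
#' @slot pSingle proportion of single-step mutations in [0, 1].
#' @slot geomQ success probability of the geometric tail of the
#'   multistep-size law (sizes = msMin + Geom(geomQ)).
#' @slot msMin smallest multistep size (1 when "multistep" may coincide with
#'   a single step, 2 when multistep means strictly more than one unit).
#' @slot theta scaled mutation rate; its interpretation is supplied by the
#'   caller (4*Ne*mu for equilibrium simulation, 2*N0*mu inside the
#'   size-change model). May be NA when the trajectory fixes Ne directly.
#' @slot mu per-locus per-generation mutation rate.
#' @export
setClass("MutationModel",
  slots = c(pSingle = "numeric", geomQ = "numeric", msMin = "integer",
            theta = "numeric", mu = "numeric")
)

setValidity("MutationModel", function(object) {
  msg <- character()
  if (length(object@pSingle) != 1 || object@pSingle < 0 || object@pSingle > 1)
    msg <- c(msg, "pSingle must be a single value in [0, 1]")
  if (length(object@geomQ) != 1 || object@geomQ <= 0 || object@geomQ > 1)
    msg <- c(msg, "geomQ must be in (0, 1]")
  if (length(object@mu) != 1 || is.na(object@mu) || object@mu < 0)
    msg <- c(msg, "mu must be a single non-negative rate")
  if (length(object@msMin) != 1 || !(object@msMin %in% c(1L, 2L)))
    msg <- c(msg, "msMin must be 1 or 2")
  if (length(object@theta) != 1 || (!is.na(object@theta) && object@theta < 0))
    msg <- c(msg, "theta must be NA or non-negative")
  if (length(msg)) msg else TRUE
})

#' DemographicTrajectory: a single backward-in-time size change
#'
#' Effective population size N(t) at time t generations before sampling:
#' N(0) = N0 (current), N(t) = N1 for t >= T (ancestral), interpolated on
#' (0, T) according to \code{shape}: \code{"exponential"}
#' (N0 * (N1/N0)^(t/T)), \code{"linear"} (N0 + (N1-N0) * t/T),
#' \code{"constant"} (N0 everywhere; N1 and T ignored) or \code{"step"}
#' (N0 up to T, an abrupt change).
#'
#' @slot N0 current effective size (> 0).
#' @slot N1 ancestral effective size (> 0).
#' @slot T time of the change in generations before sampling (>= 0).
#' @slot shape one of "constant", "exponential", "linear", "step".
#' @export
setClass("DemographicTrajectory",
  slots = c(N0 = "numeric", N1 = "numeric", T = "numeric", shape = "character")
)

setValidity("DemographicTrajectory", function(object) {
  msg <- character()
  if (!(object@shape %in% c("constant", "exponential", "linear", "step")))
    msg <- c(msg, "shape must be constant, exponential, linear or step")
  if (object@N0 <= 0 || object@N1 <= 0)
    msg <- c(msg, "population sizes must be positive")
  if (is.na(object@T) || object@T < 0)
    msg <- c(msg, "T must be non-negative")
  if (!(object@shape %in% c("constant", "step")) && object@T == 0 &&
      object@N0 != object@N1)
    msg <- c(msg, "T = 0 with N0 != N1 leaves N(t) ill-defined at t = 0")
  if (length(msg)) msg else TRUE
})

#' SubdivisionSpec: island-model population structure
#'
#' Specification of a finite island model for the structured coalescent:
#' \code{demeSizes} gives the current effective size of each deme,
#' \code{migration} the per-lineage per-generation probability of migrating
#' (destination uniform among the other demes), and \code{mergeTime} an
#' optional time (generations before present) at which all demes merge into
#' a single ancestral population (Inf = never). With multiple demes, zero
#' migration and no merge the genealogy cannot coalesce and simulation
#' refuses to run.
#'
#' @slot demeSizes numeric vector of deme effective sizes (> 0).
#' @slot migration symmetric migration rate in [0, 1).
#' @slot mergeTime generations before present at which demes merge (Inf
#'   allowed).
#' @slot demeNames character labels for the demes.
#' @export
setClass("SubdivisionSpec",
  slots = c(demeSizes = "numeric", migration = "numeric",
            mergeTime = "numeric", demeNames = "character")
)

setValidity("SubdivisionSpec", function(object) {
  msg <- character()
  if (length(object@demeSizes) < 1 || any(object@demeSizes <= 0))
    msg <- c(msg, "at least one deme with positive size is required")
  if (object@migration < 0 || object@migration >= 1)
    msg <- c(msg, "migration rate must be in [0, 1)")
  if (object@mergeTime < 0)
    msg <- c(msg, "mergeTime must be non-negative (Inf = never)")
  if (length(object@demeNames) != length(object@demeSizes))
    msg <- c(msg, "demeNames must match demeSizes in length")
  if (length(msg)) msg else TRUE
})

#' PosteriorChains: recorded MCMC samples of the size-change model
#'
#' Thinned records of one MCMC chain over the demographic parameters of the
#' single size-change model. Records are stored on the log10 scale, one row
#' per record, with columns \code{log10N0}, \code{log10N1}, \code{log10T}
#' and \code{log10theta} (the across-locus mean of log10 per-locus theta).
#'
#' @slot records numeric matrix of thinned parameter records (log10 scale).
#' @slot iterations total number of MCMC sweeps run.
#' @slot thinning sweeps between records.
#' @slot seed integer seed used for the chain.
#' @slot shape trajectory shape fitted ("exponential" or "linear").
#' @slot nLoci number of polymorphic loci in the data (0 = prior-only run).
#' @slot acceptance named numeric vector of per-move acceptance rates.
#' @slot priors the PriorSpec list used.
#' @export
setClass("PosteriorChains",
  slots = c(records = "matrix", iterations = "numeric", thinning = "numeric",
            seed = "numeric", shape = "character", nLoci = "numeric",
            acceptance = "numeric", priors = "list")
)

setValidity("PosteriorChains", function(object) {
  msg <- character()
  need <- c("log10N0", "log10N1", "log10T", "log10theta")
  if (!all(need %in% colnames(object@records)))
    msg <- c(msg, sprintf("records must have columns %s",
                          paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
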
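#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("nLoc", function(x) standardGeneric("nLoc"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("indNames", function(x) standardGeneric("indNames"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("locNames", function(x) standardGeneric("locNames"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("lociTable", function(x) standardGeneric("lociTable"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("demes", function(x) standardGeneric("demes"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("demes<-", function(x, value) standardGeneric("demes<-"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("sampleYears", function(x) standardGeneric("sampleYears"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("sampleYears<-", function(x, value) standardGeneric("sampleYears<-"))

#' @rdname GenotypeDataset-accessors
#' @export
setGeneric("alleles", function(x, locus) standardGeneric("alleles"))

#' Effective population size along a trajectory
#'
#' @param traj a [DemographicTrajectory-class] object.
#' @param t time in generations before sampling (vectorized).
#' @return population size N(t).
#' @export
setGeneric("populationSize", function(traj, t) standardGeneric("populationSize"))

#' Cumulative coalescent intensity of a trajectory
#'
#' Returns the integral of 1/N(u) du from 0 to t, the natural clock of the
#' coalescent under a variable population size (pairwise coalescence rate is
#' half this intensity for diploid gene copies). Closed forms are used for
#' the constant, exponential and linear shapes, with a constant tail beyond
#' the change time.
#'
#' @param traj a [DemographicTrajectory-class] object.
#' @param t time in generations (vectorized, >= 0).
#' @return cumulative intensity, strictly increasing in t.
#' @export
setGeneric("coalescentIntensity",
           function(traj, t) standardGeneric("coalescentIntensity"))

#' Accessors for PosteriorChains
#'
#' \code{chainRecords} returns the thinned record matrix (log10 scale).
#'
#' @param x a [PosteriorChains-class].
#' @name PosteriorChains-accessors
#' @export
setGeneric("chainRecords", function(x) standardGeneric("chainRecords"))
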
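#' Construct a GenotypeDataset
#'
#' @param allele1,allele2 integer matrices (individuals x loci) of allele
#'   sizes in repeat units; \code{NA} = missing. Pairs need not be ordered;
#'   they are canonicalized so that \code{allele1 <= allele2}. A half-missing
#'   call (one allele \code{NA}) is demoted to fully missing.
#' @param population character vector of population labels (recycled if
#'   length 1).
#' @param loci optional loci table (columns \code{name}, \code{motif_length},
#'   \code{coding}, \code{offset}); defaults to motif length 1, 3-digit
#'   coding and offset 0, i.e. allele size = Genepop code.
#' @param individuals individual IDs; default taken from row names or
#'   generated.
#' @param deme optional sub-population labels.
#' @param sampleYear optional collection years.
#' @return a [GenotypeDataset-class] object.
#' @examples
#' a1 <- matrix(c(10L, 10L, 12L, NA), 2, 2)
#' a2 <- matrix(c(12L, 10L, 12L, NA), 2, 2)
#' gd <- GenotypeDataset(a1, a2, population = "P1")
#' nInd(gd)
#' @export
GenotypeDataset <- function(allele1, allele2, population,
                            loci = NULL, individuals = NULL,
                            deme = NULL, sampleYear = NULL) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  n <- nrow(allele1)
  L <- ncol(allele1)
  if (is.null(individuals)) {
    individuals <- rownames(allele1)
    if (is.null(individuals)) individuals <- sprintf("ind%03d", seq_len(n))
  }
  if (is.null(loci)) {
    nm <- colnames(allele1)
    if (is.null(nm)) nm <- sprintf("L%02d", seq_len(L))
    loci <- defaultLoci(nm)
  }
  rownames(allele1) <- rownames(allele2) <- individuals
  colnames(allele1) <- colnames(allele2) <- loci$name
  # canonicalize: sort pairs, demote half-missing calls
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half)) {
    allele1[half] <- NA_integer_
    allele2[half] <- NA_integer_
  }
  swap <- !is.na(allele1) & !is.na(allele2) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  population <- rep_len(as.character(population), n)
  deme <- if (is.null(deme)) rep(NA_character_, n) else rep_len(as.character(deme), n)
  sampleYear <- if (is.null(sampleYear)) rep(NA_integer_, n) else
    rep_len(as.integer(sampleYear), n)
  new("GenotypeDataset", allele1 = allele1, allele2 = allele2, loci = loci,
      population = population, deme = deme, sampleYear = sampleYear)
}

#' Default loci table
#'
#' Motif length 1 and offset 0 make allele size equal to the Genepop code,
#' the right default for simulated data; real datasets should supply the
#' per-locus motif lengths and offsets of their marker panel.
#'
#' @param names locus names (or a single integer, the number of loci).
#' @param motif_length repeat-unit length(s) in base pairs.
#' @param coding Genepop digit width (2 or 3).
#' @param offset additive constant of the code-to-size map
#'   (\code{size = (code - offset) / motif_length}).
#' @return a loci \code{data.frame}.
#' @export
defaultLoci <- function(names, motif_length = 1L, coding = 3L, offset = 0L) {
  if (is.numeric(names) && length(names) == 1) {
    names <- sprintf("L%02d", seq_len(names))
  }
  data.frame(name = as.character(names),
             motif_length = as.integer(rep_len(motif_length, length(names))),
             coding = as.integer(rep_len(coding, length(names))),
             offset = as.integer(rep_len(offset, length(names))),
             stringsAsFactors = FALSE)
}

#' Accessors for GenotypeDataset
#'
#' \code{nInd}/\code{nLoc} count individuals and loci; \code{indNames},
#' \code{locNames}, \code{lociTable}, \code{populations}, \code{demes},
#' \code{sampleYears} return the metadata; \code{alleles} returns the two
#' allele columns of one locus as an n x 2 integer matrix.
#'
#' @param x a [GenotypeDataset-class] object.
#' @param locus locus name or index.
#' @param value replacement metadata vector.
#' @name GenotypeDataset-accessors
NULL

#' @rdname GenotypeDataset-accessors
#' @export
setMethod("nInd", "GenotypeDataset", function(x) nrow(x@allele1))

#' @rdname GenotypeDataset-accessors
#' @export
setMethod("nLoc", "GenotypeDataset", function(x) ncol(x@allele1))

#' @rdname GenotypeDataset-accessors
#' @export
setMethod("indNames", "GenotypeDataset", function(x) rownames(x@allele1))

#' @rdname GenotypeDataset-accessors
#' @export
setMethod("locNames", "GenotypeDataset", function(x) x@loci$name)

#' @rdname GenotypeDataset-accessors
#' @export
setMethod("lociTable", "GenotypeDataset", function(x) x@loci)

#' @rdname GenotypeDataset-accessors
#' @export
setMethod("populations", "GenotypeDataset", function(x) x@population)

#' @rdname GenotypeDataset-accessors
#' @export
setMethod("demes", "GenotypeDataset", function(x) x@deme)

#' @rdname GenotypeDataset-accessors
#' @export
setReplaceMethod("demes", "GenotypeDataset", function(x, value) {
  x@deme <- rep_len(as.character(value), nInd(x))
  validObject(x)
  x
})

#' @rdname GenotypeDataset-accessors
#' @export
setMethod("sampleYears", "GenotypeDataset", function(x) x@sampleYear)

#' @rdname GenotypeDataset-accessors
#' @export
setReplaceMethod("sampleYears", "GenotypeDataset", function(x, value) {
  x@sampleYear <- rep_len(as.integer(value), nInd(x))
  validObject(x)
  x
})

#' @rdname GenotypeDataset-accessors
#' @export
setMethod("alleles", "GenotypeDataset", function(x, locus) {
  cbind(a1 = x@allele1[, locus], a2 = x@allele2[, locus])
})

#' Subset a GenotypeDataset
#'
#' \code{x[i, j]} subsets individuals (\code{i}) and loci (\code{j}) by
#' index, name or logical mask, keeping metadata in step.
#'
#' @param x a [GenotypeDataset-class] object.
#' @param i individual selector.
#' @param j locus selector.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @export
setMethod("[", "GenotypeDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nLoc(x))
  if (is.character(j)) j <- match(j, x@loci$name)
  if (is.logical(j)) j <- which(j)
  ii <- seq_len(nInd(x))
  names(ii) <- indNames(x)
  i <- ii[i]
  new("GenotypeDataset",
      allele1 = x@allele1[i, j, drop = FALSE],
      allele2 = x@allele2[i, j, drop = FALSE],
      loci = x@loci[j, , drop = FALSE],
      population = x@population[i],
      deme = x@deme[i],
      sampleYear = x@sampleYear[i])
})

#' Select one population (and optionally one deme) of a dataset
#'
#' @param x a [GenotypeDataset-class] object.
#' @param population population label(s) to keep (NULL = all).
#' @param deme deme label(s) to keep (NULL = all).
#' @return the subset [GenotypeDataset-class].
#' @export
subsetGroup <- function(x, population = NULL, deme = NULL) {
  keep <- rep(TRUE, nInd(x))
  if (!is.null(population)) {
    if (!any(x@population %in% population))
      stop("unknown population label: ", paste(population, collapse = ", "))
    keep <- keep & x@population %in% population
  }
  if (!is.null(deme)) {
    if (!any(x@deme %in% deme))
      stop("unknown deme label: ", paste(deme, collapse = ", "))
    keep <- keep & x@deme %in% deme
  }
  x[keep, ]
}

#' Concatenate datasets sharing a locus panel
#'
#' Individuals of all datasets are stacked; loci tables must be identical.
#' Individual IDs are made unique by prefixing the population label when
#' needed.
#'
#' @param ... [GenotypeDataset-class] objects.
#' @return a combined [GenotypeDataset-class].
#' @export
bindDatasets <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !is(xs[[1]], "GenotypeDataset"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1)
  loci <- xs[[1]]@loci
  for (x in xs) {
    if (!identical(x@loci$name, loci$name))
      stop("datasets must share the same locus panel")
  }
  ids <- unlist(lapply(xs, indNames))
  if (anyDuplicated(ids)) {
    ids <- unlist(lapply(xs, function(x) paste(x@population, indNames(x),
                                               sep = ".")))
    ids <- make.unique(ids)
  }
  a1 <- do.call(rbind, lapply(xs, function(x) x@allele1))
  a2 <- do.call(rbind, lapply(xs, function(x) x@allele2))
  rownames(a1) <- rownames(a2) <- ids
  new("GenotypeDataset", allele1 = a1, allele2 = a2, loci = loci,
      population = unlist(lapply(xs, populations)),
      deme = unlist(lapply(xs, demes)),
      sampleYear = unlist(lapply(xs, sampleYears)))
}

setMethod("show", "GenotypeDataset", function(object) {
  cat("GenotypeDataset:", nInd(object), "individuals x", nLoc(object),
      "loci\n")
  tp <- table(object@population)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tp), as.integer(tp)), collapse = ", "),
      "\n")
  if (!all(is.na(object@deme))) {
    td <- table(object@deme, useNA = "no")
    cat("  demes:",
        paste(sprintf("%s (n=%d)", names(td), as.integer(td)), collapse = ", "),
        "\n")
  }
  miss <- mean(is.na(object@allele1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
})
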
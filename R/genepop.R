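#' Read a Genepop file
#'
#' Parses the classical Genepop text format (title line, locus names given
#' one per line or comma-separated, \code{POP} blocks, diploid genotypes as
#' concatenated 2- or 3-digit allele codes, \code{00}/\code{000} = missing
#' allele) into a [GenotypeDataset-class]. Allele codes are converted to
#' integer allele sizes in repeat units at load time via the per-locus affine
#' map \code{size = (code - offset) / motif_length}; all downstream
#' statistics work on the repeat-unit lattice.
#'
#' Population labels: files written by [writeGenepop()] carry the labels in
#' the title line (\code{[pops: a,b,...]}) and they are restored; otherwise
#' blocks are labelled \code{pop1}, \code{pop2}, ... or by \code{popNames}.
#' A genotype with exactly one missing allele is demoted to fully missing.
#'
#' @param path path to the Genepop file.
#' @param locusDefs optional loci table (see [defaultLoci()]); when NULL,
#'   motif length 1 and offset 0 are assumed and the digit width is inferred
#'   from the genotypes.
#' @param popNames optional character vector naming the POP blocks.
#' @return a [GenotypeDataset-class].
#' @export
readGenepop <- function(path, locusDefs = NULL, popNames = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("malformed Genepop file: fewer than 3 lines")
  title <- lines[1]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop("malformed Genepop header: no POP line after the locus names ",
         "(line ", if (is.na(first_pop)) "none" else first_pop, ")")
  locus_lines <- lines[2:(first_pop - 1)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  L <- length(locus_names)
  if (L == 0) stop("malformed Genepop header: no locus names")

  if (is.null(locusDefs)) {
    locusDefs <- defaultLoci(locus_names)
    infer_coding <- TRUE
  } else {
    if (nrow(locusDefs) != L)
      stop("locusDefs has ", nrow(locusDefs), " rows but the file lists ",
           L, " loci")
    locusDefs$name <- locus_names
    infer_coding <- FALSE
  }

  ids <- character()
  pop_idx <- integer()
  codes <- matrix(character(), 0, 2 * L)
  pop <- 0L
  for (ln in seq(first_pop, length(lines))) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (toupper(trimws(line)) == "POP") {
      pop <- pop + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2)
      stop("parse error at line ", ln, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != L)
      stop("parse error at line ", ln, ": ", length(gts),
           " genotypes for ", L, " loci")
    row <- character(2 * L)
    for (l in seq_len(L)) {
      g <- gts[l]
      if (!grepl("^[0-9]+$", g) || !(nchar(g) %in% c(4L, 6L)))
        stop("parse error at line ", ln, ", locus ", locus_names[l],
             ": genotype '", g, "' is not a 4- or 6-digit code")
      w <- nchar(g) / 2L
      row[2 * l - 1] <- substr(g, 1, w)
      row[2 * l] <- substr(g, w + 1, 2 * w)
    }
    codes <- rbind(codes, row)
    ids <- c(ids, id)
    pop_idx <- c(pop_idx, pop)
  }
  if (length(ids) == 0) stop("malformed Genepop file: no individuals")

  # enforce a single digit width per locus
  for (l in seq_len(L)) {
    w <- unique(as.vector(nchar(codes[, c(2 * l - 1, 2 * l)])))
    if (length(w) > 1)
      stop("locus ", locus_names[l],
           " mixes 2- and 3-digit allele codes across individuals")
    if (infer_coding) locusDefs$coding[l] <- as.integer(w)
    else if (w != locusDefs$coding[l])
      stop("locus ", locus_names[l], " coded with ", w,
           " digits but locusDefs says ", locusDefs$coding[l])
  }

  a1 <- matrix(NA_integer_, length(ids), L)
  a2 <- matrix(NA_integer_, length(ids), L)
  for (l in seq_len(L)) {
    c1 <- as.integer(codes[, 2 * l - 1])
    c2 <- as.integer(codes[, 2 * l])
    c1[c1 == 0L] <- NA_integer_
    c2[c2 == 0L] <- NA_integer_
    for (cc in list(c1, c2)) {
      ok <- is.na(cc) | (cc - locusDefs$offset[l]) %% locusDefs$motif_length[l] == 0
      if (!all(ok))
        stop("locus ", locus_names[l], ": allele code off the repeat-unit ",
             "lattice given motif_length ", locusDefs$motif_length[l],
             " and offset ", locusDefs$offset[l])
    }
    a1[, l] <- (c1 - locusDefs$offset[l]) %/% locusDefs$motif_length[l]
    a2[, l] <- (c2 - locusDefs$offset[l]) %/% locusDefs$motif_length[l]
  }

  labels <- popNames
  if (is.null(labels)) {
    m <- regmatches(title, regexec("\\[pops: *([^]]*)\\]", title))[[1]]
    if (length(m) == 2) labels <- trimws(strsplit(m[2], ",")[[1]])
  }
  if (is.null(labels) || length(labels) != pop)
    labels <- sprintf("pop%d", seq_len(pop))

  ids <- make.unique(ids)
  GenotypeDataset(a1, a2, population = labels[pop_idx], loci = locusDefs,
                  individuals = ids)
}

#' Write a GenotypeDataset as a canonical Genepop file
#'
#' Emits one POP block per population (in order of first appearance), one
#' individual per line, genotypes as concatenated fixed-width allele codes
#' obtained from the repeat-unit sizes by \code{code = size * motif_length +
#' offset}. Missing calls become \code{0000}/\code{000000}. Population
#' labels are recorded in the title line so that [readGenepop()] restores
#' them: the write/read round trip is lossless for allele sizes, population
#' structure and missingness.
#'
#' @param x a [GenotypeDataset-class] with at least one individual.
#' @param path output path.
#' @param title optional title line prefix.
#' @return invisibly, the path.
#' @export
writeGenepop <- function(x, path, title = "msatdemog export") {
  if (nInd(x) == 0) stop("cannot write a Genepop file with no individuals")
  loci <- x@loci
  pops <- unique(x@population)
  out <- c(sprintf("%s [pops: %s]", title, paste(pops, collapse = ",")),
           loci$name)
  for (p in pops) {
    out <- c(out, "POP")
    for (i in which(x@population == p)) {
      gts <- character(nLoc(x))
      for (l in seq_len(nLoc(x))) {
        w <- loci$coding[l]
        s1 <- x@allele1[i, l]
        s2 <- x@allele2[i, l]
        if (is.na(s1)) {
          gts[l] <- strrep("0", 2 * w)
        } else {
          c1 <- s1 * loci$motif_length[l] + loci$offset[l]
          c2 <- s2 * loci$motif_length[l] + loci$offset[l]
          if (any(c(c1, c2) < 1) || any(c(c1, c2) > 10^w - 1))
            stop("unencodable allele size at individual ", indNames(x)[i],
                 ", locus ", loci$name[l], ": code ", min(c1, c2), "..",
                 max(c1, c2), " outside 1..", 10^w - 1)
          gts[l] <- paste0(formatC(c1, width = w, flag = "0"),
                           formatC(c2, width = w, flag = "0"))
        }
      }
      out <- c(out, paste(indNames(x)[i], ",", paste(gts, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write the metadata sidecar table
#'
#' Genepop cannot encode deme membership or sample age, so they travel in a
#' tab-separated sidecar with columns \code{individual}, \code{deme},
#' \code{year} (empty/NA allowed). \code{attachMetadata} matches rows to the
#' dataset by individual ID.
#'
#' @param x a [GenotypeDataset-class].
#' @param path TSV path.
#' @return \code{readSampleMetadata}: a data.frame; \code{attachMetadata}:
#'   the updated dataset; \code{writeSampleMetadata}: the path, invisibly.
#' @export
readSampleMetadata <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' @rdname readSampleMetadata
#' @export
writeSampleMetadata <- function(x, path) {
  df <- data.frame(individual = indNames(x), deme = demes(x),
                   year = sampleYears(x), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readSampleMetadata
#' @param meta data.frame as returned by \code{readSampleMetadata}.
#' @export
attachMetadata <- function(x, meta) {
  i <- match(indNames(x), meta$individual)
  if ("deme" %in% names(meta)) x@deme <- as.character(meta$deme[i])
  if ("year" %in% names(meta)) x@sampleYear <- as.integer(meta$year[i])
  validObject(x)
  x
}

#' Drop individuals typed at too few loci
#'
#' Quality-control filter retaining exactly the individuals with at least
#' \code{minLoci} non-missing calls. Removals are reported via
#' \code{message()}. The filter is idempotent and monotone in
#' \code{minLoci}.
#'
#' @param x a [GenotypeDataset-class].
#' @param minLoci minimum number of typed loci (0..nLoc).
#' @return the filtered [GenotypeDataset-class].
#' @export
filterIndividuals <- function(x, minLoci) {
  stopifnot(minLoci >= 0, minLoci <= nLoc(x))
  typed <- rowSums(!is.na(x@allele1))
  drop <- typed < minLoci
  if (any(drop)) {
    message("filterIndividuals: removing ", sum(drop), " individual(s) ",
            "typed at < ", minLoci, " loci: ",
            paste(indNames(x)[drop], collapse = ", "))
  }
  x[!drop, ]
}

#' Per-locus allele counts for one group
#'
#' Tallies gene copies per allele size for every locus, restricted to one
#' population and/or deme. Missing calls contribute nothing; counts at a
#' locus sum to twice the number of individuals typed there.
#'
#' @param x a [GenotypeDataset-class].
#' @param population,deme optional group selectors (see [subsetGroup()]);
#'   unknown labels are an error.
#' @return named list (one element per locus) of integer vectors of counts,
#'   names = allele sizes.
#' @export
alleleCounts <- function(x, population = NULL, deme = NULL) {
  g <- subsetGroup(x, population = population, deme = deme)
  if (nInd(g) == 0) stop("selected group is empty")
  out <- vector("list", nLoc(g))
  names(out) <- locNames(g)
  for (l in seq_len(nLoc(g))) {
    v <- c(g@allele1[, l], g@allele2[, l])
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      out[[l]] <- integer(0)
    } else {
      tb <- table(v)
      cnt <- as.integer(tb)
      names(cnt) <- names(tb)
      out[[l]] <- cnt
    }
  }
  out
}
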
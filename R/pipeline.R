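## Orchestration: configuration and the end-to-end study pipeline
## (QC -> diversity/differentiation -> bottleneck battery, pooled and
## per-deme -> size-change MCMC per group and shape -> posterior summaries),
## writing TSV/JSON reports.

#' Build an analysis configuration
#'
#' All stochastic stages take explicit seeds derived from the single
#' \code{seed}; a configuration round-trips losslessly through JSON
#' ([saveConfig()] / [loadConfig()]).
#'
#' @param seed master seed.
#' @param genepopFiles optional named character vector of Genepop paths (one
#'   per sample group); when NULL the synthetic [fisherScenario()] bundle is
#'   generated.
#' @param metadataFiles optional named vector of sidecar TSV paths matching
#'   \code{genepopFiles}.
#' @param minLoci QC threshold: minimum typed loci per individual.
#' @param tpm multistep proportions for the heterozygosity-excess test.
#' @param thetaGrid theta grid for M-critical.
#' @param hetReps,mReps replicates for the bottleneck stage.
#' @param diffReps Monte Carlo tables for the genic differentiation tests.
#' @param mcmcGroups population labels to model (groups too small to mix are
#'   left out, as a 5-individual sample would be).
#' @param mcmcShapes trajectory shapes to fit.
#' @param iterations,thinning,nChains MCMC settings.
#' @param generationYears years per generation.
#' @param sampleAgeYears average age (years) of historical samples, applied
#'   to groups whose label ends in "_H".
#' @param rarefactionSize gene copies for allelic richness.
#' @return list of class \code{analysisConfig}.
#' @export
analysisConfig <- function(seed = 1, genepopFiles = NULL,
                           metadataFiles = NULL, minLoci = 7,
                           tpm = c(0.05, 0.20), thetaGrid = c(1, 2, 5, 10),
                           hetReps = 2000, mReps = 5000, diffReps = 2000,
                           mcmcGroups = c("NW_C", "SSN_H", "SSN_C"),
                           mcmcShapes = c("exponential", "linear"),
                           iterations = 20000, thinning = 10, nChains = 3,
                           generationYears = 5, sampleAgeYears = 95,
                           rarefactionSize = 8) {
  cfg <- list(seed = seed, genepopFiles = genepopFiles,
              metadataFiles = metadataFiles, minLoci = minLoci, tpm = tpm,
              thetaGrid = thetaGrid, hetReps = hetReps, mReps = mReps,
              diffReps = diffReps, mcmcGroups = mcmcGroups,
              mcmcShapes = mcmcShapes, iterations = iterations,
              thinning = thinning, nChains = nChains,
              generationYears = generationYears,
              sampleAgeYears = sampleAgeYears,
              rarefactionSize = rarefactionSize)
  class(cfg) <- "analysisConfig"
  cfg
}

#' @rdname analysisConfig
#' @param config an \code{analysisConfig}.
#' @param path JSON path.
#' @export
saveConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname analysisConfig
#' @export
loadConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysisConfig, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the full study pipeline
#'
#' Sequences QC, diversity and differentiation statistics, the bottleneck
#' battery (pooled and per-deme where deme labels exist), the size-change
#' MCMC per group and shape, and posterior summaries. Stages fail soft: an
#' error is recorded in the log and the remaining stages still run. Reports
#' are returned and, when \code{outDir} is given, written as TSV plus a JSON
#' log carrying the configuration, seeds and per-stage status.
#'
#' @param config an [analysisConfig()].
#' @param outDir optional output directory.
#' @return list with \code{diversity}, \code{differentiation},
#'   \code{bottleneck}, \code{posterior}, \code{log}.
#' @export
runFullStudy <- function(config = analysisConfig(), outDir = NULL) {
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              config = unclass(config),
              rVersion = as.character(getRversion()), stages = list())
  out <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      message("stage ", name, " failed: ", conditionMessage(e))
      structure(list(error = conditionMessage(e)), class = "stageError")
    })
    log$stages[[name]] <<- list(
      seconds = round(proc.time()[3] - t0, 2),
      status = if (inherits(res, "stageError")) res$error else "ok")
    res
  }

  ## ---- data -------------------------------------------------------------
  bundle <- stage("data", {
    if (is.null(config$genepopFiles)) {
      fisherScenario(seed = config$seed)
    } else {
      b <- lapply(config$genepopFiles, readGenepop)
      if (!is.null(config$metadataFiles)) {
        for (nm in names(config$metadataFiles)) {
          b[[nm]] <- attachMetadata(b[[nm]],
                                    readSampleMetadata(config$metadataFiles[[nm]]))
        }
      }
      names(b) <- names(config$genepopFiles)
      b
    }
  })
  if (inherits(bundle, "stageError")) return(list(log = log))

  bundle <- stage("qc", lapply(bundle, filterIndividuals,
                               minLoci = config$minLoci))
  combined <- bindDatasets(bundle)

  out$diversity <- stage("diversity",
    diversityTable(combined, rarefactionSize = config$rarefactionSize))
  out$differentiation <- stage("differentiation", {
    set.seed(deriveSeed(config$seed, 7))
    differentiationMatrix(combined, reps = config$diffReps)
  })

  out$bottleneck <- stage("bottleneck", {
    rows <- list()
    for (nm in names(bundle)) {
      byDeme <- !all(is.na(demes(bundle[[nm]])))
      bt <- bottleneckBattery(bundle[[nm]], byDeme = byDeme,
                              tpm = config$tpm,
                              thetaGrid = config$thetaGrid,
                              hetReps = config$hetReps, mReps = config$mReps,
                              seed = deriveSeed(config$seed, match(nm, names(bundle))))
      bt <- cbind(group = nm, bt)
      rows[[nm]] <- bt
    }
    do.call(rbind, rows)
  })

  out$posterior <- stage("mcmc", {
    priors <- priorSpec()
    priorS <- rpriorSamples(priors, 20000, seed = deriveSeed(config$seed, 99))
    rows <- list()
    for (nm in intersect(config$mcmcGroups, names(bundle))) {
      age <- if (grepl("_H$", nm)) config$sampleAgeYears else 0
      for (sh in config$mcmcShapes) {
        chains <- runReplicated(bundle[[nm]], priors = priors, shape = sh,
                                nChains = config$nChains,
                                iterations = config$iterations,
                                thinning = config$thinning,
                                seed = deriveSeed(config$seed,
                                                  1000 + match(nm, names(bundle))))
        sm <- summarizePosterior(chains, priorS,
                                 generationYears = config$generationYears,
                                 sampleAgeYears = age)
        rows[[paste(nm, sh)]] <- cbind(group = nm, sm)
      }
    }
    do.call(rbind, rows)
  })

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  out$log <- log

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(df, name) {
      if (!inherits(df, "stageError") && is.data.frame(df))
        utils::write.table(df, file.path(outDir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    wtsv(out$diversity, "diversity.tsv")
    if (is.matrix(out$differentiation)) {
      utils::write.table(cbind(group = rownames(out$differentiation),
                               as.data.frame(out$differentiation)),
                         file.path(outDir, "differentiation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wtsv(out$bottleneck, "bottleneck.tsv")
    wtsv(out$posterior, "posterior.tsv")
    jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
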
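#' @include AllClasses.R AllGenerics.R
NULL

#' Configure an end-to-end learning-curve experiment
#'
#' Collects everything [runExperiment()] needs: the synthetic study
#' conditions (or file paths to real inputs), the modalities and learners
#' to compare, the repeat count and split fractions, the subset schedule,
#' and fixed or searched hyperparameters.
#'
#' @param synthetic a [SyntheticConfig-class] describing the simulated
#'   study; ignored when \code{paths} is given.
#' @param paths optional named list for real-data mode: per-modality
#'   matrix files plus \code{responses}; each matrix entry may be a path
#'   or \code{list(path =, sep =, orientation =)}.
#' @param modalities modalities to model.
#' @param learners subset of \code{c("benchmark", "gbt", "nn")}; the
#'   benchmark is omics-independent and recorded once under modality
#'   \code{"none"}.
#' @param nRepeats repeated shuffled splits (default 30).
#' @param fractions (train, val, test) cell-line fractions.
#' @param kSizes number of training-subset sizes (default 8).
#' @param minSize smallest subset size in pairs (default 32).
#' @param subsetMode \code{"pairs"} or \code{"cells"}.
#' @param searchTrials random-search trials per fit; 0 fits once with the
#'   fixed parameters below.
#' @param gbtParams,nnParams fixed hyperparameters (and, under search,
#'   parameters merged beneath every sampled assignment).
#' @param seed master seed; every downstream seed derives from it.
#' @param outDir output directory for CSVs, manifest and plots.
#' @param makePlots write a log-log learning-curve figure (default
#'   FALSE).
#' @return a config list for [runExperiment()].
#' @export
experimentConfig <- function(synthetic = syntheticConfig(),
                             paths = NULL,
                             modalities = c("rnaseq", "proteomics"),
                             learners = c("benchmark", "gbt"),
                             nRepeats = 30L,
                             fractions = c(0.8, 0.1, 0.1),
                             kSizes = 8L, minSize = 32L,
                             subsetMode = "pairs",
                             searchTrials = 0L,
                             gbtParams = list(), nnParams = list(),
                             seed = 1L, outDir = tempfile("drp_run_"),
                             makePlots = FALSE) {
  stopifnot(all(learners %in% c("benchmark", "gbt", "nn")))
  list(synthetic = synthetic, paths = paths, modalities = modalities,
       learners = learners, nRepeats = as.integer(nRepeats),
       fractions = fractions, kSizes = as.integer(kSizes),
       minSize = as.integer(minSize), subsetMode = subsetMode,
       searchTrials = as.integer(searchTrials), gbtParams = gbtParams,
       nnParams = nnParams, seed = as.integer(seed), outDir = outDir,
       makePlots = isTRUE(makePlots))
}

# everything that determines the numbers, for the manifest fingerprint
.configFingerprint <- function(config) {
  syn <- config$synthetic
  list(
    synthetic = if (is.null(syn)) NULL else list(
      nCellLines = syn@nCellLines, nDrugs = syn@nDrugs,
      nFeatures = as.list(syn@nFeatures), drugMeanSD = syn@drugMeanSD,
      cellEffectSD = syn@cellEffectSD, nInformative = syn@nInformative,
      noiseSD = syn@noiseSD, missingRate = syn@missingRate,
      responseSparsity = syn@responseSparsity, seed = syn@seed),
    paths = config$paths, modalities = config$modalities,
    learners = config$learners, nRepeats = config$nRepeats,
    fractions = config$fractions, kSizes = config$kSizes,
    minSize = config$minSize, subsetMode = config$subsetMode,
    searchTrials = config$searchTrials, gbtParams = config$gbtParams,
    nnParams = config$nnParams, seed = config$seed)
}

# load omics + responses for either data mode, preprocessed and aligned
.loadExperimentData <- function(config) {
  if (is.null(config$paths)) {
    syn <- config$synthetic
    profiles <- lapply(names(syn@nFeatures),
                       function(m) generateOmicsProfiles(syn, m))
    names(profiles) <- names(syn@nFeatures)
    responses <- generateIC50Table(syn, profiles)$responses
    profiles <- profiles[config$modalities]
  } else {
    pget <- function(e, field, default) {
      if (is.list(e) && !is.null(e[[field]])) e[[field]] else default
    }
    profiles <- lapply(config$modalities, function(m) {
      e <- config$paths[[m]]
      readOmicsMatrix(if (is.list(e)) e$path else e, m,
                      sep = pget(e, "sep", NULL),
                      orientation = pget(e, "orientation",
                                         "cells-by-features"))
    })
    names(profiles) <- config$modalities
    responses <- readResponseTable(config$paths$responses)
  }
  profiles <- lapply(profiles, prepOmics)
  profiles <- dropCellLinesWithoutTargets(profiles, responses)
  cells <- intersectCellLineSets(profiles)
  responses <- responses[responses$cell_line %in% cells, , drop = FALSE]
  list(profiles = profiles, responses = responses, cells = cells)
}

# one model fit + test evaluation for a single experiment cell
.fitCondition <- function(learner, modality, trainSet, valSet, testSet,
                          config, fitSeed) {
  model <- if (learner == "benchmark") {
    trainedBenchmark(trainSet, valSet)
  } else if (config$searchTrials > 0L) {
    randomSearch(learner,
                 defaultSearchSpace(learner, config$searchTrials),
                 trainSet, valSet, seed = fitSeed,
                 fixedParams = config[[paste0(learner, "Params")]])
  } else {
    fitFun <- switch(learner, gbt = fitGBT, nn = fitNN)
    fitFun(trainSet, valSet,
           params = config[[paste0(learner, "Params")]], seed = fitSeed)
  }
  mse(predictResponse(model, testSet), testSet@targets)
}

#' Run the full learning-curve experiment
#'
#' The end-to-end protocol: build the paired dataset for every modality,
#' repeat cancer-blind splitting \code{nRepeats} times, train every
#' learner at every log-spaced training-subset size, measure test MSE,
#' and assemble averaged learning curves plus the max-size comparison
#' table. All randomness derives from the config seed, so a rerun
#' reproduces identical outputs; completed (repeat, modality, learner,
#' size) cells found in \code{outDir} are reused when the stored config
#' fingerprint matches, and a mismatching fingerprint refuses to merge.
#'
#' Writes into \code{outDir}: \code{curves_tidy.csv} (one row per repeat
#' x size x condition), \code{curves_summary.csv} (mean and standard
#' error per size), \code{comparison.csv} (per-split test MSE at the
#' maximum training size), \code{comparison_summary.csv} (mean MSE,
#' standard error and average ranking per condition),
#' \code{manifest.json} (config fingerprint, seeds, per-repeat cell-line
#' assignments) and optionally \code{learning_curves.png}.
#'
#' @param config from [experimentConfig()].
#' @return invisibly, a list: \code{curves} (named list of
#'   [LearningCurve-class]), \code{comparison} and
#'   \code{comparisonSummary} data.frames, \code{sizes}, \code{paths}.
#' @export
runExperiment <- function(config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  fp <- .configFingerprint(config)
  hash <- hashConfig(fp)
  manifestPath <- file.path(config$outDir, "manifest.json")
  tidyPath <- file.path(config$outDir, "curves_tidy.csv")
  existing <- NULL
  if (file.exists(manifestPath) && file.exists(tidyPath)) {
    old <- jsonlite::read_json(manifestPath)
    if (!identical(old$config_hash, unname(hash)))
      stop("outDir holds results for a different configuration ",
           "(fingerprint mismatch); refusing to merge")
    existing <- utils::read.csv(tidyPath, stringsAsFactors = FALSE)
  }

  dat <- .loadExperimentData(config)
  vocab <- sort(unique(dat$responses$drug))
  paired <- lapply(dat$profiles, function(m)
    buildPairs(m, dat$responses, dat$cells, vocab))

  splits <- repeatSplits(dat$cells, config$fractions, config$nRepeats,
                         baseSeed = deriveSeed(config$seed, 1L))
  refPd <- paired[[1L]]

  conditions <- list()
  for (l in config$learners) {
    if (l == "benchmark") conditions[["none|benchmark"]] <-
        c(modality = "none", learner = "benchmark")
    else for (m in config$modalities)
      conditions[[paste(m, l, sep = "|")]] <- c(modality = m, learner = l)
  }

  rows <- list()
  doneKey <- if (is.null(existing)) character() else
    with(existing, paste(rep, modality, learner, size))
  # one size grid shared by all repeats: log-spaced up to the smallest
  # full training size, so every repeat contributes to every curve point
  trainIdxAll <- lapply(splits, function(s) pairsForCells(refPd,
                                                          trainCells(s)))
  fullCommon <- if (config$subsetMode == "pairs")
    min(lengths(trainIdxAll))
  else min(vapply(splits, function(s) length(trainCells(s)), integer(1)))
  sizesRef <- round(exp(seq(log(config$minSize), log(fullCommon),
                            length.out = config$kSizes)))
  sizesRef[1L] <- config$minSize
  sizesRef[config$kSizes] <- fullCommon
  for (s in splits) {
    r <- s@repeatIndex
    trainIdx <- trainIdxAll[[r + 1L]]
    schedule <- makeSubsetSchedule(
      trainIdx, k = config$kSizes, minSize = config$minSize,
      seed = deriveSeed(config$seed, 2000L + r), mode = config$subsetMode,
      pairCells = if (config$subsetMode == "cells")
        refPd@pairIndex$cell_line[trainIdx],
      sizes = sizesRef)
    valSets <- lapply(paired, subsetPairs, cells = valCells(s))
    testSets <- lapply(paired, subsetPairs, cells = testCells(s))
    for (k in seq_along(schedule@sizes)) {
      sz <- schedule@sizes[k]
      idx <- schedule@subsets[[k]]
      for (ci in seq_along(conditions)) {
        cond <- conditions[[ci]]
        key <- paste(r, cond[["modality"]], cond[["learner"]], sz)
        if (key %in% doneKey) next
        pm <- if (cond[["modality"]] == "none") names(paired)[1L]
              else cond[["modality"]]
        err <- .fitCondition(
          cond[["learner"]], pm,
          subsetPairs(paired[[pm]], idx = idx),
          valSets[[pm]], testSets[[pm]], config,
          fitSeed = deriveSeed(config$seed,
                               3000L + r * 97L + k * 11L + ci))
        rows[[length(rows) + 1L]] <- data.frame(
          rep = r, modality = cond[["modality"]],
          learner = cond[["learner"]], size = sz, error = err)
      }
    }
  }
  tidy <- do.call(rbind, c(list(existing), rows))
  tidy <- tidy[order(tidy$rep, tidy$modality, tidy$learner, tidy$size), ]
  rownames(tidy) <- NULL

  curves <- list()
  for (ci in names(conditions)) {
    cond <- conditions[[ci]]
    sub <- tidy[tidy$modality == cond[["modality"]] &
                tidy$learner == cond[["learner"]], ]
    perRep <- stats::xtabs(error ~ rep + size, data = sub)
    sizes <- as.integer(colnames(perRep))
    curves[[ci]] <- assembleCurve(matrix(perRep, nrow = nrow(perRep),
                                         dimnames = NULL),
                                  sizes, cond[["modality"]],
                                  cond[["learner"]])
  }

  maxSize <- max(tidy$size)
  comparison <- tidy[tidy$size == maxSize,
                     c("rep", "modality", "learner", "error")]
  names(comparison)[4L] <- "test_mse"
  rownames(comparison) <- NULL
  condLabel <- paste(comparison$modality, comparison$learner, sep = "|")
  rankTab <- data.frame(split = comparison$rep, condition = condLabel,
                        mse = comparison$test_mse)
  avgRank <- averageRanking(rankTab)
  agg <- function(f) tapply(comparison$test_mse, condLabel, f)
  conds <- sort(unique(condLabel))
  comparisonSummary <- data.frame(
    condition = conds,
    modality = sub("\\|.*", "", conds),
    learner = sub(".*\\|", "", conds),
    mean_mse = as.numeric(agg(mean)[conds]),
    stderr = as.numeric(agg(stats::sd)[conds]) /
      sqrt(config$nRepeats),
    avg_rank = as.numeric(avgRank[conds]))

  summaryDf <- do.call(rbind, lapply(curves, function(cv)
    curveTables(cv)$summary))
  rownames(summaryDf) <- NULL

  paths <- list(tidy = tidyPath,
                summary = file.path(config$outDir, "curves_summary.csv"),
                comparison = file.path(config$outDir, "comparison.csv"),
                comparisonSummary = file.path(config$outDir,
                                              "comparison_summary.csv"),
                manifest = manifestPath)
  utils::write.csv(tidy, paths$tidy, row.names = FALSE, quote = FALSE)
  utils::write.csv(summaryDf, paths$summary, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(comparison, paths$comparison, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(comparisonSummary, paths$comparisonSummary,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    config_hash = unname(hash), config = fp, sizes = sizesRef,
    cells = dat$cells,
    repeats = lapply(splits, function(s) list(
      repeat_index = s@repeatIndex, seed = s@seed,
      train = s@trainCells, val = s@valCells, test = s@testCells))),
    manifestPath, auto_unbox = TRUE, digits = NA)
  if (config$makePlots) {
    p <- plotLearningCurves(curves)
    ggplot2::ggsave(file.path(config$outDir, "learning_curves.png"), p,
                    width = 7, height = 5, dpi = 150)
    paths$plot <- file.path(config$outDir, "learning_curves.png")
  }
  invisible(list(curves = curves, comparison = comparison,
                 comparisonSummary = comparisonSummary,
                 sizes = sizesRef, paths = paths))
}
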
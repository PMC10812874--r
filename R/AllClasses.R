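#' @import methods
NULL

#' OmicsMatrix: a cell-line by feature profile matrix
#'
#' Container for one omics modality: a numeric matrix with cell lines as
#' rows and molecular features (genes, proteins or phosphopeptides) as
#' columns, plus an optional logical mask marking entries that were missing
#' in the source file (e.g. proteins below the limit of quantitation).
#' Masked entries hold \code{NA} in \code{values} until imputed with
#' \code{\link{imputeMissingZero}}.
#'
#' @slot values numeric matrix, cell lines x features, with unique dimnames.
#' @slot modality single character, e.g. \code{"rnaseq"}, \code{"proteomics"},
#'   \code{"phospho"}.
#' @slot missingMask \code{NULL}, or a logical matrix of the same shape as
#'   \code{values}; \code{TRUE} marks a missing entry.
#'
#' @seealso [omicsMatrix()], [readOmicsMatrix()]
#' @export
setClass("OmicsMatrix",
  representation(values = "matrix", modality = "character",
                 missingMask = "ANY"))

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must carry cell-line rownames and feature colnames")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, paste0("duplicate cell-line ids: ",
        paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, paste0("duplicate feature ids: ",
        paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
  }
  if (length(object@modality) != 1L || !nzchar(object@modality))
    msg <- c(msg, "'modality' must be a single non-empty string")
  m <- object@missingMask
  if (!is.null(m)) {
    if (!is.logical(m) || !identical(dim(m), dim(v)))
      msg <- c(msg, "'missingMask' must be a logical matrix matching 'values'")
    else if (any(is.na(v[!m])))
      msg <- c(msg, "unmasked entries of 'values' must be non-NA")
  } else if (anyNA(v)) {
    msg <- c(msg, "'values' contains NA but no missingMask is set")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix (cell lines x features) with dimnames.
#' @param modality modality name.
#' @param missingMask optional logical matrix; where \code{TRUE}, the
#'   corresponding entry of \code{values} is set to \code{NA}.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
#' omicsMatrix(m, "rnaseq")
#' @export
omicsMatrix <- function(values, modality, missingMask = NULL) {
  storage.mode(values) <- "double"
  if (!is.null(missingMask)) {
    dimnames(missingMask) <- dimnames(values)
    values[missingMask] <- NA_real_
    if (!any(missingMask)) missingMask <- NULL
  }
  new("OmicsMatrix", values = values, modality = modality,
      missingMask = missingMask)
}

#' FeatureMap: landmark genes and cross-modality identifier maps
#'
#' Static mapping tables driving landmark-based feature selection: the
#' landmark gene panel, which proteins each gene codes for, which
#' phosphopeptides each gene targets (kinase-substrate style relation), and
#' which protein each phosphopeptide sits on.
#'
#' @slot landmarkGenes character vector of landmark gene ids.
#' @slot geneToProtein data.frame with columns \code{gene}, \code{protein}.
#' @slot geneTargets data.frame with columns \code{gene}, \code{peptide}.
#' @slot peptideToProtein data.frame with columns \code{peptide}, \code{protein}.
#' @seealso [featureMap()], [selectLandmarkFeatures()]
#' @export
setClass("FeatureMap",
  representation(landmarkGenes = "character", geneToProtein = "data.frame",
                 geneTargets = "data.frame", peptideToProtein = "data.frame"))

setValidity("FeatureMap", function(object) {
  msg <- character()
  chk <- function(df, cols, what) {
    if (!all(cols %in% names(df)))
      return(sprintf("'%s' needs columns %s", what, paste(cols, collapse = ", ")))
    if (nrow(df) && any(!nzchar(as.matrix(df[cols]))))
      return(sprintf("'%s' contains empty identifiers", what))
    NULL
  }
  if (any(!nzchar(object@landmarkGenes)))
    msg <- c(msg, "empty landmark gene id")
  msg <- c(msg,
    chk(object@geneToProtein, c("gene", "protein"), "geneToProtein"),
    chk(object@geneTargets, c("gene", "peptide"), "geneTargets"),
    chk(object@peptideToProtein, c("peptide", "protein"), "peptideToProtein"))
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMap
#'
#' @param landmarkGenes character vector of landmark gene ids.
#' @param geneToProtein data.frame with columns \code{gene}, \code{protein}.
#' @param geneTargets data.frame with columns \code{gene}, \code{peptide}.
#' @param peptideToProtein data.frame with columns \code{peptide},
#'   \code{protein}.
#' @return A [FeatureMap-class] object.
#' @export
featureMap <- function(landmarkGenes,
                       geneToProtein = data.frame(gene = character(),
                                                  protein = character()),
                       geneTargets = data.frame(gene = character(),
                                                peptide = character()),
                       peptideToProtein = data.frame(peptide = character(),
                                                     protein = character())) {
  new("FeatureMap", landmarkGenes = as.character(landmarkGenes),
      geneToProtein = geneToProtein, geneTargets = geneTargets,
      peptideToProtein = peptideToProtein)
}

#' SyntheticConfig: parameters of the synthetic multi-omics generator
#'
#' Defines the statistical structure of a simulated drug-response study:
#' per-drug mean ln(IC50) levels, a cell-line sensitivity effect carried
#' linearly by a designated informative-feature subset of every modality,
#' proteomics-style missingness, and sparsity of the response table.
#'
#' @slot nCellLines number of cell lines.
#' @slot nDrugs number of drugs.
#' @slot nFeatures named integer vector: features per modality; the names
#'   declare the modalities.
#' @slot drugMeanSD SD of drug-level mean ln(IC50) values.
#' @slot cellEffectSD SD of the per-cell-line sensitivity effect.
#' @slot nInformative number of informative features per modality.
#' @slot noiseSD SD of the residual measurement noise on ln(IC50).
#' @slot missingRate fraction of proteomics entries flagged missing.
#' @slot responseSparsity fraction of (cell, drug) pairs without a
#'   measured response.
#' @slot seed integer seed; all outputs are deterministic given the config.
#' @seealso [syntheticConfig()], [generateOmicsProfiles()],
#'   [generateIC50Table()]
#' @export
setClass("SyntheticConfig",
  representation(nCellLines = "integer", nDrugs = "integer",
                 nFeatures = "integer", drugMeanSD = "numeric",
                 cellEffectSD = "numeric", nInformative = "integer",
                 noiseSD = "numeric", missingRate = "numeric",
                 responseSparsity = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nCellLines < 1L) msg <- c(msg, "nCellLines must be positive")
  if (object@nDrugs < 1L) msg <- c(msg, "nDrugs must be positive")
  if (is.null(names(object@nFeatures)) || any(!nzchar(names(object@nFeatures))))
    msg <- c(msg, "nFeatures must be a named vector (names = modalities)")
  if (any(object@nFeatures < 1L)) msg <- c(msg, "feature counts must be positive")
  if (object@nInformative < 0L) msg <- c(msg, "nInformative must be >= 0")
  if (length(object@nFeatures) && object@nInformative > min(object@nFeatures))
    msg <- c(msg, "nInformative exceeds a modality's feature count")
  for (f in c("drugMeanSD", "cellEffectSD", "noiseSD"))
    if (slot(object, f) < 0) msg <- c(msg, paste(f, "must be >= 0"))
  for (f in c("missingRate", "responseSparsity")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, paste(f, "must be in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generating parameters of a synthetic response table
#'
#' Returned alongside the simulated response table so that recovery tests
#' can compare estimates against the generating model
#' \eqn{y(c,d) = \mu_d + e_c + \epsilon}.
#'
#' @slot drugMeans named numeric: per-drug mean ln(IC50) \eqn{\mu_d}.
#' @slot effectWeights named list: per modality, the numeric loading vector
#'   (length = feature count) embedding the cell effect; nonzero exactly at
#'   the informative features.
#' @slot cellEffects named numeric: the per-cell-line effect \eqn{e_c}.
#' @slot noiseSD residual noise SD.
#' @export
setClass("GroundTruth",
  representation(drugMeans = "numeric", effectWeights = "list",
                 cellEffects = "numeric", noiseSD = "numeric"))

#' PairedDataset: aligned (cell profile, drug one-hot, response) triples
#'
#' The supervised dataset for drug response prediction. Each row pairs a
#' cell line's omics profile with a one-hot drug encoding and the measured
#' ln(IC50). One omics profile per cell line is reused across all of that
#' cell line's drugs.
#'
#' @slot cellInputs numeric matrix, pairs x omics features.
#' @slot drugInputs numeric one-hot matrix, pairs x drugs.
#' @slot targets numeric vector of ln(IC50) values.
#' @slot pairIndex data.frame with columns \code{cell_line}, \code{drug},
#'   one row per pair, in dataset row order.
#' @slot drugVocabulary ordered character vector; the one-hot column space.
#' @seealso [buildPairs()]
#' @export
setClass("PairedDataset",
  representation(cellInputs = "matrix", drugInputs = "matrix",
                 targets = "numeric", pairIndex = "data.frame",
                 drugVocabulary = "character"))

setValidity("PairedDataset", function(object) {
  n <- length(object@targets)
  msg <- character()
  if (nrow(object@cellInputs) != n || nrow(object@drugInputs) != n ||
      nrow(object@pairIndex) != n)
    msg <- c(msg, "cellInputs, drugInputs, targets and pairIndex must agree in length")
  if (ncol(object@drugInputs) != length(object@drugVocabulary))
    msg <- c(msg, "drugInputs width must equal the drug vocabulary size")
  if (n && any(abs(rowSums(object@drugInputs) - 1) > 1e-12))
    msg <- c(msg, "every drugInputs row must sum to exactly 1")
  if (!all(c("cell_line", "drug") %in% names(object@pairIndex)))
    msg <- c(msg, "pairIndex needs columns cell_line, drug")
  if (length(msg)) msg else TRUE
})

#' CancerBlindSplit: disjoint cell-line partition
#'
#' A train/validation/test partition of cell lines in which no cell line
#' occupies more than one set, so evaluation simulates prediction for an
#' entirely unseen sample.
#'
#' @slot trainCells,valCells,testCells disjoint character vectors.
#' @slot repeatIndex integer repeat number (0-based).
#' @slot seed the seed that produced the shuffle.
#' @seealso [cancerBlindSplit()], [repeatSplits()]
#' @export
setClass("CancerBlindSplit",
  representation(trainCells = "character", valCells = "character",
                 testCells = "character", repeatIndex = "integer",
                 seed = "integer"))

setValidity("CancerBlindSplit", function(object) {
  sets <- list(object@trainCells, object@valCells, object@testCells)
  msg <- character()
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])))
      msg <- c(msg, "partitions must be pairwise disjoint")
  if (length(msg)) unique(msg) else TRUE
})

#' SubsetSchedule: nested training-subset sizes for a learning curve
#'
#' Log-spaced subset sizes n_1 < ... < n_K of the training pairs, with
#' nested membership (each subset is a prefix of one seeded shuffle), so
#' that differences between adjacent curve points reflect added data.
#'
#' @slot sizes strictly increasing integer sizes; the last equals the full
#'   training size.
#' @slot subsets list of integer pair-index vectors, nested.
#' @slot mode \code{"pairs"} (sizes count pairs) or \code{"cells"} (sizes
#'   count whole cell lines).
#' @slot seed shuffle seed.
#' @seealso [makeSubsetSchedule()]
#' @export
setClass("SubsetSchedule",
  representation(sizes = "integer", subsets = "list", mode = "character",
                 seed = "integer"))

setValidity("SubsetSchedule", function(object) {
  msg <- character()
  if (any(diff(object@sizes) <= 0))
    msg <- c(msg, "sizes must be strictly increasing")
  if (length(object@sizes) != length(object@subsets))
    msg <- c(msg, "one subset per size required")
  if (identical(object@mode, "pairs") &&
      !all(lengths(object@subsets) == object@sizes))
    msg <- c(msg, "subset lengths must equal sizes")
  for (k in seq_len(length(object@subsets) - 1L))
    if (!all(object@subsets[[k]] %in% object@subsets[[k + 1L]]))
      msg <- c(msg, "subsets must be nested")
  if (length(msg)) unique(msg) else TRUE
})

#' BenchmarkModel: the drug-average predictor
#'
#' A rule-based benchmark that ignores all omics input: it predicts, for
#' each drug, the mean of that drug's training-set ln(IC50) values, and
#' falls back to the global training mean for drugs never seen in training.
#'
#' @slot perDrugMean named numeric: training mean per drug.
#' @slot globalMean mean of all training targets.
#' @seealso [fitDrugAverage()], [predictDrugAverage()]
#' @export
setClass("BenchmarkModel",
  representation(perDrugMean = "numeric", globalMean = "numeric"))

setValidity("BenchmarkModel", function(object) {
  if (!is.finite(object@globalMean)) "globalMean must be finite" else TRUE
})

#' HyperparameterSpace: ranges for random search
#'
#' Named parameter ranges sampled uniformly (optionally on a log scale) or
#' from discrete choice sets, plus the number of random-search trials.
#'
#' @slot params named list; each element is either
#'   \code{list(choices = ...)} or \code{list(low = , high = , scale =
#'   "linear"|"log", integer = TRUE/FALSE)}.
#' @slot trialCount number of random-search trials (default 15).
#' @seealso [hyperparameterSpace()], [randomSearch()]
#' @export
setClass("HyperparameterSpace",
  representation(params = "list", trialCount = "integer"))

setValidity("HyperparameterSpace", function(object) {
  msg <- character()
  if (object@trialCount < 1L) msg <- c(msg, "trialCount must be >= 1")
  if (!length(object@params) || is.null(names(object@params)))
    msg <- c(msg, "params must be a non-empty named list")
  for (nm in names(object@params)) {
    p <- object@params[[nm]]
    ok <- (!is.null(p$choices) && length(p$choices) > 0) ||
      (!is.null(p$low) && !is.null(p$high) && p$low <= p$high)
    if (!ok) msg <- c(msg, sprintf("empty or invalid range for '%s'", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HyperparameterSpace
#'
#' @param params named list of ranges; see [HyperparameterSpace-class].
#' @param trialCount number of random-search trials.
#' @return A [HyperparameterSpace-class] object.
#' @examples
#' hyperparameterSpace(list(
#'   max_depth = list(choices = 3:10),
#'   learning_rate = list(low = 1e-3, high = 0.3, scale = "log")))
#' @export
hyperparameterSpace <- function(params, trialCount = 15L) {
  new("HyperparameterSpace", params = params,
      trialCount = as.integer(trialCount))
}

#' TrainedModel: a fitted learner with its validation score
#'
#' Wraps a fitted predictor (benchmark, gradient-boosted trees or
#' feed-forward network) together with the hyperparameters used, the
#' validation MSE that selected it, and the early-stopping round/epoch.
#'
#' @slot kind \code{"benchmark"}, \code{"gbt"} or \code{"nn"}.
#' @slot fit opaque fitted state.
#' @slot hyperparameters named list.
#' @slot validationMSE validation mean squared error (finite).
#' @slot stoppedAt best boosting round or epoch retained by early stopping.
#' @slot trials data.frame trial log from random search (may be empty).
#' @seealso [fitGBT()], [fitNN()], [randomSearch()], [predictResponse()]
#' @export
setClass("TrainedModel",
  representation(kind = "character", fit = "ANY", hyperparameters = "list",
                 validationMSE = "numeric", stoppedAt = "integer",
                 trials = "data.frame"))

setValidity("TrainedModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("benchmark", "gbt", "nn"))
    msg <- c(msg, "kind must be benchmark, gbt or nn")
  if (!is.finite(object@validationMSE))
    msg <- c(msg, "validationMSE must be finite")
  if (length(msg)) msg else TRUE
})

#' LearningCurve: mean generalization error versus training-set size
#'
#' Per-size mean test MSE with standard errors over repeated cancer-blind
#' splits, retaining the full repeats x sizes error matrix.
#'
#' @slot sizes integer training-set sizes (n).
#' @slot meanError mean test error per size (column means of
#'   \code{perRepeatError}).
#' @slot stdErr standard error per size: column SD / sqrt(repeats).
#' @slot perRepeatError numeric matrix, repeats x sizes.
#' @slot modality,learner condition labels.
#' @seealso [assembleCurve()], [fitPowerLaw()], [findCrossing()]
#' @export
setClass("LearningCurve",
  representation(sizes = "integer", meanError = "numeric",
                 stdErr = "numeric", perRepeatError = "matrix",
                 modality = "character", learner = "character"))

setValidity("LearningCurve", function(object) {
  msg <- character()
  k <- length(object@sizes)
  if (length(object@meanError) != k || length(object@stdErr) != k ||
      ncol(object@perRepeatError) != k)
    msg <- c(msg, "sizes, meanError, stdErr and perRepeatError must agree")
  else {
    if (max(abs(object@meanError - colMeans(object@perRepeatError))) > 1e-8)
      msg <- c(msg, "meanError must equal column means of perRepeatError")
  }
  if (length(msg)) msg else TRUE
})

#' PowerLawFit: epsilon(n) = alpha * n^beta fitted in log-log space
#'
#' Least-squares line fit to (log n, log mean error) over a window of
#' curve sizes; \code{alpha} is the exponentiated intercept and
#' \code{beta} the slope (negative for an improving learner).
#'
#' @slot alpha positive prefactor.
#' @slot beta exponent (log-log slope).
#' @slot fitWindow integer c(first, last) size indices used.
#' @slot residualSum sum of squared log-space residuals.
#' @seealso [fitPowerLaw()], [extrapolateError()]
#' @export
setClass("PowerLawFit",
  representation(alpha = "numeric", beta = "numeric",
                 fitWindow = "integer", residualSum = "numeric"))

setValidity("PowerLawFit", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be positive")
  if (object@residualSum < 0) msg <- c(msg, "residualSum must be >= 0")
  if (length(msg)) msg else TRUE
})
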
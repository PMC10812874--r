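#' @include AllClasses.R
NULL

#' Accessors for DRPcurves containers
#'
#' Small accessor generics for the S4 containers: cell-line and feature
#' identifiers, raw values and missing mask of an [OmicsMatrix-class]; the
#' partitions of a [CancerBlindSplit-class]; sizes, errors and labels of a
#' [LearningCurve-class].
#'
#' @param x an object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellLineIds", function(x) standardGeneric("cellLineIds"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("trainCells", function(x) standardGeneric("trainCells"))
#' @rdname accessors
#' @export
setGeneric("valCells", function(x) standardGeneric("valCells"))
#' @rdname accessors
#' @export
setGeneric("testCells", function(x) standardGeneric("testCells"))
#' @rdname accessors
#' @export
setGeneric("curveSizes", function(x) standardGeneric("curveSizes"))
#' @rdname accessors
#' @export
setGeneric("meanError", function(x) standardGeneric("meanError"))
#' @rdname accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))
#' @rdname accessors
#' @export
setGeneric("perRepeatError", function(x) standardGeneric("perRepeatError"))
#' @rdname accessors
#' @export
setGeneric("validationMSE", function(x) standardGeneric("validationMSE"))
#' @rdname accessors
#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))
#' @rdname accessors
#' @export
setGeneric("drugVocabulary", function(x) standardGeneric("drugVocabulary"))

#' Predict responses from a trained model
#'
#' @param object a fitted model ([TrainedModel-class] or
#'   [BenchmarkModel-class]).
#' @param newdata a [PairedDataset-class].
#' @param ... further arguments for methods.
#' @return numeric vector of predicted ln(IC50) values, one per pair.
#' @export
setGeneric("predictResponse",
           function(object, newdata, ...) standardGeneric("predictResponse"))

setMethod("cellLineIds", "OmicsMatrix", function(x) rownames(x@values))
setMethod("featureIds", "OmicsMatrix", function(x) colnames(x@values))
setMethod("omicsValues", "OmicsMatrix", function(x) x@values)
setMethod("missingMask", "OmicsMatrix", function(x) x@missingMask)
setMethod("modality", "OmicsMatrix", function(x) x@modality)

setMethod("trainCells", "CancerBlindSplit", function(x) x@trainCells)
setMethod("valCells", "CancerBlindSplit", function(x) x@valCells)
setMethod("testCells", "CancerBlindSplit", function(x) x@testCells)

setMethod("curveSizes", "LearningCurve", function(x) x@sizes)
setMethod("meanError", "LearningCurve", function(x) x@meanError)
setMethod("stdError", "LearningCurve", function(x) x@stdErr)
setMethod("perRepeatError", "LearningCurve", function(x) x@perRepeatError)

setMethod("validationMSE", "TrainedModel", function(x) x@validationMSE)
setMethod("pairIndex", "PairedDataset", function(x) x@pairIndex)
setMethod("drugVocabulary", "PairedDataset", function(x) x@drugVocabulary)
setMethod("cellLineIds", "PairedDataset",
          function(x) unique(x@pairIndex$cell_line))

setMethod("show", "OmicsMatrix", function(object) {
  v <- object@values
  nmiss <- if (is.null(object@missingMask)) 0L else sum(object@missingMask)
  cat(sprintf("OmicsMatrix [%s]: %d cell lines x %d features (%d missing)\n",
              object@modality, nrow(v), ncol(v), nmiss))
})

setMethod("show", "PairedDataset", function(object) {
  cat(sprintf(
    "PairedDataset: %d pairs | %d cell lines x %d omics features | %d drugs\n",
    length(object@targets), length(unique(object@pairIndex$cell_line)),
    ncol(object@cellInputs), length(object@drugVocabulary)))
})

setMethod("show", "CancerBlindSplit", function(object) {
  cat(sprintf(
    "CancerBlindSplit (repeat %d, seed %d): %d train / %d val / %d test cell lines\n",
    object@repeatIndex, object@seed, length(object@trainCells),
    length(object@valCells), length(object@testCells)))
})

setMethod("show", "LearningCurve", function(object) {
  cat(sprintf("LearningCurve [%s / %s]: %d sizes x %d repeats\n",
              object@modality, object@learner, length(object@sizes),
              nrow(object@perRepeatError)))
  print(data.frame(size = object@sizes, mean = object@meanError,
                   stderr = object@stdErr))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: eps(n) = %.4g * n^%.4g  (window %d..%d, residual %.3g)\n",
    object@alpha, object@beta, object@fitWindow[1], object@fitWindow[2],
    object@residualSum))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel [%s]: validation MSE %.4g, stopped at %d\n",
              object@kind, object@validationMSE, object@stoppedAt))
})

setMethod("show", "BenchmarkModel", function(object) {
  cat(sprintf("BenchmarkModel: %d drug means, global mean %.4g\n",
              length(object@perDrugMean), object@globalMean))
})
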